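test_that("layout validation enforces the membrane design", {
  expect_error(membrane_layout("A", n_replicates = 3), "between 4 and 6")
  expect_error(membrane_layout("A", standard_cn = c(200, 400)),
               "exactly 6")
  expect_error(membrane_layout("A", n_lambda = 0), "lambda")
  lay <- membrane_layout(c("A", "B"), n_replicates = 5)
  expect_equal(sum(lay$role == "sample" & lay$sample_id == "A"), 5)
  expect_equal(length(unique(lay$sample_id[lay$role == "standard"])), 6)
  expect_true(sum(lay$role == "lambda") >= 1)
})

test_that("rendering requires a signal for every sample", {
  lay <- membrane_layout(c("A", "B"), n_replicates = 4)
  expect_error(render_membrane(lay, c(A = 100), noise_preset("none")),
               "signal missing")
})

test_that("noise-free rendering round-trips the ledger truth", {
  lay <- membrane_layout(c("A", "B"), n_replicates = 4)
  img <- render_membrane(lay, c(A = 4000, B = 1500), noise_preset("none"),
                         rng_seed = 3, standard_signal_per_copy_ng = 10)
  meas <- quantify_integrals(img)
  truth <- img$ledger$truth[match(meas$dot_id, img$ledger$dot_id)]
  nz <- truth > 0
  expect_true(all(abs(meas$integral[nz] - truth[nz]) / truth[nz] < 0.001))
  # lambda dots carry no signal in the zero-nonspecific preset
  expect_true(all(truth[meas$role == "lambda"] == 0))
})

test_that("rendering is bit-reproducible for a fixed seed", {
  lay <- membrane_layout("A", n_replicates = 4)
  a <- render_membrane(lay, c(A = 3000), noise_preset(), rng_seed = 11)
  b <- render_membrane(lay, c(A = 3000), noise_preset(), rng_seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$ledger, b$ledger)
})

test_that("total dot intensity grows linearly with DNA amount", {
  amounts <- c(10, 20, 40, 60, 80)
  integrals <- vapply(amounts, function(ng) {
    lay <- membrane_layout("A", n_replicates = 4, sample_ng = ng)
    img <- render_membrane(lay, c(A = 2000), noise_preset("none"),
                           rng_seed = 1)
    m <- quantify_integrals(img)
    mean(m$integral[m$role == "sample"])
  }, numeric(1))
  fit <- summary(stats::lm(integrals ~ amounts))
  expect_gt(fit$r.squared, 0.999)
})

test_that("saturation is modelled and flagged in the ledger", {
  lay <- membrane_layout("A", n_replicates = 4)
  np <- noise_preset(ceiling = 2000)   # low ceiling forces clipping
  img <- render_membrane(lay, c(A = 50000), np, rng_seed = 2,
                         standard_signal_per_copy_ng = 0.01)
  expect_true(all(img$ledger$saturated[img$layout$role == "sample"]))
  expect_true(max(img$pixels) <= 2000)
})

test_that("southern band patterns follow the digest spectra", {
  g0 <- genome_rdna(400)
  spH <- digest_genome(default_unit, g0, c("HpaII", "Csp6I"))
  spM <- digest_genome(default_unit, g0, c("MspI", "Csp6I"))
  expect_equal(render_southern_pattern(spH, "p(ETS-18S)"),
               render_southern_pattern(spM, "p(ETS-18S)"))

  # a 3M genome shows extra long bands absent from the MspI arm
  g3 <- genome_rdna(400, f_hyper = 0.3)
  bH <- render_southern_pattern(
    digest_genome(default_unit, g3, c("HpaII", "Csp6I")), "p(ETS-18S)")
  bM <- render_southern_pattern(
    digest_genome(default_unit, g3, c("MspI", "Csp6I")), "p(ETS-18S)")
  extra <- setdiff(bH$length, bM$length)
  expect_true(length(extra) > 0)
  expect_true(min(extra) > max(bM$length))
  # bands sorted by length descending, intensities non-negative
  expect_true(all(diff(bH$length) < 0))
  expect_true(all(bH$intensity >= 0))

  # single-fragment digest: one band carrying the whole probe mass
  u0 <- rdna_unit(data.frame(enzyme = character(0), position = numeric(0),
                             cpg_linked = logical(0)))
  sp0 <- digest_genome(u0, g0, "Csp6I")
  b0 <- render_southern_pattern(sp0, "p(28S)")
  expect_equal(nrow(b0), 1)
  expect_equal(b0$intensity, 400 * 2413)
  expect_error(render_southern_pattern(sp0, "nope"), "unknown probe")
})

test_that("band intensity conserves probe-weighted copy mass across digests", {
  g <- genome_rdna(200, f_hyper = 0.25)
  for (enz in list("Csp6I", c("HpaII", "Csp6I"), c("MspI", "Csp6I"))) {
    sp <- digest_genome(default_unit, g, enz, rng_seed = 4)
    b <- render_southern_pattern(sp, "p(ETS-18S)")
    expect_equal(sum(b$intensity), 200 * 5836, tolerance = 1e-12)
  }
})

test_that("membrane text serialization round-trips", {
  lay <- membrane_layout("A", n_replicates = 4)
  img <- render_membrane(lay, c(A = 2000), noise_preset(), rng_seed = 5)
  path <- tempfile(fileext = ".txt")
  write_membrane(img, path)
  px <- as.matrix(utils::read.table(path))
  dimnames(px) <- NULL
  expect_equal(px, img$pixels)
  led <- utils::read.table(paste0(path, ".ledger.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(led), nrow(img$ledger))
  unlink(c(path, paste0(path, c(".ledger.tsv", ".layout.tsv"))))
})
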