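test_that("describe_cn agrees with brute-force statistics", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(50, 400, 90)
    d <- describe_cn(x)
    expect_equal(d$mean, sum(x) / length(x))
    expect_equal(d$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
    expect_equal(d$cv, d$sd / d$mean)
    expect_true(d$min <= d$median && d$median <= d$max)
  }
  expect_error(describe_cn(5), "at least 2")
  dconst <- describe_cn(rep(400, 10))
  expect_true(dconst$degenerate)
  expect_equal(dconst$cv, 0)
})

test_that("published Table-1 moments give the published CVs", {
  # samples constructed to carry the printed mean/SD exactly
  ne <- 419 + 110 * c(-1, 0, 1)
  e <- 396 + 63 * c(-1, 0, 1)
  expect_equal(round(describe_cn(ne)$cv, 2), 0.26)
  expect_equal(round(describe_cn(e)$cv, 2), 0.16)
})

test_that("Mann-Whitney matches exact enumeration on a tiny fixture", {
  # oracle: enumerate all 20 label arrangements of {1..6} into two triples
  vals <- 1:6
  combs <- combn(6, 3)
  u_stat <- function(x, y) sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  u_obs <- u_stat(1:3, 4:6)
  u_null <- apply(combs, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  p_exact <- mean(abs(u_null - 4.5) >= abs(u_obs - 4.5))  # two-sided, U symmetric about 4.5
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, p_exact)   # = 0.1
  expect_equal(mw$p, 0.1)
  expect_true(mw$exact)
})

test_that("identical samples are not distinguished", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney(x, x)$p, 1)
  expect_equal(ks_contrast(x, x)$D, 0)
  expect_error(mann_whitney(numeric(0), x), "non-empty")
})

test_that("disjoint supports give KS statistic 1", {
  expect_equal(ks_contrast(1:10, 21:30)$D, 1)
})

test_that("rank tests hold their nominal type-I error on null samples", {
  n_sim <- 400
  rej_mw <- 0; rej_ks <- 0
  set.seed(99)
  for (i in 1:n_sim) {
    x <- rnorm(20); y <- rnorm(20)
    if (mann_whitney(x, y)$p < 0.05) rej_mw <- rej_mw + 1
    if (ks_contrast(x, y)$p < 0.05) rej_ks <- rej_ks + 1
  }
  se2 <- 2 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rej_mw / n_sim - 0.05), se2 + 0.005)
  # KS is conservative at moderate n; only guard against anti-conservatism
  expect_lt(rej_ks / n_sim, 0.05 + se2)
})

test_that("the dispersion permutation test is calibrated and powerful", {
  expect_error(dispersion_permutation_test(1:10, 1:10, n_perm = 99),
               "at least 999")
  # calibration: null p-values roughly uniform (rejection at 0.1 nominal)
  set.seed(7)
  ps <- vapply(1:120, function(i) {
    x <- rnorm(30, 400, 80); y <- rnorm(30, 400, 80)
    dispersion_permutation_test(x, y, "cv_diff", n_perm = 999,
                                seed = i)$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.07)
  # power: hard-truncated synthetic elderly vs non-elderly cohort
  ne <- sample_ne_cn(525, seed = 21)
  e <- sample_e_cn(126, sample_ne_cn(5000, seed = 22), seed = 23)
  for (stat in c("cv_diff", "range_diff")) {
    d <- dispersion_permutation_test(ne, e, stat, n_perm = 999, seed = 3)
    expect_lte(d$p, 0.01)
  }
  # reproducible given the seed
  d1 <- dispersion_permutation_test(ne, e, "cv_diff", n_perm = 999, seed = 5)
  d2 <- dispersion_permutation_test(ne, e, "cv_diff", n_perm = 999, seed = 5)
  expect_identical(d1$p, d2$p)
})

test_that("age-binned dispersion profiles follow the published binning", {
  coh <- generate_cohort(seed = 13)
  prof <- bin_dispersion_profile(coh)
  expect_true(all(c("cohort", "age_mid", "n", "cn_range", "cn_cv",
                    "small_bin") %in% names(prof)))
  # 5-year NE bins over 17-71 -> 11 bins; 2-year E bins over 72-91 -> 10
  expect_equal(sum(prof$cohort == "NE"), 11)
  expect_equal(sum(prof$cohort == "E"), 10)
  # truncation: every E bin CV below the NE median CV
  expect_true(all(prof$cn_cv[prof$cohort == "E" & !prof$small_bin] <
                    median(prof$cn_cv[prof$cohort == "NE"])))
  # single-bin cohort
  tiny <- data.frame(cohort = "NE", age = c(20, 21, 22),
                     cn_true = c(300, 400, 500))
  expect_equal(nrow(bin_dispersion_profile(tiny)), 1)
})

test_that("copy-number-on-age regression behaves on fixtures", {
  coh <- generate_cohort(seed = 14)
  r <- regression_cn_age(coh)
  expect_lt(abs(r$slope), 1)      # no age trend in the generator
  expect_gt(r$p, 0.01)
  lin <- data.frame(age = 1:10, cn_true = 5 + 3 * (1:10))
  rl <- regression_cn_age(lin)
  expect_equal(rl$slope, 3, tolerance = 1e-9)
  expect_equal(rl$intercept, 5, tolerance = 1e-9)
  expect_error(regression_cn_age(lin[1:2, ]), "at least 3")
})

test_that("survivor-truncation bounds are recovered on synthetic cohorts", {
  biases <- vapply(1:60, function(s) {
    pool <- sample_ne_cn(5000, seed = 3000 + s)
    e <- sample_e_cn(126, pool, seed = 4000 + s)
    fit <- fit_survivor_model(sample_ne_cn(525, seed = 5000 + s), e)
    max(abs(fit$bounds - c(272, 541)))
  }, numeric(1))
  expect_lt(mean(biases), 10)
})

test_that("survivor fit degenerates gracefully when E equals NE", {
  ne <- sample_ne_cn(525, seed = 31)
  fit <- fit_survivor_model(ne, ne)
  expect_lte(fit$bounds[1], min(ne))
  expect_gte(fit$bounds[2], max(ne))
  expect_equal(fit$predicted$cv, describe_cn(ne)$cv)
  expect_error(fit_survivor_model(ne[1:10], ne), "at least 30")
})

test_that("soft survivor fit reproduces the E moments by moment matching", {
  ne <- sample_ne_cn(2000, seed = 32)
  e <- sample_e_cn(500, sample_ne_cn(5000, seed = 33),
                   list(mode = "soft", bounds = c(272, 541), scale = 15),
                   seed = 34)
  fit <- fit_survivor_model(ne, e, mode = "soft")
  expect_equal(fit$predicted$mean, mean(e), tolerance = 0.02)
  expect_equal(fit$predicted$sd, sd(e), tolerance = 0.10)
  # predicted dispersion below the source dispersion
  expect_lt(fit$predicted$cv, describe_cn(ne)$cv)
})

test_that("methylation survey arithmetic reproduces the printed 90%", {
  groups <- c(rep("1M", 36), rep("2M", 2), rep("3M", 2))
  tab <- meth_group_table(groups)
  expect_equal(tab$pct_1M, 90)
  expect_equal(tab$n_carriers, 4)
})
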