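test_that("dots are located to sub-pixel accuracy on clean membranes", {
  lay <- membrane_layout(c("A", "B"), n_replicates = 4)
  img <- render_membrane(lay, c(A = 4000, B = 2500), noise_preset("none"),
                         rng_seed = 1, standard_signal_per_copy_ng = 10)
  stubs <- locate_dots(img)
  keep <- img$layout$role != "lambda"   # lambda dots are blank here
  d <- sqrt((stubs$x - img$layout$x)^2 + (stubs$y - img$layout$y)^2)
  expect_true(all(d[keep] < 1))
  expect_true(all(stubs$flags[keep] == ""))
  # blank lambda dots are flagged low-signal, not mislocated
  expect_true(all(stubs$flags[!keep] == "low_signal"))
})

test_that("a dot displaced by 0.6 pitch is flagged off-grid", {
  lay <- membrane_layout("A", n_replicates = 4)
  pitch <- attr(lay, "pitch")
  lay_shift <- lay
  lay_shift$x[1] <- lay$x[1] + 0.6 * pitch   # render off its nominal spot
  img <- render_membrane(lay_shift, c(A = 4000), noise_preset("none"),
                         rng_seed = 1)
  img$layout <- lay                           # quantify against the grid
  stubs <- locate_dots(img)
  expect_match(stubs$flags[1], "off_grid|low_signal")
  # dots away from the displaced one stay clean (its immediate neighbour
  # may be contaminated by the stray dot's tail)
  expect_true(all(stubs$flags[3:4] == ""))
})

test_that("a blank membrane is flagged low-signal everywhere", {
  lay <- membrane_layout("A", n_replicates = 4)
  img <- render_membrane(lay, c(A = 0), noise_preset("none"), rng_seed = 1,
                         standard_signal_per_copy_ng = 0)
  stubs <- locate_dots(img)
  expect_true(all(stubs$flags == "low_signal"))
})

test_that("measuring a flat image yields a zero integral", {
  lay <- membrane_layout("A", n_replicates = 4)
  img <- render_membrane(lay, c(A = 0), noise_preset("none"), rng_seed = 1,
                         standard_signal_per_copy_ng = 0)
  img$pixels[] <- 137
  m <- measure_dot(img, list(dot_id = 1, x = lay$x[1], y = lay$y[1],
                             flags = ""))
  expect_equal(m$integral, 0)
  expect_equal(m$background, 137)
})

test_that("saturated dots are flagged and excluded from averaging", {
  lay <- membrane_layout("A", n_replicates = 4)
  np <- noise_preset(dot_cv = 0, pixel_sd = 0, gradient = 0,
                     ceiling = 3000, nonspecific_per_ng = 0)
  img <- render_membrane(lay, c(A = 50000), np, rng_seed = 2,
                         standard_signal_per_copy_ng = 0.001)
  meas <- quantify_integrals(img)
  samp <- meas[meas$role == "sample", ]
  expect_true(all(grepl("saturated", samp$flags)))
  est <- estimate_cn(samp, structure(list(slope = 1, intercept = 0,
                                          floor = 0, subtract_floor = TRUE),
                                     class = "calibration_curve"), ng = 50)
  expect_true(is.na(est$cn_mean))
  expect_equal(est$flags, "all_replicates_flagged")
})

test_that("calibration recovers an exact linear relation", {
  std <- data.frame(cn = seq(200, 700, 100), ng = 50)
  std$integral <- 7.5 * std$cn * std$ng
  cur <- fit_calibration(std, lambda_integrals = numeric(0))
  expect_equal(cur$slope, 7.5, tolerance = 1e-9)
  expect_equal(cur$r_squared, 1)
  # a constant nonspecific offset on every dot is removed via the floor
  std$integral <- std$integral + 123
  cur2 <- fit_calibration(std, lambda_integrals = rep(123, 2))
  expect_equal(cur2$slope, 7.5, tolerance = 1e-9)
  expect_equal(cur2$floor, 123)
})

test_that("calibration rejects degenerate or insufficient standards", {
  std <- data.frame(cn = c(400, 400, 400), ng = 50, integral = c(1, 2, 3))
  expect_error(fit_calibration(std, numeric(0)), "degenerate")
  expect_error(fit_calibration(std[1:2, ], numeric(0)), "fewer than 3")
  neg <- data.frame(cn = seq(200, 700, 100), ng = 50, integral = 0)
  expect_error(fit_calibration(neg, numeric(0)), "non-positive slope")
})

test_that("noisy calibration slopes are unbiased", {
  # Monte-Carlo oracle: 5% multiplicative noise on exact standards
  slopes <- vapply(1:100, function(s) {
    std <- data.frame(cn = seq(200, 700, 100), ng = 50)
    set.seed(s)
    std$integral <- 7.5 * std$cn * std$ng * (1 + rnorm(6, 0, 0.05))
    fit_calibration(std, numeric(0))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 7.5 - 1), 0.01)
})

test_that("noise-free end-to-end estimates recover truth within 0.5%", {
  q <- pipeline_membrane(c(400, 250, 620), noise_preset("none"))
  expect_true(all(abs(q$estimates$cn_mean - c(400, 250, 620)) /
                    c(400, 250, 620) < 0.005))
})

test_that("estimated CN is monotone in true CN on noise-free membranes", {
  cns <- c(210, 300, 390, 480, 570, 660)
  q <- pipeline_membrane(cns, noise_preset("none"))
  est <- q$estimates$cn_mean[match(sprintf("S%03d", seq_along(cns)),
                                   q$estimates$sample_id)]
  expect_true(all(diff(est) > 0))
})

test_that("a constant nonspecific signal cancels through the lambda floor", {
  base <- noise_preset(dot_cv = 0, pixel_sd = 0, gradient = 0,
                       nonspecific_per_ng = 0)
  lift <- noise_preset(dot_cv = 0, pixel_sd = 0, gradient = 0,
                       nonspecific_per_ng = 400)
  q0 <- pipeline_membrane(c(300, 500), base)
  q1 <- pipeline_membrane(c(300, 500), lift)
  expect_equal(q1$estimates$cn_mean, q0$estimates$cn_mean, tolerance = 0.002)
  expect_gt(q1$curve$floor, 0)
})

test_that("single usable replicate gives a low-confidence estimate", {
  meas <- data.frame(integral = c(1000, 1100, 900, 1050),
                     flagged = c(FALSE, TRUE, TRUE, TRUE))
  cur <- structure(list(slope = 2, intercept = 0, floor = 100,
                        subtract_floor = TRUE),
                   class = "calibration_curve")
  est <- estimate_cn(meas, cur, ng = 10)
  expect_equal(est$n_replicates, 1L)
  expect_true(is.na(est$cn_se))
  expect_equal(est$flags, "low_confidence")
  expect_equal(est$cn_mean, (1000 - 100) / (2 * 10))
})

test_that("default-noise pipeline keeps end-to-end bias under 5%", {
  # scaled down from the spec-scale 200-sample check for test runtime
  cns <- sample_ne_cn(40, seed = 8)
  biases <- c()
  for (b in 1:4) {
    idx <- 1:10 + (b - 1) * 10
    q <- pipeline_membrane(cns[idx], noise_preset(), seed = 20 + b)
    est <- q$estimates$cn_mean[match(sprintf("S%03d", 1:10),
                                     q$estimates$sample_id)]
    biases <- c(biases, est / cns[idx] - 1)
  }
  expect_lt(abs(mean(biases)), 0.05)
})
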