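# Synthetic leukocyte cohorts: copy-number distributions for the
# non-elderly (NE, 17-71 y) and elderly (E, 72-91 y) groups, methylation
# group assignment, and full cohort tables.

# Frozen quantile knots of the default NE copy-number distribution.
# A plain parametric family cannot satisfy all published constraints at
# once (support 200-711, mean 419, SD 110, median 410, 10% below 272,
# 15% above 541), so the generator uses a monotone piecewise-linear
# quantile function; the three free knot values were fitted once
# (numerically, to machine precision on mean and SD) and are frozen here.
NE_QUANTILE_KNOTS <- list(
  p = c(0, 0.10, 0.25, 0.50, 0.70, 0.85, 0.95, 1),
  q = c(200, 272, 348.6457811775, 410, 475.5928140748, 541,
        591.8946840198, 711)
)

#' Quantile function of the default NE copy-number distribution
#'
#' @param p probabilities in `[0, 1]`.
#' @param knots quantile knots (list with `p` and `q`); default the frozen
#'   NE preset.
#' @return Copy-number quantiles.
#' @export
ne_cn_quantile <- function(p, knots = NE_QUANTILE_KNOTS) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (any(diff(knots$q) <= 0) || any(diff(knots$p) <= 0))
    stop("generator construction error: knots must be strictly increasing")
  stats::approx(knots$p, knots$q, xout = p, rule = 2)$y
}

# theoretical moments of a piecewise-linear quantile function
ne_cn_moments <- function(knots = NE_QUANTILE_KNOTS) {
  w <- diff(knots$p)
  a <- utils::head(knots$q, -1); b <- utils::tail(knots$q, -1)
  m1 <- sum(w * (a + b) / 2)
  m2 <- sum(w * (a^2 + a * b + b^2) / 3)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Sample NE-group rDNA copy numbers
#'
#' Draws copy numbers by inverse-transform sampling from the monotone
#' quantile preset, which matches the published NE descriptive statistics:
#' support 200–711 copies, mean 419, SD 110, median 410, 10% of subjects
#' below 272 copies and 15% above 541.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param knots quantile knots; default the frozen NE preset.
#' @return Numeric vector of copy numbers.
#' @examples
#' x <- sample_ne_cn(10000, seed = 1)
#' mean(x); mean(x < 272); mean(x > 541)
#' @export
sample_ne_cn <- function(n, seed = 1L, knots = NE_QUANTILE_KNOTS) {
  stopifnot(n >= 1)
  withr_seed(seed, ne_cn_quantile(stats::runif(n), knots))
}

#' Sample E-group copy numbers by survivor selection
#'
#' The elderly group is modelled as survivors drawn from the NE
#' distribution with copy-number-dependent selection: individuals with
#' very low or very high rDNA copy number are under-represented among
#' those surviving past the population mean lifetime. Two modes:
#' `"hard"` truncation resamples the NE pool inside the observed E-group
#' support (272–541 by default); `"soft"` uses smooth logistic survival
#' weights at the same bounds; `"uniform"` applies no selection (null
#' model).
#'
#' @param n number of survivors to draw.
#' @param ne_pool numeric vector of NE copy numbers to select from.
#' @param survivor_params list with `mode` (`"hard"`, `"soft"` or
#'   `"uniform"`), `bounds` (length-2) and, for soft mode, `scale`
#'   (logistic scale in copies, default 15).
#' @param seed integer seed.
#' @return Numeric vector of copy numbers.
#' @export
sample_e_cn <- function(n, ne_pool,
                        survivor_params = list(mode = "hard",
                                               bounds = c(272, 541)),
                        seed = 1L) {
  if (!length(ne_pool)) stop("ne_pool must be non-empty")
  mode <- survivor_params$mode %||% "hard"
  b <- survivor_params$bounds %||% c(272, 541)
  withr_seed(seed, {
    if (mode == "hard") {
      keep <- ne_pool[ne_pool >= b[1] & ne_pool <= b[2]]
      if (!length(keep))
        stop("survivor_params yield an empty acceptance region")
      sample(keep, n, replace = TRUE)
    } else if (mode == "soft") {
      s <- survivor_params$scale %||% 15
      w <- stats::plogis((ne_pool - b[1]) / s) *
        stats::plogis((b[2] - ne_pool) / s)
      if (all(w <= 0))
        stop("survivor_params yield an empty acceptance region")
      sample(ne_pool, n, replace = TRUE, prob = w)
    } else if (mode == "uniform") {
      sample(ne_pool, n, replace = TRUE)
    } else stop("unknown survivor mode: ", mode)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign methylation groups and hypermethylated fractions
#'
#' Samples each subject's methylation group (1M/2M/3M) and a
#' group-consistent hypermethylated fraction. Defaults follow the
#' published 40+40 survey: in the NE group half the subjects are 1M,
#' 20% are 2M and 30% are 3M (so 2M+3M carriers are 20 of 40); in the E
#' group 90% are 1M (4 carriers of 40). Hypermethylated fractions are
#' drawn uniformly within 0–0.02 (1M), 0.05–0.12 (2M) and 0.13–0.30 (3M).
#'
#' @param n number of subjects.
#' @param cohort `"NE"` or `"E"` (sets the default probabilities).
#' @param probs optional probability vector (1M, 2M, 3M), must sum to 1.
#' @param seed integer seed.
#' @param f_ranges list of three length-2 ranges for f_hyper per group.
#' @return Data frame with columns `meth_group` and `f_hyper`.
#' @export
assign_methylation_group <- function(n, cohort = c("NE", "E"),
                                     probs = NULL, seed = 1L,
                                     f_ranges = list(c(0, 0.02),
                                                     c(0.05, 0.12),
                                                     c(0.13, 0.30))) {
  cohort <- match.arg(cohort)
  if (is.null(probs))
    probs <- if (cohort == "NE") c(0.50, 0.20, 0.30) else c(0.90, 0.05, 0.05)
  if (length(probs) != 3 || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("probs must be three non-negative values summing to 1")
  withr_seed(seed, {
    grp <- sample.int(3, n, replace = TRUE, prob = probs)
    f <- vapply(grp, function(g)
      stats::runif(1, f_ranges[[g]][1], f_ranges[[g]][2]), numeric(1))
    data.frame(meth_group = paste0(grp, "M"), f_hyper = f)
  })
}

#' Configuration of a synthetic two-group cohort
#'
#' @param n_ne,n_e group sizes (defaults 525 and 126, the published
#'   cohort).
#' @param age_ne,age_e age ranges in years.
#' @param survivor_params passed to [sample_e_cn()].
#' @param meth_probs_ne,meth_probs_e methylation-group probabilities.
#' @param sex_ratio proportion of male subjects (545/651 by default).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_ne = 525, n_e = 126,
                          age_ne = c(17, 71), age_e = c(72, 91),
                          survivor_params = list(mode = "hard",
                                                 bounds = c(272, 541)),
                          meth_probs_ne = c(0.50, 0.20, 0.30),
                          meth_probs_e = c(0.90, 0.05, 0.05),
                          sex_ratio = 545 / 651) {
  structure(list(n_ne = n_ne, n_e = n_e, age_ne = age_ne, age_e = age_e,
                 survivor_params = survivor_params,
                 meth_probs_ne = meth_probs_ne,
                 meth_probs_e = meth_probs_e,
                 sex_ratio = sex_ratio),
            class = "cohort_config")
}

#' Generate a full synthetic cohort table
#'
#' Produces one subject per row: id, cohort label, age (uniform within
#' the group's age range; copy number shows no published age or sex
#' dependence, so none is modelled), sex, true copy number, true
#' hypermethylated fraction and methylation group. E-group copy numbers
#' are drawn by survivor selection from a fresh NE pool.
#'
#' @param config a `cohort_config`.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return Data frame with columns `id`, `cohort`, `age`, `sex`,
#'   `cn_true`, `f_hyper_true`, `meth_group_true`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  cn_ne <- sample_ne_cn(config$n_ne, seed = seed)
  pool <- sample_ne_cn(max(5000, 10 * config$n_e), seed = seed + 1L)
  cn_e <- sample_e_cn(config$n_e, pool, config$survivor_params,
                      seed = seed + 2L)
  m_ne <- assign_methylation_group(config$n_ne, "NE",
                                   probs = config$meth_probs_ne,
                                   seed = seed + 3L)
  m_e <- assign_methylation_group(config$n_e, "E",
                                  probs = config$meth_probs_e,
                                  seed = seed + 4L)
  ages_sex <- withr_seed(seed + 5L, {
    list(age_ne = sample(config$age_ne[1]:config$age_ne[2], config$n_ne,
                         replace = TRUE),
         age_e = sample(config$age_e[1]:config$age_e[2], config$n_e,
                        replace = TRUE),
         sex = sample(c("M", "F"), config$n_ne + config$n_e,
                      replace = TRUE,
                      prob = c(config$sex_ratio, 1 - config$sex_ratio)))
  })
  n <- config$n_ne + config$n_e
  data.frame(
    id = sprintf("S%04d", seq_len(n)),
    cohort = rep(c("NE", "E"), c(config$n_ne, config$n_e)),
    age = c(ages_sex$age_ne, ages_sex$age_e),
    sex = ages_sex$sex,
    cn_true = c(cn_ne, cn_e),
    f_hyper_true = c(m_ne$f_hyper, m_e$f_hyper),
    meth_group_true = c(m_ne$meth_group, m_e$meth_group)
  )
}

#' Write a cohort table as TSV
#'
#' @param cohort data frame from [generate_cohort()].
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
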