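# Replicative senescence of cultured fibroblast lines under the
# hypermethylated-copy-loss mechanism: across passages, only fraction-3
# (hypermethylated) rDNA copies are lost; active and low-methylated copies
# are untouched, so lines starting with M ~ 1 keep a constant copy number
# while high-M lines lose copies until M falls into the 1M band.

#' Published parameters of the five fibroblast lines
#'
#' Starting parameters of the five dermal fibroblast lines (HSF-45,
#' HSF-53, HSF-57, HSF-61, HSF-66; the digits give the final passage
#' number after which division stopped): donor age, leukocyte and
#' passage-5 fibroblast rDNA copy number with standard errors, and the
#' corresponding methylation indices. Two donors (HSF-57 and HSF-66)
#' carried hypermethylated copies (group 3M).
#'
#' @return Data frame with one row per line.
#' @export
hsf_lines <- function() {
  data.frame(
    line = c("HSF-45", "HSF-53", "HSF-57", "HSF-61", "HSF-66"),
    donor_age = c(35, 21, 52, 52, 35),
    final_passage = c(45L, 53L, 57L, 61L, 66L),
    cn_leuk = c(430, 390, 570, 480, 640),
    cn_leuk_se = c(50, 40, 30, 40, 40),
    cn_fib5 = c(450, 370, 590, 470, 670),
    cn_fib5_se = c(40, 20, 40, 60, 70),
    m_leuk = c(1.1, 1.0, 2.1, 1.2, 2.2),
    m_leuk_se = c(0.2, 0.1, 0.2, 0.1, 0.2),
    m_fib5 = c(1.0, 1.2, 1.7, 1.1, 1.9),
    m_fib5_se = c(0.1, 0.2, 0.2, 0.2, 0.2)
  )
}

#' Initialize a fibroblast line at passage 5
#'
#' At passage 5, cultured fibroblasts retain the donor's leukocyte copy
#' number and methylation index, so the starting state takes the
#' leukocyte CN and inverts the leukocyte M into a hypermethylated-copy
#' count via the retention model's gain.
#'
#' @param name line name; if it ends in digits (e.g. `"HSF-57"`) they set
#'   the default final passage.
#' @param donor_age donor age in years.
#' @param cn_leukocyte leukocyte rDNA copy number.
#' @param M_leukocyte leukocyte methylation index (>= 1 up to noise).
#' @param retention a `retention_model`.
#' @param final_passage final passage number; default parsed from `name`.
#' @return Object of class `cell_line_state`: `line`, `donor_age`,
#'   `passage` (5), `final_passage`, `cn_total`, `n_hyper`, `n_base`,
#'   `f_hyper`, `M`.
#' @examples
#' ret <- retention_model()
#' init_line("HSF-53", 21, 390, 1.0, ret)$f_hyper  # ~0
#' @export
init_line <- function(name, donor_age, cn_leukocyte, M_leukocyte,
                      retention, final_passage = NULL) {
  if (M_leukocyte < 1) M_leukocyte <- 1     # measurement noise below 1
  if (is.null(final_passage)) {
    digits <- regmatches(name, regexpr("[0-9]+$", name))
    if (!length(digits)) stop("final_passage not given and not parsable from name")
    final_passage <- as.integer(digits)
  }
  if (final_passage <= 5) stop("final passage must exceed 5")
  f <- estimate_hyper_fraction(M_leukocyte, retention)$f_hat
  n_hyper <- round(cn_leukocyte * f)
  structure(list(line = name, donor_age = donor_age, passage = 5L,
                 final_passage = as.integer(final_passage),
                 cn_total = cn_leukocyte, n_hyper = n_hyper,
                 n_base = cn_leukocyte - n_hyper,
                 f_hyper = n_hyper / cn_leukocyte,
                 M = 1 + (n_hyper / cn_leukocyte) * (retention$gain - 1)),
            class = "cell_line_state")
}

#' @export
print.cell_line_state <- function(x, ...) {
  cat(sprintf("%s (donor %d y): passage %d/%d, CN %g (%d hypermethylated), M = %.2f\n",
              x$line, x$donor_age, x$passage, x$final_passage,
              x$cn_total, x$n_hyper, x$M))
  invisible(x)
}

#' Simulate passages with hypermethylated-copy loss
#'
#' From passage 5 to the line's final passage, each hypermethylated copy
#' is lost independently with per-passage probability `lambda`
#' (geometric decay of the hypermethylated pool); active and
#' low-methylated copies are never touched. The default `lambda = 0.1`
#' makes loss essentially complete by the final passage for every line
#' (expected residual fraction < 0.01 even for the shortest-lived line at
#' the maximal starting content of 30%). M is recomputed at every passage
#' from the closed form.
#'
#' @param state a `cell_line_state` from [init_line()].
#' @param lambda per-copy, per-passage loss probability in `[0, 1]`.
#' @param seed integer seed.
#' @param retention a `retention_model` (supplies the gain for M).
#' @return Object of class `passage_trajectory`: data frame with one row
#'   per passage (`passage`, `cn_total`, `n_hyper`, `f_hyper`, `M`), the
#'   line and lambda as attributes.
#' @export
simulate_passages <- function(state, lambda = 0.1, seed = 1L,
                              retention = NULL) {
  stopifnot(inherits(state, "cell_line_state"))
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  g <- if (is.null(retention)) (state$M - 1) / max(state$f_hyper, 1e-12) + 1
       else retention$gain
  if (!is.finite(g) || g <= 1) g <- 22 / 3
  passages <- state$passage:state$final_passage
  n_hyper <- integer(length(passages))
  n_hyper[1] <- state$n_hyper
  withr_seed(seed, {
    for (k in seq_along(passages)[-1]) {
      n_hyper[k] <- n_hyper[k - 1] -
        stats::rbinom(1L, n_hyper[k - 1], lambda)
    }
  })
  cn <- state$n_base + n_hyper
  traj <- data.frame(passage = passages, cn_total = cn, n_hyper = n_hyper,
                     f_hyper = n_hyper / cn,
                     M = 1 + (n_hyper / cn) * (g - 1))
  structure(traj, class = c("passage_trajectory", "data.frame"),
            line = state$line, lambda = lambda, gain = g,
            final_passage = state$final_passage)
}

#' Compare passage 5 with the final passage
#'
#' Reports the change in copy number and methylation index between the
#' first and last recorded passages. A quantity is called changed when
#' the difference exceeds twice its propagated measurement error,
#' `|delta| > 2 sqrt(se^2 + se^2)`. Default SEs are typical of the
#' published line measurements (40 copies, 0.2 M units).
#'
#' @param trajectory a `passage_trajectory` (length >= 2).
#' @param cn_se,m_se measurement standard errors for CN and M.
#' @return List: `cn_start`, `cn_final`, `delta_cn`, `m_start`,
#'   `m_final`, `delta_m`, `cn_changed`, `m_changed`, `final_group`
#'   (1M/2M/3M call at the final passage).
#' @export
compare_passages <- function(trajectory, cn_se = 40, m_se = 0.2) {
  stopifnot(inherits(trajectory, "passage_trajectory"))
  if (nrow(trajectory) < 2)
    stop("trajectory must span at least two passages")
  a <- trajectory[1, ]; b <- trajectory[nrow(trajectory), ]
  overlap <- function(m1, m2, se) abs(m1 - m2) <= 2 * sqrt(2 * se^2)
  list(cn_start = a$cn_total, cn_final = b$cn_total,
       delta_cn = b$cn_total - a$cn_total,
       m_start = a$M, m_final = b$M, delta_m = b$M - a$M,
       cn_changed = !overlap(a$cn_total, b$cn_total, cn_se),
       m_changed = !overlap(a$M, b$M, m_se),
       final_group = classify_M(max(b$M, 1e-9)))
}

#' Simulate all five published fibroblast lines
#'
#' Convenience wrapper: initializes every line of [hsf_lines()] from its
#' leukocyte parameters, simulates passages to each line's final passage
#' and returns the paired comparisons.
#'
#' @param retention a `retention_model`.
#' @param lambda per-passage loss probability.
#' @param seed integer seed.
#' @return Data frame with one row per line: start/final CN and M, the
#'   change calls and the final methylation group.
#' @export
simulate_hsf_panel <- function(retention = retention_model(),
                               lambda = 0.1, seed = 1L) {
  tab <- hsf_lines()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    st <- init_line(tab$line[i], tab$donor_age[i], tab$cn_leuk[i],
                    tab$m_leuk[i], retention)
    tr <- simulate_passages(st, lambda, seed = seed + i, retention = retention)
    cmp <- compare_passages(tr, cn_se = tab$cn_fib5_se[i],
                            m_se = tab$m_fib5_se[i])
    data.frame(line = tab$line[i], cn_start = cmp$cn_start,
               cn_final = cmp$cn_final, delta_cn = cmp$delta_cn,
               m_start = cmp$m_start, m_final = cmp$m_final,
               cn_changed = cmp$cn_changed, m_changed = cmp$m_changed,
               final_group = cmp$final_group)
  })
  do.call(rbind, out)
}
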