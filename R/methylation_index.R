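# Methylation index M from paired methylation-sensitive digests.
#
# M is the ratio of hybridization signals of the (HpaII + Csp6I) and
# (MspI + Csp6I) hydrolysates of the same DNA. MspI cuts CCGG regardless
# of internal-cytosine methylation, so the MspI arm always reduces rDNA to
# small fragments; HpaII is blocked on hypermethylated copies, which
# therefore survive as large Csp6I-only fragments. Small fragments are
# retained on the membrane less efficiently than large ones (wash-off /
# binding efficiency — an explicit model assumption, not a published
# mechanism), so hypermethylated copies hybridize more strongly in the
# HpaII arm and M rises above 1. Under the three-fraction model with no
# low-methylated copies the closed form is
#     M = 1 + f_hyper * (g - 1),
# where g is the effective retention gain of the uncut (Csp6I-only)
# spectrum over the fully cut spectrum for the probe in use.

#' Fragment-retention model for membrane hybridization
#'
#' Retention of a fragment on the membrane is modelled as a logistic
#' function of log fragment length with half-retention length `l50` and a
#' fixed steepness. The half-retention length is calibrated numerically so
#' that the effective gain g — the probe-weighted signal ratio of the
#' Csp6I-only digest to the full (MspI + Csp6I) digest of an unmethylated
#' unit — equals `gain`. The default gain 22/3 (~7.33) pins the closed
#' form `M = 1 + f(g - 1)` to the published anchors: ~10% hypermethylated
#' copies give M ~ 1.63 (inside the 1.3–1.7 band of group 2M) and 30%
#' give M = 2.9, the top of the 3M band.
#'
#' @param unit an `rdna_unit` used for calibration.
#' @param gain target effective gain g (> 1); default 22/3.
#' @param steepness logistic steepness on the log-length scale (default 4).
#' @param probe probe window used for calibration (default `"p(ETS-18S)"`,
#'   the probe used for quantitative M determination).
#' @return Object of class `retention_model` with elements `l50`,
#'   `steepness`, `gain`, `probe` and `weight(length)`.
#' @export
retention_model <- function(unit = rdna_unit(), gain = 22 / 3,
                            steepness = 4, probe = "p(ETS-18S)") {
  if (gain <= 1) stop("gain must exceed 1")
  frag_cut <- digest(unit, methylation_profile(1), c("MspI", "Csp6I"))
  frag_csp <- digest(unit, methylation_profile(1), "Csp6I")
  w <- unit$probe_windows[[probe]]
  if (is.null(w)) stop("unknown probe window: ", probe)
  probe_mass <- function(fr, l50) {
    ov <- fragment_window_overlap(fr$start, fr$end, w[1], w[2],
                                  unit$unit_length)
    sum(ov * stats::plogis(steepness * (log(fr$length) - log(l50))))
  }
  gfun <- function(l50) probe_mass(frag_csp, l50) / probe_mass(frag_cut, l50)
  lo <- 10; hi <- unit$unit_length
  if (gfun(hi) < gain)
    stop("requested gain unattainable for this unit/steepness")
  l50 <- stats::uniroot(function(x) gfun(x) - gain, c(lo, hi),
                        tol = 1e-8)$root
  structure(list(l50 = l50, steepness = steepness, gain = gain,
                 probe = probe,
                 weight = function(len)
                   stats::plogis(steepness * (log(len) - log(l50)))),
            class = "retention_model")
}

#' @export
print.retention_model <- function(x, ...) {
  cat(sprintf("retention model: logistic in log-length, L50 = %.0f bp, steepness %.1f, gain g = %.3f (probe %s)\n",
              x$l50, x$steepness, x$gain, x$probe))
  invisible(x)
}

#' Hybridization signal of a digest spectrum under one probe
#'
#' The dot-hybridization signal of a digested array is the sum over all
#' probe-overlapping fragments of copy weight x probe-overlap length x
#' retention weight of the fragment length.
#'
#' @param spectra an `rdna_spectra` from [digest_genome()].
#' @param probe probe-window name.
#' @param retention a `retention_model`, or `NULL` for unit retention
#'   (every fragment fully retained).
#' @return Scalar signal value (arbitrary units, deterministic given the
#'   spectra).
#' @export
dot_signal <- function(spectra, probe, retention = NULL) {
  unit <- attr(spectra, "unit")
  w <- unit$probe_windows[[probe]]
  if (is.null(w)) stop("unknown probe window: ", probe)
  ov <- fragment_window_overlap(spectra$start, spectra$end, w[1], w[2],
                                unit$unit_length)
  rw <- if (is.null(retention)) 1 else retention$weight(spectra$length)
  sum(spectra$weight * ov * rw)
}

#' Methylation index M of a genome
#'
#' Computes M as the ratio of hybridization signals of the
#' (HpaII + Csp6I) and (MspI + Csp6I) digests of the genome's rDNA array,
#' probed with p(ETS-18S) by default.
#'
#' Two modes are available. `"closed_form"` evaluates the signal ratio
#' directly from the digest spectra (deterministic up to fraction-2
#' methylation sampling) and is the fast path. `"membrane"` runs the full
#' forward model: each hydrolysate is spotted on a synthetic membrane,
#' rendered with the calibrated noise preset, quantified densitometrically,
#' and M is reported as the mean over `n_experiments` independent simulated
#' experiments (three, matching experimental practice).
#'
#' @param genome a `genome_rdna`.
#' @param unit an `rdna_unit`.
#' @param retention a `retention_model` for the same unit.
#' @param rng_seed integer seed.
#' @param mode `"closed_form"` or `"membrane"`.
#' @param probe probe-window name (default `"p(ETS-18S)"`).
#' @param n_experiments simulated experiments averaged in membrane mode.
#' @param n_dots replicate dots per hydrolysate per experiment.
#' @param noise `noise_preset` for membrane mode.
#' @return For `"closed_form"`, the scalar M. For `"membrane"`, a list
#'   with `M` (mean), `M_se` (standard error over experiments) and
#'   `replicates` (the per-experiment values).
#' @examples
#' unit <- rdna_unit(); ret <- retention_model(unit)
#' compute_M(genome_rdna(400, f_hyper = 0.10), unit, ret)  # ~1.63
#' @export
compute_M <- function(genome, unit, retention, rng_seed = 1L,
                      mode = c("closed_form", "membrane"),
                      probe = "p(ETS-18S)",
                      n_experiments = 3L, n_dots = 4L,
                      noise = noise_preset()) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "genome_rdna"),
            inherits(retention, "retention_model"))
  sp_h <- digest_genome(unit, genome, c("HpaII", "Csp6I"), rng_seed)
  sp_m <- digest_genome(unit, genome, c("MspI", "Csp6I"), rng_seed + 1L)
  s_h <- dot_signal(sp_h, probe, retention)
  s_m <- dot_signal(sp_m, probe, retention)
  if (s_m <= 0) stop("zero denominator signal; degenerate retention/probe")
  if (mode == "closed_form") return(s_h / s_m)

  reps <- vapply(seq_len(n_experiments), function(i) {
    simulate_m_experiment(s_h, s_m, n_dots, noise,
                          rng_seed = rng_seed * 101L + i)
  }, numeric(1))
  list(M = mean(reps),
       M_se = if (n_experiments > 1) stats::sd(reps) / sqrt(n_experiments)
              else NA_real_,
       replicates = reps)
}

# One simulated M experiment: both hydrolysates spotted on one membrane
# with standards and a lambda control, raw integral intensities averaged
# per hydrolysate, M = ratio of means.
simulate_m_experiment <- function(s_h, s_m, n_dots, noise, rng_seed) {
  base <- 4000                       # per-ng signal scale of the MspI arm
  layout <- membrane_layout(c("HpaII", "MspI"), n_replicates = n_dots)
  signals <- c("HpaII" = base * s_h / s_m, "MspI" = base)
  img <- render_membrane(layout, signals, noise, rng_seed,
                         standard_signal_per_copy_ng = base / 400)
  meas <- quantify_integrals(img)
  mh <- meas[meas$sample_id == "HpaII" & !meas$flagged, "integral"]
  mm <- meas[meas$sample_id == "MspI" & !meas$flagged, "integral"]
  if (!length(mh) || !length(mm) || mean(mm) <= 0)
    stop("unusable simulated membrane for M computation")
  mean(mh) / mean(mm)
}

#' Classify a methylation index into groups 1M/2M/3M
#'
#' Observed M values cluster into three groups: 1M (M 1.02–1.2, no
#' hypermethylated copies), 2M (M 1.3–1.7, ~10% hypermethylated) and 3M
#' (M 1.8–2.9, up to 30% hypermethylated). The published ranges leave gaps
#' (1.2–1.3 and 1.7–1.8), so the class thresholds are placed at 1.3 and
#' 1.8; a boundary value is assigned to the higher group.
#'
#' @param M methylation index (vectorized), must be positive.
#' @return Character vector of `"1M"`, `"2M"`, `"3M"`.
#' @export
classify_M <- function(M) {
  if (any(M <= 0)) stop("M must be positive")
  ifelse(M >= 1.8, "3M", ifelse(M >= 1.3, "2M", "1M"))
}

#' Invert M to a hypermethylated-copy fraction
#'
#' Inverts the closed-form relation `M = 1 + f (g - 1)`:
#' `f_hat = (M - 1) / (g - 1)`, clipped to the unit interval. When a
#' standard error of M is supplied, a normal-approximation interval on M
#' is propagated through the (linear) inversion.
#'
#' @param M methylation index (>= 1 up to noise).
#' @param retention a `retention_model` (supplies the gain g).
#' @param M_se optional standard error of M.
#' @param level confidence level for the interval (default 0.95).
#' @return List with `f_hat`, `f_lo`, `f_hi`.
#' @examples
#' ret <- retention_model()
#' estimate_hyper_fraction(1.63, ret)$f_hat  # ~0.10
#' @export
estimate_hyper_fraction <- function(M, retention, M_se = 0, level = 0.95) {
  g <- retention$gain
  if (g <= 1) stop("retention gain must exceed 1")
  clip01 <- function(x) pmin(1, pmax(0, x))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(f_hat = clip01((M - 1) / (g - 1)),
       f_lo  = clip01((M - z * M_se - 1) / (g - 1)),
       f_hi  = clip01((M + z * M_se - 1) / (g - 1)))
}

#' Alternative index: Csp6I-only over (MspI + Csp6I)
#'
#' The control ratio shown alongside M in blot experiments: the
#' hybridization signal of the Csp6I-only hydrolysate divided by the
#' (MspI + Csp6I) signal. Since every copy retains its large Csp6I-only
#' fragments in the numerator, this ratio is an upper envelope of M and
#' coincides with it when all copies are hypermethylated.
#'
#' @inheritParams compute_M
#' @return Scalar ratio (closed form).
#' @export
alt_index <- function(genome, unit, retention, rng_seed = 1L,
                      probe = "p(ETS-18S)") {
  sp_c <- digest_genome(unit, genome, "Csp6I", rng_seed)
  sp_m <- digest_genome(unit, genome, c("MspI", "Csp6I"), rng_seed + 1L)
  s_m <- dot_signal(sp_m, probe, retention)
  if (s_m <= 0) stop("zero denominator signal")
  dot_signal(sp_c, probe, retention) / s_m
}
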