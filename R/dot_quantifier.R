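# Densitometric quantification of dot-blot membranes: dot localization,
# local background estimation, integral intensity, calibration-curve
# fitting and conversion of signals to rDNA copy numbers.

#' Locate dots on a membrane
#'
#' For each expected grid position the centroid is refined by
#' intensity-weighted centroiding of background-subtracted pixels within a
#' search window of one pitch centred on the expected position. Dots whose
#' refined centroid lies farther than 0.35 pitch from the expected
#' position are flagged `off_grid`; windows with no signal above the local
#' noise floor are flagged `low_signal` and keep the expected position.
#'
#' @param image a `membrane_image` (or a plain pixel matrix).
#' @param layout a `membrane_layout`; defaults to the layout carried by
#'   the image.
#' @return Data frame of dot stubs: `dot_id`, `sample_id`, `role`, `x`,
#'   `y` (refined), `flags` (comma-separated).
#' @export
locate_dots <- function(image, layout = NULL) {
  px <- if (inherits(image, "membrane_image")) image$pixels else image
  if (is.null(layout)) {
    if (!inherits(image, "membrane_image"))
      stop("layout must be supplied for a bare pixel matrix")
    layout <- image$layout
  }
  pitch <- attr(layout, "pitch")
  H <- nrow(px); W <- ncol(px)
  need_w <- attr(layout, "pitch") * (attr(layout, "ncol") + 2)
  need_h <- attr(layout, "pitch") * (attr(layout, "nrow") + 2)
  if (W < need_w - pitch || H < need_h - pitch)
    stop("image dimensions do not match the layout grid")
  half <- floor(pitch / 2) - 1L
  out <- layout[c("dot_id", "sample_id", "role", "x", "y")]
  out <- as.data.frame(out)
  out$flags <- ""
  for (i in seq_len(nrow(out))) {
    cx <- round(layout$x[i]); cy <- round(layout$y[i])
    xs <- max(1, cx - half):min(W, cx + half)
    ys <- max(1, cy - half):min(H, cy + half)
    win <- px[ys, xs, drop = FALSE]
    med <- stats::median(win)
    floor_est <- max(6 * stats::mad(win), 1e-6)
    if (max(win) - med < floor_est) {
      out$flags[i] <- "low_signal"
      next
    }
    net <- pmax(win - med, 0)
    tot <- sum(net)
    cxr <- sum(sweep(net, 2, xs, `*`)) / tot
    cyr <- sum(sweep(net, 1, ys, `*`)) / tot
    out$x[i] <- cxr; out$y[i] <- cyr
    if (sqrt((cxr - layout$x[i])^2 + (cyr - layout$y[i])^2) > 0.35 * pitch)
      out$flags[i] <- "off_grid"
  }
  out
}

#' Measure one dot's integral intensity
#'
#' The local background is the median of an annulus around the dot
#' (1.5–2.5 aperture radii by default); annulus pixels falling inside any
#' neighbouring dot's aperture are excluded, and if too few pixels remain
#' the annulus is widened once before the dot is flagged `bg_crowded`.
#' The integral is the background-subtracted pixel sum over the aperture,
#' floored at zero. A dot with any aperture pixel at the scanner ceiling
#' is flagged `saturated`.
#'
#' @param image a `membrane_image`.
#' @param dot one-row dot stub from [locate_dots()] (or a list with `x`,
#'   `y`, `dot_id`, `flags`).
#' @param aperture_radius radius in pixels (default 3 sigma of the
#'   layout's dot profile).
#' @param annulus inner/outer annulus radii as multiples of the aperture
#'   radius.
#' @return One-row data frame: `dot_id`, `x`, `y`, `integral`,
#'   `background`, `flags`, `flagged`.
#' @export
measure_dot <- function(image, dot, aperture_radius = NULL,
                        annulus = c(1.5, 2.5)) {
  stopifnot(inherits(image, "membrane_image"))
  px <- image$pixels; layout <- image$layout
  sigma <- attr(layout, "sigma")
  if (is.null(aperture_radius)) aperture_radius <- 3 * sigma
  H <- nrow(px); W <- ncol(px)
  cx <- dot$x; cy <- dot$y
  flags <- if (!is.null(dot$flags) && nzchar(dot$flags))
    strsplit(dot$flags, ",")[[1]] else character(0)

  rr <- ceiling(annulus[2] * aperture_radius * 1.6)
  xs <- max(1, round(cx) - rr):min(W, round(cx) + rr)
  ys <- max(1, round(cy) - rr):min(H, round(cy) + rr)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sub <- px[ys, xs, drop = FALSE]

  in_ap <- d2 <= aperture_radius^2
  # exclusion mask: pixels inside any other dot's aperture
  other <- layout[layout$dot_id != dot$dot_id, ]
  near <- other[abs(other$x - cx) <= rr + aperture_radius &
                abs(other$y - cy) <= rr + aperture_radius, ]
  excl <- matrix(FALSE, length(ys), length(xs))
  for (j in seq_len(nrow(near))) {
    excl <- excl | (outer((ys - near$y[j])^2, (xs - near$x[j])^2, `+`) <=
                      aperture_radius^2)
  }
  ann_mask <- function(mult) {
    d2 >= (mult[1] * aperture_radius)^2 &
      d2 <= (mult[2] * aperture_radius)^2 & !excl & !in_ap
  }
  ann <- ann_mask(annulus)
  if (sum(ann) < 20) {
    ann <- ann_mask(annulus + 1)           # widen once
    if (sum(ann) < 20) flags <- union(flags, "bg_crowded")
  }
  bg <- if (sum(ann) > 0) stats::median(sub[ann]) else stats::median(sub)
  integral <- max(0, sum(sub[in_ap] - bg))
  if (any(sub[in_ap] >= image$noise$ceiling)) flags <- union(flags, "saturated")

  data.frame(dot_id = dot$dot_id, x = cx, y = cy, integral = integral,
             background = bg, flags = paste(flags, collapse = ","),
             flagged = length(flags) > 0)
}

#' Measure every dot on a membrane
#'
#' Convenience chain of [locate_dots()] and [measure_dot()].
#'
#' @param image a `membrane_image`.
#' @param ... passed to [measure_dot()].
#' @return Data frame with one row per laid-out dot: `dot_id`,
#'   `sample_id`, `role`, `cn`, `amount_ng`, `integral`, `background`,
#'   `flags`, `flagged`.
#' @export
quantify_integrals <- function(image, ...) {
  stubs <- locate_dots(image)
  res <- do.call(rbind, lapply(seq_len(nrow(stubs)), function(i)
    measure_dot(image, stubs[i, ], ...)))
  lay <- as.data.frame(image$layout)
  cbind(lay[match(res$dot_id, lay$dot_id),
            c("sample_id", "role", "cn", "amount_ng")],
        res[c("dot_id", "integral", "background", "flags", "flagged")])
}

#' Fit a calibration curve from standards
#'
#' Fits the signal-vs-copies relation of the calibration standards.
#' The working slope is the through-origin weighted (`1/x^2`) least
#' squares estimate, i.e. the mean of per-standard ratios
#' `(integral - floor)/(copies x ng)`: dot-blot noise is predominantly
#' multiplicative (constant relative error), and under that noise this
#' estimator is unbiased with far smaller scatter than a free-intercept
#' line (whose `1/slope` inversion is biased by several percent). An
#' unweighted OLS line is also fitted and reported purely as a
#' diagnostic (intercept, R-squared). The nonspecific
#' floor is the mean lambda-control integral; it is subtracted from the
#' standards before fitting and from sample integrals before inversion
#' (set `subtract_floor = FALSE` to use lambda only as a control). The fit
#' keeps a free intercept as a diagnostic of residual membrane offset, but
#' the inversion uses slope and floor only, matching the published
#' calculation.
#'
#' @param standards data frame with columns `cn`, `ng`, `integral`.
#' @param lambda_integrals numeric vector of lambda-control integrals.
#' @param subtract_floor subtract the lambda floor (default TRUE).
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `residual_se`, `floor`, `n_standards`,
#'   `subtract_floor`.
#' @export
fit_calibration <- function(standards, lambda_integrals,
                            subtract_floor = TRUE) {
  if (!is.data.frame(standards) ||
      !all(c("cn", "ng", "integral") %in% names(standards)))
    stop("standards needs columns cn, ng, integral")
  if (nrow(standards) < 3)
    stop("calibration failure: fewer than 3 usable standards")
  fl <- if (length(lambda_integrals)) mean(lambda_integrals) else 0
  if (fl < 0) fl <- 0
  x <- standards$cn * standards$ng
  y <- standards$integral - if (subtract_floor) fl else 0
  if (stats::sd(x) == 0)
    stop("calibration failure: degenerate standards (no spread in copies x ng)")
  if (any(x <= 0))
    stop("calibration failure: standards must have positive copies x ng")
  slope <- mean(y / x)
  fit <- stats::lm(y ~ x)          # diagnostic line only
  sm <- suppressWarnings(summary(fit))   # warns on exactly linear input
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failure: non-positive slope; membrane rejected")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residual_se = sm$sigma,
                 floor = fl,
                 n_standards = nrow(standards),
                 subtract_floor = subtract_floor),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration: signal = %.4g + %.4g x (copies x ng), R^2 = %.5f, floor = %.4g (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$floor, x$n_standards))
  invisible(x)
}

#' Convert one sample's replicate measurements to a copy-number estimate
#'
#' Each unflagged replicate dot is inverted through the calibration curve,
#' `cn = (integral - floor) / (slope x ng)` (the fitted intercept is a fit
#' diagnostic and does not enter the inversion), and replicates
#' are averaged; the standard error over replicates and the relative SE
#' (SE/mean) quantify replicate scatter. Flagged dots never enter the
#' average. With a single usable replicate the SE is undefined and the
#' estimate is flagged `low_confidence`; with none, the estimate is
#' explicitly missing (`NA`), never zero.
#'
#' @param measurements data frame for one sample with columns `integral`
#'   and `flagged` (from [quantify_integrals()]).
#' @param curve a `calibration_curve`.
#' @param ng DNA per dot in ng.
#' @return One-row data frame: `cn_mean`, `cn_se`, `rel_se`,
#'   `n_replicates`, `flags`.
#' @export
estimate_cn <- function(measurements, curve, ng) {
  stopifnot(inherits(curve, "calibration_curve"))
  use <- measurements[!measurements$flagged, , drop = FALSE]
  if (nrow(use) == 0) {
    return(data.frame(cn_mean = NA_real_, cn_se = NA_real_,
                      rel_se = NA_real_, n_replicates = 0L,
                      flags = "all_replicates_flagged"))
  }
  fl <- if (curve$subtract_floor) curve$floor else 0
  cn <- (use$integral - fl) / (curve$slope * ng)
  m <- mean(cn)
  if (nrow(use) == 1) {
    return(data.frame(cn_mean = m, cn_se = NA_real_, rel_se = NA_real_,
                      n_replicates = 1L, flags = "low_confidence"))
  }
  se <- stats::sd(cn) / sqrt(nrow(use))
  data.frame(cn_mean = m, cn_se = se, rel_se = se / m,
             n_replicates = nrow(use), flags = "")
}

#' End-to-end quantification of a membrane
#'
#' Locates and measures all dots, fits the calibration curve from the
#' membrane's own standards and lambda controls, and returns per-sample
#' copy-number estimates.
#'
#' @param image a `membrane_image`.
#' @param subtract_floor passed to [fit_calibration()].
#' @return List with `estimates` (one row per sample: `sample_id`,
#'   `cn_mean`, `cn_se`, `rel_se`, `n_replicates`, `flags`), `curve` and
#'   `measurements`.
#' @export
quantify_membrane <- function(image, subtract_floor = TRUE) {
  meas <- quantify_integrals(image)
  std <- meas[meas$role == "standard" & !meas$flagged, ]
  # lambda controls are low-signal by design; exclude only hard defects
  lam_ok <- meas$role == "lambda" &
    !grepl("saturated|off_grid|bg_crowded", meas$flags)
  lam <- meas[lam_ok, "integral"]
  curve <- fit_calibration(data.frame(cn = std$cn, ng = std$amount_ng,
                                      integral = std$integral),
                           lam, subtract_floor = subtract_floor)
  ids <- unique(meas$sample_id[meas$role == "sample"])
  est <- do.call(rbind, lapply(ids, function(sid) {
    mm <- meas[meas$sample_id == sid & meas$role == "sample", ]
    cbind(sample_id = sid,
          estimate_cn(mm, curve, ng = mm$amount_ng[1]))
  }))
  list(estimates = est, curve = curve, measurements = meas)
}
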