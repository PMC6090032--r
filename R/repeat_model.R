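# Model of the human ribosomal repeat unit and methylation-sensitive
# in-silico digestion.
#
# Coordinate convention: positions are given relative to the transcription
# initiation point (TSS = 0), upstream positions negative, and interval
# length is defined as end - start. One repeat unit spans
# [unit_start, unit_start + unit_length); the default unit starts at -515
# so that the p(ETS-18S) probe window opens the unit. Because rDNA units
# are tandemly arrayed, digestion treats the unit as circular: the segment
# downstream of the last cut is joined to the segment upstream of the
# first cut.

RDNA_ENZYMES <- c("Csp6I", "HpaII", "MspI")

#' Build a map of the human ribosomal repeat unit
#'
#' Constructs the coordinate model of one 43-kb human rDNA repeat unit:
#' the 13.3-kb coding region (18S/5.8S/28S), the hybridization probe
#' windows used for quantitative hybridization, and a table of restriction
#' sites for the methylation-insensitive enzyme Csp6I (GT^AC) and the
#' CCGG-cutting isoschizomer pair HpaII/MspI. HpaII is blocked when the
#' internal cytosine of CCGG is methylated; MspI cuts regardless.
#'
#' The two large probe windows sit at their published coordinates:
#' p(ETS-18S) from -515 to 5321 (5836 bp) and p(28S) from 8289 to 10702
#' (2413 bp), both relative to the transcription initiation point. The
#' default restriction-site table is deliberately schematic: exact site
#' coordinates within the unit are not published as numbers, so the
#' defaults are a documented, plausible placement that yields four
#' probe-detected Csp6I fragments. All downstream computations depend only
#' on this table, and it can be replaced wholesale via `site_config`.
#'
#' @param site_config optional data frame with columns `enzyme`
#'   (one of `"Csp6I"`, `"HpaII"`, `"MspI"`), `position` (TSS-relative
#'   coordinate) and `cpg_linked` (logical; may a CCGG site be methylated).
#'   Replaces the default table. Rows for HpaII are mirrored to MspI (and
#'   vice versa) if only one of the pair is supplied.
#' @param unit_length repeat-unit length in bp (default 43000).
#' @param unit_start coordinate where the unit interval opens
#'   (default -515, the upstream end of the p(ETS-18S) window).
#' @param coding_region two-element numeric, the 45S pre-rRNA coding
#'   interval (default 0 to 13300).
#' @param probe_windows named list of two-element numeric intervals.
#'   Defaults provide `p(ETS-18S)`, `p(28S)`, `oligo(18S)`, `oligo(28S)`.
#' @return An object of class `rdna_unit`: a list with elements
#'   `unit_length`, `unit_start`, `unit_end`, `coding_region`,
#'   `probe_windows` and `sites` (validated site table).
#' @examples
#' unit <- rdna_unit()
#' probe_window_length(unit, "p(28S)")     # 2413
#' probe_window_length(unit, "p(ETS-18S)") # 5836
#' @export
rdna_unit <- function(site_config = NULL,
                      unit_length = 43000,
                      unit_start = -515,
                      coding_region = c(0, 13300),
                      probe_windows = NULL) {
  stopifnot(is.numeric(unit_length), length(unit_length) == 1, unit_length > 0)
  if (is.null(probe_windows)) {
    probe_windows <- list(
      "p(ETS-18S)" = c(-515, 5321),
      "p(28S)"     = c(8289, 10702),
      "oligo(18S)" = c(4000, 4030),
      "oligo(28S)" = c(9600, 9630)
    )
  }
  if (is.null(site_config)) site_config <- default_site_table()
  sites <- validate_site_table(site_config, unit_start, unit_length)

  unit <- structure(list(
    unit_length  = unit_length,
    unit_start   = unit_start,
    unit_end     = unit_start + unit_length,
    coding_region = coding_region,
    probe_windows = probe_windows,
    sites        = sites
  ), class = "rdna_unit")

  for (nm in names(probe_windows)) {
    w <- probe_windows[[nm]]
    if (length(w) != 2 || w[2] <= w[1])
      stop("probe window '", nm, "' must be an increasing interval")
    if (w[1] < unit$unit_start || w[2] > unit$unit_end)
      stop("probe window '", nm, "' lies outside the unit")
    if (w[2] - w[1] < 30)
      stop("probe window '", nm, "' is shorter than 30 bp")
  }
  if (coding_region[1] < unit$unit_start || coding_region[2] > unit$unit_end)
    stop("coding region lies outside the unit")
  unit
}

# Schematic default placement (not sequence-derived): Csp6I sites chosen so
# that a Csp6I-only digest yields exactly four probe-detected fragments,
# two under each probe window; CCGG sites scattered through the promoter,
# the coding region and the intergenic spacer.
default_site_table <- function() {
  csp <- c(1500, 5800, 8000, 9500, 11500, 20000, 40000)
  ccgg <- c(-400, -150, 50, 800, 2500, 4500, 6500, 8700, 10000,
            13000, 18000, 25000, 35000)
  rbind(
    data.frame(enzyme = "Csp6I", position = csp,  cpg_linked = FALSE),
    data.frame(enzyme = "HpaII", position = ccgg, cpg_linked = TRUE),
    data.frame(enzyme = "MspI",  position = ccgg, cpg_linked = TRUE)
  )
}

validate_site_table <- function(sites, unit_start, unit_length) {
  need <- c("enzyme", "position", "cpg_linked")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop("site table needs columns enzyme, position, cpg_linked")
  sites <- sites[need]
  if (!all(sites$enzyme %in% RDNA_ENZYMES))
    stop("unknown enzyme in site table; allowed: ",
         paste(RDNA_ENZYMES, collapse = ", "))
  if (any(sites$position < unit_start |
          sites$position >= unit_start + unit_length))
    stop("restriction site position outside the unit interval")
  if (anyDuplicated(sites[c("enzyme", "position")]))
    stop("duplicate (enzyme, position) rows in site table")
  # mirror HpaII <-> MspI (both recognize CCGG)
  hp <- sort(sites$position[sites$enzyme == "HpaII"])
  ms <- sort(sites$position[sites$enzyme == "MspI"])
  if (length(hp) && !length(ms)) {
    add <- sites[sites$enzyme == "HpaII", ]
    add$enzyme <- "MspI"
    sites <- rbind(sites, add)
  } else if (length(ms) && !length(hp)) {
    add <- sites[sites$enzyme == "MspI", ]
    add$enzyme <- "HpaII"
    sites <- rbind(sites, add)
  } else if (!identical(hp, ms)) {
    stop("HpaII and MspI must share identical CCGG positions")
  }
  cs <- sites$position[sites$enzyme == "Csp6I"]
  if (any(cs %in% sites$position[sites$enzyme != "Csp6I"]))
    stop("Csp6I positions must be disjoint from CCGG positions")
  rownames(sites) <- NULL
  sites
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat("rDNA repeat unit:", x$unit_length, "bp, interval [",
      x$unit_start, ",", x$unit_end, ") (TSS = 0)\n")
  cat("  probe windows:", paste(names(x$probe_windows), collapse = ", "), "\n")
  tab <- table(x$sites$enzyme)
  cat("  sites:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Length of a probe window
#'
#' @param unit an `rdna_unit`.
#' @param probe probe-window name.
#' @return Window length in bp (`end - start`).
#' @export
probe_window_length <- function(unit, probe) {
  w <- unit$probe_windows[[probe]]
  if (is.null(w)) stop("unknown probe window: ", probe)
  w[2] - w[1]
}

#' Methylation profile of one rDNA fraction
#'
#' Human rDNA arrays contain three copy states: fraction 1 is
#' transcriptionally active, euchromatic and CpG-hypomethylated; fraction 2
#' is inactive with methylation restricted to some promoter-region CpG
#' sites; fraction 3 is hypermethylated heterochromatin across the whole
#' unit. The profile assigns each methylatable CCGG site a probability that
#' its internal cytosine is methylated in a given copy.
#'
#' @param fraction 1 (active), 2 (low-methylated) or 3 (hypermethylated).
#' @param promoter_region interval treated as "promoter" for fraction 2
#'   (default -200..100; the published description gives no coordinates).
#' @param promoter_p methylation probability at promoter CCGG sites in
#'   fraction 2 (default 0.8).
#' @param hyper_p methylation probability at all CCGG sites in fraction 3
#'   (default 1).
#' @return An object of class `methylation_profile`.
#' @export
methylation_profile <- function(fraction,
                                promoter_region = c(-200, 100),
                                promoter_p = 0.8,
                                hyper_p = 1.0) {
  if (!fraction %in% 1:3) stop("fraction must be 1, 2 or 3")
  structure(list(fraction = as.integer(fraction),
                 promoter_region = promoter_region,
                 promoter_p = promoter_p,
                 hyper_p = hyper_p),
            class = "methylation_profile")
}

# per-site methylation probabilities for the CCGG sites of `unit`
site_methylation_probs <- function(unit, profile) {
  ccgg <- unit$sites[unit$sites$enzyme == "HpaII", ]
  p <- numeric(nrow(ccgg))
  if (profile$fraction == 2) {
    inprom <- ccgg$position >= profile$promoter_region[1] &
      ccgg$position <= profile$promoter_region[2]
    p[inprom & ccgg$cpg_linked] <- profile$promoter_p
  } else if (profile$fraction == 3) {
    p[ccgg$cpg_linked] <- profile$hyper_p
  }
  data.frame(position = ccgg$position, prob = p)
}

#' Describe one genome's rDNA array
#'
#' @param cn_total total rDNA copies per diploid genome (the population
#'   mean is about 400).
#' @param f_active,f_low,f_hyper fractions of active, low-methylated and
#'   hypermethylated copies; must be non-negative and sum to 1.
#' @param allow_high_hyper allow `f_hyper` above 0.30 (the maximum
#'   observed in population samples; exceeding it is usually a mistake).
#' @return An object of class `genome_rdna`.
#' @examples
#' g <- genome_rdna(400, f_hyper = 0.3)
#' @export
genome_rdna <- function(cn_total, f_active = 1 - f_low - f_hyper,
                        f_low = 0, f_hyper = 0,
                        allow_high_hyper = FALSE) {
  stopifnot(is.numeric(cn_total), length(cn_total) == 1)
  if (cn_total <= 0) stop("cn_total must be positive")
  f <- c(f_active, f_low, f_hyper)
  if (any(f < -1e-12)) stop("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("fractions must sum to 1")
  if (!allow_high_hyper && f_hyper > 0.30 + 1e-12)
    stop("f_hyper > 0.30; set allow_high_hyper = TRUE to override")
  structure(list(cn_total = cn_total, f_active = f_active,
                 f_low = f_low, f_hyper = f_hyper),
            class = "genome_rdna")
}

#' @export
print.genome_rdna <- function(x, ...) {
  cat(sprintf("rDNA array: %g copies (active %.2f, low-methylated %.2f, hypermethylated %.2f)\n",
              x$cn_total, x$f_active, x$f_low, x$f_hyper))
  invisible(x)
}

# overlap of a (possibly wrapping) fragment [s, e) with window [w1, w2),
# on a circle of circumference L opened at unit_start. Fragments may have
# e > unit_end; the window is replayed one period up to catch the wrap.
fragment_window_overlap <- function(s, e, w1, w2, L) {
  seg <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))
  seg(s, e, w1, w2) + seg(s, e, w1 + L, w2 + L)
}

#' Digest one rDNA copy in silico
#'
#' Cuts one repeat unit with the requested enzymes. Csp6I cuts at every
#' GT^AC site irrespective of methylation. MspI cuts every CCGG site.
#' HpaII cuts a CCGG site only when the site's sampled methylation state
#' (a seeded Bernoulli draw from the profile's per-site probability) is
#' unmethylated. The unit is digested as a circular single repeat,
#' reflecting its tandem-array context, so fragments tile the unit exactly.
#'
#' @param unit an `rdna_unit`.
#' @param profile a `methylation_profile`.
#' @param enzymes character vector, non-empty subset of
#'   `c("Csp6I", "HpaII", "MspI")`.
#' @param rng_seed integer seed for the methylation draws.
#' @return A data frame of fragments with columns `start`, `end`, `length`
#'   and `probe_hits` (comma-separated probe windows overlapped). `end` may
#'   exceed the unit interval for the single wrap-around fragment; length
#'   is always `end - start` and fragment lengths sum to `unit_length`.
#' @export
digest <- function(unit, profile, enzymes, rng_seed = 1L) {
  stopifnot(inherits(unit, "rdna_unit"))
  if (length(enzymes) == 0) stop("enzymes must be non-empty")
  if (!all(enzymes %in% RDNA_ENZYMES))
    stop("unknown enzyme: ", paste(setdiff(enzymes, RDNA_ENZYMES), collapse = ", "))
  cuts <- realized_cuts(unit, profile, enzymes, rng_seed)
  fragments_from_cuts(unit, cuts)
}

realized_cuts <- function(unit, profile, enzymes, rng_seed) {
  cuts <- numeric(0)
  if ("Csp6I" %in% enzymes)
    cuts <- c(cuts, unit$sites$position[unit$sites$enzyme == "Csp6I"])
  if ("MspI" %in% enzymes) {
    cuts <- c(cuts, unit$sites$position[unit$sites$enzyme == "MspI"])
  } else if ("HpaII" %in% enzymes) {
    sm <- site_methylation_probs(unit, profile)
    meth <- if (all(sm$prob %in% c(0, 1))) {
      sm$prob == 1                       # deterministic, no draw needed
    } else {
      withr_seed(rng_seed, stats::rbinom(nrow(sm), 1L, sm$prob) == 1L)
    }
    cuts <- c(cuts, sm$position[!meth])
  }
  sort(unique(cuts))
}

fragments_from_cuts <- function(unit, cuts) {
  L <- unit$unit_length
  if (length(cuts) == 0) {
    fr <- data.frame(start = unit$unit_start, end = unit$unit_end)
  } else if (length(cuts) == 1) {
    fr <- data.frame(start = cuts, end = cuts + L)
  } else {
    fr <- data.frame(start = cuts,
                     end = c(cuts[-1], cuts[1] + L))
  }
  fr$length <- fr$end - fr$start
  fr$probe_hits <- vapply(seq_len(nrow(fr)), function(i) {
    hits <- names(unit$probe_windows)[vapply(unit$probe_windows, function(w)
      fragment_window_overlap(fr$start[i], fr$end[i], w[1], w[2], L) > 0,
      logical(1))]
    paste(hits, collapse = ",")
  }, character(1))
  fr
}

# run expr with a local RNG state seeded at seed
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(abs(seed) %% 2147483646L) + 1L)
  expr
}

#' Digest a whole rDNA array, fraction by fraction
#'
#' Aggregates [digest()] over the three methylation fractions of a genome,
#' weighting each realized per-copy fragment list by the number of copies
#' carrying it. Fractions 1 and 3 digest deterministically at the default
#' profiles (methylation probability 0 and 1); fraction-2 copies are
#' digested one by one because their promoter methylation is stochastic.
#'
#' @param unit an `rdna_unit`.
#' @param genome a `genome_rdna`.
#' @param enzymes enzyme set as in [digest()].
#' @param rng_seed integer seed.
#' @param profiles optional list of three `methylation_profile`s for
#'   fractions 1..3.
#' @return An object of class `rdna_spectra`: a data frame with columns
#'   `fraction`, `copy`, `weight`, `start`, `end`, `length`, `probe_hits`;
#'   the unit and enzymes are attached as attributes. Total weight per
#'   fraction equals the fraction's copy count and summed weights equal
#'   `cn_total`.
#' @export
digest_genome <- function(unit, genome, enzymes, rng_seed = 1L,
                          profiles = NULL) {
  stopifnot(inherits(genome, "genome_rdna"))
  if (is.null(profiles))
    profiles <- list(methylation_profile(1), methylation_profile(2),
                     methylation_profile(3))
  copies <- genome$cn_total * c(genome$f_active, genome$f_low, genome$f_hyper)
  out <- list()
  for (fr in 1:3) {
    if (copies[fr] <= 0) next
    prof <- profiles[[fr]]
    sm <- site_methylation_probs(unit, prof)
    deterministic <- all(sm$prob %in% c(0, 1)) ||
      !("HpaII" %in% enzymes && !("MspI" %in% enzymes))
    if (deterministic) {
      fl <- digest(unit, prof, enzymes, rng_seed)
      fl$fraction <- fr; fl$copy <- 1L; fl$weight <- copies[fr]
      out[[length(out) + 1L]] <- fl
    } else {
      ncop <- max(1L, round(copies[fr]))
      w <- copies[fr] / ncop
      for (k in seq_len(ncop)) {
        fl <- digest(unit, prof, enzymes,
                     rng_seed = rng_seed * 1000L + fr * 100L + k)
        fl$fraction <- fr; fl$copy <- k; fl$weight <- w
        out[[length(out) + 1L]] <- fl
      }
    }
  }
  spec <- do.call(rbind, out)
  spec <- spec[c("fraction", "copy", "weight", "start", "end",
                 "length", "probe_hits")]
  rownames(spec) <- NULL
  structure(spec, class = c("rdna_spectra", "data.frame"),
            unit = unit, enzymes = enzymes)
}
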