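# Osmotic fragility analysis: hemolysis curve, H50/H10/H90, heterogeneity
# width W, hydrodynamic volume curve (MCV_osm) and asphericity index,
# all computed from the per-angle scattered-light record alone.

# Per-plateau mean SLI for one angle; plateaus identified by runs of
# constant osmolality in the sample stream.
plateau_means <- function(rec, angle) {
  j <- match(angle, rec$angles)
  if (is.na(j))
    stop("angle ", angle, " not present in recording", call. = FALSE)
  osm <- rec$schedule$osmolality
  means <- vapply(osm, function(o) mean(rec$sli[rec$osmolality == o, j]),
                  numeric(1))
  data.frame(osmolality = osm, sli = means)
}

# Pick a swelling-insensitive reference angle (> 6 deg) used to count
# intact cells independently of cell volume.
intact_reference_angle <- function(rec) {
  cand <- rec$angles[rec$angles > 6]
  if (length(cand) == 0L) return(NA_real_)
  max(cand)
}

#' Hemolysis curve from an osmotic fragility recording
#'
#' The lysed fraction at each plateau is read from the decrease of the
#' scattered light relative to the isotonic (300 mOsmol) reference.
#' Because low-angle SLI also rises as intact cells swell, the estimator
#' is volume-corrected: the per-intact-cell swelling factor is estimated
#' as the ratio of the normalized low-angle channel to a normalized
#' swelling-insensitive channel (> 6 degrees), and the hemolysis channel
#' is divided by that factor before the lysed fraction is formed. When
#' the hemolysis angle itself lies above 6 degrees no correction is
#' needed. The resulting curve is regularized to be nondecreasing with
#' falling osmolality (pool-adjacent-violators) so that noise cannot
#' locally invert it.
#'
#' @param rec An `oft_recording`.
#' @param hemolysis_angle Angle (degrees, 1-12) whose intensity loss is
#'   read as hemolysis; default 6.
#' @param swelling_angle Low angle (<= 6) used for the volume
#'   correction; default 2.5.
#' @param regularize Apply isotonic regularization (default `TRUE`).
#' @return `data.frame` with `osmolality` (mOsmol) and `lysed_pct` (%),
#'   ordered from 300 mOsmol down.
#' @export
lysed_fraction_curve <- function(rec, hemolysis_angle = 6,
                                 swelling_angle = 2.5,
                                 regularize = TRUE) {
  if (!inherits(rec, "oft_recording"))
    stop("`rec` must be an oft_recording", call. = FALSE)
  if (!any(rec$schedule$osmolality == 300))
    stop("recording lacks the 300 mOsmol reference plateau", call. = FALSE)
  if (!any(rec$angles >= 1 & rec$angles <= 12))
    stop("recording has no hemolysis angle in 1-12 degrees", call. = FALSE)
  if (hemolysis_angle < 1 || hemolysis_angle > 12)
    stop("`hemolysis_angle` must lie in 1-12 degrees", call. = FALSE)

  hemo <- plateau_means(rec, hemolysis_angle)
  ref0 <- hemo$sli[hemo$osmolality == 300]
  if (ref0 <= 0) {
    # no isotonic signal: the whole population lysed immediately
    frac <- rep(1, nrow(hemo))
  } else {
    r_h <- hemo$sli / ref0
    if (hemolysis_angle <= 6) {
      ref_angle <- intact_reference_angle(rec)
      if (is.na(ref_angle))
        stop("hemolysis angle <= 6 degrees needs a swelling-insensitive ",
             "reference angle (> 6 degrees) in the recording",
             call. = FALSE)
      low <- plateau_means(rec, swelling_angle)
      hi <- plateau_means(rec, ref_angle)
      r_low <- low$sli / low$sli[low$osmolality == 300]
      r_hi <- hi$sli / hi$sli[hi$osmolality == 300]
      swell <- ifelse(r_hi > 1e-9, r_low / r_hi, 1)
      frac <- 1 - r_h / pmax(swell, 1e-9)
    } else {
      frac <- 1 - r_h
    }
    frac[r_h <= 1e-9] <- 1
  }
  frac <- pmin(pmax(frac, 0), 1)
  if (regularize && length(frac) > 1L)
    frac <- stats::isoreg(seq_along(frac), frac)$yf
  data.frame(osmolality = hemo$osmolality, lysed_pct = 100 * frac)
}

# Locate the osmolality at which the (monotone) hemolysis curve crosses
# `level` percent, by linear interpolation between bracketing plateaus.
cross_osmolality <- function(curve, level) {
  y <- curve$lysed_pct
  x <- curve$osmolality
  hit <- which(y >= level)
  if (length(hit) == 0L)
    stop(sprintf("hemolysis curve never reaches %g%% lysis", level),
         call. = FALSE)
  i <- hit[1]
  if (y[i] == level || i == 1L) {
    if (i == 1L && y[i] > level)
      stop(sprintf(
        "hemolysis curve starts above %g%% lysis; no bracketing plateau",
        level), call. = FALSE)
    return(x[i])
  }
  x[i - 1] + (x[i] - x[i - 1]) * (level - y[i - 1]) / (y[i] - y[i - 1])
}

#' Osmotic resistance summary: H50, H10, H90 and heterogeneity width W
#'
#' H50 is the osmolality at which half the cells have lysed; H10 and H90
#' the osmolalities of 10% and 90% lysis. W, the width of the osmotic
#' resistance curve between those two points, characterizes the
#' heterogeneity of the cell pool and is reported as a nonnegative span.
#' Thresholds are located by linear interpolation between the two
#' bracketing plateaus of the (isotonically regularized) curve.
#'
#' @param curve Hemolysis curve as returned by [lysed_fraction_curve()]
#'   (columns `osmolality`, `lysed_pct`), or an `oft_recording` from
#'   which the curve is computed with default settings.
#' @return List with `h50`, `h10`, `h90` (mOsmol) and `w = |h10 - h90|`.
#' @export
resistance_summary <- function(curve) {
  if (inherits(curve, "oft_recording"))
    curve <- lysed_fraction_curve(curve)
  if (!all(c("osmolality", "lysed_pct") %in% names(curve)))
    stop("`curve` needs columns osmolality and lysed_pct", call. = FALSE)
  curve <- curve[order(-curve$osmolality), ]
  # enforce monotone nondecreasing lysis for raw user-supplied curves
  curve$lysed_pct <- stats::isoreg(seq_len(nrow(curve)),
                                   curve$lysed_pct)$yf
  h50 <- cross_osmolality(curve, 50)
  h10 <- cross_osmolality(curve, 10)
  h90 <- cross_osmolality(curve, 90)
  list(h50 = h50, h10 = h10, h90 = h90, w = abs(h10 - h90))
}

#' Hydrodynamic volume curve (MCV_osm) across osmolalities
#'
#' Tracks the mean hydrodynamic volume of the intact cells as the medium
#' osmolality falls, anchored to the hematology-analyser MCV at
#' 300 mOsmol. The per-intact-cell low-angle SLI is obtained by dividing
#' the normalized low-angle channel by a normalized swelling-insensitive
#' channel (> 6 degrees, proportional to the intact count); volume is
#' recovered through the projected-area convention SLI proportional to
#' V^(2/3), i.e. V = MCV300 * (per-cell SLI ratio)^(3/2).
#'
#' @param rec An `oft_recording` containing a low-angle (<= 6 degree)
#'   channel.
#' @param mcv_300 Reference mean cell volume at 300 mOsmol (fL).
#' @param swelling_angle Low angle used; default 2.5 degrees.
#' @return `data.frame` with `osmolality` and `mcv_fl`; the first point
#'   is exactly (300, `mcv_300`). Plateaus where the intact signal has
#'   vanished give `NA`.
#' @export
mcv_osm_curve <- function(rec, mcv_300, swelling_angle = 2.5) {
  if (!inherits(rec, "oft_recording"))
    stop("`rec` must be an oft_recording", call. = FALSE)
  if (!any(rec$angles <= 6))
    stop("recording has no low-angle (<= 6 degree) channel", call. = FALSE)
  if (mcv_300 <= 0)
    stop("`mcv_300` must be positive", call. = FALSE)
  low <- plateau_means(rec, swelling_angle)
  ref0 <- low$sli[low$osmolality == 300]
  if (length(ref0) == 0L)
    stop("recording lacks the 300 mOsmol reference plateau", call. = FALSE)
  if (ref0 <= 0)
    stop("zero reference SLI at 300 mOsmol", call. = FALSE)
  r_low <- low$sli / ref0

  ref_angle <- intact_reference_angle(rec)
  if (is.na(ref_angle)) {
    # no intact-count channel: assume no lysis (valid for recordings
    # confined to osmolalities above every lysis threshold)
    r_int <- rep(1, nrow(low))
  } else {
    hi <- plateau_means(rec, ref_angle)
    r_int <- hi$sli / hi$sli[hi$osmolality == 300]
  }
  per_cell <- ifelse(r_int > 1e-9, r_low / r_int, NA_real_)
  mcv <- mcv_300 * per_cell^(3 / 2)
  mcv[low$osmolality == 300] <- mcv_300
  data.frame(osmolality = low$osmolality, mcv_fl = mcv)
}

#' Asphericity index from the isotonic SLI oscillations
#'
#' Flattened (discoid) cells rotating in the stirred cuvette modulate
#' their projected area, so the isotonic SLI trace oscillates; spheres
#' give a flat trace. The index is the normalized oscillation amplitude
#' at the registration angle, in percent:
#' `AI = 100 * 2 * sqrt(2) * SD(detrended plateau SLI) / mean(plateau SLI)`,
#' which equals peak-to-peak amplitude over mean for a sinusoid. The
#' trace is linearly detrended before the SD is taken.
#'
#' @param rec An `oft_recording` with a 300 mOsmol plateau.
#' @param angle Registration angle (degrees); default 2.5.
#' @param min_samples Minimum samples required on the plateau.
#' @return Asphericity index (%).
#' @export
asphericity_index <- function(rec, angle = 2.5, min_samples = 200L) {
  if (!inherits(rec, "oft_recording"))
    stop("`rec` must be an oft_recording", call. = FALSE)
  j <- match(angle, rec$angles)
  if (is.na(j))
    stop("angle ", angle, " not present in recording", call. = FALSE)
  sel <- rec$osmolality == 300
  if (sum(sel) < min_samples)
    stop(sprintf(
      "300 mOsmol plateau too short: %d samples (need >= %d)",
      sum(sel), min_samples), call. = FALSE)
  y <- rec$sli[sel, j]
  t <- rec$time[sel]
  m <- mean(y)
  if (m <= 0) stop("zero mean SLI on the isotonic plateau", call. = FALSE)
  resid <- stats::lm.fit(cbind(1, t), y)$residuals
  100 * 2 * sqrt(2) * stats::sd(resid) / m
}
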