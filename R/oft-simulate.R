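# Simulated laser-diffraction osmotic fragility recordings.
#
# Physics emulated: cells behave as two-parameter osmometers (van't Hoff
# swelling about an osmotically inactive volume), lyse instantaneously when
# the medium osmolality falls to their per-cell threshold, and scatter
# forward light in proportion to a projected-area term. Random in-flow
# rotation modulates the projected area of flattened cells, producing the
# SLI oscillations whose normalized amplitude is the asphericity index.

#' Stepwise osmolality schedule for an osmotic fragility recording
#'
#' @param osmolalities Plateau osmolalities (mOsmol), strictly decreasing,
#'   starting at the isotonic 300 mOsmol.
#' @param plateau_s Duration of each plateau (seconds); recycled.
#' @return A `data.frame` with columns `osmolality` and `duration_s`.
#' @export
oft_schedule <- function(osmolalities = seq(300, 100, by = -10),
                         plateau_s = 20) {
  if (length(osmolalities) < 1L)
    stop("schedule needs at least one plateau", call. = FALSE)
  if (osmolalities[1] != 300)
    stop("schedule must start at the isotonic 300 mOsmol plateau",
         call. = FALSE)
  if (length(osmolalities) > 1L && any(diff(osmolalities) >= 0))
    stop("schedule osmolalities must be strictly decreasing", call. = FALSE)
  data.frame(osmolality = osmolalities,
             duration_s = rep_len(plateau_s, length(osmolalities)))
}

# van't Hoff hydrodynamic volume of an intact cell at a given osmolality.
vant_hoff_volume <- function(v300, vs, osm) {
  vs + (v300 - vs) * (300 / osm)
}

#' Simulate a scattered-light recording of an osmotic fragility test
#'
#' Lowers the medium osmolality over the plateaus of `schedule` and
#' integrates the forward-scattered light of the surviving cells at each
#' detection angle. A cell is intact while its lysis threshold lies below
#' the current osmolality and contributes:
#' \itemize{
#'   \item at low angles (<= 6 degrees): a projected-area term
#'     proportional to its current volume^(2/3), so swelling raises the
#'     signal;
#'   \item at higher angles (6-12 degrees): a fixed cross-section set by
#'     its isotonic volume, insensitive to swelling.
#' }
#' At every angle the signal falls in proportion to the lysed fraction.
#' A shared per-sample orientation factor `1 + (1 - q) * u`, with `u`
#' uniform on \[-1, 1\], modulates each cell's contribution, giving a
#' peak-to-peak relative oscillation amplitude of `2 * (1 - q)`: spheres
#' (q = 1) produce a flat trace, flattened cells a strongly oscillating
#' one.
#'
#' @param cells Population `data.frame` from [sample_population()].
#' @param schedule Osmolality schedule from [oft_schedule()].
#' @param angles Detection angles in degrees (subset of 0-12, including
#'   the 2.5 degree swelling channel by default).
#' @param sampling_rate Samples per second.
#' @param noise_sd Additive Gaussian noise SD, expressed as a fraction of
#'   the isotonic mean SLI of each angle (0.01 = 1% noise).
#' @param seed Optional RNG seed.
#' @param track_truth Record the true lysed fraction per plateau
#'   (generator bookkeeping used by oracle tests).
#' @return An object of class `oft_recording`: list with `time`,
#'   `osmolality` (per sample), `sli` (samples x angles matrix), `angles`,
#'   `sampling_rate`, `schedule` and (optionally) `lysed_truth`.
#' @export
simulate_oft_recording <- function(cells,
                                   schedule = oft_schedule(),
                                   angles = c(2.5, 6, 12),
                                   sampling_rate = 10,
                                   noise_sd = 0,
                                   seed = NULL,
                                   track_truth = TRUE) {
  if (is.null(cells) || nrow(cells) == 0L)
    stop("`cells` must be a nonempty population", call. = FALSE)
  if (schedule$osmolality[1] != 300)
    stop("schedule must start at 300 mOsmol", call. = FALSE)
  if (any(angles < 0 | angles > 12))
    stop("detection angles must lie in 0-12 degrees", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  n_per <- pmax(1L, as.integer(round(schedule$duration_s * sampling_rate)))
  n_tot <- sum(n_per)
  n_ang <- length(angles)
  low <- angles <= 6

  sli <- matrix(0, n_tot, n_ang,
                dimnames = list(NULL, paste0("sli_", angles)))
  time <- numeric(n_tot)
  osm_col <- numeric(n_tot)
  truth <- numeric(nrow(schedule))

  a_iso <- cells$v300^(2 / 3)      # swelling-insensitive cross-section
  row0 <- 0L
  t0 <- 0
  iso_mean <- rep(NA_real_, n_ang) # isotonic mean per angle, noise scale

  for (p in seq_len(nrow(schedule))) {
    osm <- schedule$osmolality[p]
    m <- n_per[p]
    idx <- row0 + seq_len(m)
    intact <- cells$lysis_osm < osm
    truth[p] <- 1 - mean(intact)

    vol <- vant_hoff_volume(cells$v300[intact], cells$vs[intact], osm)
    a_low <- vol^(2 / 3)
    a_hi <- a_iso[intact]
    shape <- 1 - cells$axis_ratio[intact]

    # Orientation factor over the plateau: stratified midpoints of
    # [-1, 1] in randomly permuted order. Over a plateau the rotation
    # phase covers orientation space uniformly, so the plateau-mean
    # orientation factor is exactly 1 while sample-to-sample
    # oscillations keep SD ~ 1/sqrt(3).
    u <- sample(-1 + (2 * seq_len(m) - 1) / m)
    for (j in seq_len(n_ang)) {
      a <- if (low[j]) a_low else a_hi
      A <- sum(a)
      B <- sum(a * shape)
      base <- A + B * u
      if (p == 1L) iso_mean[j] <- A
      if (noise_sd > 0)
        base <- base + stats::rnorm(m, 0, noise_sd * iso_mean[j])
      sli[idx, j] <- pmax(base, 0)
    }
    time[idx] <- t0 + seq_len(m) / sampling_rate
    osm_col[idx] <- osm
    row0 <- row0 + m
    t0 <- t0 + schedule$duration_s[p]
  }

  rec <- list(time = time, osmolality = osm_col, sli = sli,
              angles = angles, sampling_rate = sampling_rate,
              schedule = schedule, seed = seed)
  if (track_truth)
    rec$lysed_truth <- data.frame(osmolality = schedule$osmolality,
                                  lysed_fraction = truth)
  structure(rec, class = "oft_recording")
}

#' @export
print.oft_recording <- function(x, ...) {
  cat("Osmotic fragility recording\n")
  cat(sprintf("  %d plateaus, %.0f -> %.0f mOsmol; %d samples at %g Hz\n",
              nrow(x$schedule), max(x$schedule$osmolality),
              min(x$schedule$osmolality), length(x$time), x$sampling_rate))
  cat("  angles (deg):", paste(x$angles, collapse = ", "), "\n")
  invisible(x)
}

#' Convert an OFT recording to a tidy data frame
#'
#' @param x An `oft_recording`.
#' @param ... Unused.
#' @return Data frame with `time`, `osmolality` and one `sli_<angle>`
#'   column per detection angle.
#' @export
as.data.frame.oft_recording <- function(x, ...) {
  cbind(data.frame(time = x$time, osmolality = x$osmolality),
        as.data.frame(x$sli))
}

#' Write / read an OFT recording as CSV
#'
#' The CSV holds one row per sample: `time`, `osmolality`, then one
#' `sli_<angle>` column per angle. Reading reconstructs the plateau
#' schedule from the runs of constant osmolality.
#'
#' @param rec An `oft_recording`.
#' @param path File path.
#' @return `read_oft_csv()` returns an `oft_recording` (without
#'   generator truth); `write_oft_csv()` returns `path` invisibly.
#' @export
write_oft_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_oft_csv
#' @export
read_oft_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sli_cols <- grep("^sli_", names(df), value = TRUE)
  if (length(sli_cols) == 0L)
    stop("no sli_<angle> columns found in ", path, call. = FALSE)
  angles <- as.numeric(sub("^sli_", "", sli_cols))
  runs <- rle(df$osmolality)
  dur <- runs$lengths * diff(df$time[1:2]) * 1
  sampling_rate <- 1 / diff(df$time[1:2])
  structure(list(time = df$time, osmolality = df$osmolality,
                 sli = as.matrix(df[sli_cols]),
                 angles = angles, sampling_rate = sampling_rate,
                 schedule = data.frame(osmolality = runs$values,
                                       duration_s = runs$lengths /
                                         sampling_rate)),
            class = "oft_recording")
}
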