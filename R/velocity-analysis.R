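# Analysis of normalized transit-velocity datasets: averaged probability
# densities across experiments, slow/fast subpopulation fractions, the
# control-tail cutoff calibration, and channel occlusion rates.

# Coerce a velocity_dataset or bare numeric vector to velocities (a.u.).
as_velocities <- function(x) {
  if (inherits(x, "velocity_dataset")) return(x$velocities)
  if (is.numeric(x)) return(x)
  stop("expected a velocity_dataset or a numeric vector", call. = FALSE)
}

#' Averaged velocity probability density across experiments
#'
#' Builds a density histogram of normalized transit velocity for each
#' experiment on a common grid (each experiment's density integrates to
#' 1), then averages pointwise across experiments and attaches the
#' standard error of the mean density in every bin. This mirrors the
#' practice of constructing per-donor probability density functions and
#' averaging them, so that donors with many tracked cells do not
#' dominate the shape.
#'
#' @param datasets A `velocity_dataset`, numeric vector, or list of
#'   either (one element per experiment).
#' @param bin_width Histogram bin width in a.u. (default 0.025, fine
#'   enough to resolve the 0.175 a.u. slow-cell cutoff region).
#' @param range Velocity range covered by the grid (default \[0, 2\]);
#'   velocities outside it are dropped (count reported as attribute
#'   `n_dropped`).
#' @return `data.frame` with `bin_center`, `density_mean`, `density_se`;
#'   per-experiment densities in attribute `density_matrix`.
#' @export
velocity_pdf <- function(datasets, bin_width = 0.025, range = c(0, 2)) {
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  if (inherits(datasets, "velocity_dataset") || is.numeric(datasets))
    datasets <- list(datasets)
  if (length(datasets) == 0L)
    stop("at least one experiment is required", call. = FALSE)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  centers <- breaks[-1] - bin_width / 2

  n_dropped <- 0L
  dens <- vapply(datasets, function(d) {
    v <- as_velocities(d)
    if (length(v) == 0L)
      stop("empty velocity dataset", call. = FALSE)
    keep <- v >= breaks[1] & v <= breaks[length(breaks)]
    n_dropped <<- n_dropped + sum(!keep)
    v <- v[keep]
    if (length(v) == 0L)
      stop("no velocities inside the histogram range", call. = FALSE)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / (length(v) * bin_width)
  }, numeric(length(centers)))
  dens <- matrix(dens, nrow = length(centers))

  m <- rowMeans(dens)
  se <- if (ncol(dens) > 1L)
    apply(dens, 1, stats::sd) / sqrt(ncol(dens))
  else rep(0, length(centers))
  out <- data.frame(bin_center = centers, density_mean = m,
                    density_se = se)
  attr(out, "density_matrix") <- dens
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Slow- and fast-cell fractions of a velocity dataset
#'
#' The slow fraction is the percentage of cells with normalized velocity
#' below `cutoff_slow` (default 0.175 a.u., the threshold under which
#' fewer than about 0.45% of control cells fall); the fast fraction,
#' when a cutoff is supplied, is the percentage above `cutoff_fast`.
#'
#' @param dataset A `velocity_dataset` or numeric vector of normalized
#'   velocities (a.u.).
#' @param cutoff_slow Slow-cell threshold in a.u. (default 0.175).
#' @param cutoff_fast Optional fast-cell threshold in a.u.; when `NULL`
#'   the fast fraction is `NA`.
#' @return List with `slow_fraction` and `fast_fraction` (percent), and
#'   the cutoffs used.
#' @export
slow_fast_fractions <- function(dataset, cutoff_slow = 0.175,
                                cutoff_fast = NULL) {
  v <- as_velocities(dataset)
  if (length(v) == 0L) stop("no velocities supplied", call. = FALSE)
  slow <- 100 * mean(v < cutoff_slow)
  fast <- if (is.null(cutoff_fast)) NA_real_ else
    100 * mean(v > cutoff_fast)
  list(slow_fraction = slow, fast_fraction = fast,
       cutoff_slow = cutoff_slow, cutoff_fast = cutoff_fast)
}

#' Calibrate the slow-cell cutoff from a control distribution
#'
#' Inverts the construction of the slow-cell threshold: given control
#' velocities, returns the velocity below which a stated fraction
#' (`tail_mass`, default 0.45%) of control cells falls. Applying
#' [slow_fast_fractions()] with the returned cutoff to the same control
#' data recovers `100 * tail_mass` percent to within one cell.
#'
#' @param control_velocities Numeric vector (or `velocity_dataset`) of
#'   control normalized velocities; at least 1,000 values.
#' @param tail_mass Target control tail mass (fraction, default 0.0045).
#' @return Cutoff velocity in a.u.
#' @export
calibrate_cutoff <- function(control_velocities, tail_mass = 0.0045) {
  v <- as_velocities(control_velocities)
  if (length(v) < 1000L)
    stop("cutoff calibration needs at least 1,000 control velocities",
         call. = FALSE)
  if (tail_mass < 0 || tail_mass > 1)
    stop("`tail_mass` must lie in [0, 1]", call. = FALSE)
  unname(stats::quantile(v, probs = tail_mass, type = 1))
}

#' Microchannel occlusion rate
#'
#' Percentage of channels occluded by an arrested cell, pooled over the
#' supplied experiments, with its binomial standard error.
#'
#' @param datasets A `velocity_dataset`, a logical vector of per-channel
#'   occlusion flags, or a list of either.
#' @return List with `occlusion_rate` (%), `se` (%), `n_channels`,
#'   `n_occluded`.
#' @export
occlusion_rate <- function(datasets) {
  if (inherits(datasets, "velocity_dataset") || is.logical(datasets))
    datasets <- list(datasets)
  flags <- unlist(lapply(datasets, function(d) {
    if (inherits(d, "velocity_dataset")) d$channel_occluded
    else if (is.logical(d)) d
    else stop("expected velocity_dataset or logical flags", call. = FALSE)
  }))
  n <- length(flags)
  if (n == 0L) stop("zero channels: occlusion rate undefined",
                    call. = FALSE)
  k <- sum(flags)
  p <- k / n
  list(occlusion_rate = 100 * p,
       se = 100 * sqrt(p * (1 - p) / n),
       n_channels = n, n_occluded = k)
}
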