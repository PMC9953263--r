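# Synthetic microchannel transit measurements: normalized per-cell
# velocities drawn from a declared mixture, per-channel occlusion events,
# and (for tracker testing) rendered grayscale image stacks with
# ground-truth trajectories.

#' Simulate a normalized transit-velocity dataset
#'
#' Draws per-cell normalized microchannel transit velocities from the
#' mixture declared in the population spec (main peak near 1 a.u., an
#' optional slow tail and an optional fast tail), assigns cells to
#' microchannels, and flags a channel as occluded when any of its cells
#' arrests (a Bernoulli event with the cell's adhesion propensity).
#'
#' @param spec A [population_spec()] declaring the velocity mixture and
#'   adhesion propensity.
#' @param n_channels Number of microchannels cells are distributed over
#'   (default 16, one microchip).
#' @param seed Optional RNG seed (overrides `spec$seed`).
#' @param wide_channel_mean Reference mean velocity in wide channels
#'   (um/s) to which the velocities are implicitly normalized.
#' @return Object of class `velocity_dataset`: list with `velocities`
#'   (a.u.), `component` (truth labels), `channel` (per-cell channel
#'   index), `channel_occluded` (logical per channel), `experiment_id`,
#'   `wide_channel_mean`.
#' @export
simulate_velocity_dataset <- function(spec, n_channels = 16L, seed = NULL,
                                      wide_channel_mean = 2000) {
  if (!inherits(spec, "population_spec"))
    stop("`spec` must be a population_spec", call. = FALSE)
  if (n_channels < 1)
    stop("`n_channels` must be at least 1", call. = FALSE)
  if (wide_channel_mean <= 0)
    stop("`wide_channel_mean` must be positive", call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(seed)) withr::local_seed(seed)

  cells <- sample_population(spec, seed = NULL)  # RNG already seeded
  n <- nrow(cells)
  channel <- sample.int(n_channels, n, replace = TRUE)
  arrest <- stats::runif(n) < cells$adhesion_propensity
  occluded <- vapply(seq_len(n_channels),
                     function(ch) any(arrest[channel == ch]),
                     logical(1))

  structure(list(velocities = cells$velocity_factor,
                 component = cells$velocity_component,
                 channel = channel,
                 channel_occluded = occluded,
                 experiment_id = spec$group_label,
                 wide_channel_mean = wide_channel_mean,
                 seed = seed),
            class = "velocity_dataset")
}

#' @export
print.velocity_dataset <- function(x, ...) {
  cat(sprintf("Velocity dataset '%s': %d cells, %d channels (%d occluded)\n",
              x$experiment_id, length(x$velocities),
              length(x$channel_occluded), sum(x$channel_occluded)))
  invisible(x)
}

#' Write / read a velocity dataset as CSV
#'
#' One row per cell: `velocity_au`, `channel`, `channel_occluded` (the
#' flag of the cell's channel, repeated), `experiment_id`,
#' `wide_channel_mean`.
#'
#' @param dataset A `velocity_dataset`.
#' @param path File path.
#' @return `read_velocity_csv()` returns a `velocity_dataset`.
#' @export
write_velocity_csv <- function(dataset, path) {
  df <- data.frame(velocity_au = dataset$velocities,
                   channel = dataset$channel,
                   channel_occluded =
                     dataset$channel_occluded[dataset$channel],
                   experiment_id = dataset$experiment_id,
                   wide_channel_mean = dataset$wide_channel_mean)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path)
  n_ch <- max(df$channel)
  occ <- rep(FALSE, n_ch)
  occ[unique(df$channel[df$channel_occluded])] <- TRUE
  structure(list(velocities = df$velocity_au,
                 component = NULL,
                 channel = df$channel,
                 channel_occluded = occ,
                 experiment_id = df$experiment_id[1],
                 wide_channel_mean = df$wide_channel_mean[1]),
            class = "velocity_dataset")
}

#' Render a microchannel transit movie with ground truth
#'
#' Produces a small grayscale image stack emulating bright-field video of
#' cells transiting a straight microchannel: dark, slightly elongated
#' Gaussian blobs on a bright background advancing along the x axis by
#' `velocity_um_s / (fps * pixel_size)` pixels per frame. Meant for
#' desk-scale testing of the tracker against a known answer.
#'
#' Conventions: frames are numbered from 0; pixel centers sit at integer
#' coordinates, with x = 0 at the left edge and y = 0 at the top row.
#'
#' @param cells `data.frame` with one row per rendered cell: columns
#'   `entry_frame` (frame at which the cell enters at x = 0),
#'   `velocity_um_s`, and optional `y_px` (transverse position; defaults
#'   to mid-channel).
#' @param n_frames Number of frames to render.
#' @param geometry List with `length_px` and `width_px` of the channel
#'   field of view.
#' @param fps Frame rate (default 400, high-speed video).
#' @param pixel_size Microns per pixel (default 0.5).
#' @param cell_radius_px Gaussian radius of the blob along x (pixels).
#' @param background Background gray level in \[0, 1\].
#' @param depth Blob darkness (subtracted at the blob center).
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param seed Optional RNG seed (only noise is random).
#' @return List with `frames` (array `width_px` x `length_px` x
#'   `n_frames`, gray levels in \[0, 1\]), `truth` (`data.frame` with
#'   `frame`, `cell_id`, `x_px`, `y_px` for every frame in which a cell
#'   is inside the field), `fps`, `pixel_size`.
#' @export
render_microchannel_frames <- function(cells,
                                       n_frames = 50L,
                                       geometry = list(length_px = 200L,
                                                       width_px = 40L),
                                       fps = 400,
                                       pixel_size = 0.5,
                                       cell_radius_px = 4,
                                       background = 0.9,
                                       depth = 0.6,
                                       noise_sd = 0,
                                       seed = NULL) {
  nx <- as.integer(geometry$length_px)
  ny <- as.integer(geometry$width_px)
  if (nx < 2L || ny < 2L) stop("geometry too small", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  if (is.null(cells) || nrow(cells) == 0L) {
    cells <- data.frame(entry_frame = integer(0),
                        velocity_um_s = numeric(0))
  }
  step_px <- cells$velocity_um_s / (fps * pixel_size)
  if (any(step_px > nx))
    stop("cell displacement per frame exceeds the channel length",
         call. = FALSE)
  y_px <- if (!is.null(cells$y_px)) cells$y_px else
    rep((ny - 1) / 2, nrow(cells))

  frames <- array(background, dim = c(ny, nx, n_frames))
  xs <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  ysm <- matrix(0:(ny - 1), ny, nx)
  sx <- cell_radius_px
  sy <- cell_radius_px * 0.7
  truth <- vector("list", n_frames)

  for (f in seq_len(n_frames)) {
    fr0 <- f - 1L  # 0-based frame index
    img <- frames[, , f]
    rows <- NULL
    for (i in seq_len(nrow(cells))) {
      cx <- (fr0 - cells$entry_frame[i]) * step_px[i]
      if (fr0 < cells$entry_frame[i] || cx > nx - 1) next
      img <- img - depth * exp(-((xs - cx)^2 / (2 * sx^2) +
                                 (ysm - y_px[i])^2 / (2 * sy^2)))
      rows <- rbind(rows, data.frame(frame = fr0, cell_id = i,
                                     x_px = cx, y_px = y_px[i]))
    }
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    frames[, , f] <- pmin(pmax(img, 0), 1)
    truth[[f]] <- rows
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), cell_id = integer(0),
                        x_px = numeric(0), y_px = numeric(0))
  list(frames = frames, truth = truth, fps = fps, pixel_size = pixel_size)
}

#' Write / read a grayscale image stack as multi-page TIFF
#'
#' @param frames Array (height x width x frames) with values in \[0, 1\].
#' @param path File path.
#' @return `read_tiff_stack()` returns such an array.
#' @export
write_tiff_stack <- function(frames, path) {
  pages <- lapply(seq_len(dim(frames)[3]), function(f) frames[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}
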