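# Cell tracking in microchannel image stacks: intensity-threshold
# detection with connected components, nearest-neighbor frame-to-frame
# linking, and robust per-track velocity estimation.

# Detect dark blobs in one grayscale frame. Returns data.frame(x, y)
# of intensity-weighted centroids in 0-based pixel coordinates.
detect_cells_frame <- function(img, threshold, min_area) {
  mask <- img < threshold
  if (!any(mask)) return(data.frame(x = numeric(0), y = numeric(0)))
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  keep <- lab > 0L
  if (!any(keep)) return(data.frame(x = numeric(0), y = numeric(0)))
  ny <- nrow(img)
  idx <- which(keep)
  lb <- lab[idx]
  # 0-based pixel coordinates; weight by darkness below threshold
  yy <- (idx - 1L) %% ny
  xx <- (idx - 1L) %/% ny
  w <- pmax(threshold - img[idx], 1e-9)
  area <- tabulate(lb)
  sw <- rowsum(w, lb)[, 1]
  cx <- rowsum(w * xx, lb)[, 1] / sw
  cy <- rowsum(w * yy, lb)[, 1] / sw
  ok <- area >= min_area
  data.frame(x = cx[ok], y = cy[ok])
}

#' Track cells through a microchannel image stack
#'
#' Detection: pixels darker than `threshold` (cells are dark on a bright
#' background) are labelled into connected components; components smaller
#' than `min_area` pixels are discarded; positions are darkness-weighted
#' centroids. Linking: each detection in frame t+1 is assigned to the
#' nearest track position from frame t within `max_disp` pixels, shortest
#' displacement first, ties broken by lowest track id; unassigned
#' detections open new tracks.
#'
#' @param frames Image stack: array (height x width x frames) or list of
#'   matrices, gray levels in \[0, 1\].
#' @param threshold Detection threshold; default
#'   `background - 0.25 * (background - minimum)` with the background
#'   taken as the median pixel value of the stack.
#' @param min_area Minimum component area in pixels (default 5).
#' @param max_disp Maximum per-frame displacement gate in pixels
#'   (default 15).
#' @return `data.frame` with `frame` (0-based), `track_id`, `x`, `y`;
#'   empty (zero rows) when nothing is detected.
#' @export
track_cells <- function(frames, threshold = NULL, min_area = 5L,
                        max_disp = 15) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  if (is.null(frames) || length(dim(frames)) != 3L || dim(frames)[3] < 1L)
    stop("`frames` must be a nonempty image stack", call. = FALSE)
  if (is.null(threshold)) {
    bg <- stats::median(frames)
    threshold <- bg - 0.25 * (bg - min(frames))
    if (threshold >= bg) threshold <- bg - 1e-6
  }

  n_frames <- dim(frames)[3]
  out <- vector("list", n_frames)
  active <- data.frame(track_id = integer(0), x = numeric(0),
                       y = numeric(0))
  next_id <- 1L

  for (f in seq_len(n_frames)) {
    det <- detect_cells_frame(frames[, , f], threshold, min_area)
    n_det <- nrow(det)
    assigned <- integer(n_det)  # track id per detection, 0 = new
    if (n_det > 0L && nrow(active) > 0L) {
      d <- outer(det$x, active$x, "-")^2 + outer(det$y, active$y, "-")^2
      d <- sqrt(d)
      # greedy: repeatedly take the globally smallest admissible pair
      repeat {
        dmin <- min(d)
        if (!is.finite(dmin) || dmin > max_disp) break
        hit <- which(d == dmin, arr.ind = TRUE)
        # ties: lowest track id, then lowest detection index
        hit <- hit[order(active$track_id[hit[, 2]], hit[, 1]), ,
                   drop = FALSE]
        i <- hit[1, 1]; j <- hit[1, 2]
        assigned[i] <- active$track_id[j]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    if (n_det > 0L) {
      new <- assigned == 0L
      if (any(new)) {
        assigned[new] <- seq.int(next_id, length.out = sum(new))
        next_id <- next_id + sum(new)
      }
      out[[f]] <- data.frame(frame = f - 1L, track_id = assigned,
                             x = det$x, y = det$y)
      active <- data.frame(track_id = assigned, x = det$x, y = det$y)
    } else {
      active <- active[0, ]
    }
  }
  traj <- do.call(rbind, out)
  if (is.null(traj))
    traj <- data.frame(frame = integer(0), track_id = integer(0),
                       x = numeric(0), y = numeric(0))
  traj[order(traj$track_id, traj$frame), , drop = FALSE]
}

# Theil-Sen slope: median of pairwise slopes. Robust to single
# mis-detections within a track.
theil_sen_slope <- function(x, y) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  stats::median((y[pairs[2, ]] - y[pairs[1, ]]) /
                  (x[pairs[2, ]] - x[pairs[1, ]]))
}

#' Per-track transit velocities from trajectories
#'
#' The velocity of each track is the Theil-Sen (median-of-pairwise)
#' slope of x versus frame, converted to um/s. Tracks spanning fewer
#' than `min_frames` detections are dropped and their count reported in
#' a message.
#'
#' @param trajectories `data.frame` from [track_cells()] (columns
#'   `frame`, `track_id`, `x`).
#' @param fps Frame rate of the recording.
#' @param pixel_size Microns per pixel.
#' @param min_frames Minimum detections per usable track (default 3).
#' @return `data.frame` with `track_id`, `n_frames`, `velocity_um_s`.
#' @export
transit_velocities <- function(trajectories, fps = 400, pixel_size = 0.5,
                               min_frames = 3L) {
  if (nrow(trajectories) == 0L)
    return(data.frame(track_id = integer(0), n_frames = integer(0),
                      velocity_um_s = numeric(0)))
  split_t <- split(trajectories, trajectories$track_id)
  lens <- vapply(split_t, nrow, integer(1))
  dropped <- sum(lens < min_frames)
  if (dropped > 0L)
    message(dropped, " track(s) shorter than ", min_frames,
            " frames dropped")
  split_t <- split_t[lens >= min_frames]
  if (length(split_t) == 0L)
    return(data.frame(track_id = integer(0), n_frames = integer(0),
                      velocity_um_s = numeric(0)))
  data.frame(
    track_id = as.integer(names(split_t)),
    n_frames = vapply(split_t, nrow, integer(1)),
    velocity_um_s = vapply(split_t, function(tr)
      theil_sen_slope(tr$frame, tr$x) * fps * pixel_size, numeric(1)),
    row.names = NULL)
}

#' Normalize transit velocities to the wide-channel reference
#'
#' Microchannel velocities are expressed in arbitrary units relative to
#' the mean cell velocity in wide channels, which matches the bulk flow
#' velocity; 1 a.u. therefore means "moving with the flow".
#'
#' @param velocities Velocities in um/s (vector, or the data frame from
#'   [transit_velocities()]).
#' @param wide_channel_mean Mean wide-channel velocity (um/s), > 0.
#' @return Normalized velocities (a.u.), same shape as the input.
#' @export
normalize_velocities <- function(velocities, wide_channel_mean) {
  if (wide_channel_mean <= 0)
    stop("`wide_channel_mean` must be positive", call. = FALSE)
  if (is.data.frame(velocities)) {
    velocities$velocity_au <-
      velocities$velocity_um_s / wide_channel_mean
    return(velocities)
  }
  velocities / wide_channel_mean
}

#' Detect occluded channels from stationary tracks
#'
#' A channel is called occluded when a track stays within `tol` pixels
#' of one position for at least `min_frames` consecutive frames: an
#' arrested cell blocking the channel.
#'
#' @param trajectories `data.frame` from [track_cells()].
#' @param tol Positional tolerance in pixels (default 2).
#' @param min_frames Minimum stationary run length (default 100, i.e.
#'   0.25 s at 400 fps).
#' @return Integer vector of track ids classified as arrested.
#' @export
detect_occlusions <- function(trajectories, tol = 2, min_frames = 100L) {
  ids <- integer(0)
  for (tr in split(trajectories, trajectories$track_id)) {
    if (nrow(tr) < min_frames) next
    x <- tr$x[order(tr$frame)]
    y <- tr$y[order(tr$frame)]
    # longest run where position stays within tol of the run's start
    run <- 1L
    anchor <- 1L
    for (i in seq_along(x)[-1]) {
      if (sqrt((x[i] - x[anchor])^2 + (y[i] - y[anchor])^2) <= tol) {
        run <- i - anchor + 1L
        if (run >= min_frames) {
          ids <- c(ids, tr$track_id[1])
          break
        }
      } else {
        anchor <- i
        run <- 1L
      }
    }
  }
  ids
}
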