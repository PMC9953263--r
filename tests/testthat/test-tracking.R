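test_that("a single rendered cell is tracked at its programmed speed", {
  # entry_frame -4 puts the blob fully inside the field from frame 0
  mv <- render_microchannel_frames(
    data.frame(entry_frame = -4, velocity_um_s = 5 * 400 * 0.5),
    n_frames = 20)
  # ground truth is an arithmetic progression with step 5 px
  expect_equal(diff(mv$truth$x_px), rep(5, nrow(mv$truth) - 1))
  tr <- track_cells(mv$frames)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_true(all(abs(diff(tr$x) - 5) < 0.5))
})

test_that("blank frames yield an empty trajectory table", {
  mv <- render_microchannel_frames(NULL, n_frames = 5)
  expect_equal(nrow(mv$truth), 0L)
  tr <- track_cells(mv$frames)
  expect_equal(nrow(tr), 0L)
})

test_that("two separated cells keep their identities", {
  mv <- render_microchannel_frames(
    data.frame(entry_frame = c(0, 10),
               velocity_um_s = c(1000, 1000), y_px = c(10, 30)),
    n_frames = 40)
  tr <- track_cells(mv$frames)
  v <- transit_velocities(tr, fps = 400, pixel_size = 0.5)
  expect_equal(nrow(v), 2L)
  expect_true(all(abs(v$velocity_um_s - 1000) < 1 * 400 * 0.5))
  # no identity swaps: each track stays in its own lane
  for (id in unique(tr$track_id))
    expect_lt(diff(range(tr$y[tr$track_id == id])), 2)
})

test_that("velocity arithmetic and normalization are exact", {
  traj <- data.frame(frame = 0:9, track_id = 1L,
                     x = 5 * (0:9), y = 20)
  v <- transit_velocities(traj, fps = 400, pixel_size = 0.5)
  expect_equal(v$velocity_um_s, 1000)
  expect_equal(normalize_velocities(1000, 2000), 0.5)
  # self-normalization of the reference cells
  set.seed(1)
  wide <- rnorm(500, 2000, 100)
  expect_lt(abs(mean(normalize_velocities(wide, mean(wide))) - 1), 0.02)
})

test_that("tracks shorter than three frames are dropped with a note", {
  traj <- data.frame(frame = c(0, 1, 0, 1, 2, 3),
                     track_id = c(1, 1, 2, 2, 2, 2),
                     x = c(0, 5, 0, 5, 10, 15), y = 0)
  expect_message(v <- transit_velocities(traj), "dropped")
  expect_equal(v$track_id, 2L)
})

test_that("rendering rejects displacements beyond the channel", {
  expect_error(render_microchannel_frames(
    data.frame(entry_frame = 0, velocity_um_s = 300 * 400 * 0.5),
    n_frames = 5, geometry = list(length_px = 100, width_px = 20)),
    "exceeds")
})

test_that("an arrested cell is flagged as an occlusion", {
  traj <- data.frame(frame = 0:149, track_id = 1L,
                     x = 50 + rnorm(150, 0, 0.3), y = 20)
  expect_equal(detect_occlusions(traj), 1L)
  moving <- data.frame(frame = 0:149, track_id = 2L,
                       x = 2 * (0:149), y = 20)
  expect_length(detect_occlusions(moving), 0L)
})

test_that("image stacks round-trip through multi-page TIFF", {
  mv <- render_microchannel_frames(
    data.frame(entry_frame = 0, velocity_um_s = 1000),
    n_frames = 4, geometry = list(length_px = 60, width_px = 20))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(mv$frames, path)
  back <- read_tiff_stack(path)
  expect_equal(dim(back), dim(mv$frames))
  expect_lt(max(abs(back - mv$frames)), 1 / 255)
})
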