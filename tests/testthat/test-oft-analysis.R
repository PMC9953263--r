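test_that("resistance summary reads exact grid points", {
  curve <- data.frame(osmolality = c(160, 150, 140, 130, 120),
                      lysed_pct = c(0, 10, 50, 90, 100))
  rs <- resistance_summary(curve)
  expect_equal(rs$h50, 140)
  expect_equal(rs$h10, 150)
  expect_equal(rs$h90, 130)
  expect_equal(rs$w, 20)
})

test_that("thresholds are located by linear interpolation", {
  curve <- data.frame(osmolality = c(160, 150, 140, 130),
                      lysed_pct = c(0, 20, 60, 100))
  rs <- resistance_summary(curve)
  expect_equal(rs$h50, 142.5)
})

test_that("a curve that never crosses a threshold names it", {
  curve <- data.frame(osmolality = c(160, 140, 120),
                      lysed_pct = c(0, 20, 40))
  expect_error(resistance_summary(curve), "50%")
})

test_that("no lysis anywhere gives a flat 0% curve", {
  cells <- constant_population(500, lysis_osm = 50)
  rec <- simulate_oft_recording(cells, noise_sd = 0, seed = 1)
  curve <- lysed_fraction_curve(rec)
  expect_equal(curve$lysed_pct, rep(0, nrow(curve)), tolerance = 1e-8)
})

test_that("lysis at the first hypotonic step gives 100% from there on", {
  cells <- constant_population(500, lysis_osm = 295)
  rec <- simulate_oft_recording(cells, noise_sd = 0, seed = 2)
  curve <- lysed_fraction_curve(rec)
  expect_equal(curve$lysed_pct[curve$osmolality == 300], 0)
  expect_equal(curve$lysed_pct[curve$osmolality < 300],
               rep(100, sum(curve$osmolality < 300)))
})

test_that("estimated curve matches generator truth on noiseless data", {
  spec <- population_spec(n_cells = 5000,
                          lysis_osm = list(mean = 142, sd = 8),
                          seed = 3)
  cells <- sample_population(spec)
  rec <- simulate_oft_recording(cells, noise_sd = 0, seed = 4)
  curve <- lysed_fraction_curve(rec)
  expect_lt(max(abs(curve$lysed_pct -
                      100 * rec$lysed_truth$lysed_fraction)), 1)
  # symmetry of the normal: interpolating the curve at the generating
  # mean lands close to 50% lysis
  est <- stats::approx(curve$osmolality, curve$lysed_pct,
                       xout = 142)$y
  expect_lt(abs(est - 50), 2)
})

test_that("hemolysis curves are monotone after regularization", {
  spec <- population_spec(n_cells = 1000,
                          lysis_osm = list(mean = 150, sd = 15), seed = 5)
  cells <- sample_population(spec)
  for (s in 1:5) {
    rec <- simulate_oft_recording(cells, noise_sd = 0.05, seed = s)
    curve <- lysed_fraction_curve(rec)
    expect_true(all(diff(curve$lysed_pct) >= 0))
  }
})

test_that("H50 estimator recovers the generating mean across seeds", {
  h50 <- vapply(1:20, function(s) {
    spec <- population_spec(n_cells = 5000,
                            lysis_osm = list(mean = 142, sd = 8),
                            seed = 100 + s)
    cells <- sample_population(spec)
    rec <- simulate_oft_recording(cells, noise_sd = 0.01,
                                  seed = 200 + s)
    resistance_summary(lysed_fraction_curve(rec))$h50
  }, numeric(1))
  expect_lt(abs(mean(h50) - 142), 0.5)
  expect_lt(stats::sd(h50), 1)
})

test_that("MCV_osm curve is anchored and follows van't Hoff swelling", {
  cells <- constant_population(400, v300 = 84.6, vs = 70.6,
                               lysis_osm = 50)
  rec <- simulate_oft_recording(cells, noise_sd = 0, seed = 6)
  mc <- mcv_osm_curve(rec, mcv_300 = 84.6)
  expect_equal(mc$mcv_fl[mc$osmolality == 300], 84.6)
  expect_lt(abs(mc$mcv_fl[mc$osmolality == 200] - 91.6), 0.5)
})

test_that("osmotically inactive cells give a flat MCV_osm curve", {
  cells <- constant_population(300, v300 = 90, vs = 90 * 0.99,
                               lysis_osm = 50)
  cells$vs <- cells$v300  # no osmotic water at all
  rec <- simulate_oft_recording(cells, noise_sd = 0, seed = 7)
  mc <- mcv_osm_curve(rec, mcv_300 = 90)
  expect_equal(mc$mcv_fl, rep(90, nrow(mc)), tolerance = 1e-8)
})

test_that("asphericity index is zero for a constant trace", {
  rec <- make_recording(list("300" = rep(100, 300)))
  expect_equal(asphericity_index(rec), 0)
})

test_that("asphericity index equals peak-to-peak/mean for a sinusoid", {
  n <- 1000
  trace <- 100 + 10 * sin(2 * pi * 50 * (1:n) / n)
  rec <- make_recording(list("300" = trace))
  expect_equal(asphericity_index(rec), 20, tolerance = 1e-3)
})

test_that("asphericity index requires a long enough plateau", {
  rec <- make_recording(list("300" = rep(100, 50)))
  expect_error(asphericity_index(rec), "too short")
})

test_that("missing 300 mOsmol reference is an error", {
  rec <- make_recording(list("250" = rep(100, 300)))
  expect_error(lysed_fraction_curve(rec), "300 mOsmol")
})
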