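test_that("per-experiment densities normalize and average correctly", {
  # all mass in one bin
  p <- velocity_pdf(rep(1.01, 100), bin_width = 0.025)
  expect_equal(max(p$density_mean), 1 / 0.025)
  expect_equal(sum(p$density_mean) * 0.025, 1, tolerance = 1e-9)
  # two identical experiments: zero SE everywhere
  v <- pmax(rnorm(2000, 1, 0.2), 0)
  p2 <- velocity_pdf(list(v, v))
  expect_equal(max(p2$density_se), 0)
  # every experiment integrates to 1
  dm <- attr(p2, "density_matrix")
  expect_equal(colSums(dm) * 0.025, c(1, 1), tolerance = 1e-6)
})

test_that("averaged pdf tracks the generating normal density", {
  set.seed(42)
  draws <- lapply(1:10, function(i) rnorm(5000, 1.0, 0.15))
  p <- velocity_pdf(draws)
  true_d <- dnorm(p$bin_center, 1.0, 0.15)
  se <- pmax(p$density_se, 1e-6)
  expect_true(all(abs(p$density_mean - true_d) <= 3 * se + 0.05))
})

test_that("slow fraction is a direct count below the cutoff", {
  fr <- slow_fast_fractions(c(0.1, 0.5, 1.0, 1.2), cutoff_slow = 0.175)
  expect_equal(fr$slow_fraction, 25)
  fr2 <- slow_fast_fractions(c(0.1, 0.5, 1.0, 1.2),
                             cutoff_fast = 1.1)
  expect_equal(fr2$fast_fraction, 25)
})

test_that("a tight main peak leaves nothing below the cutoff", {
  set.seed(7)
  v <- rnorm(1e5, 1.0, 0.15)  # 0.175 sits 5.5 SD below the mean
  fr <- slow_fast_fractions(v)
  expect_lte(fr$slow_fraction / 100, 1e-4)
})

test_that("mixture slow weights are recovered within sampling error", {
  w <- 0.089
  se3 <- 3 * sqrt(w * (1 - w) / 20000) * 100
  est <- vapply(1:5, function(s) {
    d <- simulate_velocity_dataset(mixture_spec(20000, w, seed = s))
    slow_fast_fractions(d)$slow_fraction
  }, numeric(1))
  expect_lt(abs(mean(est) - 100 * w), se3)
})

test_that("cutoff calibration inverts the control tail construction", {
  set.seed(3)
  v <- pmax(rnorm(20000, 1.0, 0.316), 0)
  expect_lt(abs(calibrate_cutoff(v) - 0.175), 0.02)
  expect_equal(calibrate_cutoff(v, tail_mass = 0),
               min(v))
  expect_lt(abs(calibrate_cutoff(v, tail_mass = 0.5) - median(v)),
            1e-3)
  expect_error(calibrate_cutoff(v[1:500]), "1,000")
})

test_that("calibration followed by counting returns the tail mass", {
  set.seed(4)
  v <- pmax(rnorm(20000, 1.0, 0.30), 0)
  cutoff <- calibrate_cutoff(v, tail_mass = 0.0045)
  got <- slow_fast_fractions(v, cutoff_slow = cutoff)$slow_fraction
  one_cell <- 100 / length(v)
  expect_lte(abs(got - 0.45), one_cell + 1e-9)
})

test_that("occlusion rate counts flagged channels", {
  expect_equal(occlusion_rate(c(rep(TRUE, 2), rep(FALSE, 6)))$
                 occlusion_rate, 25)
  expect_equal(occlusion_rate(rep(FALSE, 10))$occlusion_rate, 0)
  expect_error(occlusion_rate(logical(0)), "zero channels")
})

test_that("zero adhesion never occludes; Bernoulli adhesion does", {
  spec0 <- population_spec(n_cells = 200, adhesion_propensity = 0,
                           seed = 1)
  d0 <- simulate_velocity_dataset(spec0, n_channels = 50)
  expect_equal(sum(d0$channel_occluded), 0L)

  # one cell per channel on average, p = 0.1
  spec1 <- population_spec(n_cells = 200, adhesion_propensity = 0.1,
                           seed = 2)
  rates <- vapply(1:5, function(s) {
    d <- simulate_velocity_dataset(spec1, n_channels = 200,
                                   seed = 10 + s)
    # per-channel occlusion prob 1-(1-p)^k, k ~ Binomial(200, 1/200)
    occlusion_rate(d)$occlusion_rate
  }, numeric(1))
  p_chan <- 1 - mean((1 - 0.1)^stats::rbinom(1e5, 200, 1 / 200))
  se3 <- 3 * sqrt(p_chan * (1 - p_chan) / (200 * 5)) * 100
  expect_lt(abs(mean(rates) - 100 * p_chan), se3 + 1)
})

test_that("velocity datasets round-trip through CSV", {
  d <- simulate_velocity_dataset(mixture_spec(500, 0.1, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_velocity_csv(d, path)
  back <- read_velocity_csv(path)
  expect_equal(back$velocities, d$velocities)
  expect_equal(which(back$channel_occluded),
               which(d$channel_occluded))
})
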