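test_that("volume histograms conserve counts", {
  h <- simulate_volume_histogram(rep(90, 250))
  expect_equal(sum(h$count), 250)
  expect_equal(sum(h$count > 0), 1L)  # single occupied bin
  set.seed(1)
  h2 <- simulate_volume_histogram(rnorm(5000, 90, 10))
  expect_equal(sum(h2$count), 5000)
})

test_that("cytometry event tables honor their generating parameters", {
  ev <- simulate_cytometry_events(n_events = 20000,
                                  fitc = list(meanlog = log(100),
                                              sdlog = 0.4),
                                  seed = 2)
  expect_true(all(ev$fsc >= 0 & ev$ssc >= 0 & ev$fitc >= 0))
  expect_lt(abs(median(ev$fitc) - 100) / 100, 0.05)
  expect_identical(ev, simulate_cytometry_events(n_events = 20000,
                                                 fitc = list(
                                                   meanlog = log(100),
                                                   sdlog = 0.4),
                                                 seed = 2))
})

test_that("RDW-SD approaches the Gaussian 20%-height width", {
  set.seed(3)
  vols <- rnorm(50000, 90, 10)
  h <- hematology_summary(vols)
  expect_lt(abs(h$rdw_sd - 3.588 * 10) / (3.588 * 10), 0.03)
  expect_lt(abs(h$rdw_cv - 100 * 10 / 90), 0.3)
  expect_lt(abs(h$mcv - 90), 0.2)
})

test_that("identical volumes give zero width", {
  h <- hematology_summary(rep(88, 600))
  expect_equal(h$rdw_sd, 0)
  expect_equal(h$rdw_cv, 0)
  expect_equal(h$mcv, 88)
})

test_that("MFI normalization subtracts the negative control", {
  expect_equal(mfi_percent(rep(100, 10), rep(100, 10), 0), 100)
  expect_equal(mfi_percent(rep(50, 10), rep(100, 10), 0), 50)
  expect_equal(mfi_percent(rep(50, 10), rep(100, 10), 1.1),
               (50 - 1.1) / (100 - 1.1) * 100)
  expect_error(mfi_percent(rep(50, 10), rep(1, 10), 5),
               "negative control")
})

test_that("MFI percent is invariant to a shared affine gain", {
  set.seed(4)
  t0 <- rlnorm(1000, log(50), 0.3)
  c0 <- rlnorm(1000, log(100), 0.3)
  n0 <- rlnorm(1000, log(2), 0.3)
  base <- mfi_percent(t0, c0, mean(n0))
  gained <- mfi_percent(3 * t0 + 7, 3 * c0 + 7, mean(3 * n0 + 7))
  expect_equal(gained, base, tolerance = 1e-10)
})

test_that("positivity gating against an unstained control works", {
  un <- simulate_cytometry_events(n_events = 5000, seed = 5)
  # identical sample: about the gate's own tail is called positive
  expect_lt(abs(positive_fraction(un, un) - 0.5), 0.3)
  # everything brighter than the unstained maximum
  bright <- un
  bright$fitc <- bright$fitc + max(un$fitc)
  expect_equal(positive_fraction(bright, un), 100)
  # planted positive subpopulation, 10-fold brighter
  st <- simulate_cytometry_events(n_events = 20000,
                                  positive_fraction = 0.10,
                                  positive_fold = 10, seed = 6)
  se3 <- 3 * sqrt(0.1 * 0.9 / 20000) * 100
  expect_lt(abs(positive_fraction(st, un) - 10), se3 + 0.5)
  expect_error(positive_fraction(st, un$fitc[1:100]), "1,000")
})

test_that("microparticle gate counts small events", {
  ev <- simulate_cytometry_events(n_events = 20000,
                                  microparticle_fraction = 0.05,
                                  seed = 7)
  gate <- 100 - 3 * 15  # below the main FSC population
  got <- microparticle_fraction(ev, size_gate = gate)
  se3 <- 3 * sqrt(0.05 * 0.95 / 20000) * 100
  expect_lt(abs(got - 5), se3 + 0.5)
  expect_equal(microparticle_fraction(c(50, 60), size_gate = 10), 0)
  expect_equal(microparticle_fraction(c(50, 60), size_gate = 100), 100)
})
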