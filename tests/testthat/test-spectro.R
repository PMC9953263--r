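test_that("pure species spectra unmix to a single component", {
  for (i in 1:3) {
    f <- c(0, 0, 0); f[i] <- 1
    sp <- simulate_absorbance(f, total_hb = 0.1, noise_sd = 0)
    got <- hb_species_fractions(sp)$fractions
    expect_equal(unname(got), f, tolerance = 1e-10)
  }
})

test_that("noiseless mixtures are recovered exactly", {
  f <- c(0.7, 0.2, 0.1)
  sp <- simulate_absorbance(f, total_hb = 0.05, noise_sd = 0)
  got <- hb_species_fractions(sp)
  expect_lt(max(abs(got$fractions - f)), 1e-8)
  expect_lt(got$residual, 1e-10)
})

test_that("fractions are invariant to uniform OD scaling", {
  f <- c(0.5, 0.3, 0.2)
  sp <- simulate_absorbance(f, total_hb = 0.05, noise_sd = 0,
                            turbidity_offset = 0)
  scaled <- sp
  scaled$od <- sp$od * 3.7
  expect_equal(hb_species_fractions(scaled)$fractions,
               hb_species_fractions(sp)$fractions, tolerance = 1e-10)
})

test_that("NNLS agrees with the plain linear solve when nonnegative", {
  E <- default_extinction_matrix()[c("560", "577", "630"), ]
  set.seed(11)
  for (i in 1:20) {
    f <- stats::runif(3)
    f <- f / sum(f)
    sp <- simulate_absorbance(f, total_hb = 0.08, noise_sd = 0)
    a <- sp$od[c("560", "577", "630")] - sp$od["700"]
    exact <- solve(E, a)
    if (all(exact >= 0)) {
      got <- hb_species_fractions(sp)$concentrations
      expect_equal(unname(got), unname(exact), tolerance = 1e-8)
    }
  }
})

test_that("species fractions are robust to realistic OD noise", {
  f <- c(0.6, 0.3, 0.1)
  err <- vapply(1:100, function(s) {
    sp <- simulate_absorbance(f, total_hb = 0.1, noise_sd = 0.005,
                              seed = s)
    hb_species_fractions(sp)$fractions - f
  }, numeric(3))
  expect_lt(sqrt(mean(err^2)), 0.02)
})

test_that("free hemoglobin percent follows the 540/700 arithmetic", {
  lys <- structure(list(od = c("540" = 2.1, "700" = 0.1),
                        dilution_factor = 20, role = "whole_lysate"),
                   class = "absorbance_spectrum")
  sup <- structure(list(od = c("540" = 0.5, "700" = 0.1),
                        dilution_factor = 20, role = "supernatant"),
                   class = "absorbance_spectrum")
  expect_equal(free_hb_percent(sup, lys), 20)        # 0.4 / 2.0
  expect_equal(free_hb_percent(lys, lys), 100)       # self-reference
  turb <- structure(list(od = c("540" = 0.1, "700" = 0.1),
                         dilution_factor = 20, role = "supernatant"),
                    class = "absorbance_spectrum")
  expect_equal(free_hb_percent(turb, lys), 0)        # pure turbidity
  # shared dilution factor cancels
  sup2 <- sup; sup2$dilution_factor <- 5
  lys2 <- lys; lys2$dilution_factor <- 5
  expect_equal(free_hb_percent(sup2, lys2), 20)
})

test_that("degenerate spectra are rejected with clear errors", {
  expect_error(simulate_absorbance(c(0.5, 0.2, 0.2)), "sum to 1")
  blank <- simulate_absorbance(c(1, 0, 0), total_hb = 0,
                               turbidity_offset = 0.1, noise_sd = 0)
  expect_equal(unname(blank$od), rep(0.1, 5))  # turbidity only
  expect_error(hb_species_fractions(blank), "all zero|no hemoglobin")
  expect_error(free_hb_percent(blank, blank), "not positive")
  bad <- default_extinction_matrix()
  bad[, "metHb"] <- bad[, "oxyHb"] * (1 + 1e-9)
  sp <- simulate_absorbance(c(0.7, 0.2, 0.1), total_hb = 0.05)
  expect_error(hb_species_fractions(sp, extinction_matrix = bad),
               "ill-conditioned")
})
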