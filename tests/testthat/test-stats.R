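test_that("the normality screen separates clear cases", {
  set.seed(1)
  expect_gt(dagostino_pearson_test(rnorm(200))$p.value, 0.01)
  expect_lt(dagostino_pearson_test(rexp(200))$p.value, 0.001)
  expect_error(dagostino_pearson_test(rnorm(5)), "at least 8")
})

test_that("identical constant groups compare as a null family", {
  g <- list(Control = rep(1, 10), A = rep(1, 10), B = rep(1, 10))
  cmp <- compare_groups(g)
  expect_equal(cmp$statistic, 0)
  expect_true(all(cmp$pairwise$tier == "ns"))
})

test_that("a strongly shifted group is flagged at the top tier", {
  set.seed(2)
  g <- list(Control = rnorm(50), A = rnorm(50), B = rnorm(50, 5))
  cmp <- compare_groups(g)
  expect_match(cmp$method, "ANOVA")
  pw <- cmp$pairwise
  expect_equal(pw$tier[pw$group == "B"], "****")
  expect_equal(pw$tier[pw$group == "A"], "ns")
})

test_that("a non-normal group switches the family to the rank branch", {
  set.seed(3)
  g <- list(Control = rnorm(60), A = rnorm(60),
            B = rexp(60)^3)  # heavy-tailed
  cmp <- compare_groups(g)
  expect_match(cmp$method, "Kruskal")
  # and the branch still detects a real shift
  g2 <- list(Control = rnorm(60), A = rexp(60)^3 + 5, B = rnorm(60))
  cmp2 <- compare_groups(g2)
  expect_true(cmp2$pairwise$p_adjusted[cmp2$pairwise$group == "A"] <
                0.001)
})

test_that("group sizes and tier thresholds are enforced", {
  g <- list(Control = rnorm(10), A = rnorm(3), B = rnorm(10))
  expect_error(compare_groups(g), "at least 5")
  p <- c(2e-5, 5e-4, 5e-3, 0.04, 0.5)
  tiers <- rbcassay:::significance_tier(p)
  expect_equal(tiers, c("****", "***", "**", "*", "ns"))
})

test_that("Dunn-adjusted p-values never undercut the unadjusted ones", {
  set.seed(4)
  g <- list(Control = rexp(30), A = rexp(30) + 0.5, B = rexp(30),
            C = rexp(30) + 1)
  cmp <- compare_groups(g)
  expect_match(cmp$method, "Dunn")
  expect_true(all(cmp$pairwise$p_adjusted >=
                    cmp$pairwise$p_unadjusted - 1e-12))
  expect_true(all(cmp$pairwise$p_adjusted <= 1))
})

test_that("dose arithmetic is linear and matches the worked example", {
  d <- dose_to_concentration(175)
  expect_equal(d$blood_ug_ml, 175 * 1.81 / 4.5, tolerance = 1e-12)
  expect_equal(d$blood_ug_ml, 70.39, tolerance = 1e-3)
  expect_equal(dose_to_concentration(0)$blood_ug_ml, 0)
  expect_equal(dose_to_concentration(350)$blood_ug_ml,
               2 * d$blood_ug_ml)
  expect_equal(dose_to_concentration(175,
                                     blood_volume = 9)$blood_ug_ml,
               d$blood_ug_ml / 2)
})

test_that("suspension hematocrit sits in the physiologic band", {
  hct <- suspension_hematocrit(5e8, 84.6)
  expect_equal(hct, 4.23)
  expect_gte(hct, 4)
  expect_lte(hct, 4.5)
})
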