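# Replacement-rate estimators, the resorption-pit overlay, minimum
# handling, and tooth longevity.

test_that("direct subtraction conserves ages exactly", {
  est <- replacement_rate_direct(459, 354)
  expect_identical(est$rate_days, 105L)
  expect_identical(est$method, "direct")
  expect_false(est$is_minimum)
  expect_identical(replacement_rate_direct(147, 43)$rate_days, 104L)
  expect_identical(replacement_rate_direct(200, 0)$rate_days, 200L)
  # property: rate + replacement age = functional age, for arbitrary pairs
  set.seed(9)
  for (i in 1:50) {
    a <- sample(50:700, 1); b <- sample(0:(a - 1), 1)
    expect_identical(replacement_rate_direct(a, b)$rate_days + b, a)
  }
  expect_error(replacement_rate_direct(100, 100), class = "inconsistent_family")
  expect_error(replacement_rate_direct(100, 150), class = "inconsistent_family")
})

test_that("the replacement height is two-thirds of the pit height", {
  expect_equal(estimated_replacement_height(54), 36)
  expect_identical(estimated_replacement_height(0), 0)
  expect_equal(estimated_replacement_height(100), 66.667, tolerance = 1e-4)
  expect_error(estimated_replacement_height(-1), class = "invalid_measurement")
})

test_that("apex-line counting is inclusive at the boundary and monotone", {
  p <- apex_profile(c(10, 20, 30, 40))
  expect_identical(count_lines_from_apex(p, 25), 2L)
  expect_identical(count_lines_from_apex(p, 30), 3L)  # inclusive tie
  expect_identical(count_lines_from_apex(p, 0), 0L)
  expect_identical(count_lines_from_apex(p, 1e6), 4L) # beyond profile: full count
  # monotone non-decreasing in height, bounded by the profile length
  hs <- seq(0, 60, by = 2.5)
  counts <- vapply(hs, function(h) count_lines_from_apex(p, h), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= 4L))
  # uniform 1-um-per-line profile: the count equals the height
  u <- apex_profile(seq_len(100))
  expect_identical(count_lines_from_apex(u, 36), 36L)
  expect_identical(estimate_missing_replacement_age(u, 54), 36L)
  expect_identical(estimate_missing_replacement_age(u, 0), 0L)
})

test_that("pit-estimated replacement age composes into the published rate", {
  # functional tooth of 171 days whose pit-estimated successor is 36 days
  u <- apex_profile(seq_len(171))
  rep_age <- estimate_missing_replacement_age(u, 54)  # (2/3) * 54 = 36 lines
  expect_identical(rep_age, 36L)
  expect_identical(171L - rep_age, 135L)
})

test_that("dentine-extent ages divide extent by mean width", {
  expect_identical(dentine_extent_age(100, 10), 10L)
  expect_identical(dentine_extent_age(780, 10), 78L)
  expect_error(dentine_extent_age(0, 10), class = "invalid_measurement")
  expect_error(dentine_extent_age(100, 0), class = "invalid_measurement")
  # synthetic round-trip at zero noise: recovered age within 10% of truth
  gp <- growth_params()
  for (seed in 1:20) {
    age <- 40 + 7 * seed
    sim <- simulate_tooth(gp, age, seed = seed)
    extent <- diff(range(sim$transect$boundary_positions))
    rec <- dentine_extent_age(extent, gp$mean_daily_width)
    expect_lt(abs(rec - age) / age, 0.10)
  }
})

test_that("family dispatch selects direct, pit, or minimum correctly", {
  f157 <- tooth_record("Colobomycter", "s", age_days = 157)
  r59 <- tooth_record("Colobomycter", "s", age_days = 59)
  est <- replacement_rate_for_family(tooth_family(f157, list(r59)))
  expect_identical(est$rate_days, 98L)
  expect_identical(est$method, "direct")

  # two replacements: the oldest (immediate successor) sets the rate
  f <- tooth_record("Mesenosaurus", "s", age_days = 100)
  r_old <- tooth_record("Mesenosaurus", "s", age_days = 61)
  r_new <- tooth_record("Mesenosaurus", "s", age_days = 20)
  est2 <- replacement_rate_for_family(tooth_family(f, list(r_old, r_new)))
  expect_identical(est2$rate_days, 39L)

  # resorption pit without replacement tooth: overlay on the apex profile
  fp <- tooth_record("Seymouria", "s", age_days = 171, rp_height = 54)
  prof <- apex_profile(seq_len(171))
  est3 <- replacement_rate_for_family(tooth_family(fp), prof)
  expect_identical(est3$rate_days, 135L)
  expect_identical(est3$method, "rp_height")
  expect_error(replacement_rate_for_family(tooth_family(fp)),
               class = "missing_profile")

  # neither: a minimum equal to the functional age
  fmin <- tooth_record("Haptodus", "s", age_days = 152)
  est4 <- replacement_rate_for_family(tooth_family(fmin))
  expect_identical(est4$rate_days, 152L)
  expect_identical(est4$method, "minimum")
  expect_true(est4$is_minimum)

  # a minimum functional age marks any estimate as a minimum
  fw <- tooth_record("Watongia", "s", age_days = 81, age_is_minimum = TRUE)
  rw <- tooth_record("Watongia", "s", age_days = 10)
  expect_true(replacement_rate_for_family(tooth_family(fw, list(rw)))$is_minimum)
})

test_that("family invariants are enforced", {
  f <- tooth_record("X", "s", age_days = 100)
  too_old <- tooth_record("X", "s", age_days = 100)
  expect_error(tooth_family(f, list(too_old)), class = "inconsistent_family")
  r1 <- tooth_record("X", "s", age_days = 20)
  r2 <- tooth_record("X", "s", age_days = 60)
  expect_error(tooth_family(f, list(r1, r2)), class = "inconsistent_family")
  expect_error(tooth_record("X", "s", age_days = 10, shed = TRUE, ankylosed = TRUE),
               class = "invalid_record")
})

test_that("functional period averages the attachment ages", {
  expect_identical(functional_period(227, c(106, 135)), 107L)
  expect_identical(functional_period(227, 135), 92L)
  expect_identical(functional_period(100, 100 - 17), 17L)
  expect_error(functional_period(100, numeric(0)), class = "invalid_input")
  expect_error(functional_period(100, c(50, 120)), class = "invalid_input")
})

test_that("longevity is the functional tooth's age, minimum flag carried", {
  f <- tooth_record("Dimetrodon", "s", age_days = 459)
  r <- tooth_record("Dimetrodon", "s", age_days = 354)
  fam <- tooth_family(f, list(r))
  lon <- tooth_longevity(fam)
  expect_identical(lon$days, 459L)
  expect_false(lon$is_minimum)
  # longevity always bounds the rate from above
  expect_gte(lon$days, replacement_rate_for_family(fam)$rate_days)

  fw <- tooth_record("Watongia", "s", age_days = 81, age_is_minimum = TRUE)
  lw <- tooth_longevity(tooth_family(fw))
  expect_identical(lw$days, 81L)
  expect_true(lw$is_minimum)
})

test_that("pit-estimator validation on intact synthetic families", {
  # mirror of the published accuracy check: apply the pit estimator to
  # families whose replacement tooth is intact and of known age, and bound
  # the deviation from the direct rate
  gp <- growth_params()
  devs <- vapply(1:60, function(s) {
    sim <- simulate_family(gp, 260, seed = 500 + s)
    direct <- replacement_rate_for_family(sim$family)$rate_days
    rp_age <- estimate_missing_replacement_age(sim$profile, sim$truth$rp_height)
    rp_rate <- sim$family$functional$age_days - rp_age
    abs(rp_rate - direct) / direct
  }, numeric(1))
  expect_lte(stats::median(devs), 0.15)
})
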