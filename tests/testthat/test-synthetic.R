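test_that("generators are deterministic in the seed and leave RNG state alone", {
  expect_identical(sim_growth_curve(42), sim_growth_curve(42))
  expect_identical(as.data.frame(sim_mortality_table(42)),
                   as.data.frame(sim_mortality_table(42)))
  f1 <- sim_fame_profiles(42, n = 2)
  f2 <- sim_fame_profiles(42, n = 2)
  expect_identical(f1[[1]]$species, f2[[1]]$species)
  expect_identical(sim_assay_readings(42)$readings,
                   sim_assay_readings(42)$readings)
  # a generator call does not perturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(sim_growth_curve(7)); b <- runif(1)
  expect_identical(a, b)
})

test_that("noiseless growth curve is exactly logistic with retrievable truth", {
  s <- sim_growth_curve(seed = 5, noise_sd = 0)
  truth <- attr(s, "truth")
  expect_equal(s$dw_gL, truth$analytic(s$time_days), tolerance = 1e-12)
  # lag phase holds the inoculum level
  expect_equal(s$dw_gL[s$time_days <= truth$lag_days],
               rep(truth$dw0, sum(s$time_days <= truth$lag_days)),
               tolerance = 1e-12)
  # trajectory is nondecreasing and bounded by the carrying capacity
  expect_true(all(diff(s$dw_gL) >= 0))
  expect_true(all(s$dw_gL <= truth$carrying_capacity))
  # far from capacity the mid-log endpoint rate matches the intrinsic rate
  big <- sim_growth_curve(seed = 5, noise_sd = 0, carrying_capacity = 50)
  mu_hat <- growth_rate(big$dw_gL[big$time_days == 2],
                        big$dw_gL[big$time_days == 16], 14)
  expect_lt(abs(mu_hat - 0.20) / 0.20, 0.02)
})

test_that("mortality generator matches its stated sigmoid in expectation", {
  # expected mortality at the half-lethal exposure is exactly 50%
  tab <- sim_mortality_table(seed = 1, exposures = c(10, 32, 60), t50 = 32)
  truth <- attr(tab, "truth")
  expect_equal(unname(truth$expected_mortality_pct["32"]), 50)
  # expected mortality is monotone in exposure
  expect_true(all(diff(truth$expected_mortality_pct) > 0))
  # near-infinite steepness degenerates to a step at t50
  step <- attr(sim_mortality_table(seed = 1, steepness = 1e6),
               "truth")$expected_mortality_pct
  expect_equal(unname(step[c("10", "20", "30")]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(step[c("40", "50", "60")]), rep(100, 3),
               tolerance = 1e-9)
  # default configuration is designed to hand the screen a 40 s optimum
  d40 <- attr(sim_mortality_table(seed = 2), "truth")$designed_dose(95)
  expect_equal(d40, 40)
  # counts respect the control ceiling
  expect_true(all(tab$treated <= tab$control))
})

test_that("compositional draws stay closed, respect zeros, and centre on the archetype", {
  draws <- sim_fame_profiles(seed = 3, archetype = "WS", n = 20)
  truth <- attr(draws, "truth")
  for (d in draws) {
    expect_equal(d$total, 100, tolerance = 1e-9)
    # not-detected species stay exactly zero
    zero_labels <- truth$archetype$species$label[
      truth$archetype$species$fraction == 0]
    expect_equal(d$species$fraction[d$species$label %in% zero_labels],
                 rep(0, length(zero_labels)))
  }
  # infinite concentration returns the (renormalized) archetype exactly
  exact <- sim_fame_profiles(seed = 3, archetype = "M8",
                             concentration = Inf)[[1]]
  arch <- attr(sim_fame_profiles(seed = 3, archetype = "M8",
                                 concentration = Inf), "truth")$archetype
  expect_equal(exact$species$fraction, arch$species$fraction,
               tolerance = 1e-12)

  # law of large numbers: mean class summary approaches the archetype's
  many <- sim_fame_profiles(seed = 4, archetype = "M8", n = 500)
  sums <- vapply(many, function(p) {
    s <- fa_class_summary(p)
    c(s$sfa_pct, s$pufa_pct, s$adu)
  }, numeric(3L))
  ref <- attr(many, "truth")$summary
  expect_lt(abs(mean(sums[1, ]) - ref$sfa_pct), 1)
  expect_lt(abs(mean(sums[2, ]) - ref$pufa_pct), 1)
  expect_lt(abs(mean(sums[3, ]) - ref$adu), 0.01)

  expect_error(sim_fame_profiles(1, archetype = "nope"), "unknown archetype")
})

test_that("assay generator records truth and clamps impossible signals", {
  gen <- sim_assay_readings(seed = 9, noise_sd = 0)
  expect_equal(gen$standards$signal,
               gen$truth$slope * gen$standards$concentration +
                 gen$truth$intercept, tolerance = 1e-12)
  expect_false(any(gen$standards$clamped))

  # negative noise cannot push a signal below zero
  neg <- sim_assay_readings(seed = 10, true_conc = c(blank = 0),
                            intercept = 0, noise_sd = 0.2,
                            standards_conc = c(0, 0.1, 0.2))
  expect_true(all(neg$standards$signal >= 0))
  expect_true(all(neg$readings$signal >= 0))
  some_neg <- any(neg$standards$clamped) || any(neg$readings$clamped)
  expect_true(some_neg)  # sd 0.2 around ~0 must clip at least once here
})
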