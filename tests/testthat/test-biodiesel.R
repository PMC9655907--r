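test_that("property regressions reduce to their intercepts at ADU 0", {
  p <- estimate_properties(adu = 0, lcsf = 0)
  expect_equal(p$cn, 62.876)
  expect_equal(p$kv, 5.2065)
  expect_equal(p$iv, 12.71)
  expect_equal(p$hhv, 38.534)
  expect_equal(p$density, 0.8726)
  expect_equal(p$cp, 19.994)
  expect_equal(p$cfpp, -16.477)
  expect_error(estimate_properties(-0.1, 0), "'adu'")
  expect_error(estimate_properties(0.5, -1), "'lcsf'")
})

test_that("LCSF weights long-chain saturates and supports both variants", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  # five-term form: 0.1 C16:0 + 0.5 C18:0 + 1 C20:0 + 1.5 C22:0 + 2 C24:0
  expect_equal(compute_lcsf(profiles$M8), 11.237, tolerance = 1e-9)
  expect_equal(compute_lcsf(profiles$WS), 6.705, tolerance = 1e-9)
  # four-term variant drops 1.5 x C22:0
  expect_equal(compute_lcsf(profiles$WS, terms = "four"),
               6.705 - 1.5 * 1.09, tolerance = 1e-9)
  # unsaturated-only profile contributes nothing
  p <- fame_profile("u", c("C18:1 (ω9)" = 100))
  expect_equal(compute_lcsf(p), 0)
})

test_that("CFPP chained on the from-profile LCSF reproduces the reference value", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  lcsf <- compute_lcsf(profiles$M8)
  cfpp <- estimate_properties(adu = 0.87, lcsf = lcsf)$cfpp
  expect_equal(cfpp, 18.82, tolerance = 0.05)
})

test_that("CN/KV fall and IV/CFPP rise monotonically with unsaturation", {
  grid <- seq(0, 3, by = 0.1)
  props <- lapply(grid, estimate_properties, lcsf = 5)
  cn <- vapply(props, `[[`, numeric(1L), "cn")
  iv <- vapply(props, `[[`, numeric(1L), "iv")
  kv <- vapply(props, `[[`, numeric(1L), "kv")
  expect_true(all(diff(cn) < 0))
  expect_true(all(diff(iv) > 0))
  expect_true(all(diff(kv) < 0))
  cfpp <- vapply(seq(0, 15, by = 0.5),
                 function(l) estimate_properties(1, l)$cfpp, numeric(1L))
  expect_true(all(diff(cfpp) > 0))
  # positivity over the physically relevant ADU range
  expect_true(all(vapply(props, `[[`, numeric(1L), "kv") > 0))
  expect_true(all(vapply(props, `[[`, numeric(1L), "density") > 0))
  expect_true(all(vapply(props, `[[`, numeric(1L), "hhv") > 0))
})

test_that("compliance verdicts honour closed and open bounds", {
  astm <- biodiesel_standards("ASTM_D6751")
  en <- biodiesel_standards("EN_14214")

  m8 <- estimate_properties(adu = 0.87, lcsf = 11.23,
                            db4plus_pct = 0, c18_3_pct = 0)
  rep <- check_compliance(m8, astm)
  v <- rep$verdicts
  expect_equal(v$verdict[v$property == "cn"], "pass")   # 57.07 >= 47
  expect_equal(v$verdict[v$property == "kv"], "pass")   # 4.66 in [1.9, 6]

  # values exactly on closed bounds pass
  onb <- m8
  onb$kv <- 6.0; onb$cn <- 47; onb$density <- 0.90
  v2 <- check_compliance(onb, astm)$verdicts
  expect_equal(v2$verdict[v2$property %in% c("kv", "cn", "density")],
               rep("pass", 3L))

  # the cloud-point "> 4" is open: exactly 4 fails, 4.01 passes
  onb$cp <- 4
  expect_equal(check_compliance(onb, astm)$verdicts$verdict[
    check_compliance(onb, astm)$verdicts$property == "cp"], "fail")
  onb$cp <- 4.01
  expect_equal(check_compliance(onb, astm)$verdicts$verdict[
    check_compliance(onb, astm)$verdicts$property == "cp"], "pass")

  # wild-strain iodine value exceeds the EN cap
  ws <- estimate_properties(adu = 1.47, lcsf = 6.69,
                            db4plus_pct = 0, c18_3_pct = 8.95)
  repw <- check_compliance(ws, en)
  expect_equal(repw$verdicts$verdict[repw$verdicts$property == "iv"], "fail")
  expect_equal(repw$overall, "fail")

  # a missing composition value is not silently passed or failed
  nop <- estimate_properties(adu = 1.0, lcsf = 5)
  vn <- check_compliance(nop, en)$verdicts
  expect_equal(vn$verdict[vn$property == "db4plus_pct"], "not-evaluated")
})

test_that("compliance rejects unknown property keys and ignores order", {
  spec <- biodiesel_standards("EN_14214")
  bad <- spec
  bad$limits$octane <- list(min = 90)
  p <- estimate_properties(adu = 1, lcsf = 5)
  expect_error(check_compliance(p, bad), "unknown property")

  perm <- spec
  perm$limits <- perm$limits[rev(names(perm$limits))]
  p2 <- estimate_properties(adu = 1.2, lcsf = 7, db4plus_pct = 0,
                            c18_3_pct = 1)
  r1 <- check_compliance(p2, spec)
  r2 <- check_compliance(p2, perm)
  expect_equal(r1$overall, r2$overall)
  expect_equal(check_compliance(p2, spec)$overall, r1$overall)  # idempotent
})

test_that("estimate_biodiesel records the ADU source and raises flags", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  # from-profile path
  own <- estimate_biodiesel(profiles$M8)
  expect_equal(own$adu_source, "profile")
  expect_equal(own$adu, 0.4799, tolerance = 1e-9)
  expect_true("cp_regression_not_reconciled" %in% own$flags)

  # supplied reference ADU overrides, and the disagreement is flagged
  sup <- estimate_biodiesel(profiles$M8, adu = 0.87)
  expect_equal(sup$adu_source, "supplied")
  expect_equal(sup$adu, 0.87)
  expect_true("adu_supplied_disagrees_with_profile" %in% sup$flags)
  expect_equal(sup$adu_from_profile, 0.4799, tolerance = 1e-9)

  # agreement within tolerance raises no discrepancy flag
  agree <- estimate_biodiesel(profiles$M8, adu = 0.48)
  expect_false("adu_supplied_disagrees_with_profile" %in% agree$flags)
})
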