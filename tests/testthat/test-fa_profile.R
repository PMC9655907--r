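test_that("fatty-acid shorthand parses and canonical labels round-trip", {
  fa <- parse_fa_name("C16:0")
  expect_equal(fa$carbons, 16L)
  expect_equal(fa$double_bonds, 0L)
  expect_true(is.na(fa$omega))
  expect_equal(fa$label, "C16:0")

  fa <- parse_fa_name("C18:1 (ω9)")
  expect_equal(c(fa$carbons, fa$double_bonds, fa$omega), c(18L, 1L, 9L))
  expect_equal(fa$label, "C18:1 (ω9)")

  # flexible spelling: lower case, "w" for the omega glyph, tight spacing
  for (variant in c("c18:1(w9)", " C18 : 1 ( ω9 ) ", "C18:1 (omega 9)")) {
    expect_equal(parse_fa_name(variant)$label, "C18:1 (ω9)")
  }
  # omega distinguishes otherwise identical species
  expect_false(parse_fa_name("C18:1 (ω7)")$label ==
                 parse_fa_name("C18:1 (ω9)")$label)
  expect_false(parse_fa_name("C18:1")$label ==
                 parse_fa_name("C18:1 (ω9)")$label)
})

test_that("malformed or degenerate labels are rejected, odd chains warned", {
  expect_error(parse_fa_name("C0:0"), "below the minimum")
  expect_error(parse_fa_name("palmitic"), "cannot parse")
  expect_error(parse_fa_name("C16"), "cannot parse")
  expect_error(parse_fa_name("16:0"), "cannot parse")
  expect_warning(parse_fa_name("C17:0"), "odd chain length")
})

test_that("bundled profile table loads with not-detected cells as zero", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  expect_named(profiles, c("WS", "M1", "M2", "M4", "M5", "M8"))
  ws <- profiles$WS
  expect_s3_class(ws, "fame_profile")
  expect_equal(ws$species$fraction[ws$species$label == "C18:2 (ω6)"], 25.28)
  expect_equal(ws$total, 99.16, tolerance = 1e-12)
  # en dash marker maps to 0, stays a profile key
  expect_equal(ws$species$fraction[ws$species$label == "C8:0"], 0)
  # annotated and unassigned C18:1 species are distinct keys, added separately
  m2 <- profiles$M2$species
  expect_equal(m2$fraction[m2$label == "C18:1"], 2.64)
  expect_equal(m2$fraction[m2$label == "C18:1 (ω9)"], 42.57)
  expect_equal(fa_class_summary(profiles$M2)$mufa_pct,
               1.25 + 2.64 + 42.57 + 0.10, tolerance = 1e-9)
})

test_that("profile validation rejects bad tables", {
  f <- write_profile_csv(c("fa,S1", "C16:0,60", "C16:0,40"))
  expect_error(read_fame_profiles(f), "duplicate")

  f <- write_profile_csv(c("fa,S1", "C16:0,105", "C18:0,-5"))
  expect_error(read_fame_profiles(f), "negative")

  f <- write_profile_csv(c("fa,S1", "C16:0,50"))
  expect_error(read_fame_profiles(f), "outside accepted range")

  # single-species table summing to 100 is fine
  f <- write_profile_csv(c("fa,S1", "C16:0,100"))
  p <- read_fame_profiles(f)
  expect_equal(p$S1$total, 100)
})

test_that("normalization closes the composition and is idempotent", {
  p <- fame_profile("x", c("C16:0" = 50), total_gate = NULL)
  n1 <- normalize_profile(p)
  expect_equal(n1$species$fraction, 100)
  expect_equal(p$species$fraction, 50)  # input unchanged

  p2 <- fame_profile("y", c("C16:0" = 40, "C18:1 (ω9)" = 40),
                     total_gate = NULL)
  n2 <- normalize_profile(p2)
  expect_equal(n2$species$fraction, c(50, 50))

  expect_equal(normalize_profile(n2)$species$fraction,
               n2$species$fraction, tolerance = 1e-12)
  expect_equal(n2$total, 100, tolerance = 1e-9)

  p0 <- fame_profile("z", c("C16:0" = 0), total_gate = NULL)
  expect_error(normalize_profile(p0), "cannot normalize")
})

test_that("class summary reproduces reference strain values", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  ws <- fa_class_summary(profiles$WS)
  expect_equal(ws$pufa_pct, 35.90, tolerance = 1e-9)  # 1.67 + 25.28 + 8.95
  expect_equal(ws$c18_3_pct, 8.95)
  m8 <- fa_class_summary(profiles$M8)
  expect_equal(m8$adu, 0.4799, tolerance = 1e-9)
  expect_equal(m8$sfa_pct, 55.69, tolerance = 1e-9)

  pure <- fa_class_summary(fame_profile("p", c("C16:0" = 100)))
  expect_equal(pure$sfa_pct, 100)
  expect_equal(pure$mufa_pct, 0)
  expect_equal(pure$pufa_pct, 0)
  expect_equal(pure$adu, 0)

  # a pure monounsaturated profile has ADU exactly 1
  expect_equal(fa_class_summary(fame_profile("o", c("C18:1 (ω9)" = 100)))$adu, 1)
})

test_that("class summary obeys conservation, scaling and ADU bounds", {
  for (seed in 1:25) {
    fr <- random_fractions(seed)
    p <- fame_profile(sprintf("r%d", seed), fr, total_gate = NULL)
    s <- fa_class_summary(p)
    expect_equal(s$sfa_pct + s$mufa_pct + s$pufa_pct, p$total,
                 tolerance = 1e-9)
    expect_lte(s$db4plus_pct, s$pufa_pct + 1e-12)
    expect_gte(s$adu, 0)
    max_db <- max(p$species$double_bonds)
    expect_lte(s$adu, max_db * p$total / 100 + 1e-12)

    # scale equivariance under closure to 100
    sn <- fa_class_summary(p, renormalize = TRUE)
    k <- 100 / p$total
    expect_equal(sn$sfa_pct, k * s$sfa_pct, tolerance = 1e-9)
    expect_equal(sn$pufa_pct, k * s$pufa_pct, tolerance = 1e-9)
    expect_equal(sn$adu, k * s$adu, tolerance = 1e-9)
  }
})

test_that("class summary matches the brute-force oracle on random profiles", {
  for (seed in 1:100) {
    fr <- random_fractions(seed)
    s <- fa_class_summary(fame_profile("r", fr, total_gate = NULL))
    o <- oracle_class_summary(fr)
    expect_equal(s$sfa_pct, o$sfa, tolerance = 1e-9)
    expect_equal(s$mufa_pct, o$mufa, tolerance = 1e-9)
    expect_equal(s$pufa_pct, o$pufa, tolerance = 1e-9)
    expect_equal(s$db4plus_pct, o$db4, tolerance = 1e-9)
    expect_equal(s$c18_3_pct, o$c183, tolerance = 1e-9)
    expect_equal(s$adu, o$adu, tolerance = 1e-9)
  }
})

test_that("summarize_profiles builds one tidy row per strain", {
  profiles <- read_fame_profiles(fixture_profiles_path())
  tab <- summarize_profiles(profiles)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$pufa[tab$strain == "WS"], 35.90, tolerance = 1e-9)
  expect_equal(tab$adu[tab$strain == "M8"], 0.4799, tolerance = 1e-9)
})
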