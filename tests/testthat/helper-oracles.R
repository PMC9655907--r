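# Independent brute-force oracles and small fixture builders. These
# deliberately avoid the package's own parsing/summary code paths.

fixture_profiles_path <- function() {
  system.file("extdata", "fame_profiles_pkessleri.csv",
              package = "phycodiesel", mustWork = TRUE)
}

fixture_fuel_inputs_path <- function() {
  system.file("extdata", "reference_fuel_inputs.csv",
              package = "phycodiesel", mustWork = TRUE)
}

fixture_composition_path <- function() {
  system.file("extdata", "composition_pctdw.csv",
              package = "phycodiesel", mustWork = TRUE)
}

# Minimal independent label parser: "C<carbons>:<bonds>" with optional
# parenthesized omega tag, ignored here (class membership only needs
# carbons and bonds).
oracle_parse <- function(label) {
  core <- sub("\\s*\\(.*\\)\\s*$", "", trimws(label))
  parts <- strsplit(sub("^[Cc]", "", core), ":", fixed = TRUE)[[1L]]
  c(carbons = as.integer(parts[1L]), bonds = as.integer(parts[2L]))
}

# Brute-force class summary: explicit loop over species.
oracle_class_summary <- function(fractions) {
  sfa <- mufa <- pufa <- db4 <- c183 <- adu <- 0
  for (lab in names(fractions)) {
    f <- fractions[[lab]]
    pc <- oracle_parse(lab)
    n <- pc[["bonds"]]
    if (n == 0) sfa <- sfa + f
    else if (n == 1) mufa <- mufa + f
    else pufa <- pufa + f
    if (n >= 4) db4 <- db4 + f
    if (pc[["carbons"]] == 18 && n == 3) c183 <- c183 + f
    adu <- adu + n * f / 100
  }
  list(sfa = sfa, mufa = mufa, pufa = pufa, db4 = db4, c183 = c183, adu = adu)
}

# Random compositional profile over a fixed species pool.
random_fractions <- function(seed, n_species = 10) {
  pool <- c("C14:0", "C16:0", "C16:1 (ω7)", "C16:2", "C18:0",
            "C18:1 (ω9)", "C18:2 (ω6)", "C18:3 (ω3)",
            "C20:4 (ω6)", "C22:6 (ω3)")
  set.seed(seed)
  labs <- sample(pool, n_species)
  raw <- stats::runif(n_species)
  stats::setNames(100 * raw / sum(raw), labs)
}

# Brute-force mutant ranking: filter, then repeated max extraction.
oracle_rank <- function(records, wild, k, priority = "lipid") {
  fg <- records$growth_rate / wild$growth_rate
  fl <- records$lipid_gL / wild$lipid_gL
  keep <- which(fg > 1 & fl > 1)
  ids <- records$strain_id[keep]; fg <- fg[keep]; fl <- fl[keep]
  chosen <- character()
  while (length(ids) > 0L && length(chosen) < k) {
    if (priority == "lipid") {
      best <- which(fl == max(fl))
      if (length(best) > 1L) best <- best[fg[best] == max(fg[best])]
    } else {
      best <- which(fg == max(fg))
      if (length(best) > 1L) best <- best[fl[best] == max(fl[best])]
    }
    if (length(best) > 1L) best <- best[order(ids[best])][1L]
    chosen <- c(chosen, ids[best])
    ids <- ids[-best]; fg <- fg[-best]; fl <- fl[-best]
  }
  chosen
}

# Write a small profile table to a temp file.
write_profile_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f, useBytes = FALSE)
  f
}
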