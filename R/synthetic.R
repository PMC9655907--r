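# Seeded generators with known ground truth for every pipeline input.
# Each call seeds its own RNG stream and restores the caller's RNG state,
# so generators are reproducible in isolation and in any order.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a batch growth curve with known kinetics
#'
#' Logistic trajectory with a lag offset, emulating the batch culture of a
#' marine chlorophyte: a short lag phase, exponential growth, then a
#' stationary plateau at the carrying capacity. Defaults mirror a typical
#' wild-type culture: 0.025 g/L inoculum, ~0.65 g/L plateau reached around
#' day 16, a 2-day lag, sampling every 2 days for 20 days. Observations get
#' multiplicative log-normal noise; matched OD680 readings are derived
#' through a fixed dry-weight/OD ratio.
#'
#' @param seed integer RNG seed.
#' @param times sampling times (days).
#' @param dw0 inoculum dry weight (g/L).
#' @param carrying_capacity plateau dry weight (g/L).
#' @param mu intrinsic exponential growth rate (day^-1).
#' @param lag_days lag-phase duration (days).
#' @param noise_sd standard deviation of the log-normal observation noise.
#' @param od_ratio dry weight per OD680 unit ((g/L)/AU) used to derive OD
#'   readings.
#' @return data.frame with \code{time_days}, \code{od680}, \code{dw_gL} and
#'   attribute \code{truth}: the generating parameters plus
#'   \code{analytic}, a function of time returning the noiseless dry
#'   weight (use it for window-specific reference rates).
#' @examples
#' s <- sim_growth_curve(seed = 1)
#' truth <- attr(s, "truth")
#' truth$analytic(16)
#' @export
sim_growth_curve <- function(seed, times = seq(0, 20, by = 2), dw0 = 0.025,
                             carrying_capacity = 0.65, mu = 0.20,
                             lag_days = 2, noise_sd = 0.05,
                             od_ratio = 0.24) {
  stopifnot(dw0 > 0, carrying_capacity > dw0, mu > 0, lag_days >= 0,
            noise_sd >= 0, od_ratio > 0)
  K <- carrying_capacity
  A <- (K - dw0) / dw0
  analytic <- function(t) {
    tt <- pmax(t - lag_days, 0)
    K / (1 + A * exp(-mu * tt))
  }
  dw_det <- analytic(times)
  dw_obs <- with_seed(seed, dw_det * exp(stats::rnorm(length(times), 0, noise_sd)))
  out <- data.frame(time_days = times, od680 = dw_obs / od_ratio,
                    dw_gL = dw_obs)
  attr(out, "truth") <- list(dw0 = dw0, carrying_capacity = K, mu = mu,
                             lag_days = lag_days, noise_sd = noise_sd,
                             od_ratio = od_ratio, analytic = analytic)
  out
}

#' Simulate a dose-mortality screening table
#'
#' Survival falls sigmoidally with plasma exposure time:
#' \deqn{p_{surv}(t) = 1 / (1 + e^{k (t - t_{50})})}
#' and treated colony counts are binomial draws given the control count.
#' The defaults place the 50% lethal dose at 32 s with steepness 0.45 s^-1
#' and 320 control colonies, so the expected dose response crosses the 95%
#' screening threshold between 30 and 40 s and is essentially fully lethal
#' by 50 s — the dose pattern a plasma mutagenesis screen on a 10-60 s grid
#' is set up to show.
#'
#' @param seed integer RNG seed.
#' @param exposures exposure grid (seconds).
#' @param t50 exposure with 50% expected mortality (seconds).
#' @param steepness logistic steepness (per second, > 0).
#' @param control_colonies control plate colony count (> 0).
#' @return A [screening_table()] with attribute \code{truth}: generating
#'   parameters, \code{expected_mortality_pct} per exposure, and
#'   \code{designed_dose}, a function of the mortality threshold returning
#'   the exposure the configuration is designed to make
#'   [select_exposure()] pick (smallest exposure whose expected mortality
#'   meets the threshold with at least one expected survivor), or \code{NA}
#'   if none qualifies.
#' @export
sim_mortality_table <- function(seed, exposures = seq(10, 60, by = 10),
                                t50 = 32, steepness = 0.45,
                                control_colonies = 320) {
  stopifnot(steepness > 0, control_colonies > 0, length(exposures) > 0)
  p_surv <- stats::plogis(-steepness * (exposures - t50))
  treated <- with_seed(seed,
    stats::rbinom(length(exposures), size = control_colonies, prob = p_surv))
  tab <- screening_table(exposures, treated, control_colonies)
  exp_mort <- (1 - p_surv) * 100
  exp_treated <- control_colonies * p_surv
  designed_dose <- function(threshold = 95) {
    ok <- exp_mort >= threshold & exp_treated >= 1
    if (!any(ok)) NA_real_ else min(exposures[ok])
  }
  attr(tab, "truth") <- list(t50 = t50, steepness = steepness,
                             control_colonies = control_colonies,
                             expected_mortality_pct =
                               stats::setNames(exp_mort, exposures),
                             designed_dose = designed_dose)
  tab
}

#' Simulate compositional FAME profiles around an archetype
#'
#' Draws compositional jitter around one of the bundled strain profiles (or
#' a user-supplied one) with a Dirichlet distribution: detected species get
#' gamma draws with shape proportional to their archetype fraction, then
#' the vector is closed to a 100% total. Species the archetype reports as
#' not detected stay exactly zero. Larger \code{concentration} means
#' tighter draws; \code{concentration = Inf} returns the archetype itself
#' (renormalized to 100).
#'
#' @param seed integer RNG seed.
#' @param archetype name of a bundled strain column (\code{"WS"},
#'   \code{"M1"}, \code{"M2"}, \code{"M4"}, \code{"M5"}, \code{"M8"}),
#'   ignored when \code{profile} is given.
#' @param n number of profiles to draw.
#' @param concentration Dirichlet concentration parameter (> 0, or Inf).
#' @param profile optional [fame_profile] to use as the archetype.
#' @return List of \code{n} [fame_profile] objects with attribute
#'   \code{truth}: the archetype profile and its [fa_class_summary()].
#' @export
sim_fame_profiles <- function(seed, archetype = "M8", n = 1,
                              concentration = 500, profile = NULL) {
  stopifnot(n >= 1, concentration > 0)
  if (is.null(profile)) {
    path <- system.file("extdata", "fame_profiles_pkessleri.csv",
                        package = "phycodiesel", mustWork = TRUE)
    profiles <- read_fame_profiles(path)
    if (!archetype %in% names(profiles)) {
      stop(sprintf("unknown archetype '%s' (bundled: %s)", archetype,
                   paste(names(profiles), collapse = ", ")), call. = FALSE)
    }
    profile <- profiles[[archetype]]
  }
  arch <- normalize_profile(profile)
  p <- arch$species$fraction / 100
  nz <- p > 0
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      f <- numeric(length(p))
      if (is.finite(concentration)) {
        g <- stats::rgamma(sum(nz), shape = concentration * p[nz], rate = 1)
        f[nz] <- 100 * g / sum(g)
      } else {
        f[nz] <- 100 * p[nz]
      }
      fame_profile(sprintf("%s_sim%d", arch$strain_id, i),
                   stats::setNames(f, arch$species$label),
                   total_gate = NULL)
    })
  })
  attr(draws, "truth") <- list(archetype = arch,
                               summary = fa_class_summary(arch))
  draws
}

#' Simulate assay standards and readings with known truth
#'
#' Linear signal model \code{signal = slope x concentration + intercept +
#' Gaussian noise} for a colorimetric/fluorometric assay. Negative noise
#' cannot push a signal below zero: such values are clamped to 0 and
#' flagged. Defaults emulate a Nile-red triglyceride assay on a 0-600
#' µg/mL standard ladder with culture concentrations around the wild-type
#' (~320 µg/mL) and a high-lipid mutant (~565 µg/mL).
#'
#' @param seed integer RNG seed.
#' @param true_conc named numeric vector of true sample concentrations.
#' @param slope,intercept true line parameters.
#' @param noise_sd Gaussian signal noise standard deviation.
#' @param standards_conc standard-ladder concentrations.
#' @param analyte label passed through to [fit_standard_curve()] users.
#' @return List with \code{standards} (data.frame: concentration, signal,
#'   clamped), \code{readings} (data.frame: sample, signal, clamped,
#'   true_concentration) and \code{truth} (slope, intercept, noise_sd,
#'   analyte).
#' @export
sim_assay_readings <- function(seed,
                               true_conc = c(WS = 318, M8 = 565.2),
                               slope = 0.0015, intercept = 0.02,
                               noise_sd = 0.005,
                               standards_conc = seq(0, 600, by = 100),
                               analyte = "tag_nile_red") {
  stopifnot(slope != 0, noise_sd >= 0, length(standards_conc) >= 3)
  clamp <- function(x) {
    cl <- x < 0
    list(signal = pmax(x, 0), clamped = cl)
  }
  res <- with_seed(seed, {
    s_std <- slope * standards_conc + intercept +
      stats::rnorm(length(standards_conc), 0, noise_sd)
    s_rd <- slope * true_conc + intercept +
      stats::rnorm(length(true_conc), 0, noise_sd)
    list(std = clamp(s_std), rd = clamp(s_rd))
  })
  list(
    standards = data.frame(concentration = standards_conc,
                           signal = res$std$signal,
                           clamped = res$std$clamped),
    readings = data.frame(sample = names(true_conc),
                          signal = res$rd$signal,
                          clamped = res$rd$clamped,
                          true_concentration = as.numeric(true_conc),
                          stringsAsFactors = FALSE),
    truth = list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                 analyte = analyte)
  )
}

#' Simulate a mutant screening record set
#'
#' Draws per-mutant growth-rate and lipid-content fold changes from
#' log-normal distributions centred near the wild strain, for exercising
#' [rank_mutants()] on data with known truth. The defaults emulate a
#' 15-colony plasma-mutagenesis screen against a wild strain growing at
#' 0.20 day^-1 with 0.22 g/L lipid.
#'
#' @param seed integer RNG seed.
#' @param n_mutants number of mutant records.
#' @param wild list with positive \code{growth_rate} (day^-1) and
#'   \code{lipid_gL} (g/L).
#' @param meanlog,sdlog log-normal parameters of the fold distributions
#'   (shared by both traits).
#' @return List with \code{records} (data.frame: strain_id, growth_rate,
#'   lipid_gL), \code{wild}, and \code{truth} (the drawn folds).
#' @export
sim_mutant_screen <- function(seed, n_mutants = 15,
                              wild = list(growth_rate = 0.20,
                                          lipid_gL = 0.22),
                              meanlog = 0.1, sdlog = 0.35) {
  stopifnot(n_mutants >= 1, wild$growth_rate > 0, wild$lipid_gL > 0)
  folds <- with_seed(seed, {
    list(growth = stats::rlnorm(n_mutants, meanlog, sdlog),
         lipid = stats::rlnorm(n_mutants, meanlog, sdlog))
  })
  records <- data.frame(
    strain_id = sprintf("M%d", seq_len(n_mutants)),
    growth_rate = wild$growth_rate * folds$growth,
    lipid_gL = wild$lipid_gL * folds$lipid,
    stringsAsFactors = FALSE
  )
  list(records = records, wild = wild,
       truth = list(fold_growth = folds$growth, fold_lipid = folds$lipid))
}
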