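#' Pigment content from methanol-extract absorbances
#'
#' Spectrophotometric chlorophyll and carotenoid equations for 90% methanol
#' extracts read at 663, 644 and 452 nm (per-volume concentrations in
#' µg/mL):
#' \deqn{Chl\,a = 10.3 A_{663} - 0.913 A_{644}}
#' \deqn{Chl\,b = 19.07 A_{644} - 3.87 A_{663}}
#' \deqn{Car = 4.2 A_{452} - (0.0264\, Chl\,a + 0.426\, Chl\,b)}
#' The chlorophyll-b leading coefficient defaults to 19.07, the magnitude
#' consistent with the chlorophyll-a coefficient and with methanol-extract
#' spectrophotometry; it is overridable. Per-volume concentrations are
#' converted to µg/mgDW via the extract volume and the dry biomass in the
#' aliquot. Blank-subtraction noise can drive an equation negative; negative
#' pigments are floored at 0 with a warning (the unfloored values are kept
#' in \code{raw}).
#'
#' @param a663,a644,a452 absorbances (>= 0).
#' @param biomass_mg dry biomass in the extracted aliquot (mg, > 0).
#' @param extract_volume_mL extract volume (mL, > 0).
#' @param chlb_coef leading coefficient of the chlorophyll-b equation.
#' @return Object of class \code{"pigment_result"}: list with per-DW
#'   \code{chl_a}, \code{chl_b}, \code{carotenoids}, \code{total} (all
#'   µg/mgDW, floored), \code{raw} (per-volume µg/mL, unfloored) and
#'   \code{floored} (character vector of floored components).
#' @examples
#' pigment_content(a663 = 0.8, a644 = 0.4, a452 = 0.5,
#'                 biomass_mg = 10, extract_volume_mL = 5)
#' @export
pigment_content <- function(a663, a644, a452, biomass_mg = 1,
                            extract_volume_mL = 1, chlb_coef = 19.07) {
  stopifnot(is.numeric(a663), is.numeric(a644), is.numeric(a452))
  if (any(c(a663, a644, a452) < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  if (!is.numeric(biomass_mg) || biomass_mg <= 0) {
    stop("'biomass_mg' must be positive", call. = FALSE)
  }
  if (!is.numeric(extract_volume_mL) || extract_volume_mL <= 0) {
    stop("'extract_volume_mL' must be positive", call. = FALSE)
  }
  chl_a <- 10.3 * a663 - 0.913 * a644
  chl_b <- chlb_coef * a644 - 3.87 * a663
  car <- 4.2 * a452 - (0.0264 * chl_a + 0.426 * chl_b)
  raw <- c(chl_a = chl_a, chl_b = chl_b, carotenoids = car)
  floored <- names(raw)[raw < 0]
  if (length(floored)) {
    warning(sprintf("negative pigment value(s) floored to 0: %s",
                    paste(floored, collapse = ", ")), call. = FALSE)
  }
  per_dw <- pmax(raw, 0) * extract_volume_mL / biomass_mg
  structure(list(
    chl_a = unname(per_dw["chl_a"]),
    chl_b = unname(per_dw["chl_b"]),
    carotenoids = unname(per_dw["carotenoids"]),
    total = sum(per_dw),
    raw = raw,
    floored = floored
  ), class = "pigment_result")
}

#' @export
print.pigment_result <- function(x, ...) {
  cat(sprintf("<pigments> Chl a %.3f, Chl b %.3f, carotenoids %.3f, total %.3f ug/mgDW\n",
              x$chl_a, x$chl_b, x$carotenoids, x$total))
  if (length(x$floored)) {
    cat("  floored to 0:", paste(x$floored, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fit a standard curve for a colorimetric or fluorometric assay
#'
#' Least-squares line of signal on concentration, for sunflower-oil SPV
#' lipid, phenol-sulfuric carbohydrate, Bradford protein, or Nile-red
#' triglyceride standards.
#'
#' @param concentration standard concentrations (>= 3 distinct values
#'   spanning a nonzero range).
#' @param signal measured absorbance or fluorescence.
#' @param analyte label, one of \code{"lipid_SPV"}, \code{"carbohydrate"},
#'   \code{"protein"}, \code{"tag_nile_red"} (or any string).
#' @return Object of class \code{"standard_curve"}: \code{analyte},
#'   \code{slope}, \code{intercept}, \code{r2}, \code{conc_range},
#'   \code{signal_range}, \code{n}.
#' @export
fit_standard_curve <- function(concentration, signal, analyte = "lipid_SPV") {
  stopifnot(is.numeric(concentration), is.numeric(signal))
  keep <- stats::complete.cases(concentration, signal)
  concentration <- concentration[keep]; signal <- signal[keep]
  if (length(concentration) < 3L) {
    stop("standard curve needs at least 3 points", call. = FALSE)
  }
  if (stats::sd(concentration) == 0) {
    stop("standards must span a nonzero concentration range", call. = FALSE)
  }
  fit <- stats::lm(signal ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (slope == 0) stop("degenerate standard curve: zero slope", call. = FALSE)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((signal - mean(signal))^2)
  structure(list(
    analyte = analyte,
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    conc_range = range(concentration),
    signal_range = range(slope * range(concentration) +
                           unname(stats::coef(fit)[1L])),
    n = length(concentration)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard curve> %s: signal = %.4g * conc %+.4g  (R2 = %.4f, n = %d)\n",
              x$analyte, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Invert a standard curve: signal to concentration
#'
#' Solves the fitted line for concentration. Readings outside the fitted
#' signal range are still inverted but flagged as extrapolation rather than
#' silently accepted.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param signal measured signal(s).
#' @return data.frame with \code{signal}, \code{concentration},
#'   \code{extrapolated} (logical).
#' @export
invert_curve <- function(curve, signal) {
  stopifnot(inherits(curve, "standard_curve"), is.numeric(signal))
  conc <- (signal - curve$intercept) / curve$slope
  lo <- min(curve$signal_range); hi <- max(curve$signal_range)
  data.frame(signal = signal, concentration = conc,
             extrapolated = signal < lo | signal > hi)
}

#' Cellular composition table with fold changes versus the wild strain
#'
#' Converts per-strain analyte contents into the standard per-dry-weight
#' units: mg analyte per g dry biomass (mg/gDW) and percent of dry weight
#' (%DW = mg/gDW / 10), and appends the fold change and percent increase of
#' each strain over the wild strain.
#'
#' @param strains data frame with columns \code{strain} and \code{mg_gDW}
#'   (analyte content in mg per g dry biomass), or \code{pct_dw} (converted
#'   via mg/gDW = 10 x %DW).
#' @param wild id of the wild/reference strain (must be present).
#' @return data.frame with \code{strain}, \code{mg_gDW}, \code{pct_dw},
#'   \code{fold_vs_wild}, \code{percent_increase}.
#' @export
composition_table <- function(strains, wild = "WS") {
  stopifnot(is.data.frame(strains), "strain" %in% names(strains))
  if (!"mg_gDW" %in% names(strains)) {
    if (!"pct_dw" %in% names(strains)) {
      stop("need an 'mg_gDW' or 'pct_dw' column", call. = FALSE)
    }
    strains$mg_gDW <- strains$pct_dw * 10
  }
  strains$pct_dw <- strains$mg_gDW / 10
  if (!wild %in% strains$strain) {
    stop(sprintf("wild strain '%s' not present", wild), call. = FALSE)
  }
  ref <- strains$mg_gDW[strains$strain == wild][1L]
  fc <- fold_change(strains$mg_gDW, ref)
  strains$fold_vs_wild <- fc$fold
  strains$percent_increase <- fc$percent
  rownames(strains) <- NULL
  strains
}
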