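#' Fit an OD680-to-dry-weight calibration line
#'
#' Ordinary least squares of dry weight (g/L) on optical density at 680 nm.
#' Used to convert routine OD readings to biomass before any rate or
#' productivity computation.
#'
#' @param od680 numeric vector of absorbance readings.
#' @param dw numeric vector of matched dry weights (g/L).
#' @return Object of class \code{"od_dw_calibration"}: list with
#'   \code{slope} ((g/L)/AU), \code{intercept} (g/L), \code{r2}, \code{n}.
#' @examples
#' cal <- fit_od_calibration(c(0.2, 0.5, 1.0), c(0.05, 0.125, 0.25))
#' predict(cal, od680 = 0.8)
#' @export
fit_od_calibration <- function(od680, dw) {
  stopifnot(is.numeric(od680), is.numeric(dw))
  keep <- stats::complete.cases(od680, dw)
  od680 <- od680[keep]; dw <- dw[keep]
  if (length(od680) < 3L) {
    stop("calibration needs at least 3 complete (od680, dw) points",
         call. = FALSE)
  }
  if (stats::sd(od680) == 0) {
    stop("degenerate calibration design: all od680 values equal",
         call. = FALSE)
  }
  fit <- stats::lm(dw ~ od680)
  # R2 computed directly (summary.lm warns on noiseless calibrations)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((dw - mean(dw))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    n = length(od680)
  ), class = "od_dw_calibration")
}

#' @export
predict.od_dw_calibration <- function(object, od680, ...) {
  object$intercept + object$slope * od680
}

#' @export
print.od_dw_calibration <- function(x, ...) {
  cat(sprintf("<OD680 -> DW calibration> dw = %.4f * od680 %+.4f  (R2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Specific growth rate from two dry-weight readings
#'
#' \deqn{\mu = (\ln DW_t - \ln DW_0) / t}
#' in day^-1, with \eqn{t} the elapsed culture time in days. Antisymmetric
#' under swapping the two readings.
#'
#' @param dw0 initial dry weight (g/L), > 0.
#' @param dwt final dry weight (g/L), > 0.
#' @param t elapsed time (days), > 0.
#' @return Specific growth rate (day^-1).
#' @examples
#' growth_rate(0.025, 0.654, 16)
#' @export
growth_rate <- function(dw0, dwt, t) {
  stopifnot(is.numeric(dw0), is.numeric(dwt), is.numeric(t))
  if (any(dw0 <= 0) || any(dwt <= 0)) {
    stop("dry weights must be positive for a log growth rate", call. = FALSE)
  }
  if (any(t <= 0)) stop("elapsed time must be positive", call. = FALSE)
  (log(dwt) - log(dw0)) / t
}

#' Productivity over a cultivation window
#'
#' Difference between a late and an early concentration reading divided by
#' the elapsed time: biomass productivity when fed dry weights (g/L ->
#' g/L/day), lipid productivity when fed lipid concentrations (mg/L ->
#' mg/L/day). The result carries sign: it is negative if the late value is
#' below the early one.
#'
#' @param early,late concentration at the window ends (same units).
#' @param t_early,t_late window end points (days), \code{t_late > t_early}.
#' @return Productivity in concentration units per day, with attribute
#'   \code{window = c(t_early, t_late)}.
#' @examples
#' productivity(0.1, 0.9, 0, 10)   # 0.08 g/L/day
#' @export
productivity <- function(early, late, t_early, t_late) {
  stopifnot(is.numeric(early), is.numeric(late),
            is.numeric(t_early), is.numeric(t_late))
  dt <- t_late - t_early
  if (any(dt <= 0)) stop("window must have t_late > t_early", call. = FALSE)
  structure((late - early) / dt, window = c(t_early, t_late))
}

#' Fold change and percent increase of a mutant trait over the wild strain
#'
#' @param mutant_value trait value in the mutant.
#' @param wild_value trait value in the wild strain, > 0.
#' @return List with \code{fold} (mutant/wild) and \code{percent}
#'   ((fold - 1) x 100).
#' @examples
#' fold_change(565.2, 318)   # TAG, ~1.78-fold
#' @export
fold_change <- function(mutant_value, wild_value) {
  stopifnot(is.numeric(mutant_value), is.numeric(wild_value))
  if (any(wild_value <= 0)) {
    stop("wild-strain value must be positive", call. = FALSE)
  }
  fold <- mutant_value / wild_value
  list(fold = fold, percent = (fold - 1) * 100)
}

#' Read a growth series from CSV
#'
#' Expects columns \code{strain}, \code{time_days}, and at least one of
#' \code{od680}, \code{dw_gL}; missing cells blank. Times must be strictly
#' increasing within a strain; readings must be non-negative.
#'
#' @param file path to a CSV file.
#' @return Named list of data frames (one per strain) with columns
#'   \code{time_days}, \code{od680}, \code{dw_gL}.
#' @export
read_growth_series <- function(file) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file), call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("strain", "time_days")
  if (!all(need %in% names(df))) {
    stop("growth CSV needs columns: strain, time_days, and od680 and/or dw_gL",
         call. = FALSE)
  }
  if (!any(c("od680", "dw_gL") %in% names(df))) {
    stop("growth CSV needs at least one of od680, dw_gL", call. = FALSE)
  }
  if (!"od680" %in% names(df)) df$od680 <- NA_real_
  if (!"dw_gL" %in% names(df)) df$dw_gL <- NA_real_
  split_df <- split(df[, c("time_days", "od680", "dw_gL")], df$strain)
  lapply(names(split_df), function(s) {
    d <- split_df[[s]]
    d <- d[order(d$time_days), , drop = FALSE]
    if (anyDuplicated(d$time_days)) {
      stop(sprintf("strain '%s': duplicate time points", s), call. = FALSE)
    }
    if (any(d$od680 < 0, na.rm = TRUE) || any(d$dw_gL < 0, na.rm = TRUE)) {
      stop(sprintf("strain '%s': negative reading", s), call. = FALSE)
    }
    rownames(d) <- NULL
    d
  }) -> out
  names(out) <- names(split_df)
  out
}

#' Growth-rate and productivity summary for one growth series
#'
#' Converts OD-only samples to dry weight through a calibration (measured
#' dry weights are preferred where both exist), then computes the specific
#' growth rate and biomass productivity over a stated window (defaults to
#' the day 2-16 exponential phase typical of batch microalgal cultures).
#'
#' @param series data frame with \code{time_days} and \code{od680} and/or
#'   \code{dw_gL} (one element of [read_growth_series()] output).
#' @param calibration optional [fit_od_calibration()] object for OD-only
#'   samples.
#' @param window numeric length-2, the (t_early, t_late) window in days;
#'   the nearest sampled times are used.
#' @return List with \code{mu} (day^-1), \code{bp} (g/L/day),
#'   \code{window} (times actually used), and \code{calibration_used}.
#' @export
analyze_growth <- function(series, calibration = NULL, window = c(2, 16)) {
  stopifnot(is.data.frame(series), all(c("time_days") %in% names(series)))
  dw <- if ("dw_gL" %in% names(series)) series$dw_gL else rep(NA_real_, nrow(series))
  used_cal <- FALSE
  if (any(is.na(dw))) {
    if (is.null(calibration)) {
      if (all(is.na(dw))) {
        stop("series has no dry weights and no calibration was given",
             call. = FALSE)
      }
    } else {
      miss <- is.na(dw) & !is.na(series$od680)
      dw[miss] <- predict(calibration, series$od680[miss])
      used_cal <- any(miss)
    }
  }
  ok <- !is.na(dw)
  tt <- series$time_days[ok]; dw <- dw[ok]
  if (length(tt) < 2L) stop("need at least two usable samples", call. = FALSE)
  i0 <- which.min(abs(tt - window[1L]))
  i1 <- which.min(abs(tt - window[2L]))
  if (i1 <= i0) stop("window does not span two distinct samples", call. = FALSE)
  mu <- growth_rate(dw[i0], dw[i1], tt[i1] - tt[i0])
  bp <- productivity(dw[i0], dw[i1], tt[i0], tt[i1])
  list(mu = mu, bp = as.numeric(bp), window = c(tt[i0], tt[i1]),
       calibration_used = used_cal)
}
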