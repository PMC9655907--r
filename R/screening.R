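#' Mortality rate from colony counts
#'
#' \deqn{\mathrm{mortality}\,(\%) = (1 - T/C) \times 100}
#' where \eqn{T} is the treated colony count and \eqn{C} the untreated
#' control count. If \eqn{T > C} (sampling noise) the result is clamped to 0
#' with a warning. Vectorized over \code{treated}.
#'
#' @param treated colony count after mutagenic exposure (>= 0).
#' @param control colony count without exposure (> 0).
#' @return Mortality percentage in [0, 100].
#' @examples
#' mortality_rate(47, 1000)   # 95.3
#' @export
mortality_rate <- function(treated, control) {
  stopifnot(is.numeric(treated), is.numeric(control))
  if (any(control <= 0)) stop("control colony count must be positive", call. = FALSE)
  if (any(treated < 0)) stop("treated colony count must be >= 0", call. = FALSE)
  m <- (1 - treated / control) * 100
  if (any(m < 0)) {
    warning("treated count exceeds control; mortality clamped to 0%",
            call. = FALSE)
    m <- pmax(m, 0)
  }
  pmin(m, 100)
}

#' Survival rate from colony counts
#'
#' Complement of [mortality_rate()]: \code{(T/C) x 100}, clamped to
#' [0, 100].
#'
#' @inheritParams mortality_rate
#' @return Survival percentage in [0, 100].
#' @export
survival_rate <- function(treated, control) {
  100 - mortality_rate(treated, control)
}

#' Build a mutagenesis screening table
#'
#' Colony counts per plasma exposure time, with the derived mortality rate
#' per row.
#'
#' @param exposure_s exposure times in seconds (unique).
#' @param treated treated colony counts.
#' @param control control colony counts (recycled if scalar).
#' @return data.frame of class \code{"screening_table"} with columns
#'   \code{exposure_s}, \code{treated}, \code{control},
#'   \code{mortality_pct}, sorted by exposure.
#' @export
screening_table <- function(exposure_s, treated, control) {
  stopifnot(is.numeric(exposure_s), is.numeric(treated), is.numeric(control))
  if (length(control) == 1L) control <- rep(control, length(exposure_s))
  if (length(exposure_s) != length(treated) ||
      length(exposure_s) != length(control)) {
    stop("exposure_s, treated and control must have matching lengths",
         call. = FALSE)
  }
  if (anyDuplicated(exposure_s)) {
    stop("exposure times must be unique", call. = FALSE)
  }
  df <- data.frame(exposure_s = exposure_s, treated = treated,
                   control = control,
                   mortality_pct = mortality_rate(treated, control))
  df <- df[order(df$exposure_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("screening_table", "data.frame")
  df
}

#' Read a screening table from CSV
#'
#' Expects columns \code{exposure_s}, \code{treated_colonies},
#' \code{control_colonies}.
#'
#' @param file path to a CSV file.
#' @return A [screening_table()].
#' @export
read_screening_table <- function(file) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file), call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("exposure_s", "treated_colonies", "control_colonies")
  if (!all(need %in% names(df))) {
    stop(sprintf("screening CSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  screening_table(df$exposure_s, df$treated_colonies, df$control_colonies)
}

#' Select the optimal mutagenic exposure time
#'
#' Random-mutagenesis practice targets the smallest dose whose mortality
#' reaches a threshold (the positive-mutation rate peaks at >= 95%
#' lethality) while still leaving survivors to screen: a fully lethal dose
#' (mortality 100%, zero treated colonies) is useless. Returns the smallest
#' qualifying exposure; invariant under row permutation.
#'
#' @param table a [screening_table()].
#' @param threshold mortality threshold in percent, in (0, 100).
#' @return Object of class \code{"dose_selection"}: list with
#'   \code{viable} (logical), and when viable \code{exposure_s},
#'   \code{mortality_pct}, \code{treated}; \code{threshold} always.
#' @export
select_exposure <- function(table, threshold = 95) {
  stopifnot(inherits(table, "data.frame"),
            all(c("exposure_s", "mortality_pct", "treated") %in% names(table)))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 100) {
    stop("'threshold' must be in (0, 100)", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("screening table is empty", call. = FALSE)
  ord <- order(table$exposure_s)
  tab <- table[ord, , drop = FALSE]
  ok <- tab$mortality_pct >= threshold & tab$mortality_pct < 100 &
    tab$treated >= 1
  if (!any(ok)) {
    return(structure(list(viable = FALSE, threshold = threshold),
                     class = "dose_selection"))
  }
  i <- which(ok)[1L]
  structure(list(viable = TRUE,
                 exposure_s = tab$exposure_s[i],
                 mortality_pct = tab$mortality_pct[i],
                 treated = tab$treated[i],
                 threshold = threshold),
            class = "dose_selection")
}

#' @export
print.dose_selection <- function(x, ...) {
  if (!x$viable) {
    cat(sprintf("<dose selection> no viable dose at mortality >= %g%% with survivors\n",
                x$threshold))
  } else {
    cat(sprintf("<dose selection> %g s (mortality %.1f%%, %d survivor(s); threshold %g%%)\n",
                x$exposure_s, x$mortality_pct, as.integer(x$treated),
                x$threshold))
  }
  invisible(x)
}

#' Rank mutant strains against the wild strain
#'
#' Keeps only mutants that beat the wild strain on both growth rate and
#' lipid content (fold > 1 on both axes), then orders them by lipid fold
#' descending (or growth-first, configurable), ties by the other fold
#' descending, then by strain id, and returns the top \code{k}.
#'
#' @param records data frame with columns \code{strain_id},
#'   \code{growth_rate}, \code{lipid_gL} (plus any extras, carried through).
#' @param wild single-row data frame or list with positive
#'   \code{growth_rate} and \code{lipid_gL} for the wild strain.
#' @param k number of mutants to keep (> 0).
#' @param priority rank on \code{"lipid"} fold first (default) or
#'   \code{"growth"} fold first.
#' @return data.frame: the selected records plus \code{fold_growth} and
#'   \code{fold_lipid}, at most \code{k} rows, in ranked order.
#' @export
rank_mutants <- function(records, wild, k, priority = c("lipid", "growth")) {
  priority <- match.arg(priority)
  stopifnot(is.data.frame(records),
            all(c("strain_id", "growth_rate", "lipid_gL") %in% names(records)))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("'k' must be a positive count", call. = FALSE)
  }
  wg <- wild$growth_rate; wl <- wild$lipid_gL
  if (is.null(wg) || is.null(wl) || wg <= 0 || wl <= 0) {
    stop("wild-strain growth rate and lipid content must be positive",
         call. = FALSE)
  }
  out <- records
  out$fold_growth <- out$growth_rate / wg
  out$fold_lipid <- out$lipid_gL / wl
  out <- out[out$fold_growth > 1 & out$fold_lipid > 1, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  keys <- if (priority == "lipid") {
    list(-out$fold_lipid, -out$fold_growth, out$strain_id)
  } else {
    list(-out$fold_growth, -out$fold_lipid, out$strain_id)
  }
  out <- out[do.call(order, keys), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}
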