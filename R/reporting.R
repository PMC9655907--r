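#' Run the full analysis report
#'
#' Orchestrates the pipeline over a FAME profile table: class summaries,
#' biodiesel property estimates per strain, and compliance verdicts against
#' one or more standards; optionally a cellular-composition table with fold
#' changes versus the wild strain and a mutagenesis screening summary.
#' Report tables round to 2 decimals at serialization; computations keep
#' full precision.
#'
#' When a reference ADU/LCSF table is given (columns \code{strain},
#' \code{adu}, optional \code{lcsf}) those values override the from-profile
#' ones, with the ADU source recorded per strain and a discrepancy flag
#' raised where supplied and from-profile ADU disagree.
#'
#' @param profiles named list of [fame_profile] objects, or path to a
#'   profile table for [read_fame_profiles()].
#' @param adu_reference optional data frame or CSV path with columns
#'   \code{strain}, \code{adu} and optionally \code{lcsf}.
#' @param standards character vector of standard names for
#'   [biodiesel_standards()].
#' @param composition optional data frame or CSV path with columns
#'   \code{strain} and per-analyte \code{*_pctdw} columns (e.g.
#'   \code{protein_pctdw}); fold changes are computed versus \code{wild}.
#' @param screening optional [screening_table()] or CSV path for
#'   [read_screening_table()].
#' @param wild wild/reference strain id for fold changes.
#' @param renormalize compute class summaries on 100%-rescaled profiles.
#' @param lcsf_terms passed to [compute_lcsf()].
#' @param mortality_threshold percent threshold for [select_exposure()].
#' @param out_dir optional directory; when given, writes
#'   \code{report.json} plus \code{properties.csv},
#'   \code{class_summaries.csv} and (if computed) \code{composition.csv}
#'   there, all rounded to 2 decimals. Content is deterministic (no
#'   timestamps).
#' @return Object of class \code{"phyco_report"}: list with
#'   \code{class_summaries}, \code{properties}, \code{compliance},
#'   \code{composition} (or NULL), \code{screening} (or NULL), and the
#'   echoed \code{config}.
#' @export
run_full_report <- function(profiles, adu_reference = NULL,
                            standards = c("ASTM_D6751", "EN_14214"),
                            composition = NULL, screening = NULL,
                            wild = "WS", renormalize = FALSE,
                            lcsf_terms = "five", mortality_threshold = 95,
                            out_dir = NULL) {
  if (is.character(profiles)) profiles <- read_fame_profiles(profiles)
  stopifnot(is.list(profiles), length(profiles) > 0L)
  if (is.character(adu_reference)) {
    adu_reference <- utils::read.csv(adu_reference, stringsAsFactors = FALSE)
  }
  if (!is.null(adu_reference) && !all(c("strain", "adu") %in% names(adu_reference))) {
    stop("'adu_reference' needs columns strain, adu", call. = FALSE)
  }

  class_summaries <- summarize_profiles(profiles, renormalize = renormalize)

  specs <- lapply(standards, biodiesel_standards)
  prop_rows <- list()
  comp_rows <- list()
  for (p in profiles) {
    adu_ref <- NULL
    if (!is.null(adu_reference) && p$strain_id %in% adu_reference$strain) {
      adu_ref <- adu_reference$adu[adu_reference$strain == p$strain_id][1L]
    }
    pr <- estimate_biodiesel(p, adu = adu_ref, renormalize = renormalize,
                             lcsf_terms = lcsf_terms)
    if (!is.null(adu_reference) && "lcsf" %in% names(adu_reference) &&
        p$strain_id %in% adu_reference$strain) {
      lcsf_ref <- adu_reference$lcsf[adu_reference$strain == p$strain_id][1L]
      if (!is.na(lcsf_ref)) {
        pr <- estimate_properties(pr$adu, lcsf_ref,
                                  db4plus_pct = pr$db4plus_pct,
                                  c18_3_pct = pr$c18_3_pct,
                                  adu_source = pr$adu_source,
                                  flags = pr$flags)
        pr$strain_id <- p$strain_id
      }
    }
    prop_rows[[p$strain_id]] <- data.frame(
      strain = p$strain_id, adu = pr$adu, adu_source = pr$adu_source,
      kv = pr$kv, density = pr$density, cp = pr$cp, cn = pr$cn,
      iv = pr$iv, hhv = pr$hhv, lcsf = pr$lcsf, cfpp = pr$cfpp,
      db4plus_pct = pr$db4plus_pct, c18_3_pct = pr$c18_3_pct,
      flags = paste(pr$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
    for (spec in specs) {
      rep <- check_compliance(pr, spec)
      fails <- rep$verdicts$property[rep$verdicts$verdict == "fail"]
      comp_rows[[paste(p$strain_id, spec$name)]] <- data.frame(
        strain = p$strain_id, standard = spec$name, overall = rep$overall,
        failed_properties = paste(fails, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  properties <- do.call(rbind, prop_rows)
  compliance <- do.call(rbind, comp_rows)
  rownames(properties) <- rownames(compliance) <- NULL

  composition_out <- NULL
  if (!is.null(composition)) {
    if (is.character(composition)) {
      composition <- utils::read.csv(composition, stringsAsFactors = FALSE)
    }
    analyte_cols <- grep("_pctdw$", names(composition), value = TRUE)
    if (!"strain" %in% names(composition) || length(analyte_cols) == 0L) {
      stop("'composition' needs a strain column plus *_pctdw columns",
           call. = FALSE)
    }
    parts <- lapply(analyte_cols, function(col) {
      tab <- composition_table(
        data.frame(strain = composition$strain,
                   pct_dw = composition[[col]],
                   stringsAsFactors = FALSE),
        wild = wild)
      tab$analyte <- sub("_pctdw$", "", col)
      tab[, c("analyte", "strain", "mg_gDW", "pct_dw", "fold_vs_wild",
              "percent_increase")]
    })
    composition_out <- do.call(rbind, parts)
    rownames(composition_out) <- NULL
  }

  screening_out <- NULL
  if (!is.null(screening)) {
    if (is.character(screening)) screening <- read_screening_table(screening)
    sel <- select_exposure(screening, threshold = mortality_threshold)
    screening_out <- list(table = as.data.frame(screening), selection = sel)
  }

  report <- structure(list(
    class_summaries = class_summaries,
    properties = properties,
    compliance = compliance,
    composition = composition_out,
    screening = screening_out,
    config = list(standards = standards, wild = wild,
                  renormalize = renormalize, lcsf_terms = lcsf_terms,
                  mortality_threshold = mortality_threshold,
                  adu_reference_used = !is.null(adu_reference))
  ), class = "phyco_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a report bundle to disk
#'
#' Serializes a [run_full_report()] object as \code{report.json} plus tidy
#' CSVs, all rounded to 2 decimals. Output is deterministic: re-running the
#' same configuration yields byte-identical files.
#'
#' @param report a \code{phyco_report}.
#' @param out_dir output directory (created if missing).
#' @param digits decimal places for serialization.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, digits = 2) {
  stopifnot(inherits(report, "phyco_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  json <- list(
    class_summaries = round_df(report$class_summaries, digits),
    properties = round_df(report$properties, digits),
    compliance = report$compliance,
    config = report$config
  )
  if (!is.null(report$composition)) {
    json$composition <- round_df(report$composition, digits)
  }
  if (!is.null(report$screening)) {
    json$screening <- list(
      table = round_df(report$screening$table, digits),
      selection = unclass(report$screening$selection)
    )
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  for (nm in c("properties", "class_summaries", "composition")) {
    if (is.null(report[[nm]])) next
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(round_df(report[[nm]], digits), fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  invisible(paths)
}

#' @export
print.phyco_report <- function(x, ...) {
  cat("<analysis report>\n")
  cat(sprintf("  %d strain(s); standards: %s\n",
              nrow(x$properties), paste(x$config$standards, collapse = ", ")))
  cat("\n  Class summaries (%):\n")
  print(round_df(x$class_summaries), row.names = FALSE)
  cat("\n  Estimated fuel properties:\n")
  print(round_df(x$properties[, setdiff(names(x$properties), "flags")]),
        row.names = FALSE)
  cat("\n  Compliance:\n")
  print(x$compliance, row.names = FALSE)
  if (!is.null(x$composition)) {
    cat("\n  Composition vs wild:\n")
    print(round_df(x$composition), row.names = FALSE)
  }
  if (!is.null(x$screening)) {
    cat("\n  Screening:\n")
    print(x$screening$selection)
  }
  flagged <- unique(unlist(strsplit(x$properties$flags, ";", fixed = TRUE)))
  flagged <- flagged[nzchar(flagged)]
  if (length(flagged)) {
    cat("\n  Caveats:", paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}
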