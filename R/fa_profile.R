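#' Parse a fatty-acid shorthand label
#'
#' Interprets lipid shorthand of the form \code{"C<carbons>:<double bonds>"}
#' with an optional omega-position annotation, e.g. \code{"C16:0"},
#' \code{"C18:1 (ω9)"} or \code{"C18:2 (w6)"}. The omega glyph
#' \code{ω}, the letter \code{w} and the word \code{omega} are all
#' accepted; whitespace is flexible.
#'
#' Two species with equal chain length and unsaturation but different omega
#' annotation (or one annotated, one not) are distinct identities: profile
#' tables may carry, say, both \code{C18:1 (ω7)} and \code{C18:1
#' (ω9)} plus an unassigned \code{C18:1}.
#'
#' @param label character scalar, the shorthand label.
#' @return An object of class \code{"fatty_acid"}: a list with elements
#'   \code{carbons}, \code{double_bonds}, \code{omega} (integer or \code{NA}),
#'   and the canonical \code{label}.
#' @examples
#' parse_fa_name("C18:1 (ω9)")
#' parse_fa_name("c16:0")
#' @export
parse_fa_name <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("'label' must be a single character string", call. = FALSE)
  }
  pat <- "^\\s*[Cc]\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*(?:\\(\\s*(?:ω|[Ww]|[Oo]mega)\\s*-?\\s*([0-9]+)\\s*\\))?\\s*$"
  m <- regmatches(label, regexec(pat, label, perl = TRUE))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse fatty-acid label '%s'", label), call. = FALSE)
  }
  carbons <- as.integer(m[2L])
  double_bonds <- as.integer(m[3L])
  omega <- if (nzchar(m[4L])) as.integer(m[4L]) else NA_integer_
  if (carbons < 4L) {
    stop(sprintf("fatty-acid label '%s': chain length %d is below the minimum of 4 carbons",
                 label, carbons), call. = FALSE)
  }
  if (carbons %% 2L == 1L) {
    warning(sprintf("fatty-acid '%s' has an odd chain length (%d carbons); unusual for FAME data",
                    label, carbons), call. = FALSE)
  }
  canonical <- sprintf("C%d:%d", carbons, double_bonds)
  if (!is.na(omega)) canonical <- sprintf("%s (ω%d)", canonical, omega)
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         omega = omega, label = canonical),
    class = "fatty_acid"
  )
}

#' @export
print.fatty_acid <- function(x, ...) {
  om <- if (is.na(x$omega)) "unassigned" else paste0("ω", x$omega)
  cat(sprintf("<fatty acid> %s  [%d carbons, %d double bond(s), omega %s]\n",
              x$label, x$carbons, x$double_bonds, om))
  invisible(x)
}

#' Construct a FAME composition profile for one strain
#'
#' A profile is a compositional vector of relative percentages (percent of
#' total FAMEs) keyed by fatty-acid species. On construction every label is
#' parsed and canonicalized, negative fractions are rejected, and the column
#' total is checked against a plausibility gate (GC-MS relative-percentage
#' tables should sum to roughly 100).
#'
#' @param strain_id character scalar naming the strain.
#' @param fractions named numeric vector; names are fatty-acid labels
#'   understood by [parse_fa_name()], values relative percentages.
#' @param total_gate numeric length-2, the accepted range for the column
#'   total, or \code{NULL} to skip the check.
#' @return An object of class \code{"fame_profile"} with elements
#'   \code{strain_id}, \code{species} (data frame: label, carbons,
#'   double_bonds, omega, fraction) and \code{total}.
#' @examples
#' p <- fame_profile("demo", c("C16:0" = 40, "C18:1 (ω9)" = 60))
#' fa_class_summary(p)
#' @export
fame_profile <- function(strain_id, fractions, total_gate = c(95, 105)) {
  if (!is.character(strain_id) || length(strain_id) != 1L) {
    stop("'strain_id' must be a single string", call. = FALSE)
  }
  if (!is.numeric(fractions) || is.null(names(fractions)) || length(fractions) == 0L) {
    stop("'fractions' must be a non-empty named numeric vector", call. = FALSE)
  }
  if (anyNA(fractions)) {
    stop(sprintf("strain '%s': fractions contain NA", strain_id), call. = FALSE)
  }
  if (any(fractions < 0)) {
    bad <- names(fractions)[fractions < 0][1L]
    stop(sprintf("strain '%s': negative fraction for '%s'", strain_id, bad),
         call. = FALSE)
  }
  fas <- lapply(names(fractions), parse_fa_name)
  labels <- vapply(fas, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop(sprintf("strain '%s': duplicate fatty-acid label '%s'", strain_id, dup),
         call. = FALSE)
  }
  species <- data.frame(
    label = labels,
    carbons = vapply(fas, `[[`, integer(1L), "carbons"),
    double_bonds = vapply(fas, `[[`, integer(1L), "double_bonds"),
    omega = vapply(fas, `[[`, integer(1L), "omega"),
    fraction = as.numeric(fractions),
    stringsAsFactors = FALSE
  )
  total <- sum(species$fraction)
  if (!is.null(total_gate)) {
    if (total < total_gate[1L] || total > total_gate[2L]) {
      stop(sprintf("strain '%s': profile total %.4f outside accepted range [%g, %g]",
                   strain_id, total, total_gate[1L], total_gate[2L]),
           call. = FALSE)
    }
  }
  structure(list(strain_id = strain_id, species = species, total = total),
            class = "fame_profile")
}

#' @export
print.fame_profile <- function(x, ...) {
  cat(sprintf("<FAME profile> strain %s: %d species, total %.2f%%\n",
              x$strain_id, nrow(x$species), x$total))
  df <- x$species[order(-x$species$fraction), c("label", "fraction")]
  top <- utils::head(df, 5L)
  cat(paste(sprintf("  %-12s %6.2f", top$label, top$fraction), collapse = "\n"),
      "\n", sep = "")
  if (nrow(df) > 5L) cat(sprintf("  ... and %d more\n", nrow(df) - 5L))
  invisible(x)
}

#' Read FAME composition profiles from a delimited table
#'
#' Expects the wide layout of published FAME tables: first column fatty-acid
#' labels, remaining columns one strain each, cells holding relative
#' percentages. Not-detected markers (en dash, hyphen, empty cell, "ND") are
#' read as zero, i.e. below detection rather than missing. The field
#' separator is auto-detected (comma vs tab) unless given.
#'
#' @param file path to a delimited text file (UTF-8).
#' @param sep field separator, or \code{NULL} to auto-detect.
#' @param na_strings markers interpreted as not-detected (mapped to 0).
#' @param total_gate passed to [fame_profile()]; per-strain totals outside
#'   this range raise a validation error.
#' @return Named list of [fame_profile] objects, one per strain column.
#' @examples
#' path <- system.file("extdata", "fame_profiles_pkessleri.csv",
#'                     package = "phycodiesel")
#' profiles <- read_fame_profiles(path)
#' profiles$WS
#' @export
read_fame_profiles <- function(file, sep = NULL,
                               na_strings = c("–", "-", "", "ND", "nd"),
                               total_gate = c(95, 105)) {
  if (!file.exists(file)) stop(sprintf("file not found: %s", file), call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(file, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          encoding = "UTF-8", fileEncoding = "UTF-8",
                          strip.white = TRUE)
  if (ncol(df) < 2L) stop("profile table needs a label column plus at least one strain column",
                          call. = FALSE)
  labels <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate fatty-acid label '%s' in %s",
                 labels[duplicated(labels)][1L], file), call. = FALSE)
  }
  strains <- names(df)[-1L]
  out <- vector("list", length(strains))
  names(out) <- strains
  for (j in seq_along(strains)) {
    raw <- trimws(as.character(df[[j + 1L]]))
    raw[raw %in% na_strings | is.na(raw)] <- "0"
    vals <- suppressWarnings(as.numeric(raw))
    if (anyNA(vals)) {
      bad <- labels[which(is.na(vals))[1L]]
      stop(sprintf("strain '%s': non-numeric cell at '%s'", strains[j], bad),
           call. = FALSE)
    }
    fr <- stats::setNames(vals, labels)
    out[[j]] <- fame_profile(strains[j], fr, total_gate = total_gate)
  }
  out
}

#' Rescale a profile so its fractions sum to exactly 100
#'
#' GC-MS relative-percentage columns rarely total 100 exactly; this closure
#' operation rescales every fraction by \code{100/total}. The input profile
#' is unchanged (copy semantics). Idempotent.
#'
#' @param profile a [fame_profile].
#' @return A new \code{fame_profile} whose total is 100 (to within 1e-9).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "fame_profile"))
  if (profile$total <= 0) {
    stop(sprintf("strain '%s': cannot normalize a profile with total %g",
                 profile$strain_id, profile$total), call. = FALSE)
  }
  out <- profile
  out$species$fraction <- profile$species$fraction * (100 / profile$total)
  out$total <- sum(out$species$fraction)
  out
}

#' Saturation-class summary and average degree of unsaturation
#'
#' Partitions a profile's fractions by double-bond count into saturated
#' (0 bonds), monounsaturated (1) and polyunsaturated (>= 2) classes, and
#' computes the average degree of unsaturation
#' \deqn{ADU = \sum_i N_i \, M_i}{ADU = sum_i N_i * M_i}
#' where \eqn{N_i} is the number of C=C bonds of species \eqn{i} and
#' \eqn{M_i} its mass fraction on the 0–1 scale (percentage / 100), so a pure
#' C18:1 profile has ADU 1. Also reported: the percentage of species with
#' four or more double bonds (EN 14214's "Db >= 4" limit), the C18:3
#' percentage (linolenic limit), and the share of 16–18 carbon chains.
#'
#' By default classes are computed on the raw (as-loaded) percentages; set
#' \code{renormalize = TRUE} to compute them on the profile rescaled to a
#' 100% total.
#'
#' @param profile a [fame_profile].
#' @param renormalize logical; rescale to a 100 total first.
#' @return An object of class \code{"fa_class_summary"}: list with
#'   \code{strain_id}, \code{sfa_pct}, \code{mufa_pct}, \code{pufa_pct},
#'   \code{db4plus_pct}, \code{c18_3_pct}, \code{c16_c18_pct}, \code{adu},
#'   \code{total}.
#' @export
fa_class_summary <- function(profile, renormalize = FALSE) {
  stopifnot(inherits(profile, "fame_profile"))
  if (isTRUE(renormalize)) profile <- normalize_profile(profile)
  sp <- profile$species
  n <- sp$double_bonds
  f <- sp$fraction
  structure(list(
    strain_id = profile$strain_id,
    sfa_pct = sum(f[n == 0L]),
    mufa_pct = sum(f[n == 1L]),
    pufa_pct = sum(f[n >= 2L]),
    db4plus_pct = sum(f[n >= 4L]),
    c18_3_pct = sum(f[sp$carbons == 18L & n == 3L]),
    c16_c18_pct = sum(f[sp$carbons >= 16L & sp$carbons <= 18L]),
    adu = sum(n * f) / 100,
    total = sum(f)
  ), class = "fa_class_summary")
}

#' @export
print.fa_class_summary <- function(x, ...) {
  cat(sprintf("<FA class summary> strain %s\n", x$strain_id))
  cat(sprintf("  SFA %6.2f%%  MUFA %6.2f%%  PUFA %6.2f%%  (total %.2f%%)\n",
              x$sfa_pct, x$mufa_pct, x$pufa_pct, x$total))
  cat(sprintf("  Db>=4 %5.2f%%  C18:3 %5.2f%%  C16-C18 %6.2f%%  ADU %.3f\n",
              x$db4plus_pct, x$c18_3_pct, x$c16_c18_pct, x$adu))
  invisible(x)
}

#' Tabulate class summaries for a set of profiles
#'
#' @param profiles list of [fame_profile] objects (as from
#'   [read_fame_profiles()]).
#' @param renormalize passed to [fa_class_summary()].
#' @return data.frame with one row per strain: strain, sfa, mufa, pufa,
#'   db4plus, c18_3, c16_c18, adu, total.
#' @export
summarize_profiles <- function(profiles, renormalize = FALSE) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  rows <- lapply(profiles, function(p) {
    s <- fa_class_summary(p, renormalize = renormalize)
    data.frame(strain = s$strain_id, sfa = s$sfa_pct, mufa = s$mufa_pct,
               pufa = s$pufa_pct, db4plus = s$db4plus_pct,
               c18_3 = s$c18_3_pct, c16_c18 = s$c16_c18_pct,
               adu = s$adu, total = s$total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
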