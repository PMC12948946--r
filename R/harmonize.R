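# Harmonisation of the three survey tables into one analysis-ready table,
# implementing the stated filtering, derivation and recoding rules.

flour_vocabulary <- function() {
  path <- system.file("extdata", "flour_vocabulary.json", package = "sourveyor")
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Merge registration, results and laboratory tables
#'
#' Outer merge anchored on the registration table, linked by unique
#' 5-character sample codes. Result-phase variables that are missing in the
#' results table but present in registration are back-filled and flagged
#' (`registration_backfill`) in the per-cell provenance map. Result rows
#' whose code is absent from registration are quarantined with a warning;
#' laboratory rows without a registration match are reported in the QC
#' block, never silently dropped.
#'
#' @param registration registration survey data.frame (one row per sample;
#'   must carry `sample_code` and `person_id`).
#' @param results results survey data.frame (may be `NULL`).
#' @param lab laboratory measurement data.frame (may be `NULL`).
#' @return data.frame of class `integrated_table`, one row per registered
#'   sample, with attributes `provenance` (per-cell origin for back-fillable
#'   columns), `quarantine` (orphan result rows) and `qc` (counts).
#' @export
merge_tables <- function(registration, results = NULL, lab = NULL) {
  stopifnot(is.data.frame(registration),
            all(c("sample_code", "person_id") %in% names(registration)))
  check_dupes <- function(df, nm) {
    if (is.null(df)) return(invisible())
    d <- df$sample_code[duplicated(df$sample_code)]
    if (length(d)) {
      stop("duplicate sample_code in ", nm, " table: ",
           paste(unique(d), collapse = ", "), call. = FALSE)
    }
  }
  check_dupes(registration, "registration")
  check_dupes(results, "results")
  check_dupes(lab, "lab")

  out <- registration
  qc <- list(n_registration = nrow(registration),
             n_results = if (is.null(results)) 0L else nrow(results),
             n_lab = if (is.null(lab)) 0L else nrow(lab))
  quarantine <- NULL
  provenance <- list()

  if (!is.null(results) && nrow(results)) {
    orphan <- !results$sample_code %in% registration$sample_code
    if (any(orphan)) {
      quarantine <- results[orphan, , drop = FALSE]
      warning(sum(orphan), " results row(s) without a registration match ",
              "were quarantined", call. = FALSE)
      results <- results[!orphan, , drop = FALSE]
    }
    idx <- match(out$sample_code, results$sample_code)
    shared <- setdiff(intersect(names(results), names(out)),
                      c("sample_code", "person_id"))
    new_cols <- setdiff(names(results), c(names(out), "person_id"))
    for (col in new_cols) out[[col]] <- results[[col]][idx]
    # back-fill: results value wins; registration fills the gaps and is flagged
    for (col in shared) {
      res_val <- results[[col]][idx]
      reg_val <- out[[col]]
      filled <- is.na(res_val) & !is.na(reg_val) & !is.na(idx)
      prov <- rep(NA_character_, nrow(out))
      prov[!is.na(idx) & !is.na(res_val)] <- "results"
      prov[filled] <- "registration_backfill"
      out[[col]] <- ifelse(is.na(res_val), reg_val, res_val)
      provenance[[col]] <- prov
    }
    qc$n_quarantined <- if (is.null(quarantine)) 0L else nrow(quarantine)
  }

  if (!is.null(lab) && nrow(lab)) {
    orphan_lab <- lab$sample_code[!lab$sample_code %in% registration$sample_code]
    if (length(orphan_lab)) {
      warning(length(orphan_lab), " lab row(s) have no registration match",
              call. = FALSE)
    }
    qc$lab_orphans <- orphan_lab
    idx <- match(out$sample_code, lab$sample_code)
    for (col in setdiff(names(lab), c("sample_code", "person_id"))) {
      out[[col]] <- lab[[col]][idx]
      provenance[[col]] <- ifelse(is.na(idx), NA_character_, "lab")
    }
  }

  structure(out, class = c("integrated_table", "data.frame"),
            provenance = provenance, quarantine = quarantine, qc = qc)
}

#' Dough yield
#'
#' DY = (flour + water) / flour * 100; dimensionless, 200 means equal masses
#' of flour and water. Scale-invariant in the ingredient masses.
#'
#' @param flour_g flour mass in grams (> 0).
#' @param water_g water mass in grams (>= 0).
#' @return numeric dough yield; `NA` inputs propagate.
#' @export
compute_dough_yield <- function(flour_g, water_g) {
  bad <- !is.na(flour_g) & flour_g <= 0
  if (any(bad)) {
    stop("dough yield undefined for flour_g <= 0 (", sum(bad), " value(s))",
         call. = FALSE)
  }
  (flour_g + water_g) / flour_g * 100
}

#' Decompose a flour label into grain base and milling grade
#'
#' Composite survey labels such as "wholemeal rye" are split into the grain
#' base (wheat, spelt, rye, mixture) and milling grade (wholemeal,
#' semi-wholemeal, endosperm, or unspecified when no qualifier is present).
#' With `grouped = TRUE` (the view used for chi-square analyses),
#' semi-wholemeal is recoded to wholemeal; numeric/feature-space views keep
#' the two distinct.
#'
#' @param label character vector of flour labels from the controlled
#'   vocabulary.
#' @param grouped collapse semi-wholemeal into wholemeal?
#' @return data.frame with columns `grain_base` and `milling_grade`.
#' @export
decompose_flour <- function(label, grouped = FALSE) {
  voc <- flour_vocabulary()
  grades <- voc$milling_grades
  grains <- voc$grain_bases
  lab <- trimws(tolower(label))
  grain <- rep(NA_character_, length(lab))
  grade <- rep(voc$unspecified_grade, length(lab))
  remaining <- lab
  # longest grade first so "semi-wholemeal" is not matched as "wholemeal"
  for (g in grades[order(-nchar(grades))]) {
    hit <- !is.na(remaining) & startsWith(remaining, paste0(g, " "))
    grade[hit] <- g
    remaining[hit] <- trimws(substring(remaining[hit], nchar(g) + 2))
  }
  known <- remaining %in% grains
  grain[known] <- remaining[known]
  bad <- !is.na(lab) & !known
  if (any(bad)) {
    stop("unrecognised flour label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  grade[is.na(lab)] <- NA_character_
  if (grouped) grade[grade == "semi-wholemeal"] <- "wholemeal"
  data.frame(grain_base = grain, milling_grade = grade,
             stringsAsFactors = FALSE)
}

#' Bin rare categorical levels as "Other"
#'
#' Levels present at <= `threshold` prevalence among non-missing entries are
#' relabelled `"Other"` (the threshold is inclusive). Missing entries are
#' untouched; the number of distinct levels never increases.
#'
#' @param column character or factor vector.
#' @param threshold prevalence threshold (default 1%).
#' @return character vector.
#' @export
bin_rare_levels <- function(column, threshold = 0.01) {
  x <- as.character(column)
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  prev <- table(x[ok]) / sum(ok)
  rare <- names(prev)[prev <= threshold]
  x[ok & x %in% rare] <- "Other"
  x
}

#' Filter erroneous bread densities
#'
#' Bread density in g/cm3 cannot exceed 1; strictly greater values are
#' treated as reporting errors and removed. The boundary value 1 is
#' retained. The count of removed values is attached as attribute
#' `n_excluded` for the QC report; `NA`s are kept (per-variable missingness
#' is handled downstream).
#'
#' @param values numeric densities.
#' @return retained values with attribute `n_excluded`.
#' @export
filter_bread_density <- function(values) {
  drop <- !is.na(values) & values > 1
  out <- values[!drop]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Categorise a numeric variable into half-open bins
#'
#' Bins are lower-inclusive, upper-exclusive: `[a, b)`. Values at or above
#' the last edge fall into an open-ended top bin `">=b"`; values below the
#' first edge into `"<a"`.
#'
#' @param values numeric vector.
#' @param bin_edges strictly increasing numeric edges.
#' @return ordered factor.
#' @export
categorize_numeric <- function(values, bin_edges) {
  if (length(bin_edges) < 1 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing", call. = FALSE)
  }
  k <- length(bin_edges)
  labels <- c(paste0("<", bin_edges[1]),
              if (k > 1) paste0("[", bin_edges[-k], ",", bin_edges[-1], ")"),
              paste0(">=", bin_edges[k]))
  idx <- findInterval(values, bin_edges) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Harmonise a generated or loaded study into an integrated table
#'
#' Runs the full curation pass: table merge with back-filling, dough-yield
#' derivation, flour decomposition (both the grouped chi-square view and the
#' resolution-preserving view), bread-density QC filtering (erroneous values
#' are blanked, not row-dropped, so per-variable exclusion still applies),
#' and rare-level binning of categorical analysis variables.
#'
#' @param study a `sourdough_study` or a list with `registration`, `results`,
#'   `lab` data.frames.
#' @param bin_threshold rare-level prevalence threshold.
#' @return `integrated_table` with derived columns `dough_yield`,
#'   `grain_base`, `milling_grade`, `milling_grade_grouped`; QC counts in
#'   `attr(, "qc")`.
#' @export
harmonize_study <- function(study, bin_threshold = 0.01) {
  tab <- merge_tables(study$registration, study$results, study$lab)
  qc <- attr(tab, "qc")

  tab$dough_yield <- ifelse(!is.na(tab$flour_g) & tab$flour_g > 0,
                            (tab$flour_g + tab$water_g) / tab$flour_g * 100,
                            NA_real_)
  dec <- decompose_flour(tab$flour_type, grouped = FALSE)
  tab$grain_base <- dec$grain_base
  tab$milling_grade <- dec$milling_grade
  tab$milling_grade_grouped <- decompose_flour(tab$flour_type,
                                               grouped = TRUE)$milling_grade

  if ("bread_density" %in% names(tab)) {
    bad <- !is.na(tab$bread_density) & tab$bread_density > 1
    qc$n_density_excluded <- sum(bad)
    tab$bread_density[bad] <- NA
  }
  for (col in intersect(c("flour_type", "grain_base", "skill"), names(tab))) {
    tab[[col]] <- bin_rare_levels(tab[[col]], bin_threshold)
  }
  attr(tab, "qc") <- qc
  tab
}

#' Household/bakery contrast view
#'
#' Drops samples with unknown source and the rare industrial label, leaving
#' the household-versus-bakery contrast used throughout the descriptive
#' analyses.
#'
#' @param table an `integrated_table` (or data.frame with a `source` column).
#' @return filtered table with attribute `n_excluded`.
#' @export
source_contrast <- function(table) {
  keep <- !is.na(table$source) & table$source %in% c("household", "bakery")
  out <- table[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}
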