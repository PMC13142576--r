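# Delimited-text cohort IO with schema validation.

#' Cohort column dictionary
#'
#' Machine-readable description of the participant-visit table schema.
#' The same table is shipped as a plain-text sidecar at
#' `system.file("extdata", "cohort-dictionary.csv", package = "cogdisp")`.
#'
#' @return data.frame with `column`, `type`, `required`, `description`.
#' @export
cohort_dictionary <- function() {
  reg <- test_registry()
  core <- data.frame(
    column = c("participant_id", "group", "visit_index",
               "visit_offset_years", "age", "sex", "education"),
    type = c("character", "character", "integer", "numeric", "numeric",
             "character", "numeric"),
    required = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    description = c(
      "opaque participant identifier",
      "generator ground-truth group (hc/stage2); optional on real data",
      "visit number, 0 = first visit with complete battery",
      "years since baseline visit, >= 0",
      "age in years at visit",
      "binary sex category, M or F",
      "education in years, >= 0"),
    stringsAsFactors = FALSE
  )
  tests <- data.frame(
    column = reg$test, type = "numeric", required = TRUE,
    description = paste0("raw score: ", reg$label,
                         ifelse(reg$higher_is_worse,
                                " (seconds; higher = worse)", "")),
    stringsAsFactors = FALSE
  )
  scales <- data.frame(
    column = c("updrs3", "hoehn_yahr", "scopa_aut", "gds15", "quip",
               "stai_state", "upsit", "ess", "rbdsq", "moca"),
    type = "numeric", required = TRUE,
    description = c("MDS-UPDRS Part III motor score", "Hoehn & Yahr stage",
                    "SCOPA-AUT autonomic score", "GDS-15 depression score",
                    "QUIP impulsive-compulsive score", "STAI state anxiety",
                    "UPSIT smell identification (0-40)",
                    "Epworth Sleepiness Scale", "RBD Screening Questionnaire",
                    "Montreal Cognitive Assessment (0-30)"),
    stringsAsFactors = FALSE
  )
  flags <- data.frame(
    column = c("saa_positive", "dat_deficit", "hyposmia",
               "functional_impairment"),
    type = c("logical", "logical", "logical", "character"),
    required = TRUE,
    description = c(
      "CSF alpha-synuclein seed amplification assay positive (may be missing)",
      "putamen SBR < 75% of age/sex-adjusted reference (may be missing)",
      "hyposmia flag",
      "ordered functional impairment: none, slight, greater"),
    stringsAsFactors = FALSE
  )
  rbind(core, tests, scales, flags)
}

required_cohort_columns <- function() {
  d <- cohort_dictionary()
  d$column[d$required]
}

# Schema validation shared by read_cohort() and the pipeline entry.
check_cohort <- function(cohort) {
  dict <- cohort_dictionary()
  miss <- setdiff(required_cohort_columns(), names(cohort))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dup <- duplicated(cohort[c("participant_id", "visit_index")])
  if (any(dup)) {
    stop("duplicate (participant_id, visit_index) rows: ",
         paste(unique(cohort$participant_id[dup]), collapse = ", "))
  }
  num_cols <- dict$column[dict$type == "numeric" & dict$column %in% names(cohort)]
  for (cl in num_cols) {
    if (!is.numeric(cohort[[cl]])) {
      stop("column '", cl, "' must be numeric")
    }
  }
  if (any(cohort$education < 0, na.rm = TRUE)) {
    stop("column 'education' has negative values")
  }
  if (any(cohort$moca < 0 | cohort$moca > 30, na.rm = TRUE)) {
    stop("column 'moca' outside [0, 30]")
  }
  if (any(cohort$visit_offset_years < 0, na.rm = TRUE)) {
    stop("column 'visit_offset_years' has negative values")
  }
  fi <- cohort$functional_impairment
  if (!all(is.na(fi) | fi %in% c("none", "slight", "greater"))) {
    stop("column 'functional_impairment' must be none/slight/greater")
  }
  for (cl in c("saa_positive", "dat_deficit", "hyposmia")) {
    if (!is.logical(cohort[[cl]])) {
      stop("column '", cl, "' must be logical (TRUE/FALSE, blank for missing)")
    }
  }
  invisible(cohort)
}

#' Read and write participant-visit cohort tables
#'
#' UTF-8 comma-separated text, one row per participant-visit, with the
#' schema of [cohort_dictionary()]. Missing values are written as empty
#' fields. Unknown extra columns are preserved on read and write; a
#' violated schema errors naming the offending column, and duplicated
#' (participant, visit) keys are rejected.
#'
#' @param path file path.
#' @param cohort participant-visit data.frame.
#' @param dictionary if `TRUE`, also write the column dictionary next to
#'   the cohort file as `<path>.dict.csv`.
#' @return `read_cohort()` the validated data.frame; `write_cohort()`
#'   the path, invisibly.
#' @examples
#' cfg <- simulation_config(seed = 3, n_hc = 10, n_stage2 = 15, quiet = TRUE)
#' coh <- simulate_cohort(cfg)
#' tmp <- tempfile(fileext = ".csv")
#' write_cohort(coh, tmp)
#' identical(read_cohort(tmp), coh)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = "", fileEncoding = "UTF-8")
  for (cl in c("saa_positive", "dat_deficit", "hyposmia")) {
    if (cl %in% names(x) && !is.logical(x[[cl]])) {
      if (all(is.na(x[[cl]]) | x[[cl]] %in% c("TRUE", "FALSE"))) {
        x[[cl]] <- as.logical(x[[cl]])
      }
    }
  }
  if ("visit_index" %in% names(x)) x$visit_index <- as.integer(x$visit_index)
  dict <- cohort_dictionary()
  for (cl in dict$column[dict$type == "numeric"]) {
    if (cl %in% names(x) && is.numeric(x[[cl]])) x[[cl]] <- as.double(x[[cl]])
  }
  check_cohort(x)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path, dictionary = FALSE) {
  check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  if (dictionary) {
    utils::write.csv(cohort_dictionary(), paste0(path, ".dict.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
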