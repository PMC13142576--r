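# NSD-ISS stage assignment, control eligibility, and one-year
# conversion labeling.
#
# Staging is anchored on SAA positivity (neuronal alpha-synuclein
# disease present) and dopaminergic deficit (DAT putamen SBR < 75% of
# the age/sex-adjusted reference, consumed here as a precomputed flag):
#   SAA+, subtle signs, no functional impairment -> Stage 2A (no DAT
#     deficit) or 2B (DAT deficit)
#   SAA+ with slight-or-greater functional impairment -> Stage 3+
#   SAA+ without subtle signs -> Stage 1
#   SAA- -> healthy-control candidate (full eligibility is checked by
#     hc_eligibility(), which also needs the Year-1 MoCA)
# "Subtle signs or symptoms" are operationalised, for synthetic data, as
# any of: hyposmia flag, RBDSQ >= 5, or MDS-UPDRS III > 0. Real-data
# users can supply their own sign indicator via `signs`.

stage_levels <- c("HC-eligible", "1", "2A", "2B", "3plus")

#' Assign an NSD-ISS stage label to each visit record
#'
#' A pure per-record function: no information flows across visits (the
#' one-year conversion label is the only cross-visit construct, see
#' [label_conversion()]).
#'
#' @param records participant-visit data.frame.
#' @param signs optional logical vector of "subtle signs present",
#'   overriding the built-in rule.
#' @return data.frame with `participant_id`, `visit_index`, `stage`
#'   (factor with levels HC-eligible, 1, 2A, 2B, 3plus; `NA` when
#'   unstageable) and semicolon-joined `reasons` codes.
#' @export
assign_stage <- function(records, signs = NULL) {
  n <- nrow(records)
  if (is.null(signs)) {
    signs <- (records$hyposmia %in% TRUE) |
      (!is.na(records$rbdsq) & records$rbdsq >= 5) |
      (!is.na(records$updrs3) & records$updrs3 > 0)
  }
  stopifnot(length(signs) == n)
  saa <- records$saa_positive
  dat <- records$dat_deficit
  impaired <- !is.na(records$functional_impairment) &
    records$functional_impairment %in% c("slight", "greater")

  stage <- rep(NA_character_, n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (is.na(saa[i])) {
      r <- "missing_saa"
    } else if (!saa[i]) {
      stage[i] <- "HC-eligible"
      r <- "saa_negative"
    } else {
      r <- "saa_positive"
      if (impaired[i]) {
        stage[i] <- "3plus"
        r <- c(r, "functional_impairment")
      } else if (!signs[i]) {
        stage[i] <- "1"
        r <- c(r, "no_subtle_signs")
      } else if (is.na(dat[i])) {
        r <- c(r, "subtle_signs", "missing_dat")
      } else {
        stage[i] <- if (dat[i]) "2B" else "2A"
        r <- c(r, "subtle_signs",
               if (dat[i]) "dat_deficit" else "no_dat_deficit")
      }
    }
    reasons[i] <- paste(r, collapse = ";")
  }
  data.frame(participant_id = records$participant_id,
             visit_index = records$visit_index,
             stage = factor(stage, levels = stage_levels),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Healthy-control analysis eligibility
#'
#' A control qualifies when the baseline MoCA is >= 27, there is no
#' hyposmia, the SAA test is negative, the Year-1 MoCA is >= 26, and
#' the baseline-to-Year-1 decline is at most 2 points.
#'
#' @param baseline,year1 single-row records (or aligned data.frames) for
#'   the same participant(s).
#' @return data.frame with `participant_id`, `eligible`, `reasons`.
#' @export
hc_eligibility <- function(baseline, year1) {
  stopifnot(nrow(baseline) == nrow(year1) ||
              is.null(year1) || nrow(year1) == 0)
  n <- nrow(baseline)
  eligible <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    b_moca <- baseline$moca[i]
    y_moca <- if (is.null(year1) || nrow(year1) == 0) NA else year1$moca[i]
    if (is.na(baseline$saa_positive[i]) || baseline$saa_positive[i]) {
      r <- c(r, "saa_not_negative")
    }
    if (baseline$hyposmia[i] %in% TRUE) r <- c(r, "hyposmia")
    if (is.na(b_moca) || b_moca < 27) r <- c(r, "baseline_moca_below_27")
    if (is.na(y_moca)) {
      r <- c(r, "missing_year1_moca")
    } else {
      if (y_moca < 26) r <- c(r, "year1_moca_below_26")
      if (!is.na(b_moca) && b_moca - y_moca > 2) r <- c(r, "moca_decline_gt_2")
    }
    eligible[i] <- length(r) == 0
    reasons[i] <- paste(r, collapse = ";")
  }
  data.frame(participant_id = baseline$participant_id,
             eligible = eligible, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Label one-year conversion outcomes for Stage 2 participants
#'
#' A Stage 2 (2A/2B at baseline) participant is `followed` when they
#' have a complete-battery visit whose offset falls in the conversion
#' window; `converted` is `TRUE` when the earliest such visit is staged
#' 3+ and is `NA` when not followed.
#'
#' @param stages per-visit stage labels from [assign_stage()].
#' @param visits participant-visit data.frame supplying
#'   `visit_offset_years` and battery completeness (all 11 raw scores
#'   present).
#' @param registry the test registry (for the battery columns).
#' @param window numeric length-2 conversion window in years.
#' @return data.frame with one row per baseline-Stage-2 participant:
#'   `participant_id`, `baseline_stage`, `followed`, `converted`,
#'   `year1_stage`, `year1_visit_index`.
#' @export
label_conversion <- function(stages, visits, registry = test_registry(),
                             window = c(0.75, 1.25)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  key <- paste(visits$participant_id, visits$visit_index)
  skey <- paste(stages$participant_id, stages$visit_index)
  visits$stage <- stages$stage[match(key, skey)]
  visits$complete <- stats::complete.cases(visits[registry$test])

  base <- visits[visits$visit_index == 0 & visits$stage %in% c("2A", "2B"), ]
  fu <- visits[visits$visit_index > 0 & visits$complete &
                 !is.na(visits$visit_offset_years) &
                 visits$visit_offset_years >= window[1] &
                 visits$visit_offset_years <= window[2], , drop = FALSE]
  # earliest qualifying follow-up visit per participant
  fu <- fu[order(fu$participant_id, fu$visit_offset_years), , drop = FALSE]
  fu <- fu[!duplicated(fu$participant_id), , drop = FALSE]
  m <- match(base$participant_id, fu$participant_id)

  res <- data.frame(
    participant_id = base$participant_id,
    baseline_stage = as.character(base$stage),
    followed = !is.na(m),
    converted = ifelse(is.na(m), NA, fu$stage[m] == "3plus"),
    year1_stage = ifelse(is.na(m), NA_character_,
                         as.character(fu$stage[m])),
    year1_visit_index = ifelse(is.na(m), NA_integer_, fu$visit_index[m]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Baseline-by-Year-1 stage transition counts
#'
#' Tabulates followed Stage 2 participants by baseline stage and
#' follow-up stage; cell counts sum to the number followed.
#'
#' @param outcomes output of [label_conversion()].
#' @return a contingency table (baseline stage x Year-1 stage).
#' @export
transition_counts <- function(outcomes) {
  f <- outcomes[outcomes$followed, , drop = FALSE]
  table(baseline = factor(f$baseline_stage, levels = c("2A", "2B")),
        year1 = factor(f$year1_stage, levels = stage_levels))
}
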