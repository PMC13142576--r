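# End-to-end orchestration: simulate or read a cohort, norm, compute
# dispersion, stage, compare groups, correlate, fit conversion models,
# and emit the report bundle.

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

table1_variables <- c("age", "education", "updrs3", "hoehn_yahr",
                      "scopa_aut", "gds15", "quip", "stai_state", "upsit",
                      "ess", "rbdsq", "moca", "mean_composite", "cov_total",
                      "ae_composite", "cov_ae")
table2_variables <- c("mean_composite", "cov_total", "ae_composite",
                      "cov_ae", "age", "education", "updrs3", "hoehn_yahr",
                      "scopa_aut", "gds15", "quip", "stai_state", "upsit",
                      "ess", "rbdsq")
correlation_variables <- c("age", "education", "updrs3", "gds15",
                           "stai_state", "upsit")

#' Run the full dispersion analysis pipeline
#'
#' Executes, in order: cohort simulation (or file input), stage
#' assignment and healthy-control eligibility, internal norm fitting on
#' the reference group, T-scoring, dispersion computation, baseline
#' group comparisons (control vs Stage 2, and converter vs non-converter
#' among followed Stage 2), CoV-clinical correlations, the two logistic
#' conversion models, and stage transition counts. Identical
#' configuration and seed give an identical bundle.
#'
#' When the cohort contains no Stage 2 participants (or no followed
#' converters and non-converters), the conversion comparison and
#' logistic stages are skipped with an explicit notice in `$notices`.
#'
#' @param config a [simulation_config()], or a path to a cohort CSV.
#' @param alpha significance level for selective demographic correction.
#' @param q false-discovery rate for the comparison tables.
#' @param window conversion window in years.
#' @param norm_reference `"hc"` (default) fits norms on the eligible
#'   control baselines; `"all"` uses every baseline record.
#' @param out_dir optional directory: every table is written as CSV plus
#'   an aligned-text mirror, with the seed and configuration echoed.
#' @param registry the test registry.
#' @return list of class `"dispersion_report"`.
#' @export
run_full_pipeline <- function(config, alpha = 0.05, q = 0.05,
                              window = c(0.75, 1.25),
                              norm_reference = c("hc", "all"),
                              out_dir = NULL,
                              registry = test_registry()) {
  norm_reference <- match.arg(norm_reference)
  stopifnot(q > 0, q < 1, length(window) == 2, window[1] < window[2])
  notices <- character(0)

  cohort <- pipeline_stage("input", {
    if (inherits(config, "simulation_config")) {
      simulate_cohort(config, registry)
    } else if (is.character(config) && length(config) == 1) {
      read_cohort(config)
    } else stop("config must be a simulation_config or a file path")
  })
  check_cohort(cohort)

  stages <- pipeline_stage("staging", assign_stage(cohort))
  baseline <- cohort[cohort$visit_index == 0, , drop = FALSE]
  b_stage <- stages[stages$visit_index == 0, , drop = FALSE]

  ## healthy-control analysis set: SAA-negative baselines passing the
  ## MoCA eligibility rules against their Year-1 visit
  hc_candidates <- baseline[!is.na(baseline$saa_positive) &
                              !baseline$saa_positive, , drop = FALSE]
  year1 <- cohort[cohort$visit_index > 0, , drop = FALSE]
  year1 <- year1[!duplicated(year1$participant_id), , drop = FALSE]
  y1m <- year1[match(hc_candidates$participant_id, year1$participant_id), ,
               drop = FALSE]
  hc_elig <- pipeline_stage("hc_eligibility",
                            hc_eligibility(hc_candidates, y1m))
  hc_ids <- hc_elig$participant_id[hc_elig$eligible]
  s2_ids <- b_stage$participant_id[b_stage$stage %in% c("2A", "2B")]
  s2_ids <- s2_ids[!is.na(s2_ids)]

  norms <- pipeline_stage("norm_fit", {
    ref <- if (norm_reference == "hc") {
      baseline[baseline$participant_id %in% hc_ids, , drop = FALSE]
    } else baseline
    fit_norms(ref, registry, alpha = alpha)
  })
  tscores <- pipeline_stage("norm_apply", apply_norms(cohort, norms))
  dispersion <- pipeline_stage("dispersion",
                               suppressMessages(compute_dispersion(tscores, registry)))

  analysis <- pipeline_stage("analysis_frame", {
    d0 <- dispersion[dispersion$visit_index == 0, , drop = FALSE]
    af <- merge(baseline, d0[setdiff(names(d0), "visit_index")],
                by = "participant_id")
    af$analysis_group <- ifelse(af$participant_id %in% hc_ids, "hc",
                                ifelse(af$participant_id %in% s2_ids,
                                       "stage2", NA))
    af
  })

  ## Table-1-style: control vs Stage 2 at baseline
  table1 <- NULL
  if (length(hc_ids) >= 2 && length(s2_ids) >= 2) {
    table1 <- pipeline_stage("table1", {
      d <- analysis[!is.na(analysis$analysis_group), , drop = FALSE]
      compare_groups(d, "analysis_group", table1_variables,
                     categorical = "sex", q = q,
                     levels = c("hc", "stage2"))
    })
  } else {
    notices <- c(notices, "group comparison skipped: need both a control and a Stage 2 set")
  }

  ## conversion labeling among Stage 2
  outcomes <- NULL
  transitions <- NULL
  table2 <- NULL
  models <- NULL
  if (length(s2_ids)) {
    outcomes <- pipeline_stage("conversion_labels",
                               label_conversion(stages, cohort, registry,
                                                window = window))
    transitions <- transition_counts(outcomes)
    fol <- outcomes[outcomes$followed, , drop = FALSE]
    if (nrow(fol) && length(unique(fol$converted)) == 2) {
      conv_frame <- pipeline_stage("conversion_frame", {
        cf <- analysis[analysis$participant_id %in% fol$participant_id, ,
                       drop = FALSE]
        cf$converted <- fol$converted[match(cf$participant_id,
                                            fol$participant_id)]
        cf$conversion_group <- ifelse(cf$converted, "converted",
                                      "not_converted")
        cf
      })
      table2 <- pipeline_stage("table2",
        compare_groups(conv_frame, "conversion_group", table2_variables,
                       q = q, levels = c("not_converted", "converted")))
      models <- pipeline_stage("conversion_models",
        run_conversion_models(outcomes, dispersion, baseline))
    } else {
      notices <- c(notices,
                   "conversion comparison and logistic stages skipped: need followed converters and non-converters")
    }
  } else {
    notices <- c(notices, "conversion stages skipped: no Stage 2 participants")
  }

  correlations <- pipeline_stage("correlations", {
    d <- analysis[!is.na(analysis$analysis_group), , drop = FALSE]
    rows <- list()
    for (scope in c("all", "stage2")) {
      dd <- if (scope == "all") d else d[d$analysis_group == "stage2", ]
      for (metric in c("cov_total", "cov_ae")) {
        for (v in correlation_variables) {
          if (!v %in% names(dd)) next
          pr <- try(pearson_r(dd[[metric]], dd[[v]]), silent = TRUE)
          if (inherits(pr, "try-error")) next
          rows[[paste(scope, metric, v)]] <- data.frame(
            scope = scope, metric = metric, variable = v,
            r = pr$r, n = pr$n, p = pr$p, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  })

  excluded <- attr(dispersion, "excluded")
  accounting <- list(
    enrolled = length(unique(cohort$participant_id)),
    hc_candidates = nrow(hc_candidates),
    hc_eligible = length(hc_ids),
    stage2 = length(s2_ids),
    followed = if (!is.null(outcomes)) sum(outcomes$followed) else 0L,
    converted = if (!is.null(outcomes)) sum(outcomes$converted %in% TRUE) else 0L,
    panels_excluded = if (is.null(excluded)) 0L else nrow(excluded)
  )

  report <- structure(list(
    config = if (inherits(config, "simulation_config")) config else NULL,
    input = if (is.character(config)) config else NULL,
    seed = if (inherits(config, "simulation_config")) config$seed else NA,
    norms = norms, dispersion = dispersion, stages = stages,
    hc_eligibility = hc_elig, outcomes = outcomes,
    table1 = table1, table2 = table2, correlations = correlations,
    models = models, transitions = transitions,
    accounting = accounting, notices = notices
  ), class = "dispersion_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.dispersion_report <- function(x, ...) {
  a <- x$accounting
  cat("Cognitive dispersion report\n")
  cat(sprintf("  %d participants: %d eligible controls, %d Stage 2 (%d followed, %d converted)\n",
              a$enrolled, a$hc_eligible, a$stage2, a$followed, a$converted))
  if (!is.null(x$table1)) {
    cov_row <- x$table1[x$table1$variable == "cov_total", ]
    cat(sprintf("  baseline CoV: HC %.3f (%.3f) vs Stage 2 %.3f (%.3f), t = %.2f, d = %.2f\n",
                cov_row$mean1, cov_row$sd1, cov_row$mean2, cov_row$sd2,
                cov_row$statistic, cov_row$cohens_d))
  }
  if (!is.null(x$models)) {
    ct <- x$models$total$coefficients
    i <- ct$term == "cov_total"
    cat(sprintf("  conversion model: B(CoV) = %.3f, OR %.2f [%.2f, %.2f]; Nagelkerke R2 = %.3f\n",
                ct$estimate[i], ct$or[i], ct$ci_low[i], ct$ci_high[i],
                x$models$total$r2_nagelkerke))
  }
  for (nt in x$notices) cat("  note:", nt, "\n")
  invisible(x)
}

#' Emit a result table as CSV plus aligned text
#'
#' Deterministic column order; numeric columns are formatted to 2
#' decimals and p-value columns to 3 in the text mirror, matching the
#' conventions of published cohort tables. The CSV keeps full precision.
#'
#' @param rows a data.frame.
#' @param path output stem; writes `<path>.csv` and `<path>.txt`. When
#'   `NULL`, nothing is written.
#' @param digits,p_digits text-mirror rounding.
#' @return the formatted text table (character vector), invisibly.
#' @export
emit_table <- function(rows, path = NULL, digits = 2, p_digits = 3) {
  rows <- as.data.frame(rows)
  fmt <- rows
  for (nm in names(fmt)) {
    if (is.numeric(fmt[[nm]])) {
      dg <- if (grepl("^p($|_)|^p\\.|p$", nm)) p_digits else digits
      fmt[[nm]] <- ifelse(is.na(fmt[[nm]]), "",
                          formatC(fmt[[nm]], format = "f", digits = dg))
    }
  }
  cols <- lapply(names(fmt), function(nm)
    format(c(nm, as.character(fmt[[nm]]))))
  lines <- do.call(paste, c(cols, sep = "  "))
  txt <- c(lines[1], if (length(lines) > 1) lines[-1])
  if (!is.null(path)) {
    utils::write.csv(rows, paste0(path, ".csv"), row.names = FALSE, na = "")
    writeLines(txt, paste0(path, ".txt"))
  }
  invisible(txt)
}

# Write every report artifact under out_dir (CSV + text mirrors).
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(obj, name) {
    if (!is.null(obj)) emit_table(obj, file.path(out_dir, name))
  }
  emit(report$table1, "table1_group_comparison")
  emit(report$table2, "table2_conversion_comparison")
  emit(report$correlations, "correlations")
  emit(report$dispersion, "dispersion")
  emit(report$stages, "stages")
  emit(report$outcomes, "conversion_outcomes")
  if (!is.null(report$transitions)) {
    emit_table(as.data.frame(report$transitions),
               file.path(out_dir, "transitions"))
  }
  if (!is.null(report$models)) {
    emit_table(rbind(cbind(model = "total", report$models$total$coefficients),
                     cbind(model = "ae", report$models$ae$coefficients)),
               file.path(out_dir, "conversion_models"))
    fitstats <- do.call(rbind, lapply(c("total", "ae"), function(m) {
      ft <- report$models[[m]]
      data.frame(model = m, n = ft$n, ll = ft$ll, ll_null = ft$ll_null,
                 lr_chisq = ft$lr_chisq, lr_df = ft$lr_df, lr_p = ft$lr_p,
                 nagelkerke_r2 = ft$r2_nagelkerke,
                 hl_chisq = ft$hosmer_lemeshow$chisq %||% NA,
                 hl_df = ft$hosmer_lemeshow$df %||% NA,
                 hl_p = ft$hosmer_lemeshow$p %||% NA,
                 converged = ft$converged)
    }))
    emit_table(fitstats, file.path(out_dir, "conversion_fit_statistics"))
  }
  write_norms(report$norms, file.path(out_dir, "norms.dcf"))
  acc <- data.frame(quantity = names(report$accounting),
                    value = unlist(report$accounting))
  emit_table(acc, file.path(out_dir, "accounting"))
  cfgline <- if (!is.null(report$config)) {
    c(sprintf("seed: %d", report$config$seed),
      utils::capture.output(print(report$config)))
  } else sprintf("input: %s", report$input)
  writeLines(c(cfgline, report$notices), file.path(out_dir, "run_config.txt"))
  invisible(out_dir)
}
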