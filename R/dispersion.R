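# Intraindividual dispersion: coefficient of variation of a normed
# test panel.

#' Coefficient of variation of a score panel
#'
#' The dispersion metric is the standard deviation of a participant's
#' normed test scores, computed as the square root of the average
#' squared deviation from the mean (n-divisor, "population" SD), divided
#' by their mean score. The n-1 divisor is available as a sensitivity
#' option only.
#'
#' @param scores numeric vector of at least two finite T scores.
#' @param sd_type `"population"` (default, n divisor) or `"sample"`
#'   (n - 1 divisor).
#' @return dimensionless CoV, >= 0.
#' @examples
#' coefficient_of_variation(c(40, 50, 60))  # sqrt(200/3)/50 = 0.1633
#' @export
coefficient_of_variation <- function(scores,
                                     sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(scores) < 2) {
    stop("coefficient of variation needs at least 2 scores")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  m <- mean(scores)
  if (m <= 0) {
    stop("coefficient of variation is undefined for non-positive mean score")
  }
  dev2 <- sum((scores - m)^2)
  s <- if (sd_type == "population") sqrt(dev2 / length(scores))
       else sqrt(dev2 / (length(scores) - 1))
  s / m
}

#' Per-subject composite and dispersion metrics
#'
#' From a complete 11-score T panel computes the mean composite (mean of
#' all 11 scores), the total CoV over all 11, and the
#' attention/executive composite and CoV over the registry's five
#' attention/executive scores. Incomplete panels and panels with a
#' non-positive composite are excluded and counted (see the `"excluded"`
#' attribute), never silently propagated as NaN.
#'
#' @param tscores T-score table from [apply_norms()].
#' @param registry the test registry.
#' @param sd_type passed to [coefficient_of_variation()].
#' @return data.frame with `participant_id`, `visit_index`,
#'   `mean_composite`, `ae_composite`, `cov_total`, `cov_ae`; excluded
#'   rows are recorded in `attr(, "excluded")`.
#' @export
compute_dispersion <- function(tscores, registry = test_registry(),
                               sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_registry(registry)
  tests <- registry$test
  ae <- attention_executive_tests(registry)
  miss <- setdiff(tests, names(tscores))
  if (length(miss)) stop("tscores missing column(s): ",
                         paste(miss, collapse = ", "))

  complete <- if ("complete" %in% names(tscores)) tscores$complete
              else stats::complete.cases(tscores[tests])
  X <- as.matrix(tscores[tests])
  A <- X[, ae, drop = FALSE]
  div <- if (sd_type == "population") 0 else 1
  mean_total <- rowMeans(X)
  mean_ae <- rowMeans(A)
  sd_total <- sqrt(rowSums((X - mean_total)^2) / (ncol(X) - div))
  sd_ae <- sqrt(rowSums((A - mean_ae)^2) / (ncol(A) - div))

  positive <- complete & mean_total > 0 & mean_ae > 0
  out <- data.frame(
    participant_id = tscores$participant_id,
    visit_index = tscores$visit_index,
    mean_composite = mean_total,
    ae_composite = mean_ae,
    cov_total = sd_total / mean_total,
    cov_ae = sd_ae / mean_ae,
    stringsAsFactors = FALSE
  )
  excl <- out[!positive, c("participant_id", "visit_index"), drop = FALSE]
  if (nrow(excl)) {
    excl$reason <- ifelse(!complete[!positive], "incomplete_panel",
                          "non_positive_composite")
    message(nrow(excl), " panel(s) excluded from dispersion (",
            paste(unique(excl$reason), collapse = ", "), ")")
  }
  out <- out[positive, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}
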