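# Internal regression-based normative scoring.
#
# Each test is normed against a reference sample with an ordinary
# least-squares model in age, sex and education; demographic corrections
# are applied selectively (a covariate is kept only when its Wald test
# in the full model has p < alpha, with one refit on the retained set).
# A raw score is converted to a T score (reference mean 50, SD 10):
#   T = 50 + 10 * direction * (observed - predicted) / residual_scale
# where direction is -1 for timed tests recorded in seconds, so that a
# higher T always means better performance.

#' Fit internal regression norms
#'
#' @param reference participant-visit data.frame of reference records
#'   (typically the healthy-control baseline visits); needs columns
#'   `age`, `sex`, `education` and the 11 raw test columns.
#' @param registry the test registry; supplies direction flags and the
#'   candidate covariates per test.
#' @param alpha Wald significance level that a covariate must reach in
#'   the full three-covariate fit to be retained.
#' @return An object of class `"norm_set"`: a named list of per-test
#'   `"norm_model"` lists (`coefficients`, `residual_scale`,
#'   `covariates`, `higher_is_worse`, `n`).
#' @examples
#' cfg <- simulation_config(seed = 5, n_hc = 80, n_stage2 = 10, quiet = TRUE)
#' coh <- simulate_cohort(cfg)
#' ref <- coh[coh$group == "hc" & coh$visit_index == 0, ]
#' norms <- fit_norms(ref)
#' norms$sdmt$covariates
#' @export
fit_norms <- function(reference, registry = test_registry(), alpha = 0.05) {
  check_registry(registry)
  stopifnot(alpha > 0, alpha < 1)
  need <- c("age", "sex", "education", registry$test)
  miss <- setdiff(need, names(reference))
  if (length(miss)) stop("reference is missing column(s): ",
                         paste(miss, collapse = ", "))
  complete <- stats::complete.cases(reference[need])
  if (sum(complete) < 30) {
    stop("reference sample must contain at least 30 complete records, got ",
         sum(complete))
  }
  ref <- reference[complete, , drop = FALSE]
  ref$sex <- factor(ref$sex, levels = c("F", "M"))

  models <- lapply(seq_len(nrow(registry)), function(i) {
    test <- registry$test[i]
    cand <- strsplit(registry$covariates[i] %||% "age,sex,education", ",")[[1]]
    dat <- ref[c(test, cand)]
    # degenerate (constant) covariates cannot be fit; drop with a warning
    const <- vapply(cand, function(v) length(unique(dat[[v]])) < 2, logical(1))
    if (any(const)) {
      warning("constant covariate(s) dropped for test '", test, "': ",
              paste(cand[const], collapse = ", "))
      cand <- cand[!const]
    }
    full <- stats::lm(stats::reformulate(if (length(cand)) cand else "1",
                                         response = test), data = dat)
    keep <- character(0)
    if (length(cand)) {
      ct <- summary(full)$coefficients
      pv <- ct[rownames(ct) != "(Intercept)", 4]
      # map model terms (e.g. sexM) back to covariate names
      term_of <- function(v) if (v == "sex") "sexM" else v
      keep <- cand[vapply(cand, function(v) {
        t <- term_of(v)
        t %in% names(pv) && pv[[t]] < alpha
      }, logical(1))]
    }
    fit <- stats::lm(stats::reformulate(if (length(keep)) keep else "1",
                                        response = test), data = dat)
    s <- summary(fit)$sigma   # sqrt(RSS / (n - k - 1))
    structure(list(
      test = test,
      coefficients = stats::coef(fit),
      residual_scale = s,
      covariates = keep,
      higher_is_worse = registry$higher_is_worse[i],
      n = nrow(dat)
    ), class = "norm_model")
  })
  names(models) <- registry$test
  structure(models, class = "norm_set", alpha = alpha)
}

#' @export
print.norm_set <- function(x, ...) {
  cat("Internal regression norms (alpha =", attr(x, "alpha"), ")\n")
  for (m in x) {
    cat(sprintf("  %-16s scale %6.3f  covariates: %s\n", m$test,
                m$residual_scale,
                if (length(m$covariates)) paste(m$covariates, collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}

predict_norm <- function(model, records) {
  b <- model$coefficients
  pred <- rep(b[["(Intercept)"]], nrow(records))
  if ("age" %in% model$covariates) pred <- pred + b[["age"]] * records$age
  if ("education" %in% model$covariates) {
    pred <- pred + b[["education"]] * records$education
  }
  if ("sex" %in% model$covariates) {
    pred <- pred + b[["sexM"]] * (records$sex == "M")
  }
  pred
}

#' Convert raw scores to demographically corrected T scores
#'
#' Applies fitted norms to participant-visit records. Panels with any
#' missing raw score are flagged incomplete (`complete = FALSE`) and are
#' excluded by downstream dispersion computation.
#'
#' @param records participant-visit data.frame.
#' @param norms a `"norm_set"` from [fit_norms()].
#' @return data.frame with `participant_id`, `visit_index`, one T-score
#'   column per test (same column names as the raw scores) and a
#'   `complete` flag.
#' @export
apply_norms <- function(records, norms) {
  if (!inherits(norms, "norm_set")) stop("norms must be a norm_set")
  miss <- setdiff(c(names(norms), "participant_id", "visit_index"),
                  names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- records[c("participant_id", "visit_index")]
  for (m in norms) {
    raw <- records[[m$test]]
    resid <- raw - predict_norm(m, records)
    if (m$higher_is_worse) resid <- -resid
    out[[m$test]] <- 50 + 10 * resid / m$residual_scale
  }
  out$complete <- stats::complete.cases(out[names(norms)])
  out
}

#' Serialise norm sets to structured text
#'
#' One Debian-control-format block per test; round-trips exactly through
#' character representation at full double precision.
#'
#' @param norms a `"norm_set"`.
#' @param path file path.
#' @return `read_norms()` the restored `"norm_set"`.
#' @export
write_norms <- function(norms, path) {
  if (!inherits(norms, "norm_set")) stop("norms must be a norm_set")
  blocks <- lapply(norms, function(m) {
    data.frame(
      test = m$test,
      coefficients = paste(names(m$coefficients),
                           sprintf("%.17g", m$coefficients),
                           sep = "=", collapse = ";"),
      residual_scale = sprintf("%.17g", m$residual_scale),
      covariates = paste(m$covariates, collapse = ";"),
      higher_is_worse = m$higher_is_worse,
      n = m$n,
      alpha = attr(norms, "alpha"),
      stringsAsFactors = FALSE
    )
  })
  write.dcf(do.call(rbind, blocks), path)
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(d)), function(i) {
    kv <- strsplit(strsplit(d$coefficients[i], ";")[[1]], "=")
    co <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
    names(co) <- vapply(kv, `[`, character(1), 1)
    covs <- if (nzchar(d$covariates[i])) {
      strsplit(d$covariates[i], ";")[[1]]
    } else character(0)
    structure(list(
      test = d$test[i], coefficients = co,
      residual_scale = as.numeric(d$residual_scale[i]),
      covariates = covs,
      higher_is_worse = as.logical(d$higher_is_worse[i]),
      n = as.integer(d$n[i])
    ), class = "norm_model")
  })
  names(models) <- d$test
  structure(models, class = "norm_set", alpha = as.numeric(d$alpha[1]))
}
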