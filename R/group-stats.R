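# Two-group comparison engine: variance-gated t tests, chi-square,
# Cohen's d, Benjamini-Hochberg FDR flags, Pearson correlations.
#
# The comparison statistics are computed from first principles (they are
# the quantities under study); only the distribution functions pt/pf/
# pchisq come from stats.

#' Two-sample pooled-variance t statistic from summary statistics
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p` (two-sided), `sp` (pooled SD).
#' @examples
#' pooled_t(48.53, 6.22, 340, 45.66, 6.28, 100)$t  # ~ 4.05
#' @export
pooled_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1, sp = 0))
    }
    stop("zero pooled variance with unequal means: t statistic is infinite")
  }
  tt <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), sp = sqrt(sp2))
}

#' Welch two-sample t statistic with Satterthwaite df
#'
#' @inheritParams pooled_t
#' @return list with `t`, `df` (fractional), `p`.
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("zero variance with unequal means: t statistic is infinite")
  }
  tt <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Two-sided F test of equal variances
#'
#' Ratio of the larger to the smaller sample variance; the two-sided p
#' doubles the upper-tail probability. A zero variance returns p = 0 by
#' convention (forcing the Welch branch of [compare_groups()]).
#'
#' @inheritParams pooled_t
#' @return two-sided p-value.
#' @export
variance_f_test <- function(s1, n1, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 || s2 == 0) return(0)
  if (s1 >= s2) {
    F <- s1^2 / s2^2; d1 <- n1 - 1; d2 <- n2 - 1
  } else {
    F <- s2^2 / s1^2; d1 <- n2 - 1; d2 <- n1 - 1
  }
  min(2 * stats::pf(F, d1, d2, lower.tail = FALSE), 1)
}

#' Cohen's d with pooled SD
#'
#' Always uses the pooled SD, also when the Welch statistic was selected
#' for the test (matching the convention of the tabled effect sizes).
#'
#' @inheritParams pooled_t
#' @return standardised mean difference (group 1 minus group 2).
#' @export
cohens_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("effect size undefined with zero pooled SD")
  (m1 - m2) / sqrt(sp2)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic without continuity correction; expected
#' counts from the product of margins.
#'
#' @param tab an r x c matrix/table of nonnegative counts with positive
#'   margins.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  expd <- outer(rs, cs) / n
  chisq <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Ranks the p-values in ascending order, finds the largest rank k with
#' p_(k) <= k q / m, and flags every p-value not exceeding p_(k); ties
#' share fate and the original input order is preserved.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @param q desired false-discovery rate.
#' @return logical vector of flags, same order as `pvals`.
#' @examples
#' benjamini_hochberg(c(0.001, 0.01, 0.02, 0.04, 0.05))  # all TRUE
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (length(pvals) == 0) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must be in [0, 1]")
  }
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  pvals <= ps[max(ok)]
}

# BH-adjusted p-values (step-up), reported alongside the flags to
# resolve the raw-vs-adjusted ambiguity in published tables.
bh_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length, n >= 3, with nonzero
#'   variance.
#' @return list with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_r needs at least 3 complete pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) {
    stop("correlation undefined for a zero-variance input")
  }
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(list(r = r, n = n, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' Two-group comparison report
#'
#' For every continuous variable, the equality-of-variance F test at
#' p < 0.05 gates between the pooled and Welch t statistics; Cohen's d
#' (pooled SD, group 1 minus group 2) is attached. Categorical variables
#' get a Pearson chi-square. Benjamini-Hochberg flags are computed over
#' the whole row family, and both raw and BH-adjusted p-values are
#' reported.
#'
#' @param data data.frame holding the grouping column and variables.
#' @param group name of a two-level grouping column; the first level (or
#'   `levels` argument order) is group 1 for the sign convention.
#' @param variables character vector of continuous variable names.
#' @param categorical character vector of categorical variable names.
#' @param q false-discovery rate for the BH flags.
#' @param levels optional explicit group level order.
#' @return data.frame of class `"comparison_table"`, one row per
#'   variable.
#' @export
compare_groups <- function(data, group, variables,
                           categorical = character(0), q = 0.05,
                           levels = NULL) {
  g <- data[[group]]
  if (is.null(g)) stop("grouping column '", group, "' not found")
  lev <- levels %||% unique(g[!is.na(g)])
  if (length(lev) != 2) stop("grouping column must have exactly 2 levels")
  i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
  if (!length(i1) || !length(i2)) stop("both groups must be nonempty")

  rows <- list()
  for (v in c(variables, categorical)) {
    if (!v %in% names(data)) {
      message("variable '", v, "' not found; skipped")
      next
    }
    if (v %in% categorical) {
      tab <- table(factor(g[c(i1, i2)], levels = lev),
                   data[[v]][c(i1, i2)])
      ct <- chi_square_test(tab)
      rows[[v]] <- data.frame(
        variable = v, n1 = length(i1), mean1 = NA, sd1 = NA,
        n2 = length(i2), mean2 = NA, sd2 = NA,
        test = "chi-square", statistic = ct$chisq, df = ct$df,
        p = ct$p, cohens_d = NA, stringsAsFactors = FALSE)
    } else {
      x1 <- data[[v]][i1]; x2 <- data[[v]][i2]
      x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
      if (length(x1) < 2 || length(x2) < 2) {
        message("variable '", v, "' has fewer than 2 values per group; skipped")
        next
      }
      m1 <- mean(x1); s1 <- stats::sd(x1); n1 <- length(x1)
      m2 <- mean(x2); s2 <- stats::sd(x2); n2 <- length(x2)
      fp <- variance_f_test(s1, n1, s2, n2)
      tt <- if (fp < 0.05) welch_t(m1, s1, n1, m2, s2, n2)
            else pooled_t(m1, s1, n1, m2, s2, n2)
      rows[[v]] <- data.frame(
        variable = v, n1 = n1, mean1 = m1, sd1 = s1,
        n2 = n2, mean2 = m2, sd2 = s2,
        test = if (fp < 0.05) "welch-t" else "pooled-t",
        statistic = tt$t, df = tt$df, p = tt$p,
        cohens_d = cohens_d_pooled(m1, s1, n1, m2, s2, n2),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- benjamini_hochberg(out$p, q = q)
  attr(out, "groups") <- lev
  attr(out, "q") <- q
  class(out) <- c("comparison_table", "data.frame")
  out
}
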