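#' Neuropsychological test registry
#'
#' The fixed 11-score battery used throughout the package: eight
#' instruments contributing eleven scores (HVLT-R contributes three).
#' Five scores carry the attention/executive domain tag (SDMT, TMT-A,
#' LNS, lexical fluency, TMT-B). Timed trail-making scores are recorded
#' in seconds, so higher raw values mean worse performance and their
#' direction is flipped before T-scoring (`higher_is_worse`).
#'
#' The `raw_mean`/`raw_sd` columns and the demographic effect sizes
#' (`beta_age` per 10 years, `beta_edu` per 3 years of education,
#' `beta_sex` for male sex, all in raw-SD units of performance) are the
#' synthetic generator's raw-score scales. They are chosen to resemble
#' plausible published ranges; their exact values are irrelevant to the
#' analysis because regression norming standardises every test. A few
#' tests have null education or sex effects so that selective
#' demographic correction has real work to do.
#'
#' @return A data.frame with one row per test score: `test` (column
#'   identifier), `label`, `domain` (`"attention_executive"` or
#'   `"other"`), `higher_is_worse`, `covariates` (comma-joined candidate
#'   covariates for norming), and the generator scale columns.
#' @examples
#' reg <- test_registry()
#' stopifnot(nrow(reg) == 11, sum(reg$domain == "attention_executive") == 5)
#' @export
test_registry <- function() {
  reg <- data.frame(
    test = c("jlo", "hvlt_total", "hvlt_delayed", "hvlt_recog", "lns",
             "cowat", "bnt", "semantic_fluency", "sdmt", "tmt_a", "tmt_b"),
    label = c("JLO", "HVLT-R Total Recall", "HVLT-R Delayed Recall",
              "HVLT-R Recognition", "LNS", "COWAT lexical fluency",
              "modified BNT", "modified semantic fluency", "SDMT",
              "TMT-A", "TMT-B"),
    domain = c("other", "other", "other", "other", "attention_executive",
               "attention_executive", "other", "other",
               "attention_executive", "attention_executive",
               "attention_executive"),
    higher_is_worse = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, FALSE, TRUE, TRUE),
    covariates = "age,sex,education",
    raw_mean = c(25, 26, 9, 11, 10.5, 40, 13.5, 48, 42, 35, 85),
    raw_sd = c(3.5, 4.5, 2.5, 1.2, 2.5, 11, 1.5, 11, 10, 12, 40),
    beta_age = c(-0.15, -0.35, -0.35, -0.20, -0.25, -0.20, -0.15, -0.30,
                 -0.45, -0.40, -0.45),
    beta_edu = c(0.15, 0.20, 0.15, 0.10, 0.30, 0.35, 0.25, 0.20, 0.25,
                 0, 0.20),
    beta_sex = c(0.20, -0.30, -0.25, -0.15, 0, -0.20, 0, -0.15, -0.20,
                 0, 0),
    stringsAsFactors = FALSE
  )
  rownames(reg) <- reg$test
  reg
}

#' @rdname test_registry
#' @export
attention_executive_tests <- function(registry = test_registry()) {
  registry$test[registry$domain == "attention_executive"]
}

# Validate a registry-shaped data.frame; used by operations that accept
# a user-supplied registry.
check_registry <- function(registry) {
  need <- c("test", "domain", "higher_is_worse")
  miss <- setdiff(need, names(registry))
  if (length(miss)) {
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(registry) != 11L) {
    stop("registry must have exactly 11 entries, got ", nrow(registry))
  }
  if (sum(registry$domain == "attention_executive") != 5L) {
    stop("registry must tag exactly 5 attention/executive scores")
  }
  invisible(registry)
}
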