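# Shared fixtures, built in code.

# Small calibrated cohort config; memoised because the quadrature
# calibration is deterministic.
small_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulation_config(seed = 42, n_hc = 60, n_stage2 = 120,
                                  quiet = TRUE)
    }
    cache
  }
})

fullscale_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulation_config(seed = 42, quiet = TRUE)
    cache
  }
})

# A complete T-score panel row as apply_norms() would emit.
panel_row <- function(scores, id = "P1", visit = 0L,
                      registry = test_registry()) {
  stopifnot(length(scores) == nrow(registry))
  out <- data.frame(participant_id = id, visit_index = visit,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(registry))) out[[registry$test[i]]] <- scores[i]
  out$complete <- all(!is.na(scores))
  out
}

# One synthetic visit record for staging unit tests.
visit_record <- function(id = "P1", visit = 0L, saa = TRUE, dat = FALSE,
                         impairment = "none", hyposmia = FALSE,
                         rbdsq = 0, updrs3 = 0, moca = 28,
                         offset = visit * 1.0) {
  data.frame(participant_id = id, visit_index = visit,
             visit_offset_years = offset, saa_positive = saa,
             dat_deficit = dat, functional_impairment = impairment,
             hyposmia = hyposmia, rbdsq = rbdsq, updrs3 = updrs3,
             moca = moca, stringsAsFactors = FALSE)
}
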