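# shared fixture builders; everything is generated in code under fixed seeds

# a minimal valid trial row, with overrides
trial_row <- function(consonant = "b", response = consonant, vowel = "a",
                      listener_id = "L1", session_id = "S1", block = 1L,
                      recording = 1L, snr_db = 15, aided = "unaided") {
  data.frame(listener_id = listener_id, session_id = session_id,
             block = block, consonant = consonant, vowel = vowel,
             recording = recording, snr_db = snr_db, response = response,
             aided = aided, correct = response == consonant,
             stringsAsFactors = FALSE)
}

# a balanced single-listener session on the default panel with scripted
# responses (correct everywhere unless overridden)
balanced_session <- function(reps = 5L, listener_id = "L1",
                             session_id = "S1", aided = "unaided") {
  panel <- qvcv_default_panel()
  grid <- expand.grid(rep = seq_len(reps), recording = 1:2,
                      i = seq_len(nrow(panel)))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
    trial_row(consonant = panel$consonant[grid$i[j]],
              listener_id = listener_id, session_id = session_id,
              block = grid$rep[j], recording = grid$recording[j],
              snr_db = panel$snr_db[grid$i[j]], aided = aided)
  }))
}

# small calibrated cohort reused by several model tests (memoised per session)
.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 1, n_excess = 0) {
  key <- paste0("s", seed, "x", n_excess)
  if (is.null(.small_cohort_cache[[key]])) {
    .small_cohort_cache[[key]] <- simulate_cohort(n_excess = n_excess,
                                                  excess_delta_db = 10,
                                                  seed = seed)
  }
  .small_cohort_cache[[key]]
}
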