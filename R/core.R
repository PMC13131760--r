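#' Validate a table of identification trials
#'
#' A trial table has one row per closed-set identification trial with columns
#' `listener_id`, `session_id`, `block` (integer >= 1), `consonant`, `vowel`,
#' `recording` (1 or 2), `snr_db`, `response` (a consonant or `"other"`),
#' `aided` (`unaided`, `lab_aid`, `personal_aid`) and `correct` (logical).
#' Labels are normalized (IPA aliases accepted) and `correct` is checked
#' against its definition `response == consonant`; an "other" response is
#' never correct.
#'
#' @param trials data frame of trials.
#' @return the validated, normalized trial table.
#' @export
validate_trials <- function(trials) {
  req <- c("listener_id", "session_id", "block", "consonant", "vowel",
           "recording", "snr_db", "response", "aided", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop_qvcv("trial table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop_qvcv("no trials")
  trials$consonant <- normalize_consonant(trials$consonant)
  trials$vowel <- normalize_vowel(trials$vowel)
  trials$response <- normalize_response(trials$response)
  if (!all(trials$recording %in% c(1L, 2L))) {
    stop_qvcv("recording must be 1 or 2")
  }
  if (!all(trials$block >= 1L)) stop_qvcv("block must be >= 1")
  if (!all(is.finite(trials$snr_db))) stop_qvcv("snr_db must be finite")
  if (!all(trials$aided %in% c("unaided", "lab_aid", "personal_aid"))) {
    stop_qvcv("aided must be one of unaided, lab_aid, personal_aid")
  }
  expected <- trials$response == trials$consonant
  trials$correct <- as.logical(trials$correct)
  if (any(trials$correct != expected)) {
    stop_qvcv("correct column inconsistent with response == consonant at row(s) ",
              paste(utils::head(which(trials$correct != expected), 5),
                    collapse = ", "))
  }
  trials
}

#' Build a consonant confusion matrix from trials
#'
#' Counts presented-consonant x response occurrences for a single listener
#' and aided condition. The response label set is the presented consonants
#' plus `"other"`; responses outside that set (off-panel button presses) are
#' collapsed onto `"other"` when `collapse_other = TRUE`, otherwise they are
#' an error. Recordings 1 and 2 are always pooled.
#'
#' @param trials trial table (see [validate_trials()]).
#' @param consonants presented-consonant labels defining the row order;
#'   default: consonants appearing as stimuli or responses, in canonical
#'   inventory order.
#' @param aided,session_id,snr_db,block optional filters applied before
#'   counting.
#' @param collapse_other map responses outside `consonants` to `"other"`.
#' @return an object of class `qvcv_ccm`: a list with `counts`
#'   (matrix, rows presented, columns responses), `n_trials`, `listener_id`,
#'   `aided`.
#' @examples
#' tr <- data.frame(listener_id = "L1", session_id = "S1", block = 1,
#'                  consonant = "b", vowel = "a", recording = 1, snr_db = 15,
#'                  response = "d", aided = "unaided", correct = FALSE)
#' build_confusion_matrix(tr)$counts
#' @export
build_confusion_matrix <- function(trials, consonants = NULL, aided = NULL,
                                   session_id = NULL, snr_db = NULL,
                                   block = NULL, collapse_other = TRUE) {
  trials <- validate_trials(trials)
  if (!is.null(aided)) trials <- trials[trials$aided %in% aided, , drop = FALSE]
  if (!is.null(session_id)) {
    trials <- trials[trials$session_id %in% session_id, , drop = FALSE]
  }
  if (!is.null(snr_db)) trials <- trials[trials$snr_db %in% snr_db, , drop = FALSE]
  if (!is.null(block)) trials <- trials[trials$block %in% block, , drop = FALSE]
  if (nrow(trials) == 0L) stop_qvcv("empty selection: no trials left after filtering")
  if (length(unique(trials$listener_id)) > 1L) {
    stop_qvcv("trials mix listeners: ",
              paste(unique(trials$listener_id), collapse = ", "),
              "; filter to a single listener first")
  }
  if (length(unique(trials$aided)) > 1L) {
    stop_qvcv("trials mix aided conditions: ",
              paste(unique(trials$aided), collapse = ", "),
              "; use the aided filter")
  }
  if (is.null(consonants)) {
    seen <- union(trials$consonant,
                  trials$response[trials$response != qvcv_other_label()])
    consonants <- intersect(qvcv_consonants(), seen)
  } else {
    consonants <- normalize_consonant(consonants)
  }
  if (!all(trials$consonant %in% consonants)) {
    stop_qvcv("trials contain presented consonants outside the requested set")
  }
  responses <- c(consonants, qvcv_other_label())
  resp <- trials$response
  off <- !(resp %in% responses)
  if (any(off)) {
    if (!collapse_other) {
      stop_qvcv("responses outside the response set: ",
                paste(unique(resp[off]), collapse = ", "))
    }
    resp[off] <- qvcv_other_label()
  }
  counts <- table(factor(trials$consonant, levels = consonants),
                  factor(resp, levels = responses))
  counts <- matrix(as.integer(counts), nrow = length(consonants),
                   dimnames = list(presented = consonants, response = responses))
  structure(
    list(counts = counts, n_trials = nrow(trials),
         listener_id = trials$listener_id[[1L]], aided = trials$aided[[1L]]),
    class = "qvcv_ccm"
  )
}

#' @export
print.qvcv_ccm <- function(x, ...) {
  cat("Consonant confusion matrix: listener", x$listener_id,
      sprintf("(%s), %d trials, %.1f%% correct\n",
              x$aided, x$n_trials, score_percent_correct(x)))
  print(x$counts)
  invisible(x)
}

#' Percent-correct score of a confusion matrix
#'
#' 100 times the sum of the diagonal (response equals presented consonant)
#' over the total trial count. The "other" column never contributes.
#'
#' @param cm a `qvcv_ccm`.
#' @return percentage in \[0, 100\].
#' @export
score_percent_correct <- function(cm) {
  stopifnot(inherits(cm, "qvcv_ccm"))
  if (is.null(cm$n_trials) || cm$n_trials < 1L) stop_qvcv("no trials")
  pres <- rownames(cm$counts)
  diag_idx <- cbind(seq_along(pres), match(pres, colnames(cm$counts)))
  100 * sum(cm$counts[diag_idx]) / cm$n_trials
}

#' Hearing-category bands
#'
#' The four pure-tone-average bands used to group listeners: normal hearing
#' (NH, -10 to 15 dB HL), slight (16-25), mild (26-40) and moderate (41-55)
#' hearing loss. Listeners with PTA above 55 dB HL are outside the test's
#' inclusion range.
#'
#' @return data frame with columns `category`, `lo_db_hl`, `hi_db_hl`.
#' @export
category_bands <- function() {
  data.frame(category = c("NH", "slight", "mild", "moderate"),
             lo_db_hl = c(-10, 16, 26, 41),
             hi_db_hl = c(15, 25, 40, 55),
             stringsAsFactors = FALSE)
}

#' Assign a hearing category from the pure-tone average
#'
#' Non-integer PTAs are rounded half-up to the nearest integer dB before
#' banding. Values above 55 dB HL (after rounding) exceed the inclusion
#' limit and raise an error, as do values below -10 dB HL.
#'
#' @param pta_db_hl numeric vector, 3-frequency (1, 2, 4 kHz) pure-tone
#'   average in dB HL.
#' @return character vector of categories (`NH`, `slight`, `mild`,
#'   `moderate`).
#' @examples
#' assign_category(c(15, 16, 41, 55.4))
#' @export
assign_category <- function(pta_db_hl) {
  if (!all(is.finite(pta_db_hl))) stop_qvcv("pta must be finite")
  r <- round_half_up(pta_db_hl)
  if (any(r > 55)) stop_qvcv("PTA exceeds inclusion limit (55 dB HL)")
  if (any(r < -10)) stop_qvcv("PTA below -10 dB HL is outside the test range")
  b <- category_bands()
  idx <- findInterval(r, c(-10, 16, 26, 41))
  b$category[idx]
}
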