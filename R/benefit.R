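#' Hearing-aid benefit for one listener
#'
#' Benefit is quantified on two scales: percentage points of consonant
#' recognition (`delta_percent = aided - unaided score`) and decibels of
#' predicted hearing loss (`delta_db = unaided PPTA - aided PPTA`; positive
#' means the aid reduced the predicted loss). The dB benefit is significant
#' when it strictly exceeds the test's repeatability limit (5 dB).
#'
#' @param unaided_cm,aided_cm `qvcv_ccm` confusion matrices from the same
#'   listener.
#' @param model fitted `qvcv_pta`.
#' @param audibility optional `qvcv_audibility`; with `measured_pta`, adds
#'   residual loss in both conditions.
#' @param measured_pta optional measured PTA (dB HL) of the listener.
#' @param limit_db significance limit in dB.
#' @return one-row data frame: `listener_id`, `condition_pair`,
#'   `unaided_percent`, `aided_percent`, `delta_percent`, `unaided_ppta`,
#'   `aided_ppta`, `delta_db`, `significant` (plus `unaided_rhl_db`,
#'   `aided_rhl_db` when `audibility` and `measured_pta` are given).
#' @export
hearing_aid_benefit <- function(unaided_cm, aided_cm, model, audibility = NULL,
                                measured_pta = NULL,
                                limit_db = quicksin_reference()$qvcv_repeatability_db) {
  stopifnot(inherits(unaided_cm, "qvcv_ccm"), inherits(aided_cm, "qvcv_ccm"),
            inherits(model, "qvcv_pta"))
  if (!identical(unaided_cm$listener_id, aided_cm$listener_id)) {
    stop_qvcv("confusion matrices are from different listeners: ",
              unaided_cm$listener_id, " vs ", aided_cm$listener_id)
  }
  p_un <- predict(model, vectorize_ccm(unaided_cm))
  p_ai <- predict(model, vectorize_ccm(aided_cm))
  s_un <- score_percent_correct(unaided_cm)
  s_ai <- score_percent_correct(aided_cm)
  out <- data.frame(
    listener_id = unaided_cm$listener_id,
    condition_pair = paste(unaided_cm$aided, aided_cm$aided, sep = "/"),
    unaided_percent = s_un, aided_percent = s_ai,
    delta_percent = s_ai - s_un,
    unaided_ppta = p_un, aided_ppta = p_ai,
    delta_db = p_un - p_ai,
    stringsAsFactors = FALSE
  )
  out$significant <- out$delta_db > limit_db
  if (!is.null(audibility) && !is.null(measured_pta)) {
    stopifnot(inherits(audibility, "qvcv_audibility"))
    a <- predict(audibility, measured_pta)
    out$unaided_rhl_db <- p_un - a
    out$aided_rhl_db <- p_ai - a
  }
  out
}

#' Cohort-level benefit summary
#'
#' Summarizes per-listener benefit results: counts of significant dB benefit
#' per hearing category, mean deltas, and whether aided performance reaches
#' the normal-hearing ceiling (> 90% correct).
#'
#' @param results data frame of rows from [hearing_aid_benefit()].
#' @param measured_pta optional named vector (listener_id -> dB HL) used to
#'   group listeners by hearing category.
#' @param ceiling_percent aided scores at or below this are flagged as not
#'   restored to the normal-hearing ceiling.
#' @return list with `by_category` (or overall summary when no PTA given)
#'   and `results` augmented with `restored_to_ceiling`.
#' @export
benefit_report <- function(results, measured_pta = NULL,
                           ceiling_percent = 90) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("listener_id", "delta_percent", "delta_db", "significant",
                  "aided_percent") %in% names(results)))
  results$restored_to_ceiling <- results$aided_percent > ceiling_percent
  if (!is.null(measured_pta)) {
    pta <- measured_pta[as.character(results$listener_id)]
    results$measured_pta <- as.numeric(pta)
    results$category <- assign_category(results$measured_pta)
    grp <- factor(results$category, levels = category_bands()$category)
    by_category <- data.frame(
      category = levels(grp),
      n = as.integer(table(grp)),
      n_significant = as.integer(tapply(results$significant, grp, sum,
                                        default = 0L)),
      mean_delta_percent = as.numeric(tapply(results$delta_percent, grp, mean)),
      mean_delta_db = as.numeric(tapply(results$delta_db, grp, mean)),
      n_restored = as.integer(tapply(results$restored_to_ceiling, grp, sum,
                                     default = 0L))
    )
  } else {
    by_category <- data.frame(
      category = "all", n = nrow(results),
      n_significant = sum(results$significant),
      mean_delta_percent = mean(results$delta_percent),
      mean_delta_db = mean(results$delta_db),
      n_restored = sum(results$restored_to_ceiling)
    )
  }
  list(by_category = by_category, results = results)
}
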