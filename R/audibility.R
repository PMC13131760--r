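#' Audibility baseline: a floored identity on the measured PTA
#'
#' The audibility function `a(p) = max(floor, p)` is the baseline that
#' predicted PTA follows when perception is fully explained by audiometric
#' thresholds: unity slope above the floor, constant below it. The floor sits
#' near the top of the normal-hearing band (about 15 dB HL) because the test,
#' normalized to ~90% correct for normal hearing, cannot resolve differences
#' among listeners whose thresholds are better than that.
#'
#' @param floor_db_hl the floor/breakpoint in dB HL.
#' @param flagged logical, set by [fit_audibility()] when the floor was not
#'   identifiable (no listeners below it).
#' @return object of class `qvcv_audibility`.
#' @export
audibility <- function(floor_db_hl, flagged = FALSE) {
  stopifnot(is.numeric(floor_db_hl), length(floor_db_hl) == 1L,
            is.finite(floor_db_hl))
  structure(list(floor_db_hl = floor_db_hl, flagged = flagged),
            class = "qvcv_audibility")
}

#' @export
print.qvcv_audibility <- function(x, ...) {
  cat(sprintf("Audibility function a(p) = max(%.2f, p) dB HL%s\n",
              x$floor_db_hl, if (x$flagged) " [floor poorly identified]" else ""))
  invisible(x)
}

#' @export
predict.qvcv_audibility <- function(object, pta_db_hl, ...) {
  pmax(object$floor_db_hl, pta_db_hl)
}

#' Fit the audibility floor to predicted-versus-measured PTA pairs
#'
#' Least-squares fit of `a(p) = max(floor, p)` to (measured, predicted)
#' pairs, with the floor as the single free parameter (the breakpoint equals
#' the floor). The objective is piecewise quadratic in the floor, so the
#' global minimum is found exactly by minimizing on every interval between
#' consecutive sorted measured PTAs.
#'
#' @param measured_pta measured PTA per listener (dB HL).
#' @param ppta predicted PTA per listener (dB HL).
#' @return a `qvcv_audibility`; `flagged` is `TRUE` when no measured PTA lies
#'   below the fitted floor (no normal-hearing anchor, floor poorly
#'   identified).
#' @export
fit_audibility <- function(measured_pta, ppta) {
  m <- as.numeric(measured_pta)
  p <- as.numeric(ppta)
  stopifnot(length(m) == length(p), all(is.finite(m)), all(is.finite(p)))
  if (length(m) < 10L) stop_qvcv("need at least 10 listeners")

  # candidate intervals for the floor: between consecutive sorted measured
  # PTAs (inclusive of the extremes); on each interval the included set
  # {i : m_i <= f} is constant and the optimum is the mean of its predictions,
  # clamped to the interval
  knots <- sort(unique(c(min(c(m, p)) - 1, m, max(m))))
  best_f <- knots[1L]
  best_j <- Inf
  objective <- function(f) sum((p - pmax(f, m))^2)
  for (i in seq_along(knots)) {
    lo <- knots[i]
    hi <- if (i < length(knots)) knots[i + 1L] else knots[i]
    inc <- m <= lo  # listeners whose a() is the constant floor on (lo, hi]
    f_opt <- if (any(inc)) mean(p[inc]) else lo
    f_opt <- min(max(f_opt, lo), hi)
    for (f in unique(c(lo, f_opt, hi))) {
      j <- objective(f)
      if (j < best_j - 1e-12) {
        best_j <- j
        best_f <- f
      }
    }
  }
  audibility(best_f, flagged = !any(m < best_f))
}

#' Residual hearing loss and excess-loss flag
#'
#' Residual hearing loss (RHL) is the predicted PTA minus the audibility
#' baseline evaluated at the measured PTA: the part of the perceptual deficit
#' that the audiogram does not explain. Listeners with RHL above the
#' threshold (default 5 dB, the test's repeatability limit) are flagged as
#' having excess loss; the comparison is strict.
#'
#' @param ppta predicted PTA (dB HL).
#' @param measured_pta measured PTA (dB HL).
#' @param audibility a `qvcv_audibility`.
#' @param threshold_db excess-loss threshold in dB.
#' @return data frame with columns `ppta`, `measured_pta`, `audibility_db`,
#'   `rhl_db`, `excess`.
#' @examples
#' residual_loss(30, 10, audibility(15))
#' @export
residual_loss <- function(ppta, measured_pta, audibility, threshold_db = 5) {
  stopifnot(inherits(audibility, "qvcv_audibility"),
            length(ppta) == length(measured_pta))
  a <- predict(audibility, measured_pta)
  rhl <- ppta - a
  data.frame(ppta = ppta, measured_pta = measured_pta, audibility_db = a,
             rhl_db = rhl, excess = rhl > threshold_db)
}
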