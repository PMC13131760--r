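#' Test-retest agreement between two paired score lists
#'
#' Pearson correlation and mean absolute difference (MAD) between two test
#' sessions of the same listeners.
#'
#' @param scores1,scores2 paired numeric vectors (same listeners, same
#'   order), length >= 3.
#' @return list with `pearson_r` (`NA` and `flag = "zero variance"` when a
#'   list is constant), `mad`, `n`.
#' @examples
#' session_pair_stats(c(80, 90, 70), c(82, 87, 75))
#' @export
session_pair_stats <- function(scores1, scores2) {
  stopifnot(length(scores1) == length(scores2))
  if (length(scores1) < 3L) stop_qvcv("need at least 3 paired scores")
  stopifnot(all(is.finite(scores1)), all(is.finite(scores2)))
  flag <- NULL
  if (stats::sd(scores1) == 0 || stats::sd(scores2) == 0) {
    r <- NA_real_
    flag <- "zero variance"
  } else {
    r <- stats::cor(scores1, scores2)
  }
  list(pearson_r = r, mad = mean(abs(scores1 - scores2)),
       n = length(scores1), flag = flag)
}

# token-stratified subsample of t row indices from one session's trials;
# tokens are consonant x recording; counts per token differ by at most 1
.stratified_subsample <- function(trials, t) {
  tok <- interaction(trials$consonant, trials$recording, drop = TRUE)
  groups <- split(seq_len(nrow(trials)), tok)
  g <- length(groups)
  sizes <- vapply(groups, length, integer(1))
  if (t > nrow(trials)) stop_qvcv("t exceeds session length")
  base <- t %/% g
  extra <- t %% g
  per <- rep(base, g)
  if (extra > 0L) {
    per[sample.int(g, extra)] <- base + 1L
  }
  if (any(per > sizes)) {
    # more requested than available in some stratum: spill over evenly
    deficit <- sum(pmax(per - sizes, 0L))
    per <- pmin(per, sizes)
    room <- which(per < sizes)
    while (deficit > 0L && length(room) > 0L) {
      pick <- if (length(room) == 1L) room else sample(room, 1L)
      per[pick] <- per[pick] + 1L
      deficit <- deficit - 1L
      room <- which(per < sizes)
    }
  }
  unlist(lapply(seq_len(g), function(i) {
    if (per[i] == 0L) return(integer(0))
    idx <- groups[[i]]
    if (per[i] == length(idx)) idx else idx[sample.int(length(idx), per[i])]
  }), use.names = FALSE)
}

#' Repeatability as a function of test length
#'
#' For each candidate trial count `t`, repeatedly draws a token-balanced
#' random subsample of `t` trials (without replacement, stratified as evenly
#' as `t` allows over the consonant x recording tokens) from each of two
#' sessions per listener, scores both subsamples, and computes the mean
#' absolute difference (MAD) across listeners -- for percent correct and,
#' when a fitted model is supplied, for the predicted PTA. Results are
#' averaged over resamples with a percentile confidence interval.
#'
#' @param trials trial table containing exactly two sessions per listener
#'   (column `session_id`).
#' @param trial_counts integer vector of subsession lengths to evaluate.
#' @param n_resamples random subsamples per count (default 200).
#' @param seed RNG seed.
#' @param model optional `qvcv_pta` for PPTA repeatability.
#' @param panel panel defining the confusion-matrix labels for PPTA scoring.
#' @param method `"subsample"` (default) or `"truncate"` (first `t` trials in
#'   presentation order).
#' @return object of class `qvcv_repeatability`: a data frame with one row
#'   per (`measure`, `trial_count`): mean MAD and 2.5/97.5 percentile CI.
#' @export
mad_vs_trials <- function(trials, trial_counts, n_resamples = 200L,
                          seed = NULL, model = NULL,
                          panel = qvcv_default_panel(),
                          method = c("subsample", "truncate")) {
  method <- match.arg(method)
  trials <- validate_trials(trials)
  trial_counts <- sort(as.integer(trial_counts))
  by_listener <- split(trials, trials$listener_id)
  sess <- lapply(by_listener, function(d) {
    ids <- sort(unique(d$session_id))
    if (length(ids) != 2L) {
      stop_qvcv("every listener needs exactly two sessions; listener ",
                d$listener_id[1L], " has ", length(ids))
    }
    list(s1 = d[d$session_id == ids[1L], ], s2 = d[d$session_id == ids[2L], ])
  })
  min_len <- min(vapply(sess, function(s) min(nrow(s$s1), nrow(s$s2)), integer(1)))
  if (max(trial_counts) > min_len) {
    stop_qvcv("trial count ", max(trial_counts),
              " exceeds the shortest session length (", min_len, ")")
  }

  score_sub <- function(d, idx) 100 * mean(d$correct[idx])
  ppta_sub <- function(d, idx) {
    cm <- build_confusion_matrix(d[idx, , drop = FALSE],
                                 consonants = panel$consonant)
    predict(model, vectorize_ccm(cm))
  }

  with_seed_or_stream(seed, {
    rows <- list()
    for (t in trial_counts) {
      mad_pc <- numeric(n_resamples)
      mad_pp <- if (!is.null(model)) numeric(n_resamples) else NULL
      for (b in seq_len(n_resamples)) {
        d_pc <- d_pp <- numeric(length(sess))
        for (i in seq_along(sess)) {
          s <- sess[[i]]
          idx1 <- if (method == "subsample") .stratified_subsample(s$s1, t) else seq_len(t)
          idx2 <- if (method == "subsample") .stratified_subsample(s$s2, t) else seq_len(t)
          d_pc[i] <- abs(score_sub(s$s1, idx1) - score_sub(s$s2, idx2))
          if (!is.null(model)) {
            d_pp[i] <- abs(ppta_sub(s$s1, idx1) - ppta_sub(s$s2, idx2))
          }
        }
        mad_pc[b] <- mean(d_pc)
        if (!is.null(model)) mad_pp[b] <- mean(d_pp)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "percent_correct", trial_count = t,
        minutes = t / quicksin_reference()$trials_per_minute,
        mad = mean(mad_pc),
        ci_lo = stats::quantile(mad_pc, 0.025, names = FALSE),
        ci_hi = stats::quantile(mad_pc, 0.975, names = FALSE))
      if (!is.null(model)) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = "ppta_db", trial_count = t,
          minutes = t / quicksin_reference()$trials_per_minute,
          mad = mean(mad_pp),
          ci_lo = stats::quantile(mad_pp, 0.025, names = FALSE),
          ci_hi = stats::quantile(mad_pp, 0.975, names = FALSE))
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "n_listeners") <- length(sess)
    attr(out, "n_resamples") <- n_resamples
    attr(out, "seed") <- seed
    class(out) <- c("qvcv_repeatability", "data.frame")
    out
  })
}

#' @export
print.qvcv_repeatability <- function(x, ...) {
  cat("Repeatability (mean absolute difference between sessions)\n")
  cat(sprintf("  %d listeners, %d resamples per trial count\n",
              attr(x, "n_listeners"), attr(x, "n_resamples")))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Clinical reference constants for repeatability comparisons
#'
#' Published operating constants used when comparing the consonant test
#' against the QuickSIN sentence test: the repeatability limits (2.5 dB for
#' QuickSIN, 5 dB for the consonant test), the assumed presentation rate of
#' 25 trials per minute, and the one-minute duration of a QuickSIN list.
#'
#' @return named list of constants.
#' @export
quicksin_reference <- function() {
  list(quicksin_repeatability_db = 2.5,
       qvcv_repeatability_db = 5.0,
       trials_per_minute = 25,
       quicksin_list_minutes = 1)
}
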