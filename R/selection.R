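#' Mann-Whitney area under the ROC curve
#'
#' Probability that a randomly chosen hearing-loss score is lower than a
#' randomly chosen normal-hearing score, with ties counted one half
#' (the Mann-Whitney U statistic divided by `n1 * n2`). Oriented so that
#' "hearing loss performs worse" gives AUC > 0.5.
#'
#' @param scores_nh,scores_hl numeric score vectors (e.g. per-listener
#'   proportion correct) for the normal-hearing and hearing-loss groups.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(0.9, 0.95), c(0.5, 0.6))
#' @export
auc_mann_whitney <- function(scores_nh, scores_hl) {
  if (length(scores_nh) == 0L || length(scores_hl) == 0L) {
    stop_qvcv("both groups must be non-empty")
  }
  stopifnot(all(is.finite(scores_nh)), all(is.finite(scores_hl)))
  n1 <- length(scores_nh)
  n2 <- length(scores_hl)
  r <- rank(c(scores_nh, scores_hl), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

# per-listener, per-unit (consonant / vowel / token) proportion-correct scores
# from a trial table; unit_cols names the grouping columns
.listener_scores <- function(trials, unit_cols) {
  trials <- validate_trials(trials)
  agg <- stats::aggregate(trials$correct,
                          by = c(trials[c("listener_id", unit_cols)]),
                          FUN = function(z) mean(z))
  names(agg)[ncol(agg)] <- "score"
  agg
}

# AUC of NH vs HL per level of `by`, from a per-listener score table with a
# `group` column ("NH"/"HL")
.group_auc <- function(scores, by) {
  stopifnot(all(c("group", "score", by) %in% names(scores)))
  lv <- unique(scores[[by]])
  out <- data.frame(level = lv, auc = NA_real_, stringsAsFactors = FALSE)
  names(out)[1L] <- by
  for (i in seq_along(lv)) {
    sub <- scores[scores[[by]] == lv[i], ]
    out$auc[i] <- auc_mann_whitney(sub$score[sub$group == "NH"],
                                   sub$score[sub$group != "NH"])
  }
  out
}

#' Screen consonants by NH-vs-HL discriminability
#'
#' Computes, for each consonant, the AUC of per-listener proportion-correct
#' scores for normal-hearing versus hearing-loss listeners, and drops
#' consonants whose AUC falls below the threshold (default 0.9). Bootstrap
#' resampling of listeners provides the AUC distribution behind each
#' consonant's point estimate.
#'
#' @param scores per-listener score table with columns `listener_id`,
#'   `group` (`"NH"` or anything else for hearing loss), `consonant`,
#'   `score`; or a trial table plus `groups` (named vector listener -> group)
#'   from which scores are computed.
#' @param threshold_auc consonants with AUC below this are dropped.
#' @param n_boot bootstrap resamples of listeners for the AUC distributions
#'   (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @return list with `retained`, `dropped`, `auc` (per-consonant table with
#'   bootstrap quartiles when requested).
#' @export
screen_consonants <- function(scores, threshold_auc = 0.9, n_boot = 0L,
                              seed = NULL) {
  stopifnot(all(c("listener_id", "group", "consonant", "score") %in% names(scores)))
  scores$consonant <- normalize_consonant(scores$consonant)
  auc <- .group_auc(scores, "consonant")
  if (n_boot > 0L) {
    qs <- with_seed_or_stream(seed, {
      ids <- unique(scores$listener_id)
      grp <- scores$group[match(ids, scores$listener_id)]
      boot <- matrix(NA_real_, n_boot, nrow(auc))
      for (b in seq_len(n_boot)) {
        take <- c(sample(ids[grp == "NH"], replace = TRUE),
                  sample(ids[grp != "NH"], replace = TRUE))
        sub <- do.call(rbind, lapply(seq_along(take), function(j) {
          s <- scores[scores$listener_id == take[j], ]
          s$listener_id <- paste0(take[j], ".", j)
          s
        }))
        boot[b, ] <- .group_auc(sub, "consonant")$auc[
          match(auc$consonant, .group_auc(sub, "consonant")$consonant)]
      }
      t(apply(boot, 2L, stats::quantile, c(0.25, 0.5, 0.75), na.rm = TRUE))
    })
    auc$q25 <- qs[, 1L]; auc$median <- qs[, 2L]; auc$q75 <- qs[, 3L]
  }
  keep <- auc$auc >= threshold_auc
  list(retained = auc$consonant[keep], dropped = auc$consonant[!keep],
       auc = auc, threshold_auc = threshold_auc)
}

#' Select the vowel context with the best AUC distribution
#'
#' Returns the vowel maximizing the median AUC across consonants; ties are
#' broken by the smaller interquartile range, then alphabetically.
#'
#' @param vowel_auc data frame with columns `vowel` and `auc` (one row per
#'   consonant or bootstrap draw within each vowel context).
#' @return list with `vowel` (the winner) and `table` (per-vowel median and
#'   IQR).
#' @export
select_vowel <- function(vowel_auc) {
  stopifnot(all(c("vowel", "auc") %in% names(vowel_auc)))
  vowel_auc$vowel <- normalize_vowel(vowel_auc$vowel)
  if (length(unique(vowel_auc$vowel)) == 0L) stop_qvcv("no vowels supplied")
  tab <- do.call(rbind, lapply(split(vowel_auc, vowel_auc$vowel), function(s) {
    data.frame(vowel = s$vowel[1L], median_auc = stats::median(s$auc),
               iqr_auc = stats::IQR(s$auc), stringsAsFactors = FALSE)
  }))
  ord <- order(-tab$median_auc, tab$iqr_auc, tab$vowel)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(vowel = tab$vowel[1L], table = tab)
}

#' Pick the most discriminative SNR for each token
#'
#' For each consonant, returns the candidate SNR with the highest AUC; ties
#' go to the lower (more adverse) SNR, which keeps the panel's dynamic range
#' short.
#'
#' @param token_auc data frame with columns `consonant`, `snr_db`, `auc`.
#' @return data frame with one row per consonant: `consonant`, `snr_db`,
#'   `auc`.
#' @export
select_snr_per_token <- function(token_auc) {
  stopifnot(all(c("consonant", "snr_db", "auc") %in% names(token_auc)))
  token_auc$consonant <- normalize_consonant(token_auc$consonant)
  out <- do.call(rbind, lapply(split(token_auc, token_auc$consonant), function(s) {
    s <- s[order(-s$auc, s$snr_db), , drop = FALSE]
    s[1L, c("consonant", "snr_db", "auc")]
  }))
  rownames(out) <- NULL
  out[order(match(out$consonant, qvcv_consonants())), , drop = FALSE]
}

#' The packaged default token panel
#'
#' The final ten-consonant /a/-context panel with each token's fixed
#' presentation SNR and its NH-vs-HL AUC: consonants b d g k n s sh t v z at
#' SNRs 15, 4, 3, 0, 15, 0, 0, 0, 15, 0 dB with AUCs 0.96, 0.98, 0.94, 0.89,
#' 1.00, 0.94, 0.98, 0.99, 0.95, 0.98.
#'
#' @return object of class `qvcv_panel`: a data frame with columns
#'   `consonant`, `vowel`, `snr_db`, `auc`.
#' @export
qvcv_default_panel <- function() {
  as_qvcv_panel(data.frame(
    consonant = c("b", "d", "g", "k", "n", "s", "sh", "t", "v", "z"),
    vowel = "a",
    snr_db = c(15L, 4L, 3L, 0L, 15L, 0L, 0L, 0L, 15L, 0L),
    auc = c(0.96, 0.98, 0.94, 0.89, 1.00, 0.94, 0.98, 0.99, 0.95, 0.98),
    stringsAsFactors = FALSE
  ))
}

#' Construct / validate a token panel
#'
#' @param x data frame with columns `consonant`, `vowel`, `snr_db` and
#'   optionally `auc`.
#' @return `x` with class `qvcv_panel`.
#' @export
as_qvcv_panel <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("consonant", "vowel", "snr_db") %in% names(x)))
  x$consonant <- normalize_consonant(x$consonant)
  x$vowel <- normalize_vowel(x$vowel)
  if (anyDuplicated(x[c("consonant", "vowel")])) {
    stop_qvcv("panel has duplicate (consonant, vowel) entries")
  }
  if (any(x$snr_db != round(x$snr_db))) stop_qvcv("panel SNRs must be integer dB")
  x$snr_db <- as.integer(x$snr_db)
  if (!is.null(x$auc) && (any(x$auc < 0) || any(x$auc > 1))) {
    stop_qvcv("panel AUCs must lie in [0, 1]")
  }
  rownames(x) <- NULL
  class(x) <- c("qvcv_panel", "data.frame")
  x
}

#' Run the full token-selection pipeline
#'
#' Experiment-2 style screening: (1) drop consonants whose NH-vs-HL AUC is
#' below `threshold_auc`; (2) pick the vowel context with the best AUC
#' distribution; (3) pick, per retained consonant, the candidate SNR with the
#' highest AUC. The result is a `qvcv_panel`.
#'
#' @param scores per-listener score table with columns `listener_id`,
#'   `group`, `consonant`, `vowel`, `snr_db`, `score` (proportion correct on
#'   that token at that SNR).
#' @inheritParams screen_consonants
#' @return list with `panel` and the intermediate reports.
#' @export
select_panel <- function(scores, threshold_auc = 0.9) {
  stopifnot(all(c("listener_id", "group", "consonant", "vowel", "snr_db",
                  "score") %in% names(scores)))
  scores$consonant <- normalize_consonant(scores$consonant)
  scores$vowel <- normalize_vowel(scores$vowel)

  # vowel choice first, from the per-(consonant, vowel) AUC distributions
  cv <- unique(scores[c("consonant", "vowel")])
  cv$auc <- NA_real_
  for (i in seq_len(nrow(cv))) {
    sub <- scores[scores$consonant == cv$consonant[i] &
                    scores$vowel == cv$vowel[i], ]
    agg <- stats::aggregate(sub$score,
                            by = list(listener_id = sub$listener_id,
                                      group = sub$group), FUN = mean)
    cv$auc[i] <- auc_mann_whitney(agg$x[agg$group == "NH"],
                                  agg$x[agg$group != "NH"])
  }
  vow <- select_vowel(cv[c("vowel", "auc")])
  sv <- scores[scores$vowel == vow$vowel, ]

  # consonant screening within the chosen vowel (scores pooled over SNRs)
  agg <- stats::aggregate(sv$score,
                          by = list(listener_id = sv$listener_id,
                                    group = sv$group, consonant = sv$consonant),
                          FUN = mean)
  names(agg)[ncol(agg)] <- "score"
  scr <- screen_consonants(agg, threshold_auc = threshold_auc)

  # per-token SNR choice among candidates
  sc <- sv[sv$consonant %in% scr$retained, ]
  tok <- unique(sc[c("consonant", "snr_db")])
  tok$auc <- NA_real_
  for (i in seq_len(nrow(tok))) {
    sub <- sc[sc$consonant == tok$consonant[i] & sc$snr_db == tok$snr_db[i], ]
    agg2 <- stats::aggregate(sub$score,
                             by = list(listener_id = sub$listener_id,
                                       group = sub$group), FUN = mean)
    tok$auc[i] <- auc_mann_whitney(agg2$x[agg2$group == "NH"],
                                   agg2$x[agg2$group != "NH"])
  }
  snr <- select_snr_per_token(tok)
  panel <- as_qvcv_panel(data.frame(consonant = snr$consonant,
                                    vowel = vow$vowel, snr_db = snr$snr_db,
                                    auc = snr$auc, stringsAsFactors = FALSE))
  list(panel = panel, vowel = vow, screening = scr, snr_choice = snr)
}
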