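#' Psychometric-function value for the closed-set task
#'
#' Proportion correct as a function of SNR for a logistic psychometric
#' function with a guess floor and a lapse ceiling:
#' `P(s) = guess + (1 - guess - lapse) * plogis(slope * (s - midpoint))`.
#' The guess floor defaults to 1/14, the chance rate of the 14-button
#' closed-set response panel.
#'
#' @param snr_db SNR in dB.
#' @param midpoint_db SNR of the inflection point (dB).
#' @param slope_per_db logistic rate parameter (1/dB); the peak slope in
#'   proportion per dB is `(1 - guess - lapse) * slope / 4`.
#' @param guess,lapse floor and ceiling probabilities.
#' @return proportion correct in `(guess, 1 - lapse)`.
#' @export
psychometric_prob <- function(snr_db, midpoint_db, slope_per_db,
                              guess = 1 / 14, lapse = 0.02) {
  guess + (1 - guess - lapse) * stats::plogis(slope_per_db * (snr_db - midpoint_db))
}

#' Fit a per-token psychometric function from fixed-SNR blocks
#'
#' Maximum-likelihood fit of the logistic psychometric function (guess floor
#' and lapse fixed) to per-SNR binomial counts, with a weak Gaussian prior on
#' the log slope that stabilizes fits to as few as two or three SNR points.
#' The fit is deterministic (multi-start Nelder-Mead over the observed SNR
#' range).
#'
#' @param points data frame with columns `snr_db`, `n` (trials) and `k`
#'   (correct). At least two distinct SNRs.
#' @param guess,lapse fixed floor and ceiling probabilities.
#' @param slope_prior `c(mean, sd)` of the Gaussian prior on `log(slope)`.
#' @param token optional `c(consonant, vowel)` label carried in the result.
#' @return object of class `qvcv_psychfit` with elements `midpoint_db`,
#'   `slope_per_db`, `guess`, `lapse`, `points`, `degenerate`, `logLik`.
#' @examples
#' pts <- data.frame(snr_db = c(0, 6, 12), n = 100, k = c(80, 92, 97))
#' fit <- fit_psychometric(pts)
#' snr90(fit)
#' @export
fit_psychometric <- function(points, guess = 1 / 14, lapse = 0.02,
                             slope_prior = c(mean = log(0.5), sd = 1.5),
                             token = NULL) {
  stopifnot(is.data.frame(points), all(c("snr_db", "n", "k") %in% names(points)))
  points <- points[order(points$snr_db), , drop = FALSE]
  if (length(unique(points$snr_db)) < 2L) {
    stop_qvcv("need at least 2 distinct SNRs")
  }
  if (any(points$n < 1) || any(points$k < 0) || any(points$k > points$n)) {
    stop_qvcv("invalid counts: need 0 <= k <= n, n >= 1")
  }
  if (!all(is.finite(points$snr_db))) stop_qvcv("snr_db must be finite")
  stopifnot(guess >= 0, guess < 1, lapse >= 0, guess + lapse < 1)

  degenerate <- all(points$k == points$n) || all(points$k == 0)

  negpen <- function(par) {
    m <- par[[1L]]
    b <- exp(par[[2L]])
    p <- psychometric_prob(points$snr_db, m, b, guess, lapse)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(points$k * log(p) + (points$n - points$k) * log1p(-p)) +
      0.5 * ((par[[2L]] - slope_prior[[1L]]) / slope_prior[[2L]])^2
  }

  rng <- range(points$snr_db)
  starts <- expand.grid(m = seq(rng[1L] - 6, rng[2L] + 6, length.out = 7),
                        lb = log(c(0.15, 0.5, 1.5)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(starts$m[i], starts$lb[i]), negpen,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  m <- best$par[[1L]]
  b <- exp(best$par[[2L]])
  if (degenerate) {
    # likelihood is flat in m; pin the midpoint at the relevant bound
    m <- if (all(points$k == points$n)) rng[1L] - 6 else rng[2L] + 6
  }
  p <- psychometric_prob(points$snr_db, m, b, guess, lapse)
  ll <- sum(stats::dbinom(points$k, points$n, pmin(pmax(p, 1e-12), 1 - 1e-12),
                          log = TRUE))
  structure(
    list(token = token, points = points, guess = guess, lapse = lapse,
         midpoint_db = m, slope_per_db = b, degenerate = degenerate,
         logLik = ll, slope_prior = slope_prior),
    class = "qvcv_psychfit"
  )
}

#' @export
print.qvcv_psychfit <- function(x, ...) {
  tok <- if (is.null(x$token)) "" else paste0(" /", paste(x$token, collapse = ""), "/")
  cat(sprintf("Psychometric fit%s: midpoint %.2f dB, slope %.3f /dB%s\n",
              tok, x$midpoint_db, x$slope_per_db,
              if (x$degenerate) " [degenerate]" else ""))
  s9 <- snr90(x)
  cat("  SNR90:", if (is.na(s9$value)) s9$flag else sprintf("%.2f dB", s9$value),
      "\n")
  invisible(x)
}

#' @export
predict.qvcv_psychfit <- function(object, snr_db, ...) {
  psychometric_prob(snr_db, object$midpoint_db, object$slope_per_db,
                    object$guess, object$lapse)
}

#' SNR at which the fitted function reaches a target proportion correct
#'
#' Solves `P(s) = target` (default 0.90, the SNR90 used to normalize
#' normal-hearing performance). Tokens whose fitted performance already
#' exceeds the target at the lowest tested SNR are flagged `"saturated"`;
#' tokens still below target at the highest tested SNR whose extrapolated
#' crossing lies more than `extrapolation_db` beyond it are flagged
#' `"unreached"`. Crossings below `min - extrapolation_db` are also reported
#' as saturated (the token is too easy for the tested range).
#'
#' @param fit a `qvcv_psychfit`.
#' @param target target proportion correct.
#' @param extrapolation_db how far beyond the observed SNR range the crossing
#'   may be extrapolated before it is flagged.
#' @return list with `value` (dB, `NA` when flagged) and `flag` (`"ok"`,
#'   `"saturated"`, `"unreached"`, `"degenerate"`).
#' @export
snr90 <- function(fit, target = 0.90, extrapolation_db = 6) {
  stopifnot(inherits(fit, "qvcv_psychfit"))
  if (fit$degenerate) {
    flag <- if (all(fit$points$k == fit$points$n)) "saturated" else "unreached"
    return(list(value = NA_real_, flag = flag))
  }
  if (target <= fit$guess || target >= 1 - fit$lapse) {
    stop_qvcv("target outside the attainable range (guess, 1 - lapse)")
  }
  rng <- range(fit$points$snr_db)
  q <- (target - fit$guess) / (1 - fit$guess - fit$lapse)
  s <- fit$midpoint_db + stats::qlogis(q) / fit$slope_per_db
  if (predict(fit, rng[1L]) > target || s < rng[1L] - extrapolation_db) {
    return(list(value = NA_real_, flag = "saturated"))
  }
  if (predict(fit, rng[2L]) < target && s > rng[2L] + extrapolation_db) {
    return(list(value = NA_real_, flag = "unreached"))
  }
  list(value = s, flag = "ok")
}

#' Propose the refined three-SNR grid around SNR90
#'
#' The follow-up measurement grid is `{SNR90 - 3, SNR90, SNR90 + 3}` dB with
#' SNR90 rounded half-up to the nearest integer dB.
#'
#' @param fit a `qvcv_psychfit`, or a number taken as SNR90 directly.
#' @inheritParams snr90
#' @return integer vector of three SNRs.
#' @examples
#' propose_snr_grid(4.2)
#' @export
propose_snr_grid <- function(fit, target = 0.90) {
  s <- if (is.numeric(fit)) {
    stopifnot(length(fit) == 1L, is.finite(fit))
    fit
  } else {
    r <- snr90(fit, target)
    if (r$flag != "ok") {
      stop_qvcv("cannot propose a grid for a fit flagged '", r$flag, "'")
    }
    r$value
  }
  as.integer(round_half_up(s) + c(-3, 0, 3))
}

#' Fit psychometric functions for every token in a count table
#'
#' Convenience wrapper over [fit_psychometric()] for aggregated count tables
#' (columns `consonant`, `vowel`, `snr_db`, `n`, `k`), returning one row per
#' token with the fitted parameters, the SNR90 and its flag, and the proposed
#' refined SNR grid where defined.
#'
#' @param counts aggregated count table.
#' @inheritParams fit_psychometric
#' @return data frame report, one row per (consonant, vowel).
#' @export
snr90_report <- function(counts, guess = 1 / 14, lapse = 0.02) {
  stopifnot(all(c("consonant", "vowel", "snr_db", "n", "k") %in% names(counts)))
  counts$consonant <- normalize_consonant(counts$consonant)
  counts$vowel <- normalize_vowel(counts$vowel)
  keys <- unique(counts[c("consonant", "vowel")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- counts[counts$consonant == keys$consonant[i] &
                    counts$vowel == keys$vowel[i], ]
    fit <- fit_psychometric(sub[c("snr_db", "n", "k")], guess = guess,
                            lapse = lapse,
                            token = c(keys$consonant[i], keys$vowel[i]))
    s9 <- snr90(fit)
    grid <- if (s9$flag == "ok") propose_snr_grid(s9$value) else rep(NA_integer_, 3)
    out[[i]] <- data.frame(
      consonant = keys$consonant[i], vowel = keys$vowel[i],
      midpoint_db = fit$midpoint_db, slope_per_db = fit$slope_per_db,
      snr90_db = s9$value, flag = s9$flag,
      grid_lo = grid[1L], grid_mid = grid[2L], grid_hi = grid[3L],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
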