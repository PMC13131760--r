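#' Calibrated per-token response models for the synthetic listener
#'
#' Each token (consonant in /a/ context) gets a logistic psychometric
#' function in SNR whose midpoint is set so that a listener at the
#' normal-hearing knee (effective loss 15 dB HL) scores exactly `target`
#' (default 0.90) at the token's panel SNR -- the SNR90 normalization that
#' puts hearing-impaired listeners on the steep part of the function.
#' Hearing loss above the knee shifts the midpoint upward by `loss_shift` dB
#' per dB of effective loss. Error responses are drawn from a confusion
#' kernel built from articulatory similarity (softmax over negated
#' voicing/place/manner distance); a second, voicing-blind kernel models the
#' confusion signature of excess (suprathreshold) loss.
#'
#' @param panel a `qvcv_panel`.
#' @param target proportion correct at the panel SNR for a listener at the
#'   knee; must lie in `(guess, 1 - lapse)`.
#' @param guess,lapse floor and ceiling of the psychometric function.
#' @param slope_range,loss_shift_range ranges (uniform draws) for the
#'   per-token logistic rate (1/dB) and the midpoint shift per dB of
#'   effective loss above the knee.
#' @param temperature softmax temperature of the confusion kernel; large
#'   values approach a uniform kernel.
#' @param other_distance pseudo-distance assigned to the "other" button.
#' @param knee_db_hl effective loss below which performance no longer
#'   improves (the audibility floor the test is expected to recover).
#' @param seed RNG seed (`NULL` = use the current RNG stream).
#' @return object of class `qvcv_token_models`.
#' @export
calibrate_token_models <- function(panel = qvcv_default_panel(), target = 0.90,
                                   guess = 1 / 14, lapse = 0.02,
                                   slope_range = c(0.25, 0.45),
                                   loss_shift_range = c(0.2, 0.35),
                                   temperature = 0.7, other_distance = 2,
                                   knee_db_hl = 15, seed = NULL) {
  panel <- as_qvcv_panel(panel)
  if (target <= guess || target >= 1 - lapse) {
    stop_qvcv("unreachable target: must lie in (guess, 1 - lapse)")
  }
  with_seed_or_stream(seed, {
    n <- nrow(panel)
    slope <- stats::runif(n, slope_range[1L], slope_range[2L])
    shift <- stats::runif(n, loss_shift_range[1L], loss_shift_range[2L])
    q <- (target - guess) / (1 - guess - lapse)
    midpoint <- panel$snr_db - stats::qlogis(q) / slope
    params <- data.frame(consonant = panel$consonant, vowel = panel$vowel,
                         snr_db = panel$snr_db, midpoint_db = midpoint,
                         slope_per_db = slope, loss_shift = shift,
                         stringsAsFactors = FALSE)
    structure(
      list(panel = panel, params = params, guess = guess, lapse = lapse,
           target = target, knee_db_hl = knee_db_hl,
           temperature = temperature, other_distance = other_distance,
           kernel = .confusion_kernel(temperature, other_distance,
                                      c(voicing = 1, place = 1, manner = 2)),
           kernel_excess = .confusion_kernel(temperature, other_distance,
                                             c(voicing = 0, place = 1,
                                               manner = 2))),
      class = "qvcv_token_models"
    )
  })
}

# row-stochastic kernel over wrong responses (12 other consonants + "other")
.confusion_kernel <- function(temperature, other_distance, weights) {
  d <- consonant_distance(weights)
  cons <- rownames(d)
  resp <- c(cons, qvcv_other_label())
  k <- matrix(0, length(cons), length(resp), dimnames = list(cons, resp))
  for (i in seq_along(cons)) {
    dd <- c(d[i, ], other_distance)
    w <- exp(-dd / temperature)
    w[i] <- 0  # the correct response is not an "error"
    k[i, ] <- w / sum(w)
  }
  k
}

#' @export
print.qvcv_token_models <- function(x, ...) {
  cat(sprintf("Calibrated token models: %d tokens, target %.0f%% at panel SNRs (knee %g dB HL)\n",
              nrow(x$params), 100 * x$target, x$knee_db_hl))
  print(x$params, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Closed-form probability of a correct response
#'
#' `P(correct) = guess + (1 - guess - lapse) *
#'   plogis(slope * (snr - midpoint - loss_shift * max(0, loss - knee)))`,
#' where `loss` is the listener's effective loss (true PTA plus any excess
#' offset minus any aided relief, floored at -10 dB HL).
#'
#' @param token_models a `qvcv_token_models`.
#' @param consonant consonant label(s).
#' @param snr_db presentation SNR(s).
#' @param effective_loss_db effective loss in dB HL.
#' @param lapse optional per-listener lapse overriding the calibration lapse.
#' @return probability vector.
#' @export
p_correct <- function(token_models, consonant, snr_db, effective_loss_db,
                      lapse = NULL) {
  stopifnot(inherits(token_models, "qvcv_token_models"))
  pr <- token_models$params
  i <- match(normalize_consonant(consonant), pr$consonant)
  if (anyNA(i)) stop_qvcv("consonant not in the calibrated panel")
  la <- lapse %||% token_models$lapse
  shift <- pr$loss_shift[i] * pmax(0, effective_loss_db - token_models$knee_db_hl)
  token_models$guess + (1 - token_models$guess - la) *
    stats::plogis(pr$slope_per_db[i] * (snr_db - pr$midpoint_db[i] - shift))
}

#' Effective loss of a listener profile
#'
#' True PTA plus the excess offset, minus the aided relief when aided,
#' floored at -10 dB HL.
#'
#' @param profile one row of a profile table (see [simulate_listeners()]).
#' @param aided condition label; relief applies to `lab_aid` and
#'   `personal_aid`.
#' @return effective loss in dB HL.
#' @export
effective_loss <- function(profile, aided = "unaided") {
  relief <- ifelse(aided == "unaided", 0, profile$aided_relief_db)
  pmax(-10, profile$true_pta_db_hl + profile$excess_offset_db - relief)
}

#' Draw a cohort of synthetic listener profiles
#'
#' True PTAs are drawn uniformly within each hearing-category band
#' (NH -10-15, slight 16-25, mild 26-40, moderate 41-55 dB HL). A designated
#' subset receives an excess-loss offset: extra effective loss that the
#' "audiogram" (the `true_pta` field) does not show, plus the voicing-blind
#' confusion signature in [simulate_trials()].
#'
#' @param n_per_category named or positional counts for NH, slight, mild,
#'   moderate.
#' @param n_excess number of excess-loss listeners (drawn at random across
#'   the cohort); alternatively `excess_fraction`.
#' @param excess_fraction fraction of listeners given the excess offset
#'   (ignored when `n_excess` is supplied).
#' @param excess_delta_db the excess offset in dB.
#' @param aided_relief_db effective-loss reduction when aided (scalar or per
#'   listener).
#' @param lapse,guess response-model probabilities stored on the profile.
#' @param seed RNG seed (`NULL` = current stream).
#' @return data frame of class `qvcv_profiles`: `listener_id`,
#'   `true_pta_db_hl`, `category`, `excess_offset_db`, `lapse`, `guess`,
#'   `aided_relief_db`.
#' @export
simulate_listeners <- function(n_per_category = c(NH = 15, slight = 15,
                                                  mild = 15, moderate = 15),
                               n_excess = NULL, excess_fraction = 0,
                               excess_delta_db = 10, aided_relief_db = 0,
                               lapse = 0.02, guess = 1 / 14, seed = NULL) {
  stopifnot(length(n_per_category) == 4L, all(n_per_category >= 0))
  bands <- category_bands()
  with_seed_or_stream(seed, {
    pta <- unlist(lapply(seq_len(4L), function(i) {
      stats::runif(n_per_category[[i]], bands$lo_db_hl[i], bands$hi_db_hl[i])
    }))
    n <- length(pta)
    if (is.null(n_excess)) n_excess <- round(excess_fraction * n)
    if (n_excess > n) stop_qvcv("more excess listeners than listeners")
    excess <- numeric(n)
    if (n_excess > 0L) excess[sample.int(n, n_excess)] <- excess_delta_db
    out <- data.frame(
      listener_id = sprintf("L%02d", seq_len(n)),
      true_pta_db_hl = pta,
      category = assign_category(pta),
      excess_offset_db = excess,
      lapse = lapse, guess = guess,
      aided_relief_db = rep_len(aided_relief_db, n),
      stringsAsFactors = FALSE
    )
    class(out) <- c("qvcv_profiles", "data.frame")
    out
  })
}

#' Simulate closed-set identification trials
#'
#' Draws trial-level responses for every listener on every panel token. The
#' probability of a correct response follows [p_correct()]; errors are drawn
#' from the listener's confusion kernel (the voicing-blind kernel for
#' excess-loss listeners, the articulatory kernel otherwise). Sessions are
#' balanced: every token (consonant x recording) appears `reps_per_token`
#' times per session.
#'
#' @param profiles a `qvcv_profiles` table.
#' @param token_models a `qvcv_token_models`.
#' @param reps_per_token presentations of each consonant x recording token
#'   per session.
#' @param n_sessions sessions per listener.
#' @param aided condition label for all trials (`unaided`, `lab_aid`,
#'   `personal_aid`).
#' @param seed RNG seed (`NULL` = current stream).
#' @return trial table (see [validate_trials()]).
#' @export
simulate_trials <- function(profiles, token_models, reps_per_token = 5L,
                            n_sessions = 2L, aided = "unaided", seed = NULL) {
  stopifnot(inherits(token_models, "qvcv_token_models"),
            aided %in% c("unaided", "lab_aid", "personal_aid"))
  pr <- token_models$params
  with_seed_or_stream(seed, {
    out <- vector("list", nrow(profiles))
    resp_labels <- colnames(token_models$kernel)
    for (li in seq_len(nrow(profiles))) {
      prof <- profiles[li, ]
      loss <- effective_loss(prof, aided)
      kern <- if (prof$excess_offset_db > 0) token_models$kernel_excess else
        token_models$kernel
      grid <- expand.grid(session = seq_len(n_sessions),
                          rep = seq_len(reps_per_token),
                          recording = 1:2,
                          tok = seq_len(nrow(pr)))
      p <- p_correct(token_models, pr$consonant[grid$tok],
                     pr$snr_db[grid$tok], loss, lapse = prof$lapse)
      ok <- stats::runif(nrow(grid)) < p
      resp <- pr$consonant[grid$tok]
      if (any(!ok)) {
        wrong <- which(!ok)
        krow <- kern[match(resp[wrong], rownames(kern)), , drop = FALSE]
        u <- stats::runif(length(wrong))
        cum <- krow %*% upper.tri(diag(ncol(krow)), diag = TRUE)
        pick <- max.col(cum >= u, ties.method = "first")
        resp[wrong] <- resp_labels[pick]
      }
      out[[li]] <- data.frame(
        listener_id = prof$listener_id,
        session_id = sprintf("S%d", grid$session),
        block = grid$rep,
        consonant = pr$consonant[grid$tok],
        vowel = pr$vowel[grid$tok],
        recording = grid$recording,
        snr_db = pr$snr_db[grid$tok],
        response = resp,
        aided = aided,
        correct = ok & (resp == pr$consonant[grid$tok]),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate a complete test cohort
#'
#' Draws listener profiles, calibrates the token models to the target
#' normal-hearing score, and generates balanced sessions for every listener,
#' all under one seed.
#'
#' @inheritParams simulate_listeners
#' @inheritParams simulate_trials
#' @param panel a `qvcv_panel`.
#' @param target calibration target (NH proportion correct at panel SNRs).
#' @param aided condition(s) to simulate; one trial table covers all.
#' @param seed RNG seed.
#' @return object of class `qvcv_cohort`: list with `trials`, `meta`
#'   (listener metadata: `listener_id`, `measured_pta_db_hl`, `category`,
#'   `test_ear`), `profiles` (simulation ground truth), `token_models`,
#'   `panel`.
#' @export
simulate_cohort <- function(n_per_category = c(NH = 15, slight = 15,
                                               mild = 15, moderate = 15),
                            panel = qvcv_default_panel(),
                            reps_per_token = 5L, n_sessions = 2L,
                            n_excess = NULL, excess_fraction = 0,
                            excess_delta_db = 10, aided_relief_db = 0,
                            target = 0.90, aided = "unaided", seed = 1L) {
  with_seed_or_stream(seed, {
    tm <- calibrate_token_models(panel, target = target, seed = NULL)
    profiles <- simulate_listeners(n_per_category, n_excess = n_excess,
                                   excess_fraction = excess_fraction,
                                   excess_delta_db = excess_delta_db,
                                   aided_relief_db = aided_relief_db,
                                   seed = NULL)
    trials <- do.call(rbind, lapply(aided, function(cond) {
      simulate_trials(profiles, tm, reps_per_token = reps_per_token,
                      n_sessions = n_sessions, aided = cond, seed = NULL)
    }))
    meta <- data.frame(listener_id = profiles$listener_id,
                       measured_pta_db_hl = round_half_up(profiles$true_pta_db_hl),
                       category = profiles$category,
                       test_ear = "right",
                       stringsAsFactors = FALSE)
    structure(list(trials = trials, meta = meta, profiles = profiles,
                   token_models = tm, panel = as_qvcv_panel(panel)),
              class = "qvcv_cohort")
  })
}

#' @export
print.qvcv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d listeners, %d trials (%s)\n",
              nrow(x$profiles), nrow(x$trials),
              paste(unique(x$trials$aided), collapse = ", ")))
  print(table(x$profiles$category)[unique(x$profiles$category)])
  invisible(x)
}

#' Per-listener confusion matrices from a cohort or trial table
#'
#' @param trials trial table.
#' @param panel panel whose consonants define the matrix labels.
#' @param aided condition to keep.
#' @param session_id optional session filter.
#' @return named list of `qvcv_ccm`, one per listener (in order of first
#'   appearance).
#' @export
cohort_ccms <- function(trials, panel = qvcv_default_panel(),
                        aided = "unaided", session_id = NULL) {
  if (inherits(trials, "qvcv_cohort")) trials <- trials$trials
  ids <- unique(trials$listener_id)
  out <- lapply(ids, function(id) {
    build_confusion_matrix(trials[trials$listener_id == id, , drop = FALSE],
                           consonants = panel$consonant, aided = aided,
                           session_id = session_id)
  })
  names(out) <- ids
  out
}
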