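# a transparent stub model whose PPTA is 80 - 50 x (proportion of /b/ trials
# answered "b"), so benefit arithmetic can be checked exactly
stub_model <- function() {
  nf <- 110L
  feat <- names(vectorize_ccm(build_confusion_matrix(balanced_session())))
  rot <- matrix(0, nf, 1, dimnames = list(feat, "PC1"))
  rot["b>b", 1] <- 1
  core <- list(center = setNames(rep(0, nf), feat),
               scale = setNames(rep(1, nf), feat),
               rotation = rot, sdev = 1, k = 1L,
               intercept = 80, beta = -50, scores = NULL)
  structure(list(core = core, lambda = 3, pca_variance = 0.95,
                 normalization = "center", feature_names = feat,
                 n = 0L, pta = NULL, fitted_training = NULL,
                 training_mae = NA_real_, cv = NULL, classifier = NULL),
            class = "qvcv_pta")
}

# a session whose /b/ rows have a chosen accuracy, everything else correct
session_with_b_accuracy <- function(p_b, aided = "unaided", reps = 5L) {
  ses <- balanced_session(reps = reps, aided = aided)
  bidx <- which(ses$consonant == "b")
  flip <- bidx[seq_len(round((1 - p_b) * length(bidx)))]
  ses$response[flip] <- "d"
  ses$correct <- ses$response == ses$consonant
  ses
}

test_that("identical conditions give zero benefit and no significance", {
  m <- stub_model()
  cm <- build_confusion_matrix(session_with_b_accuracy(0.8))
  cma <- build_confusion_matrix(session_with_b_accuracy(0.8, aided = "lab_aid"))
  b <- hearing_aid_benefit(cm, cma, m)
  expect_equal(b$delta_percent, 0)
  expect_equal(b$delta_db, 0)
  expect_false(b$significant)
})

test_that("dB benefit is the drop in predicted loss, strict at the limit", {
  m <- stub_model()
  un <- build_confusion_matrix(session_with_b_accuracy(0.5))           # PPTA 55
  ai <- build_confusion_matrix(session_with_b_accuracy(0.9, "lab_aid")) # PPTA 35
  b <- hearing_aid_benefit(un, ai, m)
  expect_equal(b$unaided_ppta, 55)
  expect_equal(b$aided_ppta, 35)
  expect_equal(b$delta_db, 20)
  expect_true(b$significant)

  # exactly at the 5 dB limit: /b/ accuracy 0.8 -> 0.9 moves PPTA 40 -> 35
  un5 <- build_confusion_matrix(session_with_b_accuracy(0.8))
  b5 <- hearing_aid_benefit(un5, ai, m)
  expect_equal(b5$delta_db, 5)
  expect_false(b5$significant)

  # antisymmetry under swapping conditions
  brev <- hearing_aid_benefit(ai, un, m)
  expect_equal(brev$delta_db, -b$delta_db)
  expect_equal(brev$delta_percent, -b$delta_percent)

  other <- build_confusion_matrix(session_with_b_accuracy(0.9, "lab_aid",
                                                          reps = 2L))
  other$listener_id <- "L2"
  expect_error(hearing_aid_benefit(un, other, m), "different listeners")
})

test_that("benefit summary counts significance and the ceiling flag", {
  res <- data.frame(listener_id = c("A", "B", "C"),
                    delta_percent = c(0, 0, 0), delta_db = c(0, 0, 0),
                    aided_percent = c(95, 88, 91), significant = FALSE)
  rep0 <- benefit_report(res)
  expect_equal(rep0$by_category$n_significant, 0L)
  expect_equal(rep0$by_category$n_restored, 2L)  # 88% is not restored
  expect_false(rep0$results$restored_to_ceiling[2])

  pta <- c(A = 10, B = 45, C = 50)
  repc <- benefit_report(res, measured_pta = pta)
  expect_equal(sum(repc$by_category$n), 3L)
  expect_equal(repc$by_category$n[repc$by_category$category == "moderate"], 2L)
})

test_that("simulated aided relief is recovered in the dB benefit", {
  # model trained on an unaided cohort; aided listeners get delta dB of
  # effective-loss relief, which should reappear as ~delta of dB benefit
  co <- small_cohort(seed = 1)
  model <- fit_pta_model(cohort_ccms(co), co$profiles$true_pta_db_hl,
                         n_repeats = 0)
  for (delta in c(5, 10, 15)) {
    prof <- simulate_listeners(n_per_category = c(0, 0, 0, 8),
                               aided_relief_db = delta, seed = 40 + delta)
    tm <- co$token_models
    un <- simulate_trials(prof, tm, n_sessions = 2, aided = "unaided",
                          seed = 50 + delta)
    ai <- simulate_trials(prof, tm, n_sessions = 2, aided = "personal_aid",
                          seed = 60 + delta)
    deltas <- vapply(prof$listener_id, function(id) {
      hearing_aid_benefit(
        build_confusion_matrix(un[un$listener_id == id, ],
                               consonants = co$panel$consonant),
        build_confusion_matrix(ai[ai$listener_id == id, ],
                               consonants = co$panel$consonant),
        model)$delta_db
    }, numeric(1))
    expect_lt(abs(mean(deltas) - delta), 4)
    if (delta >= 10) expect_gt(mean(deltas > 5), 0.7)
  }
})
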