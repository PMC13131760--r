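test_that("percent-correct equals the diagonal proportion of the matrix", {
  ses <- balanced_session()
  cm <- build_confusion_matrix(ses)
  expect_equal(score_percent_correct(cm), 100)

  # 45 of 50 correct: flip 5 responses of a 50-trial session
  ses50 <- do.call(rbind, lapply(1:50, function(i) {
    trial_row(consonant = "d", response = if (i <= 5) "t" else "d",
              snr_db = 4)
  }))
  expect_equal(score_percent_correct(build_confusion_matrix(ses50)), 90)

  # "other" responses never score, even on a row labelled other-ish
  ses_other <- rbind(trial_row(consonant = "b", response = "other"),
                     trial_row(consonant = "b", response = "b"))
  expect_equal(score_percent_correct(build_confusion_matrix(ses_other)), 50)
})

test_that("matrix-path score equals an independent recount of the trials", {
  co <- simulate_cohort(n_per_category = c(1, 1, 1, 1), reps_per_token = 5,
                        n_sessions = 1, seed = 31)
  for (id in co$profiles$listener_id) {
    tr <- co$trials[co$trials$listener_id == id, ]
    cm <- build_confusion_matrix(tr, consonants = co$panel$consonant)
    expect_equal(score_percent_correct(cm),
                 100 * sum(tr$response == tr$consonant) / nrow(tr))
  }
})

test_that("confusion matrix counts, filters and preconditions behave", {
  one <- trial_row(consonant = "b", response = "d")
  cm <- build_confusion_matrix(one)
  expect_s3_class(cm, "qvcv_ccm")
  expect_equal(cm$counts["b", "d"], 1L)
  expect_equal(cm$n_trials, 1L)

  # balanced session: 10 per consonant row (5 reps x 2 recordings)
  cm2 <- build_confusion_matrix(balanced_session())
  expect_true(all(rowSums(cm2$counts) == 10L))
  expect_equal(cm2$n_trials, 100L)

  # two aided conditions without a filter is an error; with a filter it works
  mix <- rbind(balanced_session(aided = "unaided"),
               balanced_session(aided = "personal_aid"))
  expect_error(build_confusion_matrix(mix), "aided")
  expect_equal(build_confusion_matrix(mix, aided = "unaided")$n_trials, 100L)

  expect_error(build_confusion_matrix(
    rbind(trial_row(listener_id = "L1"), trial_row(listener_id = "L2"))),
    "listeners")
  expect_error(build_confusion_matrix(one, aided = "lab_aid"), "empty")

  # off-panel responses collapse onto "other"
  off <- trial_row(consonant = "b", response = "p")
  cmo <- build_confusion_matrix(off, consonants = qvcv_default_panel()$consonant)
  expect_equal(cmo$counts["b", "other"], 1L)
  expect_error(build_confusion_matrix(off,
                                      consonants = qvcv_default_panel()$consonant,
                                      collapse_other = FALSE), "response")
})

test_that("scoring is invariant to trial order", {
  co <- simulate_cohort(n_per_category = c(1, 0, 1, 0), reps_per_token = 3,
                        n_sessions = 1, seed = 5)
  tr <- co$trials[co$trials$listener_id == "L01", ]
  cm1 <- build_confusion_matrix(tr, consonants = co$panel$consonant)
  set.seed(99)
  cm2 <- build_confusion_matrix(tr[sample(nrow(tr)), ],
                                consonants = co$panel$consonant)
  expect_identical(cm1$counts, cm2$counts)
})

test_that("hearing categories follow the PTA bands with half-up rounding", {
  expect_equal(assign_category(15), "NH")
  expect_equal(assign_category(16), "slight")
  expect_equal(assign_category(25), "slight")
  expect_equal(assign_category(26), "mild")
  expect_equal(assign_category(40), "mild")
  expect_equal(assign_category(41), "moderate")
  expect_equal(assign_category(55.4), "moderate")
  expect_equal(assign_category(15.5), "slight")
  expect_error(assign_category(55.6), "inclusion limit")
  expect_error(assign_category(-11), "-10")

  # bands partition [-10, 55]: every integer maps to exactly one category,
  # and the per-band counts match the band widths
  grid <- -10:55
  cats <- assign_category(grid)
  expect_false(anyNA(cats))
  expect_equal(as.vector(table(factor(cats, category_bands()$category))),
               c(26L, 10L, 15L, 15L))
})

test_that("trial validation catches malformed records", {
  bad <- trial_row()
  bad$correct <- FALSE  # contradicts response == consonant
  expect_error(validate_trials(bad), "inconsistent")
  bad2 <- trial_row(); bad2$snr_db <- NaN
  expect_error(validate_trials(bad2), "finite")
  bad3 <- trial_row(); bad3$consonant <- "x"
  expect_error(validate_trials(bad3), "consonant")
  expect_error(validate_trials(trial_row()[, -3]), "missing column")

  # IPA aliases normalize
  ipa <- trial_row(consonant = "ʃ", response = "ʃ", vowel = "ɑ")
  v <- validate_trials(ipa)
  expect_equal(v$consonant, "sh")
  expect_equal(v$vowel, "a")
})
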