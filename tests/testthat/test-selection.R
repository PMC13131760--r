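# exhaustive pair-counting oracle for the Mann-Whitney AUC
auc_pairs <- function(nh, hl) {
  wins <- ties <- 0
  for (a in nh) for (b in hl) {
    if (a > b) wins <- wins + 1 else if (a == b) ties <- ties + 1
  }
  (wins + ties / 2) / (length(nh) * length(hl))
}

test_that("AUC equals exhaustive pair counting and the trapezoidal ROC area", {
  expect_equal(auc_mann_whitney(c(0.9, 0.95), c(0.5, 0.6)), 1)
  expect_equal(auc_mann_whitney(c(0.7, 0.8), c(0.7, 0.8)), 0.5)
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.7), c(0.85, 0.6)), 4 / 6)

  set.seed(20)
  for (r in 1:20) {
    nh <- round(runif(sample(1:20, 1)), 2)  # rounding forces ties
    hl <- round(runif(sample(1:20, 1)), 2)
    a <- auc_mann_whitney(nh, hl)
    expect_equal(a, auc_pairs(nh, hl))
    roc <- pROC::roc(response = c(rep(1, length(nh)), rep(0, length(hl))),
                     predictor = c(nh, hl), quiet = TRUE,
                     direction = "<")
    expect_equal(a, as.numeric(pROC::auc(roc)))
  }
  expect_error(auc_mann_whitney(numeric(0), 1), "non-empty")
})

test_that("consonants with no group signal are screened out", {
  set.seed(8)
  null_cons <- c("f", "m", "p")
  listeners <- sprintf("L%02d", 1:30)
  group <- rep(c("NH", "HL"), each = 15)
  scores <- do.call(rbind, lapply(qvcv_consonants(), function(cc) {
    base <- if (cc %in% null_cons) rep(0.75, 30) else
      ifelse(group == "NH", 0.92, 0.55)
    data.frame(listener_id = listeners, group = group, consonant = cc,
               score = pmin(1, pmax(0, base + rnorm(30, 0, 0.05))))
  }))
  scr <- screen_consonants(scores, threshold_auc = 0.9)
  expect_setequal(scr$dropped, null_cons)
  expect_setequal(scr$retained, setdiff(qvcv_consonants(), null_cons))
  expect_length(screen_consonants(scores, threshold_auc = 0)$retained, 13L)
})

test_that("vowel choice maximizes median AUC with IQR then alphabetical ties", {
  va <- data.frame(vowel = rep(c("a", "i"), each = 5),
                   auc = c(0.96, 0.97, 0.97, 0.98, 0.97,
                           0.93, 0.95, 0.95, 0.97, 0.96))
  expect_equal(select_vowel(va)$vowel, "a")

  tie <- data.frame(vowel = rep(c("a", "i"), each = 3),
                    auc = c(0.90, 0.95, 1.00, 0.94, 0.95, 0.96))
  expect_equal(select_vowel(tie)$vowel, "i")  # same median, tighter IQR

  expect_equal(select_vowel(data.frame(vowel = "u", auc = 0.8))$vowel, "u")
})

test_that("per-token SNR choice is argmax AUC with lower-SNR ties", {
  tok <- data.frame(consonant = "t", snr_db = c(0, 3, -3),
                    auc = c(0.99, 0.95, 0.90))
  expect_equal(select_snr_per_token(tok)$snr_db, 0)
  tie <- data.frame(consonant = "s", snr_db = c(3, 0, 6), auc = 0.9)
  expect_equal(select_snr_per_token(tie)$snr_db, 0)
  one <- data.frame(consonant = "b", snr_db = 15, auc = 0.96)
  expect_equal(select_snr_per_token(one)$snr_db, 15)
})

test_that("the packaged panel is the final ten-consonant /a/ set", {
  p <- qvcv_default_panel()
  expect_equal(nrow(p), 10L)
  expect_true(all(p$vowel == "a"))
  expect_setequal(p$consonant, c("b", "d", "g", "k", "n", "s", "sh", "t", "v", "z"))
  expect_equal(p$snr_db[p$consonant == "b"], 15L)
  expect_equal(p$snr_db[p$consonant == "t"], 0L)
  expect_equal(p$auc[p$consonant == "z"], 0.98)
  expect_equal(p$auc[p$consonant == "n"], 1.00)
})

test_that("panel validation rejects duplicates and non-integer SNRs", {
  expect_error(as_qvcv_panel(data.frame(consonant = c("b", "b"), vowel = "a",
                                        snr_db = c(0, 3))), "duplicate")
  expect_error(as_qvcv_panel(data.frame(consonant = "b", vowel = "a",
                                        snr_db = 1.5)), "integer")
})

test_that("end-to-end selection recovers a 10-consonant /a/ panel", {
  # simulated screening cohort: 13 consonants in /a/ and /i/; /f m p/ carry
  # no hearing-loss signal (loss shift zeroed); /i/ is noisier (fewer trials)
  set.seed(77)
  mk_panel <- function(vowel) as_qvcv_panel(
    data.frame(consonant = qvcv_consonants(), vowel = vowel, snr_db = 3L))
  # NH versus clearly impaired listeners: screening needs the contrast a
  # real screening cohort provides, not a borderline one
  profiles <- simulate_listeners(n_per_category = c(15, 0, 8, 7), seed = NULL)
  scores <- NULL
  for (vw in c("a", "i")) {
    tm <- calibrate_token_models(mk_panel(vw), seed = NULL)
    tm$params$loss_shift[tm$params$consonant %in% c("f", "m", "p")] <- 0
    if (vw == "i") {
      # noisier vowel context: same signal, shallower slopes and fewer trials
      tm$params$slope_per_db <- tm$params$slope_per_db * 0.6
    }
    reps <- if (vw == "a") 10L else 5L
    tr <- simulate_trials(profiles, tm, reps_per_token = reps,
                          n_sessions = 1L, seed = NULL)
    agg <- aggregate(tr$correct,
                     by = list(listener_id = tr$listener_id,
                               consonant = tr$consonant, snr_db = tr$snr_db),
                     FUN = mean)
    names(agg)[ncol(agg)] <- "score"
    agg$vowel <- vw
    agg$group <- ifelse(profiles$category[match(agg$listener_id,
                                                profiles$listener_id)] == "NH",
                        "NH", "HL")
    scores <- rbind(scores, agg)
  }
  sel <- select_panel(scores, threshold_auc = 0.9)
  expect_equal(unique(sel$panel$vowel), "a")
  expect_setequal(sel$panel$consonant,
                  setdiff(qvcv_consonants(), c("f", "m", "p")))
  expect_equal(nrow(sel$panel), 10L)
  # deterministic given inputs
  sel2 <- select_panel(scores, threshold_auc = 0.9)
  expect_identical(sel$panel, sel2$panel)
})
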