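test_that("vectorized confusion matrices are row-normalized in fixed order", {
  ses <- balanced_session()
  cm <- build_confusion_matrix(ses)
  v <- vectorize_ccm(cm)
  expect_length(v, 10 * 11)
  diag_pos <- paste(rownames(cm$counts), rownames(cm$counts), sep = ">")
  expect_true(all(v[diag_pos] == 1))
  expect_true(all(v[setdiff(names(v), diag_pos)] == 0))

  # every presented row sums to one for an arbitrary matrix
  co <- small_cohort(seed = 2)
  cm2 <- cohort_ccms(co)[[5]]
  v2 <- vectorize_ccm(cm2)
  expect_equal(unname(rowSums(matrix(v2, nrow = 10, byrow = TRUE))),
               rep(1, 10))

  cm$counts["b", ] <- 0L
  expect_error(vectorize_ccm(cm), "zero trials")
})

test_that("PCA + ridge equals an independently built normal-equations oracle", {
  set.seed(3)
  n <- 8; p <- 4; lambda <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n, 20, 10)

  core <- qvcv:::.pta_fit_core(X, y, lambda, pca_variance = 1,
                               normalization = "center")
  pred <- qvcv:::.pta_predict_core(core, X, clip = c(-Inf, Inf))

  # oracle: eigen-decomposition of the covariance (not prcomp/svd), explicit
  # unit-variance scores, explicit penalized normal equations
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
  Z <- Xc %*% ev$vectors
  Z <- sweep(Z, 2, sqrt(ev$values), "/")
  beta <- solve(t(Z) %*% Z + 2 * lambda * diag(p), t(Z) %*% (y - mean(y)))
  oracle <- mean(y) + drop(Z %*% beta)
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-8)
})

test_that("ridge-logistic head matches a numeric-optimizer oracle", {
  set.seed(4)
  Z <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.integer(runif(40) < plogis(0.5 + Z %*% c(1, -0.5, 0.2)))
  lambda <- 2
  fit <- qvcv:::.ridge_logistic(Z, y, lambda)
  obj <- function(th) {
    eta <- th[1] + drop(Z %*% th[-1])
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(th[-1]^2)
  }
  orc <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(c(fit$intercept, fit$beta), orc$par, tolerance = 1e-4)
  expect_lte(obj(c(fit$intercept, fit$beta)), orc$value + 1e-8)
})

test_that("noise-free linear features are recovered as lambda shrinks", {
  set.seed(6)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5)
  b <- c(8, -5, 3, 2, -1)
  y <- 22 + drop(X %*% b)  # spans several hearing categories
  m <- fit_pta_model(X, y, lambda = 1e-8, n_repeats = 40, pca_variance = 1,
                     seed = 9)
  expect_lt(m$cv$mae, 0.5)
  expect_lt(m$training_mae, 1e-6)

  # huge lambda collapses predictions to the training mean
  m2 <- fit_pta_model(X, y, lambda = 1e9, n_repeats = 0, pca_variance = 1)
  expect_equal(unname(fitted(m2)), rep(mean(y), n), tolerance = 1e-4)
})

test_that("prediction clips, checks feature length, and honors the intercept", {
  co <- small_cohort(seed = 1)
  m <- fit_pta_model(cohort_ccms(co), co$profiles$true_pta_db_hl,
                     n_repeats = 0)
  expect_error(predict(m, matrix(0, 1, 5)), "does not match")
  # features at the training mean predict the training-mean PTA
  xbar <- matrix(m$core$center, nrow = 1)
  expect_equal(unname(predict(m, xbar)), mean(co$profiles$true_pta_db_hl),
               tolerance = 1e-8)
  expect_true(all(predict(m, cohort_ccms(co)) >= -10))
})

test_that("a near-ceiling listener maps into the normal-hearing band", {
  co <- small_cohort(seed = 1)
  ccms <- cohort_ccms(co)
  m <- fit_pta_model(ccms, co$profiles$true_pta_db_hl, seed = 21)
  scores <- vapply(ccms, score_percent_correct, numeric(1))
  hi <- which(scores > 90 & co$profiles$category == "NH")[1]
  expect_lte(m$cv$ppta[hi], 20)
})

test_that("cross-validated error is no better than training error on average", {
  gaps <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(24 * 8), 24, 8)
    y <- 20 + drop(X %*% rnorm(8, 0, 4)) + rnorm(24, 0, 5)
    y <- pmin(pmax(y, -10), 55)
    m <- fit_pta_model(X, y, n_repeats = 40, seed = 100 + s)
    m$cv$mae - m$training_mae
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("the fit is reproducible under a seed and serializes bit-identically", {
  co <- small_cohort(seed = 1)
  ccms <- cohort_ccms(co)
  m1 <- fit_pta_model(ccms, co$profiles$true_pta_db_hl, n_repeats = 10,
                      seed = 33)
  m2 <- fit_pta_model(ccms, co$profiles$true_pta_db_hl, n_repeats = 10,
                      seed = 33)
  expect_equal(m1$cv$ppta, m2$cv$ppta, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_pta_model(m1, path)
  m3 <- read_pta_model(path)
  expect_equal(predict(m1, ccms), predict(m3, ccms), tolerance = 1e-12)
})

test_that("excess-loss detection behaves at the null and at perfect signal", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  lab_null <- rep(c(TRUE, FALSE), 20)
  a0 <- excess_loss_auc(X, lab_null, n_repeats = 60, seed = 5)
  expect_lt(abs(a0$auc - 0.5), 0.2)

  lab_perfect <- X[, 1] > 0
  a1 <- excess_loss_auc(X, lab_perfect, n_repeats = 60, seed = 5)
  expect_gte(a1$auc, 0.9)

  expect_error(excess_loss_auc(X, rep(c(TRUE, FALSE), c(2, 38))), "at least 3")
})

test_that("model methods print, summarize and expose coefficients coherently", {
  co <- small_cohort(seed = 1)
  m <- fit_pta_model(cohort_ccms(co), co$profiles$true_pta_db_hl,
                     hl = co$profiles$category != "NH", n_repeats = 10,
                     seed = 2)
  expect_output(print(m), "cross-validated MAE")
  s <- summary(m)
  expect_equal(sum(s$by_category$n), 60L)
  # component- and feature-space coefficients give the same predictions
  cf <- coef(m, space = "features")
  X <- do.call(rbind, lapply(cohort_ccms(co), vectorize_ccm))
  manual <- cf[1] + drop(X %*% cf[-1])
  expect_equal(unname(pmin(pmax(manual, -10), 80)),
               unname(predict(m, X)), tolerance = 1e-8)
  # classifier head separates NH from HL on the training data
  pr <- predict_hl_prob(m)
  expect_gt(auc_mann_whitney(pr[co$profiles$category != "NH"],
                             pr[co$profiles$category == "NH"]), 0.9)
})
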