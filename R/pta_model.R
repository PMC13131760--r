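#' Vectorize a consonant confusion matrix into a feature vector
#'
#' Rows of the confusion matrix are normalized to response proportions and
#' flattened in a fixed (presented, response) order. For the default
#' ten-consonant panel with the "other" response column this yields
#' 10 x 11 = 110 features.
#'
#' @param cm a `qvcv_ccm`.
#' @return named numeric vector; names are `"presented>response"`.
#' @export
vectorize_ccm <- function(cm) {
  stopifnot(inherits(cm, "qvcv_ccm"))
  rs <- rowSums(cm$counts)
  if (any(rs == 0)) {
    stop_qvcv("presented consonant(s) with zero trials: ",
              paste(rownames(cm$counts)[rs == 0], collapse = ", "))
  }
  p <- cm$counts / rs
  v <- as.vector(t(p))
  names(v) <- as.vector(t(outer(rownames(p), colnames(p), paste, sep = ">")))
  v
}

# features from a list of CCMs (or pass a matrix / single vector through)
.as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, nrow = 1L, dimnames = list(NULL, names(x))))
  if (inherits(x, "qvcv_ccm")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "qvcv_ccm"))) {
    m <- do.call(rbind, lapply(x, vectorize_ccm))
    ids <- vapply(x, function(cm) as.character(cm$listener_id), character(1))
    rownames(m) <- ids
    return(m)
  }
  stop_qvcv("features must be a numeric matrix, a qvcv_ccm, or a list of qvcv_ccm")
}

# closed-form ridge with unpenalized intercept under the
# 1/2 ||y - a - Z b||^2 + lambda ||b||^2 convention
.ridge_solve <- function(Z, y, lambda) {
  a <- mean(y)
  k <- ncol(Z)
  b <- solve(crossprod(Z) + diag(2 * lambda, k), crossprod(Z, y - a))
  list(intercept = a, beta = drop(b))
}

# ridge-penalized logistic regression (IRLS / penalized Newton), intercept
# unpenalized; objective: -loglik + lambda ||b||^2
.ridge_logistic <- function(Z, y01, lambda, max_iter = 100L, tol = 1e-9) {
  k <- ncol(Z)
  X <- cbind(1, Z)
  th <- rep(0, k + 1L)
  pen <- diag(c(0, rep(2 * lambda, k)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% th)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X, y01 - mu) - pen %*% th
    H <- crossprod(X * w, X) + pen
    step <- solve(H, g)
    th <- th + step
    if (max(abs(step)) < tol) break
  }
  list(intercept = th[[1L]], beta = th[-1L], iterations = it)
}

# normalize -> PCA (training data only) -> ridge on unit-variance scores;
# "center" keeps the confusion proportions on their common probability scale
# (standardizing would inflate near-constant, rarely-confused cells to unit
# variance and hand most of the retained PCA variance to binomial noise)
.pta_fit_core <- function(X, y, lambda, pca_variance,
                          normalization = "center") {
  ctr <- colMeans(X)
  if (normalization == "standardize") {
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    scl <- rep(1, ncol(X))
  }
  Xs <- scale(X, center = ctr, scale = scl)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  pos <- pc$sdev > 1e-10
  cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
  k <- which(cum >= pca_variance)[1L]
  if (is.na(k)) k <- sum(pos)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sdev <- pc$sdev[seq_len(k)]
  Z <- (Xs %*% rot) / rep(sdev, each = nrow(Xs))
  rg <- .ridge_solve(Z, y, lambda)
  list(center = ctr, scale = scl, rotation = rot, sdev = sdev, k = k,
       intercept = rg$intercept, beta = rg$beta, scores = Z)
}

.pta_scores <- function(core, X) {
  Xs <- scale(X, center = core$center, scale = core$scale)
  (Xs %*% core$rotation) / rep(core$sdev, each = nrow(Xs))
}

.pta_predict_core <- function(core, X, clip = c(-10, 80)) {
  Z <- .pta_scores(core, X)
  p <- core$intercept + drop(Z %*% core$beta)
  pmin(pmax(p, clip[1L]), clip[2L])
}

#' Fit the confusion-matrix to pure-tone-average prediction model
#'
#' The headline pipeline: vectorized confusion matrices are centered (or
#' standardized), reduced by principal component analysis, and the measured
#' pure-tone
#' average (PTA) is regressed on the unit-variance component scores with a
#' ridge penalty (`1/2 ||y - Xb||^2 + lambda ||b||^2`, intercept
#' unpenalized; default `lambda = 3`). Generalization is assessed by
#' repeated random 70/30 train/validation splits: the PCA and the scaling
#' are refitted on every training split, and each listener's cross-validated
#' predicted PTA (PPTA) is the average of the predictions from splits where
#' that listener was held out. A ridge-logistic head for binary NH-vs-HL
#' classification is fitted on the same component scores.
#'
#' @param features numeric matrix (listeners x features) or list of
#'   `qvcv_ccm` (vectorized internally).
#' @param pta measured PTA per listener (dB HL).
#' @param hl optional logical (or two-level) vector labelling hearing loss
#'   for the classifier head.
#' @param lambda ridge regularization factor (default 3).
#' @param split_fraction fraction of listeners in each training split.
#' @param n_repeats number of random splits (0 = no cross-validation).
#' @param pca_variance retain the smallest number of components explaining at
#'   least this fraction of training variance.
#' @param normalization `"center"` (default; proportions keep their common
#'   probability scale) or `"standardize"` (unit variance per feature).
#' @param seed RNG seed for the repeated splits.
#' @return object of class `qvcv_pta`; see [predict.qvcv_pta()],
#'   [residuals.qvcv_pta()], [coef.qvcv_pta()], [plot.qvcv_pta()].
#' @export
fit_pta_model <- function(features, pta, hl = NULL, lambda = 3,
                          split_fraction = 0.7, n_repeats = 100L,
                          pca_variance = 0.95,
                          normalization = c("center", "standardize"),
                          seed = NULL) {
  normalization <- match.arg(normalization)
  X <- .as_feature_matrix(features)
  y <- as.numeric(pta)
  if (nrow(X) != length(y)) stop_qvcv("features and pta disagree in length")
  if (nrow(X) < 20L) {
    stop_qvcv("need at least 20 listeners to fit the PTA model")
  }
  if (length(unique(assign_category(y))) < 2L) {
    stop_qvcv("cohort must span at least two hearing categories")
  }
  stopifnot(lambda >= 0, split_fraction > 0, split_fraction < 1)
  n <- nrow(X)

  final <- .pta_fit_core(X, y, lambda, pca_variance, normalization)
  fitted_in <- .pta_predict_core(final, X)

  cv <- NULL
  if (n_repeats > 0L) {
    cv <- with_seed_or_stream(seed, {
      n_tr <- max(2L, floor(split_fraction * n))
      pred_sum <- numeric(n)
      pred_cnt <- integer(n)
      for (r in seq_len(n_repeats)) {
        tr <- sample.int(n, n_tr)
        te <- setdiff(seq_len(n), tr)
        core <- .pta_fit_core(X[tr, , drop = FALSE], y[tr], lambda,
                              pca_variance, normalization)
        p <- .pta_predict_core(core, X[te, , drop = FALSE])
        pred_sum[te] <- pred_sum[te] + p
        pred_cnt[te] <- pred_cnt[te] + 1L
      }
      pred <- ifelse(pred_cnt > 0L, pred_sum / pmax(pred_cnt, 1L), fitted_in)
      list(ppta = pred, heldout_counts = pred_cnt,
           mae = mean(abs(pred - y)), n_repeats = n_repeats,
           split_fraction = split_fraction, seed = seed)
    })
  }

  classifier <- NULL
  if (!is.null(hl)) {
    hl01 <- if (is.logical(hl)) as.integer(hl) else as.integer(factor(hl)) - 1L
    if (length(unique(hl01)) < 2L) {
      stop_qvcv("classifier head needs both NH and HL listeners")
    }
    classifier <- .ridge_logistic(final$scores, hl01, lambda)
  }

  structure(
    list(core = final, lambda = lambda, pca_variance = pca_variance,
         normalization = normalization,
         feature_names = colnames(X), n = n, pta = y,
         fitted_training = fitted_in, training_mae = mean(abs(fitted_in - y)),
         cv = cv, classifier = classifier, call = match.call()),
    class = "qvcv_pta"
  )
}

#' Predict PTA for new confusion matrices
#'
#' @param object a fitted `qvcv_pta`.
#' @param newdata feature matrix, single `qvcv_ccm`, or list of `qvcv_ccm`;
#'   omitted = training fitted values.
#' @param ... unused.
#' @return predicted PTA (PPTA) in dB HL, clipped to \[-10, 80\].
#' @export
predict.qvcv_pta <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_training)
  X <- .as_feature_matrix(newdata)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(object$core$center)) {
    stop_qvcv("feature length (", ncol(X), ") does not match the model (",
              length(object$core$center), ")")
  }
  .pta_predict_core(object$core, X)
}

#' @export
fitted.qvcv_pta <- function(object, ...) object$fitted_training

#' Model residuals
#'
#' @param object a `qvcv_pta`.
#' @param type `"cv"` (cross-validated PPTA minus measured PTA; default) or
#'   `"training"`.
#' @param ... unused.
#' @export
residuals.qvcv_pta <- function(object, type = c("cv", "training"), ...) {
  type <- match.arg(type)
  if (type == "cv") {
    if (is.null(object$cv)) stop_qvcv("model was fitted without cross-validation")
    object$cv$ppta - object$pta
  } else {
    object$fitted_training - object$pta
  }
}

#' Model coefficients
#'
#' @param object a `qvcv_pta`.
#' @param space `"components"` (ridge weights on the unit-variance principal
#'   component scores) or `"features"` (equivalent weights on the original
#'   standardized confusion proportions).
#' @param ... unused.
#' @export
coef.qvcv_pta <- function(object, space = c("components", "features"), ...) {
  space <- match.arg(space)
  core <- object$core
  if (space == "components") {
    c(`(Intercept)` = core$intercept,
      stats::setNames(core$beta, colnames(core$rotation)))
  } else {
    w <- drop(core$rotation %*% (core$beta / core$sdev)) / core$scale
    c(`(Intercept)` = core$intercept - sum(w * core$center),
      stats::setNames(w, object$feature_names))
  }
}

#' @export
print.qvcv_pta <- function(x, ...) {
  cat("Confusion-matrix PTA prediction model (PCA + ridge)\n")
  cat(sprintf("  listeners: %d, features: %d, components retained: %d (%.0f%% var)\n",
              x$n, length(x$feature_names), x$core$k, 100 * x$pca_variance))
  cat(sprintf("  lambda: %g; training MAE: %.2f dB\n", x$lambda, x$training_mae))
  if (!is.null(x$cv)) {
    cat(sprintf("  cross-validated MAE: %.2f dB (%d x %.0f/%.0f splits)\n",
                x$cv$mae, x$cv$n_repeats, 100 * x$cv$split_fraction,
                100 * (1 - x$cv$split_fraction)))
  }
  if (!is.null(x$classifier)) cat("  NH/HL logistic head: fitted\n")
  invisible(x)
}

#' @export
summary.qvcv_pta <- function(object, ...) {
  out <- list(model = object,
              cv_mae = if (!is.null(object$cv)) object$cv$mae else NA_real_,
              training_mae = object$training_mae,
              by_category = NULL)
  cat_ <- assign_category(object$pta)
  if (!is.null(object$cv)) {
    err <- abs(object$cv$ppta - object$pta)
    out$by_category <- data.frame(
      category = category_bands()$category,
      n = as.integer(table(factor(cat_, levels = category_bands()$category))),
      mae_db = as.numeric(tapply(err, factor(cat_, levels = category_bands()$category), mean))
    )
  }
  class(out) <- "summary.qvcv_pta"
  out
}

#' @export
print.summary.qvcv_pta <- function(x, ...) {
  print(x$model)
  if (!is.null(x$by_category)) {
    cat("\nCross-validated absolute error by hearing category:\n")
    print(x$by_category, row.names = FALSE)
  }
  invisible(x)
}

#' Plot predicted versus measured PTA
#'
#' @param x a `qvcv_pta` fitted with cross-validation.
#' @param audibility optional `qvcv_audibility` baseline drawn as a dashed
#'   line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qvcv_pta <- function(x, audibility = NULL, ...) {
  if (is.null(x$cv)) stop_qvcv("model was fitted without cross-validation")
  graphics::plot(x$pta, x$cv$ppta, xlab = "Measured PTA (dB HL)",
                 ylab = "Predicted PTA (dB HL)", ...)
  graphics::abline(0, 1, col = "grey60")
  if (!is.null(audibility)) {
    g <- seq(min(x$pta), max(x$pta), length.out = 200)
    graphics::lines(g, predict(audibility, g), lty = 2)
  }
  invisible(x)
}

#' Probability of hearing loss from the logistic head
#'
#' @param object a `qvcv_pta` fitted with `hl` labels.
#' @param newdata features as in [predict.qvcv_pta()]; omitted = training
#'   data.
#' @return probabilities of the "hearing loss" class.
#' @export
predict_hl_prob <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "qvcv_pta"))
  if (is.null(object$classifier)) stop_qvcv("model has no classifier head")
  Z <- if (is.null(newdata)) object$core$scores else
    .pta_scores(object$core, .as_feature_matrix(newdata))
  stats::plogis(object$classifier$intercept + drop(Z %*% object$classifier$beta))
}

#' Cross-validated detection of excess loss from confusion features alone
#'
#' Fits, on repeated random training splits, a PCA + ridge-logistic
#' classifier that predicts an excess-loss label from the vectorized
#' confusion matrix -- without access to the measured PTA -- and reports the
#' ROC AUC of the averaged held-out scores.
#'
#' @param features feature matrix or list of `qvcv_ccm`.
#' @param labels logical vector, `TRUE` for excess-loss listeners.
#' @inheritParams fit_pta_model
#' @return list with `auc`, per-listener held-out `scores`, `labels`, and the
#'   split settings.
#' @export
excess_loss_auc <- function(features, labels, lambda = 3, split_fraction = 0.7,
                            n_repeats = 100L, pca_variance = 0.95,
                            normalization = c("center", "standardize"),
                            seed = NULL) {
  normalization <- match.arg(normalization)
  X <- .as_feature_matrix(features)
  lab <- as.logical(labels)
  if (nrow(X) != length(lab)) stop_qvcv("features and labels disagree in length")
  if (sum(lab) < 3L || sum(!lab) < 3L) {
    stop_qvcv("need at least 3 listeners in each class")
  }
  n <- nrow(X)
  with_seed_or_stream(seed, {
    n_tr <- max(2L, floor(split_fraction * n))
    s_sum <- numeric(n)
    s_cnt <- integer(n)
    for (r in seq_len(n_repeats)) {
      tr <- sample.int(n, n_tr)
      if (length(unique(lab[tr])) < 2L) next
      te <- setdiff(seq_len(n), tr)
      core <- .pta_fit_core(X[tr, , drop = FALSE], as.numeric(lab[tr]),
                            lambda, pca_variance, normalization)
      cls <- .ridge_logistic(core$scores, as.integer(lab[tr]), lambda)
      Zte <- .pta_scores(core, X[te, , drop = FALSE])
      sc <- stats::plogis(cls$intercept + drop(Zte %*% cls$beta))
      s_sum[te] <- s_sum[te] + sc
      s_cnt[te] <- s_cnt[te] + 1L
    }
    if (any(s_cnt == 0L)) {
      warning("some listeners were never held out; increase n_repeats")
    }
    scores <- s_sum / pmax(s_cnt, 1L)
    list(auc = auc_mann_whitney(scores[lab], scores[!lab]), scores = scores,
         labels = lab, n_repeats = n_repeats, split_fraction = split_fraction,
         lambda = lambda, seed = seed)
  })
}
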