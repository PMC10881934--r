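# AdaBoost.R2 regression ensemble over gradient-boosted tree base learners.
#
# The adaptive-boosting wrapper (linear loss, weighted-median prediction)
# follows the classical AdaBoost.R2 scheme; each base learner is a gradient
# boosting regressor (xgboost: squared-error trees). One departure from the
# resampling formulation: the per-round sample weights are passed to the
# base learner directly instead of drawing a weighted bootstrap, which makes
# training deterministic without changing the weighting logic.

xgb_gbr <- function(X, y, w, config, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y, weight = w * length(y))
  # Noise-free training curves make every FIA coordinate exactly collinear,
  # so split gains tie across features; deterministic tie-breaking would
  # collapse every tree onto one coordinate and forfeit the ensemble's
  # noise-averaging. Drawing ~2 candidate features per split restores the
  # randomized feature choice of classical CART implementations.
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = config$learning_rate,
                  max_depth = config$max_depth,
                  colsample_bynode = min(1, 2 / ncol(X)),
                  tree_method = "hist", nthread = 1,
                  seed = seed %||% 0),
    data = dm, nrounds = config$nrounds, verbose = 0)
}

ada_fit <- function(X, y, config, seed = NULL) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  learners <- list()
  log_inv_beta <- numeric(0)
  for (m in seq_len(config$n_learners)) {
    bst <- xgb_gbr(X, y, w, config, derive_seed(seed, m))
    pred <- stats::predict(bst, X)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax <= 0) {  # exact interpolation: keep the learner, stop boosting
      learners[[m]] <- bst
      log_inv_beta[m] <- config$ada_learning_rate * log(1e12)
      break
    }
    loss <- err / emax
    avg_loss <- sum(w * loss)
    if (avg_loss >= 0.5) {
      if (m == 1) {  # degenerate data; keep a single unweighted learner
        learners[[1]] <- bst
        log_inv_beta[1] <- 1
      }
      break
    }
    beta <- max(avg_loss / (1 - avg_loss), 1e-12)
    learners[[m]] <- bst
    log_inv_beta[m] <- config$ada_learning_rate * log(1 / beta)
    w <- w * beta^(config$ada_learning_rate * (1 - loss))
    w <- w / sum(w)
  }
  structure(list(learners = learners, log_inv_beta = log_inv_beta,
                 config = config), class = "ada_r2")
}

# Weighted median of the member predictions, per row of X.
ada_predict <- function(model, X) {
  stopifnot(inherits(model, "ada_r2"))
  preds <- vapply(model$learners, function(b) stats::predict(b, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(X))
  wts <- model$log_inv_beta
  apply(preds, 1, function(p) {
    ord <- order(p)
    cw <- cumsum(wts[ord])
    p[ord][which(cw >= 0.5 * sum(wts))[1]]
  })
}
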