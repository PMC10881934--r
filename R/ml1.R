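# ML1: binary fit-model classifier.
#
# A soft-voting ensemble of two L2-penalized logistic-regression models
# trained on the raw curve coordinates. The two voters share the convex
# ridge-logistic loss but are solved by two different optimizers (coordinate
# descent via glmnet; in-package iteratively reweighted least squares), so
# each voter converges independently and their class probabilities are
# averaged.

#' Feature vector of a curve for the ML systems
#'
#' Deterministic layout `[t_1 .. t_N, fia_1 .. fia_N]` (2N features), with a
#' trailing model-class indicator (0 = MEf, 1 = BEf) appended when
#' `model_class` is given (2N + 1 features, the regressor input).
#'
#' @param tac A [tac_points()] curve.
#' @param model_class Optional `"MEf"`/`"BEf"` class label.
#' @return Numeric feature vector.
#' @export
#' @examples
#' tac <- tac_points(make_time_grid(4), c(0.9, 0.5, 0.3, 0.05))
#' length(build_features(tac))          # 8
#' length(build_features(tac, "BEf"))   # 9
build_features <- function(tac, model_class = NULL) {
  stopifnot(inherits(tac, "tac_points"))
  x <- c(tac$times, tac$fia)
  if (!is.null(model_class)) {
    x <- c(x, as.numeric(match_kind(model_class) == BEF))
  }
  x
}

# Feature matrix of a whole dataset; one row per curve.
dataset_features <- function(dataset, classes = NULL) {
  n <- dataset$spec$n_points
  X <- t(vapply(dataset$curves, function(cv) c(cv$times, cv$fia),
                numeric(2 * n)))
  if (!is.null(classes)) X <- cbind(X, as.numeric(classes == BEF))
  X
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares: minimizes sum(log-loss) + n * lambda / 2 * ||beta||^2 (intercept
# unpenalized). Returns the coefficient vector (intercept first) and a
# convergence flag.
ridge_logistic_irls <- function(X, y, lambda, maxit = 500, tol = 1e-9) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(nrow(X1) * lambda, p - 1)), p)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(X1 * w)
    beta_new <- solve(xtw %*% X1 + pen, xtw %*% z)
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged, iterations = it)
}

#' Train the soft-voting logistic classifier (ML1)
#'
#' Trains the two ridge-logistic voters on the 2N coordinate features of a
#' (normally noise-free) training dataset with both model classes present.
#' The ridge penalty `lambda` (default `1/n_curves`, the conventional
#' weak-regularization scale) keeps both optimizers convergent even when the
#' noise-free classes are perfectly separable.
#'
#' @param dataset A [generate_dataset()] result containing both classes.
#' @param seed Optional seed stored with the model (training itself is
#'   deterministic).
#' @param lambda Ridge penalty per the glmnet scale.
#' @return An object of class `tac_ml1`.
#' @export
train_classifier <- function(dataset, seed = NULL, lambda = NULL) {
  stopifnot(inherits(dataset, "tac_dataset"))
  X <- dataset_features(dataset)
  y <- as.numeric(dataset_kinds(dataset) == BEF)
  ml1_train_xy(X, y, n_points = dataset$spec$n_points, seed = seed,
               lambda = lambda)
}

ml1_train_xy <- function(X, y, n_points, seed = NULL, lambda = NULL) {
  if (length(unique(y)) < 2) {
    stop("classifier training needs both MEf and BEf curves", call. = FALSE)
  }
  lambda <- lambda %||% (1 / nrow(X))
  voter1 <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = lambda, standardize = FALSE,
                           thresh = 1e-10, maxit = 1e6)
  voter2 <- ridge_logistic_irls(X, y, lambda)
  structure(list(n_points = as.integer(n_points), voter1 = voter1,
                 voter2 = voter2, lambda = lambda, seed = seed),
            class = "tac_ml1")
}

#' @export
print.tac_ml1 <- function(x, ...) {
  cat(sprintf(
    "ML1 soft-voting logistic classifier (N = %d, lambda = %.3g, IRLS %s)\n",
    x$n_points, x$lambda,
    if (x$voter2$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Averaged class-probability matrix [p_me, p_be], one row per row of X.
ml1_probs <- function(ml1, X) {
  p1 <- drop(stats::predict(ml1$voter1, X, type = "response"))
  p2 <- stats::plogis(drop(cbind(1, X) %*% ml1$voter2$beta))
  p_be <- (p1 + p2) / 2
  cbind(p_me = 1 - p_be, p_be = p_be)
}

#' Classify one curve with ML1
#'
#' Soft voting: the two voters' class probabilities are averaged and the
#' curve is assigned to BEf when the averaged bi-exponential probability
#' exceeds 0.5 (an exact tie goes to the simpler MEf).
#'
#' @param ml1 A [train_classifier()] model.
#' @param tac A [tac_points()] curve with the model's number of points.
#' @return A `model_selection` with `class_probs = c(p_me, p_be)`.
#' @export
classify <- function(ml1, tac) {
  stopifnot(inherits(ml1, "tac_ml1"), inherits(tac, "tac_points"))
  if (tac$n != ml1$n_points) {
    stop("curve has ", tac$n, " points but the classifier was trained for ",
         ml1$n_points, call. = FALSE)
  }
  pr <- ml1_probs(ml1, matrix(build_features(tac), nrow = 1))
  chosen <- if (pr[1, "p_be"] > 0.5) BEF else MEF
  new_model_selection(chosen, "ML",
                      class_probs = c(p_me = unname(pr[1, "p_me"]),
                                      p_be = unname(pr[1, "p_be"])))
}

#' Classify every curve of a dataset with ML1
#'
#' @param ml1 A [train_classifier()] model.
#' @param dataset A [generate_dataset()] result with matching N.
#' @return Data frame `curve_id, chosen, p_me, p_be`.
#' @export
classify_dataset <- function(ml1, dataset) {
  stopifnot(inherits(ml1, "tac_ml1"), inherits(dataset, "tac_dataset"))
  if (dataset$spec$n_points != ml1$n_points) {
    stop("dataset N does not match the classifier's N", call. = FALSE)
  }
  pr <- ml1_probs(ml1, dataset_features(dataset))
  data.frame(curve_id = seq_along(dataset$curves) - 1L,
             chosen = ifelse(pr[, "p_be"] > 0.5, BEF, MEF),
             p_me = pr[, "p_me"], p_be = pr[, "p_be"])
}

#' Repeated-split cross-validation of ML1
#'
#' Performs `n_splits` independent stratified random splits of the dataset
#' (default 80% training / 20% testing), trains ML1 on each training portion
#' and scores classification accuracy on the held-out portion.
#'
#' @param dataset A [generate_dataset()] result.
#' @param seed Seed for the split randomization.
#' @param n_splits Number of repeated splits.
#' @param train_frac Training fraction of each split.
#' @return List with `accuracies` (percent, one per split) and `mean`.
#' @export
cross_validate_classifier <- function(dataset, seed = NULL, n_splits = 10,
                                      train_frac = 0.8) {
  stopifnot(inherits(dataset, "tac_dataset"), n_splits >= 1,
            train_frac > 0, train_frac < 1)
  X <- dataset_features(dataset)
  y <- as.numeric(dataset_kinds(dataset) == BEF)
  if (length(y) < 10) stop("dataset too small to cross-validate", call. = FALSE)
  acc <- with_seed(seed, vapply(seq_len(n_splits), function(s) {
    tr_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(train_frac * length(idx)))
    }), use.names = FALSE)
    ml1 <- ml1_train_xy(X[tr_idx, , drop = FALSE], y[tr_idx],
                        n_points = dataset$spec$n_points)
    pr <- ml1_probs(ml1, X[-tr_idx, , drop = FALSE])
    pred <- as.numeric(pr[, "p_be"] > 0.5)
    100 * mean(pred == y[-tr_idx])
  }, numeric(1)))
  list(accuracies = acc, mean = mean(acc))
}
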