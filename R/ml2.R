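# ML2: per-N biokinetic-parameter regressor.
#
# One boosted-ensemble regressor per output parameter per model class (MEf:
# A, lambda; BEf: A1, lambda1, A2, lambda2), every one consuming the same
# 2N + 1 feature vector (curve coordinates + class indicator). Boosted tree
# regressors emit a single output, so the class banks keep tau well-defined
# for MEf without dummy targets.

#' Hyperparameter configuration of the ML2 ensembles
#'
#' Defaults follow the reference architecture: each output parameter is
#' predicted by an AdaBoost ensemble (linear loss, learning rate 0.1) of 5
#' gradient-boosted regressors, each a chain of 1000 depth-5 squared-error
#' trees with learning rate 0.1.
#'
#' @param n_learners Gradient-boosted regressors per AdaBoost ensemble.
#' @param nrounds Trees per gradient-boosted regressor.
#' @param learning_rate Shrinkage of the tree chain.
#' @param max_depth Depth of each tree.
#' @param ada_learning_rate AdaBoost learning rate.
#' @return A list of class `ml2_config`.
#' @export
ml2_config <- function(n_learners = 5, nrounds = 1000, learning_rate = 0.1,
                       max_depth = 5, ada_learning_rate = 0.1) {
  stopifnot(n_learners >= 1, nrounds >= 1, learning_rate > 0, max_depth >= 1,
            ada_learning_rate > 0)
  structure(list(n_learners = as.integer(n_learners),
                 nrounds = as.integer(nrounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 ada_learning_rate = ada_learning_rate),
            class = "ml2_config")
}

ml2_target_names <- function(kind) {
  if (kind == MEF) c("A1", "lambda1") else c("A1", "lambda1", "A2", "lambda2")
}

ml2_truth_target <- function(params, name) {
  switch(name,
         A1 = params$amplitudes[1], lambda1 = params$rates[1],
         A2 = params$amplitudes[2], lambda2 = params$rates[2])
}

#' Train the parameter regressor (ML2)
#'
#' Fits, for each model class, one [ml2_config()] boosted ensemble per
#' biokinetic parameter, using the 2N + 1 feature vectors of the training
#' curves and their known generating parameters as targets. Training data
#' are normally noise-free; every curve must carry its truth parameters.
#'
#' @param dataset A [generate_dataset()] result with truth parameters.
#' @param seed Seed for the tree learners.
#' @param config An [ml2_config()].
#' @return An object of class `tac_ml2` holding the per-class regressor
#'   banks.
#' @export
train_regressor <- function(dataset, seed = NULL, config = ml2_config()) {
  stopifnot(inherits(dataset, "tac_dataset"), inherits(config, "ml2_config"))
  if (any(vapply(dataset$curves, function(cv) is.null(cv$truth), logical(1)))) {
    stop("every training curve must carry truth parameters", call. = FALSE)
  }
  kinds <- dataset_kinds(dataset)
  X <- dataset_features(dataset, classes = kinds)
  banks <- list()
  bank_idx <- 0L
  for (kind in MODEL_KINDS) {
    rows <- which(kinds == kind)
    if (length(rows) == 0) next
    bank <- list()
    for (name in ml2_target_names(kind)) {
      bank_idx <- bank_idx + 1L
      y <- vapply(dataset$curves[rows],
                  function(cv) ml2_truth_target(cv$truth, name), numeric(1))
      bank[[name]] <- ada_fit(X[rows, , drop = FALSE], y, config,
                              seed = derive_seed(seed, bank_idx))
    }
    banks[[kind]] <- bank
  }
  structure(list(n_points = dataset$spec$n_points, banks = banks,
                 config = config, seed = seed,
                 train_spec = dataset$spec), class = "tac_ml2")
}

#' @export
print.tac_ml2 <- function(x, ...) {
  cat(sprintf(
    "ML2 parameter regressor (N = %d; banks: %s; %d x %d-tree ensembles)\n",
    x$n_points, paste(names(x$banks), collapse = ", "),
    x$config$n_learners, x$config$nrounds))
  invisible(x)
}

# Predict all parameters of one class bank for a block of feature rows.
ml2_predict_block <- function(ml2, X, kind) {
  bank <- ml2$banks[[kind]]
  if (is.null(bank)) {
    stop("no trained ", kind, " bank in this ML2 model", call. = FALSE)
  }
  vapply(ml2_target_names(kind), function(name) ada_predict(bank[[name]], X),
         numeric(nrow(X)))
}

ml2_params_from_row <- function(kind, vals) {
  vals <- pmax(vals, 1e-9)  # trees cannot leave the target range, but guard
  if (kind == MEF) return(exp_params(MEF, vals[["A1"]], vals[["lambda1"]]))
  a <- c(vals[["A1"]], vals[["A2"]])
  l <- c(vals[["lambda1"]], vals[["lambda2"]])
  if (l[1] < l[2]) {
    a <- rev(a)
    l <- rev(l)
  } else if (l[1] == l[2]) {
    l[1] <- l[1] * (1 + 1e-12)
  }
  exp_params(BEF, a, l)
}

#' Predict biokinetic parameters for one curve (ML2)
#'
#' Routes the curve's 2N + 1 feature vector to the regressor bank of the
#' given model class and assembles the predicted parameters (fast-first for
#' BEf). The class normally comes from [classify()] (full chain) or from the
#' ground truth (error-free classification test).
#'
#' @param ml2 A [train_regressor()] model.
#' @param tac A [tac_points()] curve with the model's number of points.
#' @param model_class `"MEf"` or `"BEf"`.
#' @return An [exp_params()] object.
#' @export
predict_parameters <- function(ml2, tac, model_class) {
  stopifnot(inherits(ml2, "tac_ml2"), inherits(tac, "tac_points"))
  model_class <- match_kind(model_class)
  if (tac$n != ml2$n_points) {
    stop("curve has ", tac$n, " points but the regressor was trained for ",
         ml2$n_points, call. = FALSE)
  }
  X <- matrix(build_features(tac, model_class), nrow = 1)
  vals <- ml2_predict_block(ml2, X, model_class)
  ml2_params_from_row(model_class, drop(vals)[ml2_target_names(model_class)])
}

#' Predict parameters and tau for every curve of a dataset (ML2)
#'
#' Batch version of [predict_parameters()]: curves are grouped by their
#' assigned class and each class bank predicts its block at once.
#'
#' @param ml2 A [train_regressor()] model.
#' @param dataset A [generate_dataset()] result with matching N.
#' @param classes Character vector of `"MEf"`/`"BEf"` labels, one per curve
#'   (from ML1, truth, or a file column).
#' @return Data frame `curve_id, class, A1, lambda1, A2, lambda2, tau`
#'   (`A2`/`lambda2` `NA` for MEf predictions).
#' @export
predict_parameters_dataset <- function(ml2, dataset, classes) {
  stopifnot(inherits(ml2, "tac_ml2"), inherits(dataset, "tac_dataset"),
            length(classes) == length(dataset$curves))
  if (dataset$spec$n_points != ml2$n_points) {
    stop("dataset N does not match the regressor's N", call. = FALSE)
  }
  out <- data.frame(curve_id = seq_along(dataset$curves) - 1L,
                    class = as.character(classes),
                    A1 = NA_real_, lambda1 = NA_real_,
                    A2 = NA_real_, lambda2 = NA_real_, tau = NA_real_)
  X <- dataset_features(dataset, classes = classes)
  for (kind in MODEL_KINDS) {
    rows <- which(classes == kind)
    if (length(rows) == 0) next
    vals <- ml2_predict_block(ml2, X[rows, , drop = FALSE], kind)
    for (i in seq_along(rows)) {
      p <- ml2_params_from_row(kind, vals[i, ])
      out[rows[i], c("A1", "lambda1")] <- c(p$amplitudes[1], p$rates[1])
      if (kind == BEF) {
        out[rows[i], c("A2", "lambda2")] <- c(p$amplitudes[2], p$rates[2])
      }
      out$tau[rows[i]] <- tau(p)
    }
  }
  out
}
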