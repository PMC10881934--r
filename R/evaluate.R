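# Benchmark harness: classification accuracy and the distribution of the
# signed percentage error of tau across estimation chains and curve counts.

#' Classification accuracy
#'
#' Percentage of curves assigned their true generating model:
#' `100 * (CC_ME + CC_BE) / total`.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Accuracy in percent.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth labels must have equal length", call. = FALSE)
  }
  100 * mean(predicted == truth)
}

#' Signed percentage error of tau
#'
#' `100 * (tau_est - tau_true) / tau_true`; negative values are
#' underestimates.
#'
#' @param tau_est Estimated areas under the curve (hours).
#' @param tau_true True areas (hours, > 0).
#' @return Percent differences.
#' @export
delta_tau <- function(tau_est, tau_true) {
  if (any(tau_true <= 0)) stop("tau_true must be > 0", call. = FALSE)
  100 * (tau_est - tau_true) / tau_true
}

#' Summary of a Delta-tau distribution
#'
#' Median, quartiles (linear-interpolation convention, [stats::quantile()]
#' type 7), interquartile width and the maximum error range (MER: minimum
#' and maximum of the distribution).
#'
#' @param deltas Non-empty vector of percent differences.
#' @param n_points Optional N annotation.
#' @param chain Optional chain-name annotation.
#' @return A one-row data frame of class `delta_tau_summary` with columns
#'   `n_points, chain, median, q1, q3, iqr_width, mer_lo, mer_hi, n_curves`.
#' @export
summarize_deltas <- function(deltas, n_points = NA, chain = NA_character_) {
  if (length(deltas) == 0) stop("no Delta-tau values to summarize",
                                call. = FALSE)
  q <- unname(stats::quantile(deltas, c(0.25, 0.5, 0.75), type = 7))
  out <- data.frame(n_points = n_points, chain = chain,
                    median = q[2], q1 = q[1], q3 = q[3],
                    iqr_width = q[3] - q[1],
                    mer_lo = min(deltas), mer_hi = max(deltas),
                    n_curves = length(deltas))
  class(out) <- c("delta_tau_summary", class(out))
  out
}

#' Configuration of a benchmark experiment
#'
#' Bundles the study conditions: the set of curve sizes N, the per-class
#' training and test counts, the test noise level, the F-test significance
#' level, the sampling law and the master seed (every dataset and training
#' run derives its own documented sub-seed from it).
#'
#' @param n_set Values of N to sweep.
#' @param n_train_me,n_train_be Training curves per class (noise-free).
#' @param n_test_me,n_test_be Test curves per class (noisy).
#' @param noise Relative test noise (0.05 = 5%).
#' @param alpha F-test significance level.
#' @param seed Master seed.
#' @param ml2 An [ml2_config()].
#' @param law Sampling law, see [sample_parameters()].
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_set = c(4, 5, 6, 8, 10, 12, 14, 16, 18, 20),
                             n_train_me = 5000, n_train_be = 5000,
                             n_test_me = 1000, n_test_be = 1000,
                             noise = 0.05, alpha = 0.05, seed = 1,
                             ml2 = ml2_config(),
                             law = c("curve", "independent")) {
  stopifnot(all(n_set >= 4), n_train_me > 0, n_train_be > 0, n_test_me > 0,
            n_test_be > 0, noise >= 0, alpha > 0, alpha < 1)
  structure(list(n_set = as.integer(n_set), n_train_me = as.integer(n_train_me),
                 n_train_be = as.integer(n_train_be),
                 n_test_me = as.integer(n_test_me),
                 n_test_be = as.integer(n_test_be), noise = noise,
                 alpha = alpha, seed = as.integer(seed), ml2 = ml2,
                 law = match.arg(law)),
            class = "benchmark_config")
}

# Sub-seed keys: one slot per (N, role).
bench_seed <- function(config, n_points, role) {
  role_id <- match(role, c("train", "test", "ml1", "ml2", "cv"))
  derive_seed(config$seed, n_points * 10 + role_id)
}

bench_train_set <- function(config, n_points) {
  generate_dataset(dataset_spec(n_points, config$n_train_me,
                                config$n_train_be, 0,
                                seed = bench_seed(config, n_points, "train"),
                                law = config$law))
}

bench_test_set <- function(config, n_points) {
  generate_dataset(dataset_spec(n_points, config$n_test_me, config$n_test_be,
                                config$noise,
                                seed = bench_seed(config, n_points, "test"),
                                law = config$law))
}

# Tau of the fit selected by an analytic chain, given both fits.
chain_tau <- function(fits, chosen) {
  tau(if (chosen == MEF) fits$me else fits$be)
}

#' Benchmark test 1: estimation with error-free classification
#'
#' For each N in the sweep: generates the noise-free training set and the
#' noisy test set, then measures the Delta-tau distribution of (a) the
#' least-squares fit of each curve's true model (`fit_only`) and (b) the
#' ML2 regressor supplied with the true class (`ml2_only`). This bounds the
#' best possible performance of both estimators, free of classification
#' errors.
#'
#' @param config A [benchmark_config()].
#' @return A `benchmark_report` list: `delta_summary` (data frame of
#'   [summarize_deltas()] rows), `config`.
#' @export
run_test1_known_class <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  rows <- list()
  for (n_points in config$n_set) {
    ts <- bench_test_set(config, n_points)
    kinds <- dataset_kinds(ts)
    tau_true <- dataset_truth_tau(ts)

    tau_fit <- mapply(function(cv, kind) tau(fit_tac(cv, kind)),
                      ts$curves, kinds)
    rows[[length(rows) + 1L]] <-
      summarize_deltas(delta_tau(tau_fit, tau_true), n_points, "fit_only")

    tr <- bench_train_set(config, n_points)
    ml2 <- train_regressor(tr, seed = bench_seed(config, n_points, "ml2"),
                           config = config$ml2)
    pred <- predict_parameters_dataset(ml2, ts, kinds)
    rows[[length(rows) + 1L]] <-
      summarize_deltas(delta_tau(pred$tau, tau_true), n_points, "ml2_only")
  }
  structure(list(delta_summary = do.call(rbind, rows),
                 ca = NULL, config = config),
            class = "benchmark_report")
}

#' Benchmark test 2: full estimation chains
#'
#' For each N: runs the four complete chains on the noisy test set —
#' `fit_aicc` (minimum AICc, N >= 6), `fit_aiccw` (AICc-weighted tau
#' averaging, N >= 6; its accuracy is scored by the larger weight),
#' `fit_ftest` (extra-sum-of-squares F-test, N >= 5) and `ml1_ml2` (ML
#' classification then ML regression, any N) — recording classification
#' accuracy and the Delta-tau distribution of each. Chains below their
#' applicability threshold are skipped at that N.
#'
#' @param config A [benchmark_config()].
#' @return A `benchmark_report` list: `ca` (data frame `n_points, chain,
#'   ca`), `delta_summary`, `config`.
#' @export
run_test2_full_chains <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  ca_rows <- list()
  delta_rows <- list()
  for (n_points in config$n_set) {
    ts <- bench_test_set(config, n_points)
    kinds <- dataset_kinds(ts)
    tau_true <- dataset_truth_tau(ts)
    tr <- bench_train_set(config, n_points)

    fits <- if (n_points >= 5) lapply(ts$curves, fit_both) else NULL

    add <- function(chain, chosen, tau_est) {
      ca_rows[[length(ca_rows) + 1L]] <<-
        data.frame(n_points = n_points, chain = chain,
                   ca = classification_accuracy(chosen, kinds))
      delta_rows[[length(delta_rows) + 1L]] <<-
        summarize_deltas(delta_tau(tau_est, tau_true), n_points, chain)
    }

    if (n_points >= 6) {
      sel <- lapply(fits, function(fb) aicc_select(fb$me, fb$be))
      chosen <- vapply(sel, `[[`, character(1), "chosen")
      add("fit_aicc",
          chosen,
          mapply(chain_tau, fits, chosen))
      add("fit_aiccw",
          chosen,  # AICc-W shares the argmax-weight classification
          mapply(function(fb, s) {
            tau_aicc_weighted(tau(fb$me), tau(fb$be), s$w_me, s$w_be)
          }, fits, sel))
    }
    if (n_points >= 5) {
      chosen <- vapply(fits, function(fb) {
        f_test_select(fb$me, fb$be, alpha = config$alpha)$chosen
      }, character(1))
      add("fit_ftest", chosen, mapply(chain_tau, fits, chosen))
    }

    ml1 <- train_classifier(tr, seed = bench_seed(config, n_points, "ml1"))
    ml2 <- train_regressor(tr, seed = bench_seed(config, n_points, "ml2"),
                           config = config$ml2)
    cls <- classify_dataset(ml1, ts)$chosen
    pred <- predict_parameters_dataset(ml2, ts, cls)
    add("ml1_ml2", cls, pred$tau)
  }
  structure(list(ca = do.call(rbind, ca_rows),
                 delta_summary = do.call(rbind, delta_rows),
                 config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (seed", x$config$seed, ")\n")
  if (!is.null(x$ca)) {
    cat("\nClassification accuracy (%):\n")
    print(x$ca, row.names = FALSE)
  }
  cat("\nDelta-tau summaries (%):\n")
  df <- x$delta_summary
  df[] <- lapply(df, function(col) if (is.numeric(col)) signif(col, 4) else col)
  print(df, row.names = FALSE)
  invisible(x)
}
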