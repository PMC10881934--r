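# Model selection between the mono- and bi-exponential fits: corrected
# Akaike information criterion, Akaike weights (two-model case), the
# extra-sum-of-squares F-test, and AICc-weighted model averaging of tau.

#' Corrected Akaike information criterion for a least-squares fit
#'
#' `AICc = N ln(SS/N) + 2K + 2K(K+1)/(N - K - 1)` with `K` the number of
#' fitted model parameters (2 for MEf, 4 for BEf; the error variance is not
#' counted). The correction term requires `N - K - 1 >= 1`, so the
#' bi-exponential score needs at least 6 points.
#'
#' @param ss Sum of squared deviations (> 0; an exactly-zero residual yields
#'   `-Inf`, the strongest possible evidence).
#' @param n Number of points.
#' @param k Number of fitted parameters.
#' @return The AICc score (lower is better).
#' @export
#' @examples
#' aicc_score(ss = 10, n = 10, k = 2)  # 4 + 12/7
aicc_score <- function(ss, n, k) {
  stopifnot(ss >= 0, k >= 1)
  if (n - k - 1 < 1) {
    stop("AICc not applicable: need N - K - 1 >= 1 (N >= ", k + 2, ")",
         call. = FALSE)
  }
  n * log(ss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights for the two candidate models
#'
#' Two-model Akaike weights: with `Delta_i = AICc_i - AICc_other`,
#' `w_i = exp(-Delta_i/2) / (1 + exp(-Delta_i/2))`, i.e. the relative
#' likelihood that model i is the better of the pair. The weights sum to 1
#' and the lower-AICc model always receives the larger weight.
#'
#' @param aicc_me,aicc_be Finite AICc scores (or `-Inf` for a perfect fit).
#' @return Named numeric `c(w_me, w_be)`.
#' @export
#' @examples
#' akaike_weights(10, 10 + 2 * log(9))  # w_me = 0.9
akaike_weights <- function(aicc_me, aicc_be) {
  if (is.infinite(aicc_me) && is.infinite(aicc_be) && aicc_me == aicc_be) {
    return(c(w_me = 0.5, w_be = 0.5))  # two exact fits: no evidence either way
  }
  delta <- (aicc_me - aicc_be) / 2
  # each weight through its own logistic keeps tiny weights at full
  # relative precision (1 - plogis(x) would cancel catastrophically)
  c(w_me = stats::plogis(-delta), w_be = stats::plogis(delta))
}

new_model_selection <- function(chosen, method, ...) {
  structure(c(list(chosen = chosen, method = method), list(...)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model selection (%s): chosen = %s\n", x$method, x$chosen))
  extras <- setdiff(names(x), c("chosen", "method"))
  for (nm in extras) {
    cat(sprintf("  %s = %s\n", nm,
                paste(signif(unlist(x[[nm]]), 6), collapse = ", ")))
  }
  invisible(x)
}

#' Extra-sum-of-squares F-test between the nested fits
#'
#' `F = ((SS_ME - SS_BE)/SS_BE) / ((DF_ME - DF_BE)/DF_BE)` with
#' `DF = N - K`; the p-value is the upper tail of the F distribution with
#' `(DF_ME - DF_BE, DF_BE)` degrees of freedom. The mono-exponential null is
#' rejected (bi-exponential chosen) when `p < alpha`. A negative numerator —
#' impossible for exact optima of nested models, possible through optimizer
#' round-off — is clipped to `F = 0`. Needs `DF_BE >= 1`, i.e. at least 5
#' points.
#'
#' @param fit_me,fit_be [fit_tac()] results for the MEf and BEf models of
#'   the same curve.
#' @param alpha Significance level (default 0.05).
#' @return A `model_selection` with fields `f_stat`, `p_value`, `alpha`.
#' @export
f_test_select <- function(fit_me, fit_be, alpha = 0.05) {
  stopifnot(inherits(fit_me, "fit_result"), inherits(fit_be, "fit_result"),
            fit_me$n == fit_be$n, alpha > 0, alpha < 1)
  if (fit_be$df < 1) {
    stop("F-test not applicable: need df_be >= 1 (N >= 5)", call. = FALSE)
  }
  if (fit_be$ss <= 0) {
    return(new_model_selection(BEF, "FTest", f_stat = Inf, p_value = 0,
                               alpha = alpha))
  }
  num <- max(fit_me$ss - fit_be$ss, 0)
  f_stat <- (num / fit_be$ss) / ((fit_me$df - fit_be$df) / fit_be$df)
  p_value <- stats::pf(f_stat, fit_me$df - fit_be$df, fit_be$df,
                       lower.tail = FALSE)
  chosen <- if (p_value < alpha) BEF else MEF
  new_model_selection(chosen, "FTest", f_stat = f_stat, p_value = p_value,
                      alpha = alpha)
}

#' Minimum-AICc model selection
#'
#' Scores both fits with [aicc_score()] and chooses the model with the lower
#' score; an exact tie goes to the simpler mono-exponential model. Akaike
#' weights are reported alongside. Needs at least 6 points (the
#' bi-exponential AICc correction).
#'
#' @param fit_me,fit_be [fit_tac()] results for the same curve.
#' @return A `model_selection` with fields `aicc_me`, `aicc_be`, `w_me`,
#'   `w_be`.
#' @export
aicc_select <- function(fit_me, fit_be) {
  stopifnot(inherits(fit_me, "fit_result"), inherits(fit_be, "fit_result"),
            fit_me$n == fit_be$n)
  aicc_me <- aicc_score(fit_me$ss, fit_me$n, fit_me$k)
  aicc_be <- aicc_score(fit_be$ss, fit_be$n, fit_be$k)
  w <- akaike_weights(aicc_me, aicc_be)
  chosen <- if (aicc_me <= aicc_be) MEF else BEF
  new_model_selection(chosen, "AICc", aicc_me = aicc_me, aicc_be = aicc_be,
                      w_me = unname(w["w_me"]), w_be = unname(w["w_be"]))
}

#' AICc-weighted model-averaged tau
#'
#' Convex combination `tau = tau_me * w_me + tau_be * w_be` of the two
#' models' areas under the curve, with Akaike weights as the mixing
#' probabilities.
#'
#' @param tau_me,tau_be Areas under the curve (hours) of the two fits.
#' @param w_me,w_be Akaike weights; must sum to 1.
#' @return Model-averaged tau in hours.
#' @export
tau_aicc_weighted <- function(tau_me, tau_be, w_me, w_be) {
  if (abs(w_me + w_be - 1) > 1e-8) {
    stop("weights must sum to 1", call. = FALSE)
  }
  tau_me * w_me + tau_be * w_be
}
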