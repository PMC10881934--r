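#' Parameter band of plausible whole-body FIA curves
#'
#' Closed intervals for the amplitudes (dimensionless fractions of injected
#' activity) and decay rates (per hour) of the mono-exponential (`MEf`) and
#' bi-exponential (`BEf`) whole-body retention models for radioiodine therapy
#' of metastatic differentiated thyroid carcinoma. Every simulated curve is
#' drawn from inside this band.
#'
#' @return A named list with elements `MEf` (intervals `A`, `lambda`) and
#'   `BEf` (intervals `A1`, `lambda1`, `A2`, `lambda2`), each a length-2
#'   numeric `c(min, max)`.
#' @export
#' @examples
#' tiac_band()$MEf$A
tiac_band <- function() {
  list(
    MEf = list(A = c(0.78, 1.00), lambda = c(0.0165, 0.0676)),
    BEf = list(A1 = c(0.46, 0.70), lambda1 = c(0.0225, 0.1078),
               A2 = c(0.30, 0.34), lambda2 = c(0.0044, 0.0476))
  )
}

# Midpoint of each band interval; fallback initialization for degenerate data.
band_midpoint <- function(kind) {
  band <- tiac_band()
  if (kind == MEF) {
    exp_params(MEF, mean(band$MEf$A), mean(band$MEf$lambda))
  } else {
    exp_params(BEF,
               c(mean(band$BEf$A1), mean(band$BEf$A2)),
               c(mean(band$BEf$lambda1), mean(band$BEf$lambda2)))
  }
}

#' Exponential-sum model parameters
#'
#' Container for the time-integrated activity coefficients (TIAc) of a
#' whole-body curve: one amplitude/rate pair for a mono-exponential model
#' (`MEf`), two pairs for a bi-exponential model (`BEf`). For `BEf` the
#' components must be ordered fast-first (`rates[1] > rates[2]`).
#'
#' @param kind `"MEf"` or `"BEf"`.
#' @param amplitudes Positive dimensionless amplitudes `A_i`; length 1
#'   (`MEf`) or 2 (`BEf`).
#' @param rates Positive decay rates `lambda_i` in 1/h, same length as
#'   `amplitudes`.
#' @param check_band If `TRUE`, additionally require every parameter to lie
#'   inside [tiac_band()] and, for `BEf`, `A1 + A2 <= 1` (as for simulated
#'   curves; fitted parameters need not stay in the band).
#' @return An object of class `exp_params`.
#' @export
#' @examples
#' exp_params("BEf", c(0.6, 0.3), c(0.05, 0.01))
exp_params <- function(kind, amplitudes, rates, check_band = FALSE) {
  kind <- match_kind(kind)
  amplitudes <- as.numeric(amplitudes)
  rates <- as.numeric(rates)
  n_comp <- if (kind == MEF) 1L else 2L
  if (length(amplitudes) != n_comp || length(rates) != n_comp) {
    stop(kind, " requires ", n_comp, " amplitude/rate pair(s)", call. = FALSE)
  }
  if (!all(is.finite(amplitudes)) || !all(is.finite(rates)) ||
      any(amplitudes <= 0) || any(rates <= 0)) {
    stop("amplitudes and rates must be finite and > 0", call. = FALSE)
  }
  if (kind == BEF && rates[1] <= rates[2]) {
    stop("BEf rates must be ordered fast-first (lambda1 > lambda2)",
         call. = FALSE)
  }
  if (check_band) {
    band <- tiac_band()[[kind]]
    vals <- if (kind == MEF) list(amplitudes[1], rates[1])
            else list(amplitudes[1], rates[1], amplitudes[2], rates[2])
    ok <- mapply(function(v, b) v >= b[1] && v <= b[2], vals, band)
    if (!all(ok)) stop("parameters outside the simulation band", call. = FALSE)
    if (kind == BEF && sum(amplitudes) > 1) {
      stop("BEf amplitudes must satisfy A1 + A2 <= 1", call. = FALSE)
    }
  }
  structure(list(kind = kind, amplitudes = amplitudes, rates = rates),
            class = "exp_params")
}

#' @export
print.exp_params <- function(x, ...) {
  cat(x$kind, "parameters:\n")
  for (i in seq_along(x$amplitudes)) {
    cat(sprintf("  A%d = %.6g, lambda%d = %.6g /h\n",
                i, x$amplitudes[i], i, x$rates[i]))
  }
  invisible(x)
}

#' Evaluate a fraction-of-injected-activity curve
#'
#' Computes `FIA(t) = sum_i A_i * exp(-lambda_i * t)`.
#'
#' @param params An [exp_params()] object.
#' @param times Non-negative times in hours.
#' @return Numeric vector of FIA values, same length as `times`.
#' @export
#' @examples
#' evaluate_fia(exp_params("MEf", 0.9, 0.05), c(0, 24, 160))
evaluate_fia <- function(params, times) {
  stopifnot(inherits(params, "exp_params"))
  times <- as.numeric(times)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  drop(exp(outer(times, -params$rates)) %*% params$amplitudes)
}

#' Time-integrated activity coefficient (area under the curve)
#'
#' The integral of the exponential-sum FIA model from 0 to infinity,
#' `tau = sum_i A_i / lambda_i`, in hours. `tau` is proportional to the
#' absorbed dose per unit administered activity.
#'
#' @param x An [exp_params()] object or a [fit_tac()] result.
#' @param ... Unused.
#' @return Tau in hours.
#' @export
#' @examples
#' tau(exp_params("MEf", 1, 0.0165))
tau <- function(x, ...) UseMethod("tau")

#' @export
tau.exp_params <- function(x, ...) sum(x$amplitudes / x$rates)

#' @export
tau.fit_result <- function(x, ...) tau(x$params)
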