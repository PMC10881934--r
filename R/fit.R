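# Nonlinear least-squares fitting of exponential-sum retention models.
#
# Initial values come from classical curve stripping (exponential peeling);
# the bounded Levenberg-Marquardt refinement then minimizes the unweighted
# sum of squared FIA deviations.

# Physically informed box bounds for the optimizer. Amplitudes may be driven
# to (near) zero so that the bi-exponential model nests the mono-exponential;
# the upper amplitude bound allows a noisy FIA slightly above 1. Rates are
# confined to the envelope of the simulation band's rate intervals: letting
# the slow rate go to zero lets tau = A/lambda diverge on poorly constrained
# few-point curves, which a whole-body washout cannot physically do.
fit_bounds <- function() {
  band <- tiac_band()
  rates <- range(unlist(band$MEf["lambda"]),
                 unlist(band$BEf[c("lambda1", "lambda2")]))
  list(amp = c(1e-6, 1.1), rate = rates)
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

# Log-linear regression of y on t: returns c(A, lambda) of A*exp(-lambda*t),
# or NULL when the decay estimate is degenerate (non-finite or non-decaying).
loglin_component <- function(t, y) {
  co <- stats::lsfit(t, log(y))$coefficients
  if (!all(is.finite(co)) || co[2] >= 0) return(NULL)
  c(A = unname(exp(co[1])), lambda = unname(-co[2]))
}

#' Curve-stripping initial estimates
#'
#' Classical exponential peeling used to seed the least-squares fit. For a
#' mono-exponential model, a log-linear regression of `log(FIA)` on time.
#' For a bi-exponential model the slow component is first estimated from the
#' last two points (the time grid has a single late follow-up point, so the
#' tail pair is what constrains it), its contribution is subtracted from the
#' earlier points, the residuals are floored at a small positive value, and
#' a second log-linear fit of the residuals gives the fast component.
#'
#' Degenerate data (non-decaying or constant) fall back to the band-midpoint
#' parameters of [tiac_band()].
#'
#' @param tac A [tac_points()] curve with all FIA > 0.
#' @param kind `"MEf"` or `"BEf"` (`BEf` needs >= 5 points).
#' @return An [exp_params()] object; approximate for `BEf` by construction.
#' @export
strip_estimates <- function(tac, kind) {
  stopifnot(inherits(tac, "tac_points"))
  kind <- match_kind(kind)
  t <- tac$times
  y <- tac$fia
  if (kind == BEF && tac$n < 5L) {
    stop("BEf stripping needs at least 5 points", call. = FALSE)
  }

  if (kind == MEF) {
    comp <- loglin_component(t, y)
    if (is.null(comp)) return(band_midpoint(MEF))
    bb <- fit_bounds()
    return(exp_params(MEF, clamp(comp["A"], bb$amp),
                      clamp(comp["lambda"], bb$rate)))
  }

  n <- tac$n
  slow <- loglin_component(t[(n - 1):n], y[(n - 1):n])
  if (is.null(slow)) return(band_midpoint(BEF))
  head_idx <- 1:(n - 2)
  resid <- y[head_idx] - slow["A"] * exp(-slow["lambda"] * t[head_idx])
  resid <- pmax(resid, 1e-8 * max(y))
  fast <- loglin_component(t[head_idx], resid)
  if (is.null(fast)) return(band_midpoint(BEF))

  bb <- fit_bounds()
  a <- clamp(c(fast["A"], slow["A"]), bb$amp)
  l <- clamp(c(fast["lambda"], slow["lambda"]), bb$rate)
  if (l[1] <= l[2]) {  # peeling can invert poorly separated rates; reorder
    a <- rev(a)
    l <- rev(l)
  }
  if (l[1] <= l[2]) l[1] <- l[2] * (1 + 1e-6)
  exp_params(BEF, a, l)
}

params_to_vector <- function(params) {
  as.numeric(rbind(params$amplitudes, params$rates))
}

vector_to_params <- function(kind, par) {
  if (kind == MEF) return(exp_params(MEF, par[1], par[2]))
  a <- c(par[1], par[3])
  l <- c(par[2], par[4])
  if (l[1] < l[2]) {  # report fast component first
    a <- rev(a)
    l <- rev(l)
  } else if (l[1] == l[2]) {
    l[1] <- l[1] * (1 + 1e-12)
  }
  exp_params(kind, a, l)
}

# One bounded Levenberg-Marquardt run from a single starting point.
fit_from_init <- function(tac, kind, init) {
  k <- if (kind == MEF) 2L else 4L
  bb <- fit_bounds()
  lower <- rep(c(bb$amp[1], bb$rate[1]), k / 2)
  upper <- rep(c(bb$amp[2], bb$rate[2]), k / 2)
  par0 <- pmin(pmax(params_to_vector(init), lower), upper)
  amp_idx <- seq(1, k, by = 2)
  rate_idx <- seq(2, k, by = 2)
  resid_fn <- function(par) {
    tac$fia - drop(exp(outer(tac$times, -par[rate_idx])) %*% par[amp_idx])
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-10,
                                         ptol = 1e-10))
  structure(list(params = vector_to_params(kind, fit$par), ss = fit$deviance,
                 n = tac$n, k = k, df = tac$n - k,
                 converged = fit$info %in% 1:4),
            class = "fit_result")
}

#' Fit an exponential-sum model to a time-activity curve
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) of
#' `FIA(t) = sum_i A_i exp(-lambda_i t)`. Residuals are unweighted:
#' per-point measurement uncertainties are deliberately not modelled. All
#' parameters carry physically informed box bounds (see the package
#' vignette): amplitudes in `[1e-6, 1.1]`, rates confined to the envelope of
#' the [tiac_band()] rate intervals so that the slow-component area
#' `A/lambda` cannot diverge on poorly constrained curves.
#'
#' When `init` is not given the optimizer is multi-started from the
#' [strip_estimates()] peeling solution, the band midpoint and the band's
#' fast and slow limit-curve parameter sets, keeping the lowest-residual
#' optimum (the bounded Levenberg-Marquardt iteration can stall on a box
#' corner from a single unlucky start).
#'
#' @param tac A [tac_points()] curve with at least `k + 1` points
#'   (`k` = 2 for MEf, 4 for BEf).
#' @param kind `"MEf"` or `"BEf"`.
#' @param init Optional [exp_params()] starting point (disables the
#'   multi-start).
#' @return An object of class `fit_result`: `params` (fast-first for BEf),
#'   `ss` (sum of squared deviations), `n`, `k`, `df = n - k`, `converged`.
#' @export
#' @examples
#' truth <- exp_params("MEf", 0.9, 0.05)
#' tac <- tac_points(make_time_grid(6), evaluate_fia(truth, make_time_grid(6)))
#' fit_tac(tac, "MEf")
fit_tac <- function(tac, kind, init = NULL) {
  stopifnot(inherits(tac, "tac_points"))
  kind <- match_kind(kind)
  k <- if (kind == MEF) 2L else 4L
  if (tac$n < k + 1L) {
    stop(kind, " fit needs at least ", k + 1L, " points", call. = FALSE)
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "exp_params"), init$kind == kind)
    return(fit_from_init(tac, kind, init))
  }
  lim <- band_limit_curves(kind)
  inits <- list(strip_estimates(tac, kind), band_midpoint(kind),
                lim$low, lim$high)
  fits <- lapply(inits, function(ini) fit_from_init(tac, kind, ini))
  fits[[which.min(vapply(fits, function(f) f$ss, numeric(1)))]]
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s least-squares fit (SS = %.4g, df = %d, %s)\n",
              x$params$kind, x$ss, x$df,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Fit both candidate models with the nesting safeguard
#'
#' Fits the mono-exponential model, then the bi-exponential model twice: once
#' from the stripping starting point and once from a start equivalent to the
#' fitted mono-exponential solution (amplitude split in half, rates split
#' infinitesimally). The better bi-exponential optimum is kept, which
#' enforces the nested-model property `ss_be <= ss_me` up to optimizer
#' round-off.
#'
#' @param tac A [tac_points()] curve with at least 5 points.
#' @return List with elements `me` and `be`, both `fit_result`s.
#' @export
fit_both <- function(tac) {
  fit_me <- fit_tac(tac, MEF)
  fit_be <- fit_tac(tac, BEF)
  a <- fit_me$params$amplitudes
  l <- fit_me$params$rates
  bb <- fit_bounds()
  rates <- clamp(c(l * (1 + 1e-4), l * (1 - 1e-4)), bb$rate)
  if (rates[1] <= rates[2]) rates[1] <- rates[2] * (1 + 1e-9)
  degen <- exp_params(BEF, c(a / 2, a / 2), rates)
  fit_be2 <- fit_tac(tac, BEF, init = degen)
  if (fit_be2$ss < fit_be$ss) fit_be <- fit_be2
  list(me = fit_me, be = fit_be)
}
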