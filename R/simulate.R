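# Synthetic whole-body FIA curve simulator.
#
# Emulates the measurement schedule of radioiodine whole-body retention
# studies: frequent counts during the hospitalization window and a single
# late follow-up point.

#' Measurement time grid for an N-point curve
#'
#' The first `n_points - 1` times are equally spaced over the closed
#' hospitalization window \[0, 54\] h; the last point is the late follow-up
#' at 160 h.
#'
#' @param n_points Number of points N (>= 4).
#' @return Numeric vector of `n_points` strictly increasing times in hours.
#' @export
#' @examples
#' make_time_grid(4)   # 0, 27, 54, 160
make_time_grid <- function(n_points) {
  n_points <- as.integer(n_points)
  if (length(n_points) != 1L || is.na(n_points) || n_points < 4L) {
    stop("n_points must be a single integer >= 4", call. = FALSE)
  }
  c(seq(0, 54, length.out = n_points - 1L), 160)
}

# Pointwise envelope of every curve whose parameters lie in the band box:
# FIA is increasing in each amplitude and decreasing in each rate, so the
# (A_max, lambda_min) / (A_min, lambda_max) combinations bound all draws.
# (Distinct from band_limit_curves(): Table 1 pairs A2's maximum with the
# fast rates, so the sampling law's limit curves are not a pointwise bound.)
band_envelope <- function(kind) {
  band <- tiac_band()[[kind]]
  if (kind == MEF) {
    list(low = exp_params(MEF, band$A[1], band$lambda[2]),
         high = exp_params(MEF, band$A[2], band$lambda[1]))
  } else {
    list(low = exp_params(BEF, c(band$A1[1], band$A2[1]),
                          c(band$lambda1[2], band$lambda2[2])),
         high = exp_params(BEF, c(band$A1[2], band$A2[2]),
                           c(band$lambda1[1], band$lambda2[1])))
  }
}

# Parameter sets of the two limit curves delimiting each family's band:
# the "low" curve pairs the small amplitudes with the fast rates, the "high"
# curve the large amplitudes with the slow rates, so every interpolated curve
# lies pointwise between them.
band_limit_curves <- function(kind) {
  band <- tiac_band()[[kind]]
  if (kind == MEF) {
    list(low = exp_params(MEF, band$A[1], band$lambda[2]),
         high = exp_params(MEF, band$A[2], band$lambda[1]))
  } else {
    list(low = exp_params(BEF, c(band$A1[1], band$A2[2]),
                          c(band$lambda1[2], band$lambda2[2])),
         high = exp_params(BEF, c(band$A1[2], band$A2[1]),
                           c(band$lambda1[1], band$lambda2[1])))
  }
}

#' Draw model parameters from the simulation band
#'
#' Two sampling laws over the [tiac_band()] band are available:
#'
#' * `"curve"` (default): curve-level sampling. One `alpha ~ U(0, 1)` per
#'   curve interpolates every amplitude and rate linearly between the
#'   parameter sets of the band's two limit curves (small amplitudes / fast
#'   rates at `alpha = 0`, large amplitudes / slow rates at `alpha = 1`).
#'   The drawn curve sweeps the band from its lower to its upper limit
#'   curve; rate ordering (`lambda1 > lambda2`) and `A1 + A2 <= 1` hold by
#'   construction. This is the default because the resulting mono- and
#'   bi-exponential populations are cleanly separable in the absence of
#'   noise, as a population of physiologically coherent patients is.
#' * `"independent"`: each amplitude and rate drawn independently and
#'   uniformly between its interval endpoints; bi-exponential draws
#'   violating `lambda1 > lambda2` or `A1 + A2 <= 1` are rejected and
#'   redrawn. This law also fills the band but most of its bi-exponential
#'   draws have poorly separated rates and are statistically
#'   indistinguishable from mono-exponentials.
#'
#' Uses the current RNG stream.
#'
#' @param kind `"MEf"` or `"BEf"`.
#' @param law `"curve"` or `"independent"`.
#' @param max_tries Safety cap on rejection redraws (independent law).
#' @return An [exp_params()] object inside the band.
#' @export
#' @examples
#' set.seed(1)
#' sample_parameters("BEf")
sample_parameters <- function(kind, law = c("curve", "independent"),
                              max_tries = 10000L) {
  kind <- match_kind(kind)
  law <- match.arg(law)
  band <- tiac_band()[[kind]]

  if (law == "curve") {
    lim <- band_limit_curves(kind)
    alpha <- stats::runif(1)
    return(exp_params(
      kind,
      lim$low$amplitudes + alpha * (lim$high$amplitudes - lim$low$amplitudes),
      lim$low$rates + alpha * (lim$high$rates - lim$low$rates)))
  }

  if (kind == MEF) {
    return(exp_params(MEF,
                      stats::runif(1, band$A[1], band$A[2]),
                      stats::runif(1, band$lambda[1], band$lambda[2])))
  }
  for (i in seq_len(max_tries)) {
    a1 <- stats::runif(1, band$A1[1], band$A1[2])
    l1 <- stats::runif(1, band$lambda1[1], band$lambda1[2])
    a2 <- stats::runif(1, band$A2[1], band$A2[2])
    l2 <- stats::runif(1, band$lambda2[1], band$lambda2[2])
    if (l1 > l2 && a1 + a2 <= 1) {
      return(exp_params(BEF, c(a1, a2), c(l1, l2)))
    }
  }
  stop("rejection sampling failed to produce a valid BEf draw", call. = FALSE)
}

#' Gaussian relative measurement noise
#'
#' Replaces each FIA value by a Gaussian draw centred on it with standard
#' deviation `sigma_rel` times the value, emulating counting/measurement
#' error. Non-positive draws are redrawn so the returned activities stay
#' physical. Uses the current RNG stream.
#'
#' @param fia Positive FIA values.
#' @param sigma_rel Relative standard deviation (e.g. 0.05 for 5%); 0 returns
#'   the input unchanged.
#' @return Noisy FIA vector, all values > 0.
#' @export
add_measurement_noise <- function(fia, sigma_rel) {
  stopifnot(sigma_rel >= 0, all(fia > 0))
  if (sigma_rel == 0) return(fia)
  out <- stats::rnorm(length(fia), mean = fia, sd = sigma_rel * fia)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean = fia[bad],
                             sd = sigma_rel * fia[bad])
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' One measured or simulated time-activity curve
#'
#' @param times Strictly increasing times in hours, length >= 4.
#' @param fia Positive FIA values, same length.
#' @param truth Optional [exp_params()] that generated the curve.
#' @param noisy Whether measurement noise was applied.
#' @return An object of class `tac_points` with fields `times`, `fia`, `n`,
#'   `truth`, `noisy`.
#' @export
tac_points <- function(times, fia, truth = NULL, noisy = FALSE) {
  times <- as.numeric(times)
  fia <- as.numeric(fia)
  if (length(times) != length(fia)) {
    stop("times and fia must have the same length", call. = FALSE)
  }
  if (length(times) < 4L) stop("a curve needs at least 4 points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(fia)) || any(fia <= 0)) {
    stop("all FIA values must be finite and > 0", call. = FALSE)
  }
  if (!is.null(truth)) stopifnot(inherits(truth, "exp_params"))
  structure(list(times = times, fia = fia, n = length(times),
                 truth = truth, noisy = isTRUE(noisy)),
            class = "tac_points")
}

#' @export
print.tac_points <- function(x, ...) {
  cat(sprintf("TAC with %d points (%s)%s\n", x$n,
              if (x$noisy) "noisy" else "noise-free",
              if (is.null(x$truth)) "" else paste0(", truth: ", x$truth$kind)))
  print(data.frame(t_h = x$times, fia = signif(x$fia, 6)))
  invisible(x)
}

#' Specification of one synthetic dataset
#'
#' @param n_points Points per curve N (>= 4).
#' @param n_me,n_be Number of mono- and bi-exponential curves.
#' @param noise_sigma_rel Relative Gaussian noise on FIA (0 = noise-free
#'   training data; 0.05 = the default test-set noise).
#' @param seed RNG seed making the dataset reproducible.
#' @param law Sampling law for [sample_parameters()].
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_points, n_me, n_be, noise_sigma_rel = 0,
                         seed = NULL, law = c("curve", "independent")) {
  stopifnot(n_points >= 4, n_me >= 0, n_be >= 0, n_me + n_be > 0,
            noise_sigma_rel >= 0)
  structure(list(n_points = as.integer(n_points), n_me = as.integer(n_me),
                 n_be = as.integer(n_be),
                 noise_sigma_rel = as.numeric(noise_sigma_rel),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 law = match.arg(law)),
            class = "dataset_spec")
}

#' Generate a synthetic dataset of whole-body FIA curves
#'
#' Draws `n_me` mono-exponential and `n_be` bi-exponential curves with
#' parameters uniform in the [tiac_band()] band, evaluates each on the
#' [make_time_grid()] schedule, and (for test sets) perturbs the FIA values
#' with Gaussian relative noise. Curves are ordered MEf block first, then
#' BEf. Fully reproducible from `spec$seed`.
#'
#' @param spec A [dataset_spec()].
#' @return An object of class `tac_dataset`: a list with `curves` (list of
#'   [tac_points()], each carrying its generating truth) and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(dataset_spec(6, 3, 3, 0.05, seed = 42))
#' length(ds$curves)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  grid <- make_time_grid(spec$n_points)
  kinds <- c(rep(MEF, spec$n_me), rep(BEF, spec$n_be))
  curves <- with_seed(spec$seed, lapply(kinds, function(kind) {
    truth <- sample_parameters(kind, law = spec$law %||% "curve")
    fia <- evaluate_fia(truth, grid)
    if (spec$noise_sigma_rel > 0) {
      fia <- add_measurement_noise(fia, spec$noise_sigma_rel)
    }
    tac_points(grid, fia, truth = truth, noisy = spec$noise_sigma_rel > 0)
  }))
  structure(list(curves = curves, spec = spec), class = "tac_dataset")
}

#' @export
print.tac_dataset <- function(x, ...) {
  cat(sprintf(
    "tac_dataset: %d curves (%d MEf + %d BEf), N = %d points, noise = %g%s\n",
    length(x$curves), x$spec$n_me, x$spec$n_be, x$spec$n_points,
    x$spec$noise_sigma_rel,
    if (is.null(x$spec$seed)) "" else sprintf(", seed = %d", x$spec$seed)))
  invisible(x)
}

#' True generating model of every curve in a dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return Character vector of `"MEf"`/`"BEf"` labels.
#' @export
dataset_kinds <- function(dataset) {
  stopifnot(inherits(dataset, "tac_dataset"))
  vapply(dataset$curves, function(cv) cv$truth$kind, character(1))
}

#' True tau of every curve in a dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return Numeric vector of true areas under the curve, in hours.
#' @export
dataset_truth_tau <- function(dataset) {
  stopifnot(inherits(dataset, "tac_dataset"))
  vapply(dataset$curves, function(cv) tau(cv$truth), numeric(1))
}

#' @export
as.data.frame.tac_dataset <- function(x, ...) {
  n <- x$spec$n_points
  ids <- rep(seq_along(x$curves) - 1L, each = n)
  do.call(rbind, c(list(make.row.names = FALSE), Map(function(cv, id) {
    data.frame(curve_id = id, model_kind = cv$truth$kind, t_h = cv$times,
               fia = cv$fia, noisy = cv$noisy)
  }, x$curves, seq_along(x$curves) - 1L)))
}

#' Truth parameter table of a synthetic dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return Data frame with columns `curve_id, kind, A1, lambda1, A2, lambda2`
#'   (`A2`/`lambda2` are `NA` for MEf curves).
#' @export
truth_parameters <- function(dataset) {
  stopifnot(inherits(dataset, "tac_dataset"))
  rows <- lapply(seq_along(dataset$curves), function(i) {
    p <- dataset$curves[[i]]$truth
    data.frame(curve_id = i - 1L, kind = p$kind,
               A1 = p$amplitudes[1], lambda1 = p$rates[1],
               A2 = if (p$kind == BEF) p$amplitudes[2] else NA_real_,
               lambda2 = if (p$kind == BEF) p$rates[2] else NA_real_)
  })
  do.call(rbind, rows)
}
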