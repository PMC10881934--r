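# tacfit

Model selection and time-integrated activity estimation for whole-body
time-activity curves in molecular radiotherapy.

## The problem

Internal dosimetry after radionuclide therapy (here: [131I]I-NaI for
metastatic differentiated thyroid carcinoma) needs the *time-integrated
activity coefficient*: the area under the whole-body time-activity curve
(TAC), expressed as fraction of injected activity (FIA). The washout is
modelled as an exponential sum,

    FIA(t) = sum_i A_i * exp(-lambda_i * t),      tau = sum_i A_i / lambda_i

with one component (mono-exponential, MEf) or two (bi-exponential, BEf).
With only a handful of measurement points per patient, two questions
dominate the accuracy of `tau`: *which model* should be fitted, and *how
well* can its parameters be estimated. `tacfit` implements and benchmarks
the competing answers:

* **Analytic chains** — bounded nonlinear least squares (curve-stripping
  initialization, Levenberg-Marquardt refinement) of both models, then
  selection by the corrected Akaike information criterion
  (`AICc = N ln(SS/N) + 2K + 2K(K+1)/(N-K-1)`), by Akaike-weight model
  averaging of `tau`, or by the extra-sum-of-squares F-test
  (`F = ((SS_ME - SS_BE)/SS_BE) / ((DF_ME - DF_BE)/DF_BE)`).
* **ML chains** — a soft-voting ensemble of two ridge-logistic classifiers
  (ML1) picks the model from the raw curve coordinates; per-parameter
  AdaBoost ensembles of gradient-boosted regression trees (ML2) predict the
  `A_i, lambda_i` directly.
* **A synthetic-curve simulator** — whole-body FIA curves drawn from a
  clinically derived parameter band, on the therapy-ward sampling schedule
  (N-1 points in [0, 54] h plus one at 160 h), with 5% relative Gaussian
  measurement noise on test data.
* **A benchmark harness** — classification accuracy and the distribution of
  the signed percent error of `tau` (median, interquartile width, maximum
  error range) for every chain as the number of points N varies from 4
  to 20.

It is aimed at medical physicists and methodologists studying fit-model
selection for dosimetry; patient curves can be supplied as CSV once
converted to FIA.

## Worked example

```r
library(tacfit)

# simulate a 6-point test set: 3 mono- + 3 bi-exponential noisy curves
ds <- generate_dataset(dataset_spec(6, 3, 3, noise_sigma_rel = 0.05, seed = 42))
tac <- ds$curves[[4]]                 # a bi-exponential curve
tau_true <- tau(tac$truth)

fits <- fit_both(tac)                 # MEf and BEf least-squares fits
f_test_select(fits$me, fits$be)
#> model selection (FTest): chosen = BEf
#>   f_stat = 66.1919
#>   p_value = 0.0148827
#>   alpha = 0.05
aicc_select(fits$me, fits$be)
#> model selection (AICc): chosen = MEf
#>   aicc_me = -34.9601
#>   aicc_be = -20.2054
#>   w_me = 0.999375
#>   w_be = 0.000624871
c(truth = tau_true, fitted = tau(fits$be))
#>    truth   fitted
#> 25.81486 25.71757
```

The two selectors disagree on this 6-point curve, and that disagreement is
the crux of the small-N problem: the F statistic finds the bi-exponential
residual reduction overwhelming (p = 0.015 < 0.05, mono-exponential
rejected), while AICc — whose small-sample correction term
`2K(K+1)/(N-K-1)` is at its harshest for K = 4 at N = 6 — still prefers
the simpler model. The bi-exponential fit recovers the true area
(25.8 h) within 0.4% despite 5% noise on every point.

The ML chain works the same way at scale: `train_classifier()` /
`train_regressor()` on a noise-free training set, then `classify()` and
`predict_parameters()` on measured curves. `run_test1_known_class()` and
`run_test2_full_chains()` reproduce the full benchmark;
`exec/tacfit` exposes `simulate | fit | train | classify | predict |
benchmark` for shell use.

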