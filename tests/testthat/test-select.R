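test_that("AICc matches its closed form and applicability limits", {
  expect_equal(aicc_score(10, 10, 2), 4 + 12 / 7)
  expect_equal(aicc_score(10, 10, 4), 16)
  expect_equal(aicc_score(exp(1) * 8, 8, 2),
               8 * log(exp(1) * 8 / 8) + 4 + 12 / 5)
  expect_error(aicc_score(1, 5, 4), "not applicable")
  expect_error(aicc_score(1, 6, 5), "not applicable")
  expect_identical(aicc_score(0, 10, 2), -Inf)
})

test_that("Akaike weights follow the two-model logistic form", {
  expect_equal(akaike_weights(10, 10), c(w_me = 0.5, w_be = 0.5))
  w <- akaike_weights(0, 2 * log(9))
  expect_equal(unname(w["w_me"]), 0.9)
  set.seed(5)
  for (i in 1:50) {
    a <- rnorm(1, 0, 20)
    b <- rnorm(1, 0, 20)
    w <- akaike_weights(a, b)
    expect_equal(unname(sum(w)), 1, tolerance = 1e-12)
    # permutation consistency
    w_swap <- akaike_weights(b, a)
    expect_equal(unname(w["w_me"]), unname(w_swap["w_be"]), tolerance = 1e-12)
    # lower score gets the larger weight
    if (a < b) expect_gt(w["w_me"], 0.5)
    if (a > b) expect_lt(w["w_me"], 0.5)
  }
})

fake_fit <- function(ss, n, k) {
  structure(list(params = NULL, ss = ss, n = n, k = k, df = n - k,
                 converged = TRUE), class = "fit_result")
}

test_that("the extra-sum-of-squares F-test matches its closed form", {
  sel <- f_test_select(fake_fit(1, 10, 2), fake_fit(1, 10, 4))
  expect_equal(sel$f_stat, 0)
  expect_equal(sel$p_value, 1)
  expect_equal(sel$chosen, "MEf")

  sel <- f_test_select(fake_fit(2, 10, 2), fake_fit(1, 10, 4))
  expect_equal(sel$f_stat, 3)
  # closed-form upper tail of F(2, d2): (1 + 2F/d2)^(-d2/2)
  expect_equal(sel$p_value, (1 + 2 * 3 / 6)^(-3))
  expect_equal(sel$p_value, 0.125)
  expect_equal(sel$chosen, "MEf")

  sel <- f_test_select(fake_fit(2, 10, 2), fake_fit(1e-12, 10, 4))
  expect_equal(sel$chosen, "BEf")
  # negative numerator (optimizer round-off) clips to F = 0
  sel <- f_test_select(fake_fit(0.9, 10, 2), fake_fit(1, 10, 4))
  expect_equal(sel$f_stat, 0)
  expect_equal(sel$chosen, "MEf")
  expect_error(f_test_select(fake_fit(2, 4, 2), fake_fit(1, 4, 4)),
               "not applicable")
})

test_that("selection agrees with a direct-formula oracle on random fixtures", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    ss_be <- runif(1, 1e-4, 1)
    ss_me <- ss_be * (1 + rexp(1, rate = 2))
    fme <- fake_fit(ss_me, n, 2)
    fbe <- fake_fit(ss_be, n, 4)

    # independent oracle: formulas computed directly in the test
    o_aicc_me <- n * log(ss_me / n) + 4 + 12 / (n - 3)
    o_aicc_be <- n * log(ss_be / n) + 8 + 40 / (n - 5)
    o_f <- ((ss_me - ss_be) / ss_be) / (((n - 2) - (n - 4)) / (n - 4))
    o_p <- (1 + 2 * o_f / (n - 4))^(-(n - 4) / 2)

    sel_a <- aicc_select(fme, fbe)
    expect_equal(sel_a$aicc_me, o_aicc_me, tolerance = 1e-12)
    expect_equal(sel_a$aicc_be, o_aicc_be, tolerance = 1e-12)
    expect_equal(sel_a$chosen, if (o_aicc_me <= o_aicc_be) "MEf" else "BEf")
    expect_equal(sel_a$w_me + sel_a$w_be, 1, tolerance = 1e-12)
    expect_equal(sel_a$chosen == "MEf", sel_a$w_me >= 0.5)

    sel_f <- f_test_select(fme, fbe)
    expect_equal(sel_f$f_stat, o_f, tolerance = 1e-12)
    expect_equal(sel_f$p_value, o_p, tolerance = 1e-10)
    expect_equal(sel_f$chosen, if (o_p < 0.05) "BEf" else "MEf")
  }
})

test_that("AICc ties break to the simpler model", {
  sel <- aicc_select(fake_fit(1, 10, 2), fake_fit(exp((4 + 12 / 7 - 16) / 10) * 10 / 10, 10, 4))
  # construct exact tie: ss_be chosen so both scores are equal
  ss_be <- 10 * exp((aicc_score(1, 10, 2) - 8 - 40 / 5) / 10)
  sel <- aicc_select(fake_fit(1, 10, 2), fake_fit(ss_be, 10, 4))
  expect_equal(sel$aicc_me, sel$aicc_be, tolerance = 1e-12)
  expect_equal(sel$chosen, "MEf")
})

test_that("tau sums component areas in hours", {
  expect_equal(tau(exp_params("MEf", 1, 1)), 1)
  expect_equal(tau(exp_params("MEf", 1.00, 0.0165)), 1 / 0.0165)
  expect_equal(round(tau(exp_params("MEf", 1.00, 0.0165)), 2), 60.61)
  t_be <- tau(exp_params("BEf", c(0.70, 0.30), c(0.0225, 0.0044)))
  expect_equal(t_be, 0.70 / 0.0225 + 0.30 / 0.0044)
  expect_equal(round(t_be, 2), 99.29)
})

test_that("AICc-weighted tau is the convex combination of the two areas", {
  expect_equal(tau_aicc_weighted(60, 100, 1, 0), 60)
  expect_equal(tau_aicc_weighted(60, 100, 0.5, 0.5), 80)
  set.seed(9)
  for (i in 1:30) {
    w <- runif(1)
    t1 <- runif(1, 10, 100)
    t2 <- runif(1, 10, 100)
    mix <- tau_aicc_weighted(t1, t2, w, 1 - w)
    expect_gte(mix, min(t1, t2) - 1e-12)
    expect_lte(mix, max(t1, t2) + 1e-12)
  }
  expect_error(tau_aicc_weighted(60, 100, 0.7, 0.7), "sum to 1")
})
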