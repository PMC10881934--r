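test_that("time grid spaces N-1 points over [0, 54] h plus 160 h", {
  expect_equal(make_time_grid(4), c(0, 27, 54, 160))
  g10 <- make_time_grid(10)
  expect_length(g10, 10)
  expect_equal(g10[1:9], seq(0, 54, by = 6.75))
  for (n in c(4, 5, 8, 20)) {
    g <- make_time_grid(n)
    expect_equal(g[length(g)], 160)
    expect_equal(g[1], 0)
    expect_equal(g[n - 1], 54)
    expect_equal(diff(g[1:(n - 1)]), rep(54 / (n - 2), n - 2))
  }
  expect_error(make_time_grid(3), "n_points")
})

test_that("sampled parameters satisfy band and ordering invariants", {
  band <- tiac_band()
  in_interval <- function(x, iv) x >= iv[1] & x <= iv[2]
  for (law in c("curve", "independent")) {
    set.seed(7)
    for (i in 1:200) {
      pm <- sample_parameters("MEf", law = law)
      expect_true(in_interval(pm$amplitudes, band$MEf$A))
      expect_true(in_interval(pm$rates, band$MEf$lambda))
      pb <- sample_parameters("BEf", law = law)
      expect_true(in_interval(pb$amplitudes[1], band$BEf$A1))
      expect_true(in_interval(pb$amplitudes[2], band$BEf$A2))
      expect_true(in_interval(pb$rates[1], band$BEf$lambda1))
      expect_true(in_interval(pb$rates[2], band$BEf$lambda2))
      expect_gt(pb$rates[1], pb$rates[2])
      expect_lte(sum(pb$amplitudes), 1)
      expect_true(is.finite(tau(pb)) && tau(pb) > 0)
    }
  }
})

test_that("FIA evaluation is the exponential sum with the right endpoints", {
  expect_equal(evaluate_fia(exp_params("MEf", 0.9, 0.05), 0), 0.9)
  expect_equal(evaluate_fia(exp_params("MEf", 1.00, 0.0165), 160),
               exp(-0.0165 * 160))
  expect_equal(round(evaluate_fia(exp_params("MEf", 1.00, 0.0165), 160), 4),
               0.0714)
  expect_equal(evaluate_fia(be_fixture, 0), sum(be_fixture$amplitudes))
  fia <- evaluate_fia(be_fixture, make_time_grid(12))
  expect_true(all(diff(fia) < 0))
  expect_error(evaluate_fia(be_fixture, -1), ">= 0")
})

test_that("measurement noise is relative, unbiased and positive", {
  fia <- c(0.9, 0.5, 0.1, 0.01)
  expect_identical(add_measurement_noise(fia, 0), fia)
  set.seed(11)
  draws <- add_measurement_noise(rep(1, 1e5), 0.05)
  expect_equal(mean(draws), 1, tolerance = 1e-3)
  expect_equal(sd(draws), 0.05, tolerance = 0.02)
  set.seed(12)
  tiny <- add_measurement_noise(rep(1e-4, 1e4), 0.5)
  expect_true(all(tiny > 0))
})

test_that("datasets have the requested composition and are seed-reproducible", {
  spec <- dataset_spec(10, 25, 35, 0.05, seed = 99)
  ds1 <- generate_dataset(spec)
  ds2 <- generate_dataset(spec)
  expect_length(ds1$curves, 60)
  expect_equal(sum(dataset_kinds(ds1) == "MEf"), 25)
  expect_equal(sum(dataset_kinds(ds1) == "BEf"), 35)
  expect_identical(ds1, ds2)
  expect_true(all(vapply(ds1$curves, function(cv) cv$noisy, logical(1))))

  clean <- generate_dataset(dataset_spec(10, 5, 5, 0, seed = 99))
  expect_false(any(vapply(clean$curves, function(cv) cv$noisy, logical(1))))
  # noise-free curves reproduce their truth exactly
  for (cv in clean$curves) {
    expect_equal(cv$fia, evaluate_fia(cv$truth, cv$times), tolerance = 1e-12)
  }
})

test_that("every noise-free curve lies inside its family's band", {
  grid <- seq(0, 160, length.out = 81)
  for (law in c("curve", "independent")) {
    ds <- small_dataset(8, 40, 40, noise = 0, seed = 5, law = law)
    for (kind in c("MEf", "BEf")) {
      lim <- tacfit:::band_envelope(kind)
      lo <- evaluate_fia(lim$low, grid)
      hi <- evaluate_fia(lim$high, grid)
      for (cv in ds$curves[dataset_kinds(ds) == kind]) {
        fia <- evaluate_fia(cv$truth, grid)
        expect_true(all(fia >= lo - 1e-12 & fia <= hi + 1e-12))
      }
    }
  }
})

test_that("dataset export tables carry one row per point and per curve", {
  ds <- small_dataset(6, 3, 4, noise = 0.05, seed = 3)
  df <- as.data.frame(ds)
  expect_equal(nrow(df), 7 * 6)
  expect_named(df, c("curve_id", "model_kind", "t_h", "fia", "noisy"))
  expect_equal(unique(df$curve_id), 0:6)
  tp <- truth_parameters(ds)
  expect_equal(nrow(tp), 7)
  expect_true(all(is.na(tp$A2[tp$kind == "MEf"])))
  expect_true(all(tp$lambda1[tp$kind == "BEf"] > tp$lambda2[tp$kind == "BEf"]))
})

test_that("curve containers validate their invariants", {
  expect_error(tac_points(c(0, 1, 2), c(1, 0.5, 0.2)), "at least 4")
  expect_error(tac_points(c(0, 2, 1, 3), c(1, 0.5, 0.2, 0.1)),
               "strictly increasing")
  expect_error(tac_points(0:3, c(1, 0.5, -0.1, 0.1)), "> 0")
  expect_error(exp_params("BEf", c(0.5, 0.3), c(0.01, 0.02)), "fast-first")
  expect_error(exp_params("MEf", -1, 0.05))
  expect_error(sample_parameters("XYf"), "MEf")
})
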