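test_that("feature vectors have the documented layout and length", {
  tac <- exact_tac(me_fixture, 5)
  f <- build_features(tac)
  expect_length(f, 10)
  expect_equal(f, c(tac$times, tac$fia))
  f1 <- build_features(tac, "BEf")
  expect_length(f1, 11)
  expect_equal(f1[11], 1)
  expect_equal(build_features(tac, "MEf")[11], 0)
  expect_identical(build_features(tac), build_features(tac))
})

test_that("classifier training requires both classes", {
  ds <- generate_dataset(dataset_spec(6, 20, 0, 0, seed = 1))
  expect_error(train_classifier(ds), "both")
})

test_that("ML1 separates the noise-free families and reports probabilities", {
  tr <- small_dataset(6, 150, 150, noise = 0, seed = 8)
  # small fixture: weaken the ridge penalty below its full-size default
  ml1 <- train_classifier(tr, seed = 1, lambda = 1e-5)
  cls <- classify_dataset(ml1, tr)
  expect_gte(classification_accuracy(cls$chosen, dataset_kinds(tr)), 98)
  expect_true(all(abs(cls$p_me + cls$p_be - 1) < 1e-12))

  sel <- classify(ml1, tr$curves[[1]])
  expect_s3_class(sel, "model_selection")
  expect_equal(sel$method, "ML")
  expect_equal(unname(sum(sel$class_probs)), 1, tolerance = 1e-12)
  expect_equal(sel$chosen, cls$chosen[1])

  other <- exact_tac(me_fixture, 8)
  expect_error(classify(ml1, other), "trained for")
})

test_that("ML1 probabilities are the arithmetic mean of the two voters", {
  tr <- small_dataset(5, 80, 80, noise = 0, seed = 13)
  ml1 <- train_classifier(tr)
  X <- tacfit:::dataset_features(tr)
  p1 <- drop(stats::predict(ml1$voter1, X, type = "response"))
  p2 <- stats::plogis(drop(cbind(1, X) %*% ml1$voter2$beta))
  pr <- tacfit:::ml1_probs(ml1, X)
  expect_equal(unname(pr[, "p_be"]), unname((p1 + p2) / 2), tolerance = 1e-12)
})

test_that("repeated-split cross-validation returns one accuracy per split", {
  tr <- small_dataset(5, 60, 60, noise = 0, seed = 21)
  cv <- cross_validate_classifier(tr, seed = 3, n_splits = 5)
  expect_length(cv$accuracies, 5)
  expect_true(all(cv$accuracies >= 0 & cv$accuracies <= 100))
  expect_equal(cv$mean, mean(cv$accuracies))
  cv2 <- cross_validate_classifier(tr, seed = 3, n_splits = 5)
  expect_identical(cv, cv2)
})

test_that("ML2 training demands truth parameters and matching N", {
  tr <- small_dataset(5, 25, 25, noise = 0, seed = 31)
  stripped <- tr
  stripped$curves[[1]]$truth <- NULL
  expect_error(train_regressor(stripped, config = tiny_ml2()), "truth")

  ml2 <- train_regressor(tr, seed = 2, config = tiny_ml2())
  expect_error(predict_parameters(ml2, exact_tac(me_fixture, 8), "MEf"),
               "trained for")
})

test_that("ML2 predicts the right parameter count, ordering and band range", {
  tr <- small_dataset(6, 120, 120, noise = 0, seed = 41)
  ml2 <- train_regressor(tr, seed = 7, config = tiny_ml2())
  ts <- small_dataset(6, 25, 25, noise = 0.05, seed = 42)
  band <- tiac_band()

  p_me <- predict_parameters(ml2, ts$curves[[1]], "MEf")
  expect_equal(p_me$kind, "MEf")
  expect_length(p_me$amplitudes, 1)

  p_be <- predict_parameters(ml2, ts$curves[[30]], "BEf")
  expect_length(p_be$amplitudes, 2)
  expect_gt(p_be$rates[1], p_be$rates[2])

  pred <- predict_parameters_dataset(ml2, ts, dataset_kinds(ts))
  pad <- function(iv) c(iv[1] * 0.99, iv[2] * 1.01)
  me_rows <- pred$class == "MEf"
  # tree regressors cannot extrapolate beyond the training target range
  expect_true(all(pred$A1[me_rows] >= pad(band$MEf$A)[1] &
                  pred$A1[me_rows] <= pad(band$MEf$A)[2]))
  expect_true(all(pred$lambda1[!me_rows] >= pad(band$BEf$lambda1)[1] &
                  pred$lambda1[!me_rows] <= pad(band$BEf$lambda1)[2]))
  expect_true(all(is.finite(pred$tau) & pred$tau > 0))
})

test_that("ML training and prediction are deterministic given the seed", {
  tr <- small_dataset(5, 40, 40, noise = 0, seed = 51)
  ts <- small_dataset(5, 10, 10, noise = 0.05, seed = 52)
  a <- train_regressor(tr, seed = 5, config = tiny_ml2())
  b <- train_regressor(tr, seed = 5, config = tiny_ml2())
  pa <- predict_parameters_dataset(a, ts, dataset_kinds(ts))
  pb <- predict_parameters_dataset(b, ts, dataset_kinds(ts))
  expect_identical(pa, pb)
  m1 <- train_classifier(tr, seed = 5)
  m2 <- train_classifier(tr, seed = 5)
  expect_identical(classify_dataset(m1, ts), classify_dataset(m2, ts))
})

test_that("a trained chain survives the save/load round trip", {
  tr <- small_dataset(5, 40, 40, noise = 0, seed = 61)
  ts <- small_dataset(5, 8, 8, noise = 0.05, seed = 62)
  ml1 <- train_classifier(tr, seed = 1)
  ml2 <- train_regressor(tr, seed = 2, config = tiny_ml2())
  dir <- withr::local_tempdir()
  ml_save_chain(ml1, ml2, dir)
  chain <- ml_load_chain(dir)
  expect_identical(classify_dataset(chain$ml1, ts), classify_dataset(ml1, ts))
  expect_equal(predict_parameters_dataset(chain$ml2, ts, dataset_kinds(ts)),
               predict_parameters_dataset(ml2, ts, dataset_kinds(ts)))
  meta <- jsonlite::read_json(file.path(dir, "chain.json"))
  expect_equal(meta$n_points, 5)
})

test_that("ML1 trains on noisy curves as well as on clean ones", {
  n_pts <- 8
  clean <- generate_dataset(dataset_spec(n_pts, 400, 400, 0, seed = 71))
  noisy <- generate_dataset(dataset_spec(n_pts, 400, 400, 0.05, seed = 71))
  ts <- generate_dataset(dataset_spec(n_pts, 250, 250, 0.05, seed = 72))
  truth <- dataset_kinds(ts)
  for (tr in list(clean, noisy)) {
    ml1 <- train_classifier(tr, lambda = 1e-5)
    ca <- classification_accuracy(classify_dataset(ml1, ts)$chosen, truth)
    expect_gt(ca, 55)  # clearly above chance either way
  }
})
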