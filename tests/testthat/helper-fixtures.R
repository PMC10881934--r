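# Shared fixtures: exact curves, small datasets, and a light ML2
# configuration for mechanics-level tests (the acceptance tests use the
# full-size defaults).

exact_tac <- function(params, n_points = 10) {
  grid <- make_time_grid(n_points)
  tac_points(grid, evaluate_fia(params, grid), truth = params)
}

noisy_tac <- function(params, n_points = 10, sigma = 0.05, seed = 1) {
  grid <- make_time_grid(n_points)
  fia <- tacfit:::with_seed(seed,
                            add_measurement_noise(evaluate_fia(params, grid),
                                                  sigma))
  tac_points(grid, fia, truth = params, noisy = TRUE)
}

small_dataset <- function(n_points = 6, n_me = 30, n_be = 30, noise = 0,
                          seed = 42, law = "curve") {
  generate_dataset(dataset_spec(n_points, n_me, n_be, noise, seed = seed,
                                law = law))
}

tiny_ml2 <- function() ml2_config(n_learners = 2, nrounds = 60)

me_fixture <- exp_params("MEf", 0.9, 0.05)
be_fixture <- exp_params("BEf", c(0.6, 0.32), c(0.08, 0.012))
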