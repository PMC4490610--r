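test_that("hill_eval reproduces basal, half-maximum and saturation behaviour", {
  p <- hill_params(A = 30, B = 3000, C = 1e-4, n = 2)
  expect_equal(hill_eval(p, 0), 30)
  expect_equal(hill_eval(p, 1e-4), 30 + 3000 / 2)
  expect_equal(hill_eval(p, 1e4), 30 + 3000, tolerance = 1e-8)
  expect_lt(hill_eval(p, 1), 3030)  # bounded strictly below A + B
  expect_error(hill_eval(p, -1), "must be >= 0")
  expect_error(hill_params(A = -1, B = 1, C = 1, n = 1), "A must be")
  expect_error(hill_params(A = 1, B = 1, C = 0, n = 1), "C must be")
})

test_that("hill_eval is monotone non-decreasing and hits B/2 exactly at C", {
  set.seed(11)
  for (k in 1:25) {
    p <- random_hill_params()
    x <- sort(c(0, 10^runif(20, -8, 0)))
    y <- hill_eval(p, x)
    expect_true(all(diff(y) >= -1e-12))
    expect_equal(hill_eval(p, p$C) - p$A, p$B / 2)
  }
})

test_that("normalized_activation is the basal-subtracted fractional form", {
  p <- hill_params(A = 30, B = 3000, C = 1.1e-4, n = 2)
  expect_equal(normalized_activation(p, 0), 0)
  expect_equal(normalized_activation(p, p$C), 0.5)
  expect_equal(normalized_activation(p, 7e-3),
               1 / (1 + (1.1e-4 / 7e-3)^2), tolerance = 1e-12)
  expect_equal(normalized_activation(p, 7e-3), 0.99975, tolerance = 1e-4)
  expect_equal(normalized_activation(p, 5e-4),
               (hill_eval(p, 5e-4) - p$A) / p$B)
  degen <- hill_params(A = 30, B = 0, C = 1e-4, n = 2)
  expect_error(normalized_activation(degen, 1e-4), "degenerate")
})

test_that("rescale_rbs scales A and B by a shared factor and commutes with evaluation", {
  strong <- input_device("pBAD", "arabinose",
                         hill_params(30, 3000, 1.1e-4, 2))
  x_max <- 2.8e-2
  # identity calibration
  same <- rescale_rbs(strong, device_eval(strong, x_max), x_max)
  expect_equal(same$rbs_alpha, 1)
  # alpha = 0.5 halves A and B, leaves C and n untouched
  half <- rescale_rbs(strong, 0.5 * device_eval(strong, x_max), x_max)
  eff <- effective_hill(half)
  expect_equal(eff$A, 15)
  expect_equal(eff$B, 1500)
  expect_equal(eff$C, 1.1e-4)
  expect_equal(eff$n, 2)
  # proportionality identity across the whole grid
  x <- make_grid()$concentrations
  expect_equal(device_eval(half, x), 0.5 * device_eval(strong, x))
  expect_warning(rescale_rbs(strong, 100, x_max = 1e-4 / 10),
                 "not.*saturating|saturating")
  expect_error(rescale_rbs(strong, -5, x_max), "> 0")
})

test_that("rescale_rbs recovers a weak device from one saturating measurement", {
  strong <- input_device("pBAD", "arabinose",
                         hill_params(30, 3000, 1.1e-4, 2))
  true_weak <- input_device("pBAD", "arabinose", strong$hill,
                            rbs_label = "weak", rbs_alpha = 0.3)
  grid <- make_grid()
  sim <- simulate_titration(device_predictor(true_weak, "a"), grid_a = grid,
                            noise = noise_spec(cv = 0.05, floor_sd = 2,
                                               seed = 7))
  norm <- normalize_od(sim)
  y_at_max <- mean(norm$fluorescence[norm$conc_a == max(norm$conc_a)])
  est_weak <- rescale_rbs(strong, y_at_max, max(norm$conc_a))
  expect_equal(est_weak$rbs_alpha, 0.3, tolerance = 0.1)
  # predicted curve tracks the generating truth within the noise envelope
  mu_true <- device_eval(true_weak, grid$concentrations)
  mu_pred <- device_eval(est_weak, grid$concentrations)
  expect_lt(max(abs(mu_pred - mu_true) / (mu_true + 10)), 0.15)
})

test_that("crosstalk_index separates orthogonal from cross-activating devices", {
  cognate <- hill_params(30, 3000, 1.1e-4, 2)
  flat <- titration_dataset(conc_a = rep(make_grid()$concentrations, 2),
                            conc_b = 0,
                            replicate = rep(1:2, each = 17),
                            fluorescence = 30, od600 = 0.5,
                            normalized = TRUE)
  res <- crosstalk_index(flat, cognate, axis = "a")
  expect_lt(res$index, 1e-6)
  expect_true(res$orthogonal)

  x <- make_grid()$concentrations
  full <- titration_dataset(x, 0, 1, hill_eval(cognate, x), 0.5,
                            normalized = TRUE)
  res_full <- crosstalk_index(full, cognate, axis = "a")
  expect_equal(res_full$index, 1, tolerance = 0.01)
  expect_false(res_full$orthogonal)

  # 3 % injected cross-activation
  cross <- titration_dataset(x, 0,
                             1, 30 + 0.03 * 3000 * normalized_activation(cognate, x),
                             0.5, normalized = TRUE)
  res_x <- crosstalk_index(cross, cognate, axis = "a")
  expect_equal(res_x$index, 0.03, tolerance = 0.005)
  expect_true(res_x$orthogonal)
  expect_error(crosstalk_index(flat, hill_params(30, 0, 1e-4, 1), "a"),
               "degenerate")
})

test_that("normalize_od blanks, scales by density and rejects bad rows loudly", {
  d <- titration_dataset(conc_a = c(0, 0, 1e-4), conc_b = 0, replicate = 1,
                         fluorescence = c(50, 1050, 1050),
                         od600 = c(0.5, 0.5, 0.5),
                         blank_fluorescence = 50, blank_od = 0)
  n <- normalize_od(d)
  expect_equal(n$fluorescence, c(0, 2000, 2000))
  bad <- titration_dataset(conc_a = c(0, 1e-4), conc_b = 0, replicate = 1,
                           fluorescence = c(100, 100), od600 = c(0.05, 0.5),
                           blank_fluorescence = 50, blank_od = 0.1)
  expect_warning(nb <- normalize_od(bad), "rejected")
  expect_equal(nrow(nb), 1L)
  expect_error(normalize_od(n), "already")
})

test_that("simulated OD-scaled data normalises back to the model surface", {
  dev <- default_input_devices()$pRHAB
  sim <- simulate_titration(device_predictor(dev, "b"), grid_a = 0,
                            grid_b = make_grid(),
                            noise = noise_spec(cv = 0, floor_sd = 0, seed = 3))
  norm <- normalize_od(sim)
  expect_equal(norm$fluorescence, device_eval(dev, norm$conc_b),
               tolerance = 1e-10)
})
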