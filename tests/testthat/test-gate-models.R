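li <- as.list(logic_inputs())

test_that("and_predict is off with any input absent and multiplies activations", {
  ag <- default_and_gate()
  expect_equal(and_predict(ag, 0, 0), 50)
  expect_equal(and_predict(ag, 0, li$b), 50)
  expect_equal(and_predict(ag, li$a, 0), 50)
  both <- and_predict(ag, li$a, li$b)
  expect_equal(both, 1049, tolerance = 1e-3)
  expect_equal(both - 50,
               1000 * normalized_activation(ag$device_s$hill, li$a) *
                 normalized_activation(ag$device_r$hill, li$b))
  # near-saturating inputs approach G0 + Gmax
  expect_equal(and_predict(ag, 1, 1), 1050, tolerance = 1e-3)
})

test_that("and_predict is symmetric under exchange of identical devices", {
  dev <- default_input_devices()$pBAD
  ag <- and_gate(dev, dev)
  set.seed(21)
  for (k in 1:10) {
    xa <- 10^runif(1, -6, -1); xr <- 10^runif(1, -6, -1)
    expect_equal(and_predict(ag, xa, xr), and_predict(ag, xr, xa))
  }
})

test_that("reporter copy number amplifies output linearly; activator dosage does not", {
  ag <- default_and_gate()
  expect_equal(copy_amplification_ratio(ag, 5, 5), 1)
  expect_equal(copy_amplification_ratio(ag, 100, 5), 20)
  expect_gte(copy_amplification_ratio(ag, 100, 5), 4)
  # activator modules above pHrpL saturation: moving them between copy
  # classes leaves the prediction untouched (copy enters via the reporter
  # module only)
  hi_act <- and_gate(ag$device_s, ag$device_r, reporter_copy = 5)
  lo_act <- and_gate(ag$device_s, ag$device_r, reporter_copy = 5)
  expect_equal(and_predict(hi_act, li$a, li$b),
               and_predict(lo_act, li$a, li$b))
})

test_that("or_predict is additive for functional designs and loses the pBAD arm in design II", {
  og <- default_or_gate()
  expect_equal(or_predict(og, 0, 0), 30 + 25)
  only_a <- or_predict(og, li$a, 0)
  expect_equal(unname(only_a), 3054, tolerance = 1e-3)
  # conservation: exact sum of the two arm evaluations
  set.seed(22)
  for (k in 1:10) {
    xa <- 10^runif(1, -7, -1); xr <- 10^runif(1, -7, -1)
    expect_equal(or_predict(og, xa, xr),
                 device_eval(og$device_a, xa) + device_eval(og$device_b, xr))
  }
  d2 <- default_or_gate(architecture = "tandem_design_II")
  expect_equal(unname(or_predict(d2, li$a, 0)), 25)       # no arabinose response
  expect_equal(unname(or_predict(d2, 0, li$b)),
               unname(device_eval(d2$device_b, li$b)))
  capped <- default_or_gate(saturation_cap = 4000)
  expect_lt(or_predict(capped, li$a, li$b),
            or_predict(og, li$a, li$b))
  expect_lt(or_predict(capped, li$a, li$b), 4000)
})

test_that("repression_factor follows the descending Hill form with site and distance multipliers", {
  rm2 <- repression_model(n_sites = 2, Kr = 0.15, h = 2, leak_floor = 0.02)
  expect_equal(repression_factor(rm2, 0), 1)
  expect_equal(repression_factor(rm2, 0.15), 0.02 + 0.98 / 2)
  expect_equal(repression_factor(rm2, 0.858), 0.049, tolerance = 1e-2)
  # single operator site: negligible repression even at full repressor level
  rm1 <- repression_model(n_sites = 1, Kr = 0.15, h = 2, leak_floor = 0.02)
  expect_gt(repression_factor(rm1, 1), 0.99)
  # distal sites need more repressor for the same transmission
  rm_dist <- repression_model(n_sites = 2, Kr = 0.15, h = 2,
                              leak_floor = 0.02, distance_class = "distal")
  expect_gt(repression_factor(rm_dist, 0.858), repression_factor(rm2, 0.858))
  # monotone non-increasing in cl
  cl <- seq(0, 3, length.out = 50)
  expect_true(all(diff(repression_factor(rm2, cl)) <= 1e-12))
  expect_error(repression_model(n_sites = 3), "unsupported")
  expect_error(repression_factor(rm2, -1), ">= 0")
})

test_that("utr_penalty passes 3 hairpins and blocks 7", {
  expect_equal(utr_penalty(0), 1, tolerance = 1e-4)
  expect_gte(utr_penalty(3), 0.95)
  expect_lte(utr_penalty(7), 0.02)
  expect_true(all(diff(utr_penalty(0:10)) < 0))
  expect_error(utr_penalty(-1), ">= 0")
})

test_that("nimply_predict expresses only with input B and fails with 4 operator sites", {
  cg <- default_composite_gate()
  out <- logic_grid_outputs(function(a, b) nimply_predict(cg, a, b))
  # ON: input B alone, at the arm-sum level times the UTR penalty
  expect_equal(out[3],
               (device_eval(cg$device_a, 0) + device_eval(cg$device_b, li$b)) *
                 utr_penalty(3), tolerance = 1e-6)
  # both inputs: suppressed below 10 % of ON
  expect_lt(out[4], 0.1 * out[3])
  expect_identical(unname(truth_table("nimply", out)),
                   c(FALSE, FALSE, TRUE, FALSE))
  # 4 sites -> 7 accumulated hairpins: dead in every condition
  cg4 <- default_composite_gate(repression = repression_model(n_sites = 4),
                                utr_hairpins = 7)
  out4 <- logic_grid_outputs(function(a, b) nimply_predict(cg4, a, b))
  expect_true(all(out4 < 0.02 * out[3]))
})

test_that("xor_predict is high for exactly one input and degenerates to OR when cl_max -> 0", {
  cg <- default_composite_gate()
  out <- logic_grid_outputs(function(a, b) xor_predict(cg, a, b))
  expect_equal(out[1], (30 + 25) * utr_penalty(3), tolerance = 1e-6)
  expect_identical(unname(truth_table("xor", out)),
                   c(FALSE, TRUE, TRUE, FALSE))
  # single input: repressor effectively absent (product of activations ~ 0)
  expect_equal(out[2],
               (device_eval(cg$device_a, li$a) + device_eval(cg$device_b, 0)) *
                 utr_penalty(3), tolerance = 1e-3)
  # limit equivalence: cl_max -> 0 gives the additive OR surface times u(3)
  cg0 <- default_composite_gate(cl_max = 1e-12)
  og <- default_or_gate()
  set.seed(23)
  for (k in 1:8) {
    xa <- 10^runif(1, -7, -1); xr <- 10^runif(1, -7, -1)
    expect_equal(xor_predict(cg0, xa, xr),
                 or_predict(og, xa, xr) * utr_penalty(3), tolerance = 1e-9)
  }
})

test_that("activator competition shares follow copy-number weighting", {
  expect_equal(unname(competition_shares(gamma = 0)), c(0.5, 0.5))
  w <- competition_shares(5, 100, 0.6)
  expect_equal(sum(w), 1)
  expect_equal(1 / w[["w_low"]], 1 + 20^0.6)
  # closed form matches brute-force share computation
  set.seed(24)
  for (k in 1:20) {
    cl <- sample(1:20, 1); ch <- sample(20:300, 1); g <- runif(1, 0, 1.5)
    w <- competition_shares(cl, ch, g)
    expect_equal(w[["w_low"]], cl^g / (cl^g + ch^g))
    expect_equal(1 / w[["w_low"]], 1 + (ch / cl)^g)
  }
})

test_that("half adder produces XOR SUM and AND CARRY with a ~7x competition cost on CARRY", {
  cg <- default_composite_gate()
  ha <- lapply(seq_len(4), function(i) {
    cond <- logic_conditions()
    half_adder_predict(cg, cond$conc_a[i], cond$conc_b[i])
  })
  sums <- vapply(ha, `[[`, 0, "sum_out")
  carries <- vapply(ha, `[[`, 0, "carry_out")
  expect_identical(unname(truth_table("half_adder_sum", sums)),
                   expected_truth_table("half_adder_sum"))
  expect_identical(unname(truth_table("half_adder_carry", carries)),
                   expected_truth_table("half_adder_carry"))
  standalone <- and_predict(cg$and_gate, li$a, li$b) - cg$and_gate$G0
  ratio <- unname(standalone / (carries[4] - cg$and_gate$G0))
  expect_equal(ratio, 1 + (100 / 5)^0.6, tolerance = 1e-10)
  expect_equal(ratio, 7, tolerance = 0.05)
})

test_that("half subtractor: DIFFERENCE is XOR, BORROW is A AND NOT B", {
  cg <- default_composite_gate()
  cond <- logic_conditions()
  hs <- lapply(seq_len(4), function(i)
    half_subtractor_predict(cg, cond$conc_a[i], cond$conc_b[i]))
  diffs <- vapply(hs, `[[`, 0, "difference_out")
  borrows <- vapply(hs, `[[`, 0, "borrow_out")
  expect_identical(unname(truth_table("half_subtractor_difference", diffs)),
                   expected_truth_table("half_subtractor_difference"))
  expect_identical(unname(truth_table("half_subtractor_borrow", borrows)),
                   expected_truth_table("half_subtractor_borrow"))
  # A alone: both outputs ON; both inputs: both suppressed
  expect_gt(borrows[2], 0.5 * max(borrows))
  expect_lt(borrows[4], 0.1 * borrows[2])
  expect_lt(diffs[4], 0.2 * mean(diffs[2:3]))
  # no input: both at (penalised) basal
  expect_equal(borrows[1], 30 * utr_penalty(3), tolerance = 1e-6)
})

test_that("all gate outputs are non-negative and finite over random inputs", {
  cg <- default_composite_gate()
  og <- default_or_gate()
  set.seed(25)
  for (k in 1:20) {
    xa <- 10^runif(1, -8, 0); xr <- 10^runif(1, -8, 0)
    vals <- c(and_predict(cg$and_gate, xa, xr), or_predict(og, xa, xr),
              nimply_predict(cg, xa, xr), xor_predict(cg, xa, xr),
              unlist(half_adder_predict(cg, xa, xr)),
              unlist(half_subtractor_predict(cg, xa, xr)))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})
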