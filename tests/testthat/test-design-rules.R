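# compact builders for DRC fixtures -----------------------------------------

prom <- function(name, sigma = "sigma70", dual = FALSE, inducer = NULL,
                 sites = 0, site_id = "CI2A") {
  list(name = name, sigma_class = sigma, regulator = if (dual) "AraC" else "X",
       regulator_dual_function = dual, inducer = inducer,
       operator_sites = rep(list(list(identity = site_id,
                                      dyad_perfect = TRUE)), sites))
}

cassette <- function(plasmid, promoters, cds = "RFP", alpha = 1) {
  list(plasmid = plasmid, promoters = promoters,
       rbs = list(label = "rbs", alpha = alpha), cds = cds,
       terminator = TRUE)
}

design_of <- function(cassettes, evidence = list(),
                      plasmids = list(list(id = "p1", copy_class = "high"),
                                      list(id = "p2", copy_class = "low"))) {
  circuit_design(plasmids, cassettes, evidence)
}

test_that("check_crosstalk warns per unevidenced input-device pair", {
  two <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose")), "GFP"),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "RFP")))
  expect_equal(nrow(check_crosstalk(two)), 1L)
  evidenced <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose")), "GFP"),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "RFP")),
    evidence = list("pBAD|pRHAB" = TRUE))
  expect_equal(nrow(check_crosstalk(evidenced)), 0L)
  three <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose")), "GFP"),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "RFP"),
    cassette("p2", list(prom("pTET", inducer = "aTc")), "YFP")),
    evidence = list("pBAD|pRHAB" = TRUE))
  expect_equal(nrow(check_crosstalk(three)), 2L)  # 3 choose 2 minus 1
})

test_that("check_sigma54_proximity flags the downstream co-resident sigma-54 promoter", {
  same <- design_of(list(
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "lambdaCI"),
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "GFP")))
  v <- check_sigma54_proximity(same)
  expect_equal(nrow(v), 1L)
  expect_equal(v$severity, "error")
  expect_equal(v$cassette, 2L)  # the downstream cassette is at risk
  split_design <- design_of(list(
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "lambdaCI"),
    cassette("p2", list(prom("pHrpL", sigma = "sigma54")), "GFP")))
  expect_equal(nrow(check_sigma54_proximity(split_design)), 0L)
  single <- design_of(list(
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "GFP")))
  expect_equal(nrow(check_sigma54_proximity(single)), 0L)
})

test_that("plasmid separation is a monotone repair for a sigma-54 violation", {
  same <- design_of(list(
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "lambdaCI"),
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "GFP")))
  before <- run_drc(same)
  expect_true(attr(before, "has_errors"))
  repaired <- design_of(list(
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "lambdaCI"),
    cassette("p2", list(prom("pHrpL", sigma = "sigma54")), "GFP")))
  after <- run_drc(repaired)
  expect_false(attr(after, "has_errors"))
  # exactly the sigma-54 violation disappears and nothing new appears
  expect_identical(setdiff(before$rule_id, after$rule_id),
                   "sigma54_proximity")
  expect_length(setdiff(after$rule_id, before$rule_id), 0)
})

test_that("check_tandem_interference: dual-function regulator must not sit downstream", {
  bad <- design_of(list(cassette("p1", list(
    prom("pRHAB", inducer = "rhamnose"),
    prom("pBAD", dual = TRUE, inducer = "arabinose")))))
  v <- check_tandem_interference(bad)
  expect_equal(v$severity, "error")
  good <- design_of(list(cassette("p1", list(
    prom("pBAD", dual = TRUE, inducer = "arabinose"),
    prom("pRHAB", inducer = "rhamnose")))))
  expect_equal(nrow(check_tandem_interference(good)), 0L)
  dual_cassette <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose"))),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")))))
  expect_equal(nrow(check_tandem_interference(dual_cassette)), 0L)
})

test_that("check_operator_repeats grades 1, 2 and 4+ identical sites correctly", {
  four <- design_of(list(cassette("p1", list(prom("pBAD", sites = 4)))))
  v4 <- check_operator_repeats(four)
  expect_equal(v4$rule_id, "operator_repeat_4x")
  expect_equal(v4$severity, "error")
  one <- design_of(list(cassette("p1", list(prom("pBAD", sites = 1)))))
  v1 <- check_operator_repeats(one)
  expect_equal(v1$rule_id, "operator_single_site")
  expect_equal(v1$severity, "warning")
  # dual sites within a single promoter's transcript: the working NIMPLY
  two_same <- design_of(list(cassette("p1", list(prom("pBAD", sites = 2)))))
  expect_equal(nrow(check_operator_repeats(two_same)), 0L)
  # identical sites split across the arms of a tandem transcript
  split_arms <- design_of(list(cassette("p1", list(
    prom("pBAD", sites = 1), prom("pRHAB", sites = 1)))))
  va <- check_operator_repeats(split_arms)
  expect_equal(va$rule_id, "operator_tandem_repeat")
  expect_equal(va$severity, "warning")
})

test_that("check_rbs_balance flags stoichiometric mismatch and leak-prone NOT stages", {
  devs <- default_input_devices()
  matched <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose")),
             "HrpS"),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "HrpR")))
  expect_equal(nrow(check_rbs_balance(matched, devs)), 0L)
  mismatched <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose")),
             "HrpS", alpha = 1),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "HrpR",
             alpha = 0.1)))
  vm <- check_rbs_balance(mismatched, devs)
  expect_equal(vm$rule_id, "rbs_imbalance")
  leaky_not <- design_of(list(
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose",
                             sites = 2)), "RFP", alpha = 1)))
  vl <- check_rbs_balance(leaky_not, devs)
  expect_true("not_gate_strong_rbs" %in% vl$rule_id)
  missing_dev <- design_of(list(
    cassette("p1", list(prom("pNEW", inducer = "iptg")), "HrpS"),
    cassette("p1", list(prom("pRHAB", inducer = "rhamnose")), "HrpR")))
  expect_error(check_rbs_balance(missing_dev, devs), "configuration error")
})

test_that("run_drc is deterministic, clean on the half adder, failing on XOR design II", {
  devs <- default_input_devices()
  ha <- half_adder_design()
  r1 <- run_drc(ha, devs)
  r2 <- run_drc(ha, devs)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(attr(r1, "has_errors"))
  expect_equal(sum(r1$severity == "error"), 0L)

  # XOR design II: tandem hybrid promoters, identical operator sites repeated
  # in one transcript
  xor2 <- design_of(list(
    cassette("p2", list(prom("pBAD", dual = TRUE, inducer = "arabinose")), "HrpS"),
    cassette("p2", list(prom("pRHAB", inducer = "rhamnose")), "HrpR"),
    cassette("p1", list(prom("pHrpL", sigma = "sigma54")), "lambdaCI"),
    cassette("p1", list(prom("pBAD", dual = TRUE, inducer = "arabinose",
                             sites = 2),
                        prom("pRHAB", inducer = "rhamnose", sites = 2)),
             "RFP")),
    evidence = list("pBAD|pRHAB" = TRUE))
  rx <- run_drc(xor2, devs)
  expect_true(attr(rx, "has_errors"))
  expect_true("operator_repeat_4x" %in% rx$rule_id)

  empty <- circuit_design(list(list(id = "p1", copy_class = "low")), list())
  expect_equal(nrow(run_drc(empty)), 0L)
})

test_that("every documented failure mode maps to an existing check", {
  tab <- drc_rule_table()
  expect_gte(nrow(tab), 9L)
  for (fn in unique(tab$check)) {
    expect_true(is.function(getExportedValue("gatestack", fn)), info = fn)
  }
  # the aggregate runner exercises every listed check
  expect_setequal(unique(tab$check),
                  c("check_crosstalk", "check_rbs_balance",
                    "check_sigma54_proximity", "check_tandem_interference",
                    "check_operator_repeats"))
})

test_that("circuit designs round-trip through JSON", {
  ha <- half_adder_design()
  path <- withr::local_tempfile(fileext = ".json")
  write_circuit_json(ha, path)
  back <- read_circuit_json(path)
  devs <- default_input_devices()
  expect_identical(as.data.frame(run_drc(ha, devs)),
                   as.data.frame(run_drc(back, devs)))
})
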