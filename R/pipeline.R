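#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown fields are
#' rejected so that typos cannot silently change a run.
#'
#' @param seed Integer RNG seed used by every stochastic stage.
#' @param out_dir Output directory for the report bundle.
#' @param replicates Replicates per condition in the simulated experiments.
#' @param cv,floor_sd Noise parameters (see [noise_spec()]).
#' @param threshold_frac Digital-call threshold fraction
#'   (see [threshold_calls()]).
#' @param orthogonality_threshold Crosstalk-index call threshold.
#' @param drc_max_ratio Tolerated RBS imbalance (see [check_rbs_balance()]).
#' @param ... Must be empty; any extra argument is an error.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, replicates = 3,
                       cv = 0.05, floor_sd = 2, threshold_frac = 0.4,
                       orthogonality_threshold = 0.05, drc_max_ratio = 5,
                       ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration field(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer.", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 replicates = replicates, cv = cv, floor_sd = floor_sd,
                 threshold_frac = threshold_frac,
                 orthogonality_threshold = orthogonality_threshold,
                 drc_max_ratio = drc_max_ratio),
            class = "run_config")
}

#' Reference half-adder circuit description
#'
#' The working architecture: pHrpL-GFP (CARRY) on the low-copy plasmid;
#' pHrpL-lambdaCI plus the two hybrid reporter cassettes (pBAD-CI2 and
#' pRHAB-CI2, two operator sites each) on the high-copy plasmid; input
#' devices evidenced as orthogonal.
#'
#' @return A [circuit_design()].
#' @export
half_adder_design <- function() {
  circuit_design(
    plasmids = list(list(id = "pLow", copy_class = "low"),
                    list(id = "pHigh", copy_class = "high")),
    cassettes = list(
      list(plasmid = "pLow",
           promoters = list(list(name = "pHrpL", sigma_class = "sigma54")),
           rbs = list(label = "strong", alpha = 1), cds = "GFP"),
      list(plasmid = "pLow",
           promoters = list(list(name = "pBAD", sigma_class = "sigma70",
                                 regulator = "AraC",
                                 regulator_dual_function = TRUE,
                                 inducer = "arabinose")),
           rbs = list(label = "strong", alpha = 1), cds = "HrpS"),
      list(plasmid = "pLow",
           promoters = list(list(name = "pRHAB", sigma_class = "sigma70",
                                 regulator = "RhaS",
                                 inducer = "rhamnose")),
           rbs = list(label = "strong", alpha = 1), cds = "HrpR"),
      list(plasmid = "pHigh",
           promoters = list(list(name = "pHrpL", sigma_class = "sigma54")),
           rbs = list(label = "strong", alpha = 1), cds = "lambdaCI"),
      list(plasmid = "pHigh",
           promoters = list(list(
             name = "pBAD", sigma_class = "sigma70", regulator = "AraC",
             regulator_dual_function = TRUE, inducer = "arabinose",
             operator_sites = list(list(identity = "CI2B", dyad_perfect = FALSE),
                                   list(identity = "CI2B", dyad_perfect = FALSE)))),
           rbs = list(label = "weak", alpha = 0.4), cds = "RFP"),
      list(plasmid = "pHigh",
           promoters = list(list(
             name = "pRHAB", sigma_class = "sigma70", regulator = "RhaS",
             inducer = "rhamnose",
             operator_sites = list(list(identity = "CI2B", dyad_perfect = FALSE),
                                   list(identity = "CI2B", dyad_perfect = FALSE)))),
           rbs = list(label = "weak", alpha = 0.4), cds = "RFP")),
    orthogonality_evidence = list("pBAD|pRHAB" = TRUE))
}

#' Run the end-to-end characterisation pipeline
#'
#' Simulate titrations for the two input devices, fit their Hill transfer
#' functions, assemble the default composite model around the fitted devices,
#' predict the four logic conditions for the half adder, evaluate digital
#' performance of both channels, and run the design-rule checker over the
#' half-adder architecture. When `config$out_dir` is set, writes
#' `report.json`, the fitted device JSONs and the prediction CSV there.
#'
#' @param config A [run_config()].
#' @return List with `devices`, `fits`, `model`, `performance` (per channel
#'   [evaluate_digital()] results), `drc` ([run_drc()] report) and `ok`
#'   (TRUE iff both truth tables pass and the DRC reports no errors).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- default_input_devices()
  grid <- make_grid()

  fits <- list(); devices <- list()
  for (k in seq_along(truth)) {
    dev <- truth[[k]]
    axis <- if (k == 1L) "a" else "b"
    sim <- simulate_titration(
      device_predictor(dev, axis),
      grid_a = if (axis == "a") grid else 0,
      grid_b = if (axis == "b") grid else 0,
      replicates = config$replicates,
      noise = noise_spec(config$cv, config$floor_sd,
                         seed = config$seed + k),
      device = dev$name)
    fit <- fit_hill(normalize_od(sim), axis = axis)
    fits[[dev$name]] <- fit
    devices[[dev$name]] <- input_device(dev$name, dev$inducer, fit$params)
  }

  model <- composite_gate(and_gate(devices$pBAD, devices$pRHAB))
  cond <- logic_conditions()
  ha <- mapply(function(xa, xr) unlist(half_adder_predict(model, xa, xr)),
               cond$conc_a, cond$conc_b)
  predictions <- data.frame(condition = cond$condition,
                            conc_a_M = cond$conc_a, conc_b_M = cond$conc_b,
                            sum_au = ha["sum_out", ],
                            carry_au = ha["carry_out", ])

  performance <- list(
    sum = evaluate_digital(predictions$sum_au, "half_adder_sum",
                           config$threshold_frac),
    carry = evaluate_digital(predictions$carry_au, "half_adder_carry",
                             config$threshold_frac))
  drc <- run_drc(half_adder_design(), devices,
                 max_ratio = config$drc_max_ratio)
  ok <- performance$sum$passes && performance$carry$passes &&
    !isTRUE(attr(drc, "has_errors"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(devices))
      write_device_json(devices[[nm]],
                        file.path(config$out_dir, paste0(nm, ".json")))
    utils::write.csv(predictions,
                     file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- list(
      seed = config$seed,
      devices = lapply(devices, function(d)
        c(d$hill[c("A", "B", "C", "n")], rbs_alpha = d$rbs_alpha)),
      performance = lapply(performance, function(p)
        list(mean_au = as.list(p$mean), delta_au = p$delta,
             fold_change = p$fold_change, leak_pct = p$leak_pct,
             truth_table = as.integer(p$truth_table),
             passes = p$passes)),
      drc = as.data.frame(drc), ok = ok)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(devices = devices, fits = fits, model = model,
       performance = performance, drc = drc, ok = ok)
}
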