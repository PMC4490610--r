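#' Four-condition logic induction set
#'
#' The four induction conditions used for digital characterisation, in fixed
#' order (0,0), (A,0), (0,B), (A,B) with defaults 7 mM arabinose and 28 mM
#' rhamnose.
#'
#' @param a Input A (arabinose) level, mol/L, > 0.
#' @param b Input B (rhamnose) level, mol/L, > 0.
#' @return data.frame with columns `condition`, `conc_a`, `conc_b`.
#' @export
logic_conditions <- function(a = logic_inputs()["a"],
                             b = logic_inputs()["b"]) {
  if (a <= 0 || b <= 0) stop("input levels must be > 0.", call. = FALSE)
  data.frame(condition = c("00", "A0", "0B", "AB"),
             conc_a = unname(c(0, a, 0, a)),
             conc_b = unname(c(0, 0, b, b)),
             stringsAsFactors = FALSE)
}

#' Expected Boolean truth tables
#'
#' Reference output patterns over the condition order (0,0), (A,0), (0,B),
#' (A,B). The half adder follows the operational channel assignment of the
#' physical device (CARRY = GFP from the AND gate, SUM = RFP from the XOR
#' path); the half subtractor's BORROW is A AND NOT B (GFP produced only
#' with input A), as realised by its pBAD-driven borrow module.
#'
#' @param gate_kind One of `"and"`, `"or"`, `"nimply"`, `"xor"`,
#'   `"half_adder_sum"`, `"half_adder_carry"`,
#'   `"half_subtractor_difference"`, `"half_subtractor_borrow"`.
#' @return Logical vector of length 4.
#' @export
expected_truth_table <- function(gate_kind) {
  tables <- list(
    and = c(FALSE, FALSE, FALSE, TRUE),
    or = c(FALSE, TRUE, TRUE, TRUE),
    nimply = c(FALSE, FALSE, TRUE, FALSE),      # B AND NOT A
    xor = c(FALSE, TRUE, TRUE, FALSE),
    half_adder_sum = c(FALSE, TRUE, TRUE, FALSE),
    half_adder_carry = c(FALSE, FALSE, FALSE, TRUE),
    half_subtractor_difference = c(FALSE, TRUE, TRUE, FALSE),
    half_subtractor_borrow = c(FALSE, TRUE, FALSE, FALSE))  # A AND NOT B
  if (!gate_kind %in% names(tables))
    stop("unknown gate_kind '", gate_kind, "'.", call. = FALSE)
  tables[[gate_kind]]
}

#' Threshold four-condition outputs into Boolean calls
#'
#' A condition is called ON when its output reaches
#' `min + threshold_frac * (max - min)` of the channel's observed dynamic
#' range. The call is range-relative, hence invariant under affine rescaling
#' of the outputs.
#'
#' @param outputs Numeric vector of 4 outputs in condition order (0,0),
#'   (A,0), (0,B), (A,B).
#' @param threshold_frac Fraction of the dynamic range (default 0.4).
#' @return Logical vector of length 4.
#' @export
threshold_calls <- function(outputs, threshold_frac = 0.4) {
  if (length(outputs) != 4L || any(!is.finite(outputs)))
    stop("need 4 finite outputs in condition order.", call. = FALSE)
  rng <- range(outputs)
  if (diff(rng) == 0)
    stop("undefined metric: outputs have zero dynamic range.", call. = FALSE)
  outputs >= rng[1L] + threshold_frac * diff(rng)
}

#' @rdname threshold_calls
#' @param gate_kind Gate kind (see [expected_truth_table()]); used only to
#'   validate the name.
#' @export
truth_table <- function(gate_kind, outputs, threshold_frac = 0.4) {
  expected_truth_table(gate_kind)  # validates gate_kind
  threshold_calls(outputs, threshold_frac)
}

#' Digital performance of a four-condition experiment
#'
#' Computes the standard digital metrics from per-condition outputs:
#'
#' * `delta` — mean output over expected-ON conditions minus the maximum
#'   output over expected-OFF conditions (au);
#' * `fold_change` — ON mean / OFF max;
#' * `leak_pct` — `100 * (worst expected-OFF output - min output) /
#'   (ON mean - min output)`: residual OFF-state output as a percentage of
#'   the ON level, with the global minimum subtracted so that shared basal
#'   output does not inflate the leak;
#' * `truth_table` — thresholded calls (see [threshold_calls()]) and
#'   `passes`, their agreement with the expected table.
#'
#' @param outputs Either a numeric vector of 4 condition means, or a
#'   data.frame with columns `condition` and `fluorescence` (replicates are
#'   averaged; condition levels must be `00`, `A0`, `0B`, `AB`).
#' @param expected Logical vector of length 4 (see
#'   [expected_truth_table()]), or a gate kind string.
#' @param threshold_frac Fraction of dynamic range for the ON call.
#' @return An object of class `digital_performance`.
#' @export
evaluate_digital <- function(outputs, expected, threshold_frac = 0.4) {
  if (is.character(expected)) expected <- expected_truth_table(expected)
  if (length(expected) != 4L || !is.logical(expected))
    stop("expected table must be 4 logicals.", call. = FALSE)
  if (all(expected) || !any(expected))
    stop("undefined metric: expected table must contain both ON and OFF conditions.",
         call. = FALSE)
  cond_order <- c("00", "A0", "0B", "AB")
  if (is.data.frame(outputs)) {
    if (!all(c("condition", "fluorescence") %in% names(outputs)))
      stop("outputs data.frame needs 'condition' and 'fluorescence' columns.",
           call. = FALSE)
    mean_au <- vapply(cond_order, function(cc)
      mean(outputs$fluorescence[outputs$condition == cc]), 0)
    sd_au <- vapply(cond_order, function(cc)
      stats::sd(outputs$fluorescence[outputs$condition == cc]), 0)
  } else {
    if (length(outputs) != 4L)
      stop("need 4 condition outputs.", call. = FALSE)
    mean_au <- as.numeric(outputs)
    sd_au <- rep(0, 4L)
  }
  names(mean_au) <- names(sd_au) <- cond_order
  calls <- threshold_calls(mean_au, threshold_frac)
  on_mean <- mean(mean_au[expected])
  off_max <- max(mean_au[!expected])
  leak <- 100 * (off_max - min(mean_au)) / (on_mean - min(mean_au))
  structure(list(mean = mean_au, sd = sd_au,
                 delta = on_mean - off_max,
                 fold_change = on_mean / off_max,
                 leak_pct = leak,
                 truth_table = unname(calls),
                 expected_table = unname(expected),
                 passes = identical(unname(calls), unname(expected)),
                 threshold_frac = threshold_frac),
            class = "digital_performance")
}

#' @export
print.digital_performance <- function(x, ...) {
  cat("Digital performance (conditions 00, A0, 0B, AB)\n")
  cat("  means (au):", paste(sprintf("%.4g", x$mean), collapse = ", "), "\n")
  cat(sprintf("  delta = %.4g au, fold change = %.3g, leak = %.3g%%\n",
              x$delta, x$fold_change, x$leak_pct))
  cat("  calls:   ", paste(as.integer(x$truth_table), collapse = ""),
      if (x$passes) " (matches expected)" else
        paste0(" (expected ", paste(as.integer(x$expected_table),
                                    collapse = ""), ")"), "\n", sep = "")
  invisible(x)
}

#' Classify a flow-cytometry population
#'
#' Gates a single-channel event population at a fluorescence threshold:
#' reports the fraction of events above the gate, the population median, and
#' an ON/OFF call by whether the median clears the gate.
#'
#' @param sample A [flow_sample()] (or numeric vector of event
#'   fluorescences, au, all > 0).
#' @param gate_threshold Gate position (au).
#' @return List with `fraction_on`, `median`, `call` (`"ON"`/`"OFF"`).
#' @export
classify_flow <- function(sample, gate_threshold) {
  events <- if (inherits(sample, "flow_sample")) sample$events else sample
  if (!is.numeric(events) || any(events <= 0))
    stop("flow events must be positive fluorescence values.", call. = FALSE)
  if (length(events) < 100L)
    stop("need at least 100 events to classify a population.", call. = FALSE)
  med <- stats::median(events)
  list(fraction_on = mean(events > gate_threshold),
       median = med,
       call = if (med > gate_threshold) "ON" else "OFF")
}
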