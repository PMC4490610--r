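#' Inducible input device
#'
#' A named promoter + ribosome binding site (RBS) unit with a fitted Hill
#' transfer function. RBS strength enters as a proportional factor
#' `rbs_alpha` applied to both the basal output A and the dynamic range B;
#' the switch point C and cooperativity n are properties of the
#' promoter/inducer pair and are left unchanged.
#'
#' @param name Device identifier (e.g. `"pBAD"`).
#' @param inducer Inducer identifier (e.g. `"arabinose"`).
#' @param hill A [hill_params()] object: the transfer function measured with
#'   the reference (strong) RBS.
#' @param rbs_label RBS identifier; `"strong"` denotes the reference.
#' @param rbs_alpha Proportional RBS scale factor (> 0); 1 = reference RBS.
#' @return An object of class `input_device`.
#' @examples
#' dev <- input_device("pBAD", "arabinose", hill_params(30, 3000, 1.1e-4, 2))
#' device_eval(dev, 7e-3)
#' @export
input_device <- function(name, inducer, hill, rbs_label = "strong",
                         rbs_alpha = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(inducer), length(inducer) == 1L)
  if (!is.numeric(rbs_alpha) || length(rbs_alpha) != 1L ||
      !is.finite(rbs_alpha) || rbs_alpha <= 0)
    stop("rbs_alpha must be a single finite number > 0.", call. = FALSE)
  structure(list(name = name, inducer = inducer,
                 rbs_label = rbs_label, rbs_alpha = rbs_alpha,
                 hill = as_hill_params(hill)),
            class = "input_device")
}

#' @export
print.input_device <- function(x, ...) {
  cat(sprintf("Input device %s (inducer: %s, RBS: %s, alpha = %.3g)\n",
              x$name, x$inducer, x$rbs_label, x$rbs_alpha))
  print(effective_hill(x))
  invisible(x)
}

#' Effective Hill parameters of a device
#'
#' Applies the RBS scale factor: `(alpha * A, alpha * B, C, n)`.
#'
#' @param device An [input_device()].
#' @return A [hill_params()] object.
#' @export
effective_hill <- function(device) {
  stopifnot(inherits(device, "input_device"))
  with(device, hill_params(rbs_alpha * hill$A, rbs_alpha * hill$B,
                           hill$C, hill$n))
}

#' Evaluate a device's effective transfer function
#'
#' @param device An [input_device()].
#' @param x Inducer concentration(s), mol/L.
#' @return Output (au), RBS scaling applied.
#' @export
device_eval <- function(device, x) {
  hill_eval(effective_hill(device), x)
}

#' Rescale a characterised device to a weaker RBS
#'
#' Given a fully characterised (strong-RBS) device and a single measurement of
#' a weaker-RBS variant's output at a saturating inducer concentration, returns
#' the predicted weaker device: A and B are scaled by the shared factor
#' `alpha = y_weak_at_max / hill_eval(strong, x_max)`; C and n are unchanged.
#' This gives a-priori transfer functions for RBS variants from one
#' calibration point instead of a full titration.
#'
#' @param strong The characterised reference [input_device()].
#' @param y_weak_at_max Measured output of the weaker variant at `x_max` (au),
#'   must be > 0.
#' @param x_max Calibration inducer concentration (mol/L); should be
#'   saturating (at least 4 times the switch point C), otherwise a warning is
#'   issued.
#' @param rbs_label Label for the new RBS (default `"weak"`).
#' @return A new [input_device()] with the rescaled transfer function.
#' @export
rescale_rbs <- function(strong, y_weak_at_max, x_max, rbs_label = "weak") {
  stopifnot(inherits(strong, "input_device"))
  if (!is.numeric(y_weak_at_max) || length(y_weak_at_max) != 1L ||
      y_weak_at_max <= 0)
    stop("y_weak_at_max must be a single value > 0.", call. = FALSE)
  eff <- effective_hill(strong)
  if (x_max < 4 * eff$C)
    warning("calibration point x_max is below 4*C; the measurement is not ",
            "saturating and the inferred RBS factor will be biased.",
            call. = FALSE)
  alpha <- y_weak_at_max / hill_eval(eff, x_max)
  input_device(name = strong$name, inducer = strong$inducer,
               hill = strong$hill, rbs_label = rbs_label,
               rbs_alpha = strong$rbs_alpha * alpha)
}

#' Inducer crosstalk index
#'
#' Quantifies activation of a device by a NON-cognate inducer: the mean
#' OD-normalised output at the highest non-cognate concentration minus the
#' mean output at zero, expressed as a fraction of the cognate dynamic
#' range B. Devices are called orthogonal when the index is below
#' `threshold`.
#'
#' @param data A [titration_dataset()] of the device's response to its
#'   non-cognate inducer (normalised, see [normalize_od()]).
#' @param cognate_fit [hill_params()] of the device's cognate response.
#' @param axis Which concentration column varies: `"a"` or `"b"`.
#' @param threshold Orthogonality call threshold (default 0.05).
#' @return A list with `index` (dimensionless) and `orthogonal` (logical).
#' @export
crosstalk_index <- function(data, cognate_fit, axis = c("a", "b"),
                            threshold = 0.05) {
  axis <- match.arg(axis)
  cognate_fit <- as_hill_params(cognate_fit)
  if (cognate_fit$B <= 0)
    stop("degenerate cognate fit: B must be > 0.", call. = FALSE)
  x <- data[[paste0("conc_", axis)]]
  y <- data$fluorescence
  y_top <- mean(y[x == max(x)])
  y_zero <- mean(y[x == min(x)])
  idx <- (y_top - y_zero) / cognate_fit$B
  list(index = idx, orthogonal = idx < threshold)
}

#' Write / read a fitted device as JSON
#'
#' Serialises the effective parameter set
#' `{"A":…, "B":…, "C":…, "n":…, "rbs_alpha":…}` together with the device
#' identity fields.
#'
#' @param device An [input_device()].
#' @param path Output file.
#' @return `write_device_json` returns `path` invisibly; `read_device_json`
#'   returns an [input_device()].
#' @export
write_device_json <- function(device, path) {
  stopifnot(inherits(device, "input_device"))
  obj <- list(schema_version = 1L,
              name = device$name, inducer = device$inducer,
              rbs_label = device$rbs_label,
              A = device$hill$A, B = device$hill$B,
              C = device$hill$C, n = device$hill$n,
              rbs_alpha = device$rbs_alpha)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_device_json
#' @export
read_device_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("name", "inducer", "A", "B", "C", "n")
  if (!all(needed %in% names(obj)))
    stop("device JSON is missing fields: ",
         paste(setdiff(needed, names(obj)), collapse = ", "), call. = FALSE)
  input_device(obj$name, obj$inducer,
               hill_params(obj$A, obj$B, obj$C, obj$n),
               rbs_label = if (is.null(obj$rbs_label)) "strong" else obj$rbs_label,
               rbs_alpha = if (is.null(obj$rbs_alpha)) 1 else obj$rbs_alpha)
}
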