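#' Serial-dilution concentration grid
#'
#' Geometric dilution series generated upward from the smallest non-zero
#' concentration: `start * fold^k`, k = 0..n_nonzero-1, optionally prefixed
#' with 0. The defaults reproduce the 17-point twofold series used for
#' characterisation (0 M, 8.38e-7 M doubling up to 2.75e-2 M at 3
#' significant figures).
#'
#' @param start Smallest non-zero concentration (mol/L), > 0.
#' @param fold Dilution factor between successive points, > 0.
#' @param n_nonzero Number of non-zero points, >= 1.
#' @param include_zero Prepend a zero-inducer point?
#' @return An object of class `dilution_grid`: list with `concentrations`
#'   (sorted, mol/L), `top`, `fold`, `n_nonzero`.
#' @examples
#' g <- make_grid()
#' signif(g$top, 3)  # 0.0275
#' @export
make_grid <- function(start = 8.38e-7, fold = 2, n_nonzero = 16,
                      include_zero = TRUE) {
  if (!is.numeric(start) || start <= 0)
    stop("start concentration must be > 0.", call. = FALSE)
  if (!is.numeric(fold) || fold <= 0)
    stop("dilution fold must be > 0.", call. = FALSE)
  if (n_nonzero < 1L) stop("n_nonzero must be >= 1.", call. = FALSE)
  conc <- start * fold^(seq_len(n_nonzero) - 1L)
  if (include_zero) conc <- c(0, conc)
  structure(list(concentrations = conc, top = max(conc), fold = fold,
                 n_nonzero = as.integer(n_nonzero)),
            class = "dilution_grid")
}

#' Export a dilution grid at 3 significant figures
#'
#' @param grid A [make_grid()] object.
#' @return Character vector of concentrations in scientific notation, 3
#'   significant figures (e.g. `"2.75e-02"`), with zero rendered `"0.00e+00"`.
#' @export
format_grid <- function(grid) {
  stopifnot(inherits(grid, "dilution_grid"))
  sprintf("%.2e", grid$concentrations)
}

#' Measurement noise specification
#'
#' Multiplicative lognormal noise (coefficient of variation `cv`) with an
#' additive background floor (`floor_sd`), emulating plate-reader error that
#' scales with signal plus detector background.
#'
#' @param cv Lognormal coefficient of variation, >= 0 (default 0.05).
#' @param floor_sd Additive background SD (au), >= 0 (default 2).
#' @param seed Integer RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(cv = 0.05, floor_sd = 2, seed = 1L) {
  if (cv < 0 || floor_sd < 0)
    stop("cv and floor_sd must be >= 0.", call. = FALSE)
  structure(list(cv = cv, floor_sd = floor_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Single-axis predictor from a device
#'
#' Wraps an [input_device()] as a two-argument predictor `f(xa, xb)` that
#' responds only along the chosen axis, for use with the simulators.
#'
#' @param device An [input_device()].
#' @param axis `"a"` or `"b"`: which inducer the device responds to.
#' @return Function of `(xa, xb)` returning au.
#' @export
device_predictor <- function(device, axis = c("a", "b")) {
  axis <- match.arg(axis)
  force(device)
  if (axis == "a") function(xa, xb) device_eval(device, xa)
  else function(xa, xb) device_eval(device, xb)
}

#' Simulate a plate-reader titration experiment
#'
#' Draws replicate measurements of a steady-state predictor over a
#' concentration grid: the per-cell output is
#' `y = f(xa, xb) * exp(sigma * Z) + N(0, floor_sd)` with
#' `sigma = sqrt(log(1 + cv^2))`; the culture density is simulated at
#' OD600 0.5 with 5 % jitter and the recorded fluorescence column stores
#' `y * od600`, so [normalize_od()] recovers the per-cell output.
#'
#' @param predictor Function `(xa, xb) -> au`, e.g. [device_predictor()],
#'   or a one-sided gate wrapper.
#' @param grid_a,grid_b [make_grid()] objects or numeric concentration
#'   vectors for the two inducers; a single value fixes that axis.
#' @param replicates Number of replicates per grid point (default 3).
#' @param noise A [noise_spec()].
#' @param device Dataset label.
#' @return A raw (un-normalised) [titration_dataset()] with zero blanks.
#' @export
simulate_titration <- function(predictor, grid_a = make_grid(), grid_b = 0,
                               replicates = 3, noise = noise_spec(),
                               device = "simulated") {
  stopifnot(is.function(predictor), inherits(noise, "noise_spec"))
  ga <- if (inherits(grid_a, "dilution_grid")) grid_a$concentrations else grid_a
  gb <- if (inherits(grid_b, "dilution_grid")) grid_b$concentrations else grid_b
  pts <- expand.grid(conc_a = ga, conc_b = gb, replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE)
  set.seed(noise$seed)
  sigma <- sqrt(log(1 + noise$cv^2))
  mu <- mapply(predictor, pts$conc_a, pts$conc_b)
  y <- mu * exp(sigma * stats::rnorm(nrow(pts))) +
    stats::rnorm(nrow(pts), 0, noise$floor_sd)
  od <- 0.5 * (1 + 0.05 * stats::rnorm(nrow(pts)))
  titration_dataset(pts$conc_a, pts$conc_b, pts$replicate,
                    fluorescence = y * od, od600 = od, device = device,
                    blank_fluorescence = 0, blank_od = 0)
}

#' Flow-cytometry event sample
#'
#' @param events Per-event fluorescence values (au), all > 0.
#' @param channel Channel label.
#' @return An object of class `flow_sample` with `events`, `n_events`,
#'   `channel`.
#' @export
flow_sample <- function(events, channel = "FITC") {
  if (!length(events) || any(events <= 0))
    stop("flow events must be a non-empty vector of positive values.",
         call. = FALSE)
  structure(list(events = as.numeric(events),
                 n_events = length(events), channel = channel),
            class = "flow_sample")
}

#' Simulate a flow-cytometry population
#'
#' Draws a lognormal event population whose median equals the model output
#' at the given condition, emulating the cell-to-cell expression variability
#' of a clonal population.
#'
#' @param predictor Function `(xa, xb) -> au`.
#' @param xa,xr Condition inducer concentrations (mol/L).
#' @param n_events Number of events (default 10000).
#' @param sigma_log Log-scale SD of the population (default 0.4).
#' @param seed Integer RNG seed.
#' @param channel Channel label.
#' @return A [flow_sample()].
#' @export
simulate_flow <- function(predictor, xa, xr, n_events = 10000,
                          sigma_log = 0.4, seed = 1L, channel = "FITC") {
  stopifnot(is.function(predictor))
  if (n_events < 1L) stop("n_events must be >= 1.", call. = FALSE)
  if (sigma_log < 0) stop("sigma_log must be >= 0.", call. = FALSE)
  mu <- predictor(xa, xr)
  if (mu <= 0) stop("model output must be > 0 to centre a lognormal population.",
                    call. = FALSE)
  set.seed(seed)
  flow_sample(stats::rlnorm(n_events, meanlog = log(mu), sdlog = sigma_log),
              channel = channel)
}

#' Simulate a four-condition digital experiment
#'
#' Runs the titration simulator restricted to the four logic conditions and
#' labels the rows, ready for [evaluate_digital()].
#'
#' @param predictor Function `(xa, xb) -> au`.
#' @param conditions A [logic_conditions()] table.
#' @param replicates Replicates per condition.
#' @param noise A [noise_spec()].
#' @param normalize OD-normalise before returning (default TRUE)?
#' @return data.frame with columns `condition`, `conc_a`, `conc_b`,
#'   `replicate`, `fluorescence`, `od600`.
#' @export
make_four_condition_dataset <- function(predictor,
                                        conditions = logic_conditions(),
                                        replicates = 3,
                                        noise = noise_spec(),
                                        normalize = TRUE) {
  stopifnot(is.function(predictor), inherits(noise, "noise_spec"))
  pts <- conditions[rep(seq_len(nrow(conditions)), each = replicates), ]
  pts$replicate <- rep(seq_len(replicates), times = nrow(conditions))
  set.seed(noise$seed)
  sigma <- sqrt(log(1 + noise$cv^2))
  mu <- mapply(predictor, pts$conc_a, pts$conc_b)
  y <- mu * exp(sigma * stats::rnorm(nrow(pts))) +
    stats::rnorm(nrow(pts), 0, noise$floor_sd)
  od <- 0.5 * (1 + 0.05 * stats::rnorm(nrow(pts)))
  out <- data.frame(condition = pts$condition, conc_a = pts$conc_a,
                    conc_b = pts$conc_b, replicate = pts$replicate,
                    fluorescence = if (normalize) y else y * od,
                    od600 = od, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
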