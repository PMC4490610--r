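#' Fit a Hill transfer function to titration data
#'
#' Nonlinear least-squares estimation of (A, B, C, n) from an OD-normalised
#' titration dataset. The objective is the unweighted sum of squared residuals
#' on the normalised output; an optional log-output objective is available for
#' data spanning several decades. Fitting uses Levenberg-Marquardt
#' (`minpack.lm::nlsLM`) with box constraints and a multi-start over the Hill
#' coefficient, keeping the start with the lowest SSE:
#'
#' * starts: `n` in `{0.5, 1, 2, 4}`; `C` at the geometric median of the
#'   non-zero concentrations; `A = min(y)`; `B = max(y) - min(y)`;
#' * bounds: `A >= 0`, `B >= 0`, `C` within `[min/10, max*10]` of the observed
#'   non-zero concentrations, `n` in `(0, 10]`.
#'
#' Flat data (total range below 3 replicate standard deviations) are reported
#' as a degenerate device (`B ~ 0`, `degenerate = TRUE`) rather than fitted.
#'
#' @param data A [titration_dataset()], normalised (see [normalize_od()]).
#' @param axis Which inducer column to fit against: `"a"` or `"b"`.
#' @param objective `"sse"` (default) or `"log_sse"` (residuals on
#'   `log(y + 1)`).
#' @return An object of class `hill_fit`: list with `params`
#'   ([hill_params()]), `residual_sse` (au^2), `converged`, `degenerate`,
#'   `n_starts_used`, `covariance_diag` (per-parameter variance estimates, NA
#'   when unavailable).
#' @examples
#' grid <- make_grid()
#' dev <- input_device("pBAD", "arabinose", hill_params(30, 3000, 1.1e-4, 2))
#' sim <- simulate_titration(device_predictor(dev, "a"), grid_a = grid,
#'                           noise = noise_spec(cv = 0, floor_sd = 0, seed = 1))
#' fit_hill(normalize_od(sim), axis = "a")
#' @export
fit_hill <- function(data, axis = c("a", "b"),
                     objective = c("sse", "log_sse")) {
  axis <- match.arg(axis)
  objective <- match.arg(objective)
  stopifnot(inherits(data, "titration_dataset"))
  if (!isTRUE(attr(data, "normalized")))
    warning("fitting a dataset that has not been OD-normalised.",
            call. = FALSE)
  x <- data[[paste0("conc_", axis)]]
  y <- data$fluorescence
  xu <- sort(unique(x))
  if (sum(xu > 0) < 2L)
    stop("need at least 2 distinct non-zero concentrations to fit.",
         call. = FALSE)
  if (length(xu) < 4L)
    stop("need at least 4 distinct concentrations to fit a Hill curve.",
         call. = FALSE)

  # pooled replicate SD per concentration point
  rep_sd <- stats::aggregate(y, by = list(x = x), FUN = stats::sd)$x
  rep_sd <- mean(rep_sd, na.rm = TRUE)
  if (!is.finite(rep_sd)) rep_sd <- 0

  if (diff(range(y)) < 3 * rep_sd || diff(range(y)) == 0) {
    params <- hill_params(max(mean(y), 0), 0,
                          exp(stats::median(log(xu[xu > 0]))), 1)
    return(structure(list(params = params,
                          residual_sse = sum((y - mean(y))^2),
                          converged = TRUE, degenerate = TRUE,
                          n_starts_used = 0L,
                          covariance_diag = rep(NA_real_, 4L)),
                     class = "hill_fit"))
  }

  c0 <- exp(stats::median(log(xu[xu > 0])))  # geometric median of non-zero grid
  lower <- c(A = 0, B = 0, C = min(xu[xu > 0]) / 10, n = 1e-6)
  upper <- c(A = Inf, B = Inf, C = max(xu) * 10, n = 10)
  a0 <- max(min(y), 0)
  b0 <- max(max(y) - min(y), 1e-9)

  yt <- if (objective == "log_sse") log(pmax(y, 0) + 1) else y
  model_fun <- if (objective == "log_sse") {
    function(A, B, C, n) log(A + B * ifelse(x == 0, 0, 1 / (1 + (C / x)^n)) + 1)
  } else {
    function(A, B, C, n) A + B * ifelse(x == 0, 0, 1 / (1 + (C / x)^n))
  }

  best <- NULL
  n_used <- 0L
  for (n0 in c(0.5, 1, 2, 4)) {
    n_used <- n_used + 1L
    fit <- tryCatch(
      minpack.lm::nlsLM(yt ~ model_fun(A, B, C, n),
                        start = list(A = a0, B = b0, C = c0, n = n0),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(fit = fit, sse = sse)
  }

  if (is.null(best))
    stop("Hill fit failed to converge from all starts.", call. = FALSE)

  cf <- stats::coef(best$fit)
  covd <- tryCatch(diag(stats::vcov(best$fit)),
                   error = function(e) rep(NA_real_, 4L))
  # residual SSE is always reported on the linear output scale
  pred <- hill_eval(hill_params(cf["A"], cf["B"], cf["C"], cf["n"]), x)
  structure(list(params = hill_params(cf[["A"]], cf[["B"]], cf[["C"]], cf[["n"]]),
                 residual_sse = sum((y - pred)^2),
                 converged = TRUE, degenerate = FALSE,
                 n_starts_used = n_used,
                 covariance_diag = as.numeric(covd)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s, SSE = %.4g au^2, %d starts)\n",
              if (x$degenerate) "degenerate: flat data" else
                if (x$converged) "converged" else "NOT converged",
              x$residual_sse, x$n_starts_used))
  print(x$params)
  invisible(x)
}

#' Fit an input device from a titration CSV
#'
#' Convenience wrapper: reads a titration CSV (plus its JSON metadata
#' sidecar), OD-normalises unless already normalised, fits the Hill transfer
#' function along `axis` and returns the fitted [input_device()] together
#' with the fit diagnostics.
#'
#' @param path Titration CSV path (see [read_titration_csv()]).
#' @param name,inducer Device identity; default taken from the CSV metadata.
#' @inheritParams fit_hill
#' @return List with `device` ([input_device()]) and `fit` (`hill_fit`).
#' @export
fit_device_from_csv <- function(path, name = NULL, inducer = "unknown",
                                axis = c("a", "b"),
                                objective = c("sse", "log_sse")) {
  axis <- match.arg(axis)
  data <- read_titration_csv(path)
  if (!isTRUE(attr(data, "normalized"))) data <- normalize_od(data)
  fit <- fit_hill(data, axis = axis, objective = match.arg(objective))
  if (is.null(name)) name <- attr(data, "device")
  list(device = input_device(name, inducer, fit$params), fit = fit)
}
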