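#' Four-parameter Hill transfer function
#'
#' Constructs the parameter set of the sigmoidal steady-state transfer function
#' \deqn{Y = A + \frac{B [X]^n}{C^n + [X]^n}}{Y = A + B x^n / (C^n + x^n)}
#' relating reporter output \eqn{Y} (arbitrary fluorescence units, au) to the
#' concentration \eqn{[X]} of a chemical inducer (mol/L).
#'
#' @param A Basal output at zero input (au), `A >= 0`.
#' @param B Dynamic range, i.e. maximal inducible increase over basal (au),
#'   `B >= 0`.
#' @param C Switch point: the inducer concentration giving half-maximal
#'   activation (mol/L), `C > 0`.
#' @param n Hill coefficient (cooperativity), dimensionless, `n > 0`.
#'
#' @return An object of class `hill_params`.
#' @seealso [hill_eval()], [normalized_activation()], [fit_hill()]
#' @examples
#' p <- hill_params(A = 30, B = 3000, C = 1.1e-4, n = 2)
#' hill_eval(p, c(0, 1.1e-4, 1))
#' @export
hill_params <- function(A, B, C, n) {
  vals <- c(A = A, B = B, C = C, n = n)
  if (length(vals) != 4L || !is.numeric(vals) || any(!is.finite(vals)))
    stop("Hill parameters A, B, C, n must be single finite numbers.", call. = FALSE)
  if (A < 0) stop("basal output A must be >= 0.", call. = FALSE)
  if (B < 0) stop("dynamic range B must be >= 0.", call. = FALSE)
  if (C <= 0) stop("switch point C must be > 0.", call. = FALSE)
  if (n <= 0) stop("Hill coefficient n must be > 0.", call. = FALSE)
  structure(list(A = A, B = B, C = C, n = n), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(
    "Hill transfer function: A = %.4g au, B = %.4g au, C = %.4g M, n = %.3g\n",
    x$A, x$B, x$C, x$n))
  invisible(x)
}

as_hill_params <- function(x) {
  if (inherits(x, "hill_params")) return(x)
  if (is.list(x) && all(c("A", "B", "C", "n") %in% names(x)))
    return(hill_params(x$A, x$B, x$C, x$n))
  stop("cannot interpret object as Hill parameters.", call. = FALSE)
}

#' Evaluate a Hill transfer function
#'
#' Steady-state output at inducer concentration `x`. Monotone non-decreasing
#' in `x` and bounded in `[A, A + B)`.
#'
#' @param params A [hill_params()] object (or a list with fields A, B, C, n).
#' @param x Inducer concentration(s), mol/L, `x >= 0`. Vectorised.
#' @return Numeric vector of outputs (au).
#' @export
hill_eval <- function(params, x) {
  params <- as_hill_params(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("inducer concentration x must be finite numeric.", call. = FALSE)
  if (any(x < 0))
    stop("inducer concentration x must be >= 0.", call. = FALSE)
  # (C/x)^-n form avoids overflow of x^n at large x
  act <- ifelse(x == 0, 0, 1 / (1 + (params$C / x)^params$n))
  params$A + params$B * act
}

#' Basal-subtracted, range-normalised activation
#'
#' The fractional promoter activation \eqn{x^n / (C^n + x^n)} in `[0, 1)`,
#' equal to `(hill_eval(params, x) - A) / B`. This is the quantity gate
#' composition works with.
#'
#' @inheritParams hill_eval
#' @return Numeric vector in `[0, 1)`.
#' @export
normalized_activation <- function(params, x) {
  params <- as_hill_params(params)
  if (params$B <= 0)
    stop("degenerate device: dynamic range B must be > 0 to normalise.",
         call. = FALSE)
  (hill_eval(params, x) - params$A) / params$B
}
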