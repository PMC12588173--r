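#' Greenwood frequency-position parameters
#'
#' Parameters (A, a, k) of the Greenwood frequency-position function
#' \deqn{F(x) = A\,(10^{a x} - k)}
#' where `x` is the proportional distance from the cochlear apex (`x = 0` at
#' the helicotrema, `x = 1` at the base), so frequency increases basally.
#' Defaults are the standard human map (A = 165.4 Hz, a = 2.1, k = 0.88).
#'
#' @param A scale in Hz (> 0).
#' @param a exponent per unit proportional length (> 0).
#' @param k dimensionless offset, `0 <= k < 1`.
#' @return An object of class `greenwood_params`.
#' @examples
#' p <- greenwood_params()
#' greenwood_forward(0, p)  # apical minimum, ~20 Hz
#' @export
greenwood_params <- function(A = 165.4, a = 2.1, k = 0.88) {
  if (!is.numeric(A) || length(A) != 1L || A <= 0)
    stop("A must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("a must be a single positive number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k >= 1)
    stop("k must satisfy 0 <= k < 1", call. = FALSE)
  structure(list(A = A, a = a, k = k), class = "greenwood_params")
}

#' @export
print.greenwood_params <- function(x, ...) {
  cat(sprintf("Greenwood map F(x) = A (10^(a x) - k):  A = %.4g Hz, a = %.4g, k = %.4g\n",
              x$A, x$a, x$k))
  cat(sprintf("  range: %.1f Hz (apex, x = 0) to %.0f Hz (base, x = 1)\n",
              x$A * (1 - x$k), x$A * (10^x$a - x$k)))
  invisible(x)
}

#' Greenwood function: proportional position to frequency
#'
#' Evaluates `F(x) = A (10^(a x) - k)` at proportional distance `x` from the
#' apex. Strictly increasing in `x`.
#'
#' @param x proportional distance from the apex, in `[0, 1]` (vectorized).
#' @param params a [greenwood_params()].
#' @return Characteristic frequency in Hz.
#' @examples
#' round(greenwood_forward((34.10 - 21.38) / 34.10)) # 859 Hz at end of turn 1
#' @export
greenwood_forward <- function(x, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("x must lie in [0, 1]", call. = FALSE)
  params$A * (10^(params$a * x) - params$k)
}

#' Greenwood function inverse: frequency to proportional position
#'
#' Closed-form inverse `x = log10(f/A + k) / a`; round-trips with
#' [greenwood_forward()] to 1e-12 relative.
#'
#' @param f frequency in Hz (vectorized), within the map's range
#'   `[A(1-k), A(10^a - k)]`.
#' @param params a [greenwood_params()].
#' @return Proportional distance from the apex in `[0, 1]`.
#' @export
greenwood_inverse <- function(f, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"))
  lo <- params$A * (1 - params$k)
  hi <- params$A * (10^params$a - params$k)
  tol <- 1e-9 * hi
  if (any(!is.finite(f)) || any(f < lo - tol) || any(f > hi + tol))
    stop(sprintf("frequency outside the map range [%.4g, %.4g] Hz", lo, hi),
         call. = FALSE)
  x <- log10(pmax(f, lo) / params$A + params$k) / params$a
  pmin(pmax(x, 0), 1)
}

#' Fit Greenwood parameters to position-frequency samples
#'
#' Nonlinear least-squares fit of the Greenwood map to observed
#' (proportional position, frequency) samples. Residuals are taken in
#' log10-frequency, since cochlear frequencies span three decades and
#' multiplicative (semitone-scale) error is the natural metric. Fitting uses
#' Levenberg-Marquardt with box constraints (A > 0, a > 0, 0 <= k < 1).
#'
#' @param x proportional distances from the apex (>= 4 distinct values).
#' @param f observed frequencies in Hz (same length, all > 0).
#' @param init a [greenwood_params()] used as the starting point.
#' @return An object of class `greenwood_fit` (inheriting
#'   `greenwood_params`): the fitted parameters plus `converged`,
#'   `residual_sd_log10`, `n`, and the underlying `nls` fit. Supports
#'   [coef()], [predict()], [print()].
#' @examples
#' p <- greenwood_params()
#' xx <- seq(0, 1, length.out = 20)
#' fit <- fit_greenwood(xx, greenwood_forward(xx, p))
#' coef(fit)
#' @export
fit_greenwood <- function(x, f, init = greenwood_params()) {
  stopifnot(inherits(init, "greenwood_params"))
  x <- as.numeric(x); f <- as.numeric(f)
  if (length(x) != length(f))
    stop("x and f must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(f)
  if (!all(ok)) stop("x and f must be finite", call. = FALSE)
  if (length(unique(x)) < 4L)
    stop("fit_greenwood needs at least 4 samples with distinct x",
         call. = FALSE)
  if (any(f <= 0)) stop("frequencies must be positive", call. = FALSE)

  dat <- data.frame(x = x, lf = log10(f))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lf ~ log10(A * (10^(a * x) - k)),
      data = dat,
      start = list(A = init$A, a = init$a, k = init$k),
      lower = c(A = 1e-6, a = 1e-6, k = 0),
      upper = c(A = Inf, a = Inf, k = 1 - 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e)
      stop("Greenwood fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
  )
  est <- stats::coef(fit)
  out <- greenwood_params(A = est[["A"]], a = est[["a"]], k = est[["k"]])
  out$converged <- fit$convInfo$isConv
  out$residual_sd_log10 <- stats::sigma(fit)
  out$n <- length(x)
  out$nls <- fit
  class(out) <- c("greenwood_fit", "greenwood_params")
  out
}

#' @export
coef.greenwood_fit <- function(object, ...) {
  c(A = object$A, a = object$a, k = object$k)
}

#' @export
predict.greenwood_fit <- function(object, x, ...) {
  greenwood_forward(x, greenwood_params(object$A, object$a, object$k))
}

#' @export
print.greenwood_fit <- function(x, ...) {
  cat(sprintf(
    "Greenwood fit (log10-frequency least squares, n = %d)%s\n", x$n,
    if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  print(greenwood_params(x$A, x$a, x$k))
  cat(sprintf("  residual sd: %.4g log10-Hz\n", x$residual_sd_log10))
  invisible(x)
}
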