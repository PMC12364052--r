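#' Sigmoid affinity-fitness response parameters
#'
#' The intrinsic birth rate of a cell with affinity `x` is
#' `lambda(x) = yc / (1 + exp(-xc * (x - xh))) + yh` (1/day):
#' * `xc` -- steepness of the transition (1/affinity-unit), > 0;
#' * `xh` -- affinity midpoint of the transition;
#' * `yc` -- vertical scale; the fitness ceiling is `yh + yc` (1/day), > 0;
#' * `yh` -- vertical shift, the floor rate of very low-affinity cells
#'   (tonic signalling), >= 0.
#'
#' @param xc,xh,yc,yh Numeric scalars as described above.
#' @return An object of class `response_params`.
#' @export
response_params <- function(xc, xh, yc, yh) {
  stopifnot(is.finite(xc), is.finite(xh), is.finite(yc), is.finite(yh))
  if (xc <= 0) stop("xc must be > 0")
  if (yc <= 0) stop("yc must be > 0")
  if (yh < 0) stop("yh must be >= 0")
  structure(list(xc = xc, xh = xh, yc = yc, yh = yh),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf(
    "<response_params> xc=%.4g xh=%.4g yc=%.4g yh=%.4g (naive rate %.4g/day)\n",
    x$xc, x$xh, x$yc, x$yh, naive_rate(x)))
  invisible(x)
}

#' Evaluate the sigmoid affinity-fitness response
#'
#' Overflow-safe: for large `|xc * (x - xh)|` the asymptotes `yh` and
#' `yh + yc` are returned exactly.
#'
#' @param x Affinity value(s).
#' @param p A [response_params()].
#' @return Intrinsic birth rate(s), 1/day, in `(yh, yh + yc)`.
#' @export
sigmoid_response <- function(x, p) {
  stopifnot(inherits(p, "response_params"))
  z <- -p$xc * (x - p$xh)
  # plogis is the numerically safe logistic
  p$yc * stats::plogis(-z) + p$yh
}

#' Naive (zero-affinity) birth rate
#'
#' `lambda0 = yc / (1 + exp(xc * xh))`, neglecting the small tonic floor
#' `yh` -- the quantity constrained when sampling training parameters.
#'
#' @param p A [response_params()].
#' @return Rate (1/day).
#' @export
naive_rate <- function(p) {
  stopifnot(inherits(p, "response_params"))
  p$yc * stats::plogis(-p$xc * p$xh)
}

#' Parameter bounds for training-set sampling
#'
#' Box bounds on the four sigmoid parameters plus bounds on the naive birth
#' rate `lambda0`. The defaults are the training ranges used throughout:
#' `xc` in \[0.01, 2\], `xh` in \[-0.5, 3\], `yc` in \[0.5, 35\], `yh` in
#' \[0, 0.6\], `lambda0` in \[0.1, 15\].
#'
#' @param xc,xh,yc,yh,lambda0 Length-2 numeric `c(lower, upper)` intervals.
#' @return An object of class `param_bounds`.
#' @export
param_bounds <- function(xc = c(0.01, 2), xh = c(-0.5, 3), yc = c(0.5, 35),
                         yh = c(0, 0.6), lambda0 = c(0.1, 15)) {
  b <- list(xc = xc, xh = xh, yc = yc, yh = yh, lambda0 = lambda0)
  for (nm in names(b)) {
    v <- b[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop("bounds for ", nm, " must be c(lower, upper) with lower < upper")
  }
  structure(b, class = "param_bounds")
}

#' Sample response parameters under naive-rate constraints
#'
#' Draws a sigmoid parameter set uniformly within its box bounds subject to
#' the naive birth rate `lambda0 = yc / (1 + exp(xc * xh))` lying inside its
#' own bounds. The draw proceeds sequentially: `xc` uniform in its interval;
#' `xh` uniform in the intersection of its interval with
#' `log(yc_l / lambda0_u - 1)/xc < xh < log(yc_u / lambda0_l - 1)/xc`
#' (a one-sided constraint becomes vacuous when the log argument is
#' non-positive); `yc` uniform in the intersection of its interval with
#' `lambda0_l (1 + exp(xc xh)) < yc < lambda0_u (1 + exp(xc xh))`; and `yh`
#' uniform in its own interval, independently (tonic floor excluded from the
#' `lambda0` constraint). If an intersection is empty the `xc` draw is
#' retried, with an error after `max_tries` failures.
#'
#' @param bounds A [param_bounds()].
#' @param max_tries Retry budget for infeasible `xc` draws (default 100).
#' @return A [response_params()] satisfying all bounds.
#' @export
sample_response_params <- function(bounds = param_bounds(), max_tries = 100L) {
  stopifnot(inherits(bounds, "param_bounds"))
  l0l <- bounds$lambda0[1]; l0u <- bounds$lambda0[2]
  ycl <- bounds$yc[1]; ycu <- bounds$yc[2]
  for (i in seq_len(max_tries)) {
    xc <- runif(1L, bounds$xc[1], bounds$xc[2])
    lo <- if (ycl / l0u > 1) log(ycl / l0u - 1) / xc else -Inf
    hi <- if (ycu / l0l > 1) log(ycu / l0l - 1) / xc else Inf
    lo <- max(lo, bounds$xh[1]); hi <- min(hi, bounds$xh[2])
    if (lo >= hi) next
    xh <- runif(1L, lo, hi)
    exh <- 1 + exp(xc * xh)
    ylo <- max(ycl, l0l * exh); yhi <- min(ycu, l0u * exh)
    if (ylo >= yhi) next
    yc <- runif(1L, ylo, yhi)
    yh <- runif(1L, bounds$yh[1], bounds$yh[2])
    return(response_params(xc, xh, yc, yh))
  }
  stop("sample_response_params: no feasible draw in ", max_tries,
       " tries; check that the bounds admit a non-empty region")
}

#' Evaluate a response curve on a uniform affinity grid
#'
#' @param p A [response_params()].
#' @param domain Affinity interval `c(lo, hi)`; default `c(-2.5, 3)`, the
#'   domain on which curves are compared throughout the package.
#' @param n Number of grid points (>= 2).
#' @return Numeric vector of `n` rates.
#' @export
response_curve_on_grid <- function(p, domain = c(-2.5, 3), n = 512L) {
  stopifnot(length(domain) == 2L, domain[1] < domain[2], n >= 2L)
  sigmoid_response(seq(domain[1], domain[2], length.out = n), p)
}
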