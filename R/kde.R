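#' Kernel functions for density estimation
#'
#' @param name \code{"gaussian"} or \code{"epanechnikov"}.
#' @return A vectorized function \code{K(u)}.
#' @export
kde_kernel <- function(name = c("gaussian", "epanechnikov")) {
  name <- match.arg(name)
  switch(name,
    gaussian = function(u) stats::dnorm(u),
    epanechnikov = function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0))
}

#' Check the moment constraints of a density kernel
#'
#' A valid kernel must integrate to 1, have zero first moment and a strictly
#' positive second moment. The integrals are evaluated by the trapezoid rule
#' on a wide grid and checked to tolerance \code{tol}.
#'
#' @param kernel A vectorized function \code{K(u)}, or a kernel name
#'   accepted by [kde_kernel()].
#' @param tol Numeric tolerance for the first two constraints.
#' @param lim Half-width of the integration interval.
#' @return \code{TRUE} iff all three constraints hold.
#' @export
validate_kernel <- function(kernel, tol = 1e-3, lim = 10) {
  if (is.character(kernel)) kernel <- kde_kernel(kernel)
  u <- seq(-lim, lim, length.out = 20001)
  Ku <- kernel(u)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(u))
  m0 <- trap(Ku)
  m1 <- trap(u * Ku)
  m2 <- trap(u^2 * Ku)
  abs(m0 - 1) < tol && abs(m1) < tol && m2 > tol
}

#' Kernel density estimate on a grid
#'
#' \code{f_hat(x) = (1 / (n h)) sum_i K((x - X_i) / h)}, evaluated at the
#' caller-supplied grid points.
#'
#' @param x Numeric sample (1-D projections or distances).
#' @param grid Evaluation points.
#' @param h Bandwidth (> 0). \code{NULL} uses Silverman's rule of thumb
#'   (\code{stats::bw.nrd0}).
#' @param kernel Kernel name or function; must satisfy [validate_kernel()].
#' @return Numeric vector of non-negative density values, one per grid
#'   point.
#' @export
kde_density <- function(x, grid, h = NULL, kernel = "gaussian") {
  if (is.null(h)) h <- stats::bw.nrd0(x)
  if (!is.finite(h) || h <= 0) stop("bandwidth h must be > 0")
  K <- if (is.character(kernel)) kde_kernel(kernel) else kernel
  if (!validate_kernel(K))
    stop("kernel fails the moment constraints (integral 1, zero mean, ",
         "positive second moment)")
  n <- length(x)
  vapply(grid, function(g) sum(K((g - x) / h)) / (n * h), numeric(1))
}
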