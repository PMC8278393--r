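#' Finite-difference derivatives with Richardson extrapolation
#'
#' Central differences at steps h and h/2 combined as (4 D_{h/2} - D_h) / 3,
#' eliminating the leading O(h^2) error. Used to verify the analytic
#' derivative stack (`--verify-fd` in the CLI and throughout the test
#' suite); the finite-difference path touches only energy (or function)
#' evaluations, never the analytic derivative code.
#'
#' @param f Scalar function of a numeric vector.
#' @param x Evaluation point.
#' @param h Base step.
#' @param richardson Apply Richardson extrapolation (default `TRUE`).
#' @return Numeric gradient of length `length(x)`.
#' @export
fd_gradient <- function(f, x, h = 1e-3, richardson = TRUE) {
  central <- function(step) {
    vapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + step; xm[i] <- xm[i] - step
      (f(xp) - f(xm)) / (2 * step)
    }, numeric(1))
  }
  if (richardson) (4 * central(h / 2) - central(h)) / 3 else central(h)
}

#' @rdname fd_gradient
#' @param fv Vector-valued function; the result is the Jacobian with one
#'   column per component of `x`.
#' @export
fd_jacobian <- function(fv, x, h = 1e-3, richardson = TRUE) {
  central <- function(step) {
    cols <- lapply(seq_along(x), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + step; xm[i] <- xm[i] - step
      (fv(xp) - fv(xm)) / (2 * step)
    })
    do.call(cbind, cols)
  }
  if (richardson) (4 * central(h / 2) - central(h)) / 3 else central(h)
}
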