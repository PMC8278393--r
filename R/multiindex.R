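#' Multi-index algebra for Cartesian multipole expansions
#'
#' A multi-index is a triple of non-negative integers (ax, ay, az) counting
#' Cartesian derivative orders. It underpins the open-ended notation used for
#' interaction tensors and multipole components throughout the package.
#'
#' @param ax,ay,az Non-negative integers.
#' @return An object of class `multi_index` (named integer vector).
#' @examples
#' mi(1, 2, 0)
#' @export
mi <- function(ax, ay, az) {
  a <- c(ax = as.integer(ax), ay = as.integer(ay), az = as.integer(az))
  if (anyNA(a) || any(a < 0)) {
    stop("multi-index components must be non-negative integers")
  }
  structure(a, class = "multi_index")
}

#' @export
print.multi_index <- function(x, ...) {
  cat(sprintf("(%d, %d, %d)  |alpha| = %d\n", x[1], x[2], x[3], sum(x)))
  invisible(x)
}

#' Absolute value |alpha| of a multi-index
#' @param alpha A `multi_index`.
#' @export
mi_order <- function(alpha) sum(unclass(alpha))

#' Multi-index factorial alpha! = ax! ay! az!
#' @param alpha A `multi_index`.
#' @export
mi_factorial <- function(alpha) {
  prod(factorial(unclass(alpha)))
}

#' Multi-index power R^alpha = Rx^ax Ry^ay Rz^az
#' @param R Numeric 3-vector.
#' @param alpha A `multi_index`.
#' @export
mi_power <- function(R, alpha) {
  stopifnot(length(R) == 3)
  prod(R^unclass(alpha))
}

#' Component-wise multi-index addition / subtraction
#'
#' Subtraction producing a negative component is an error, matching the
#' algebraic requirement that multi-indices stay in the non-negative octant.
#'
#' @param a,b `multi_index` objects.
#' @export
mi_add <- function(a, b) mi(a[1] + b[1], a[2] + b[2], a[3] + b[3])

#' @rdname mi_add
#' @export
mi_sub <- function(a, b) {
  d <- unclass(a) - unclass(b)
  if (any(d < 0)) stop("multi-index subtraction would give a negative component")
  mi(d[1], d[2], d[3])
}

#' Enumerate all multi-indices up to a maximum order
#'
#' Indices are grouped by |alpha| ascending and ordered lexicographically by
#' (ax, ay, az) descending within each group, i.e. order 1 enumerates as
#' (1,0,0), (0,1,0), (0,0,1). There are (k+1)(k+2)/2 indices of order k.
#'
#' @param max_order Non-negative integer.
#' @return List of `multi_index` objects.
#' @export
enumerate_multiindices <- function(max_order) {
  if (length(max_order) != 1 || is.na(max_order) || max_order < 0) {
    stop("max_order must be a non-negative integer")
  }
  out <- list()
  for (k in 0:max_order) {
    for (ax in k:0) {
      for (ay in (k - ax):0) {
        out[[length(out) + 1L]] <- mi(ax, ay, k - ax - ay)
      }
    }
  }
  out
}

#' Multi-indices of exactly one order
#' @param k Non-negative integer order.
#' @return List of `multi_index` of order `k`, in enumeration order.
#' @export
multiindices_of_order <- function(k) {
  Filter(function(a) mi_order(a) == k, enumerate_multiindices(k))
}
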