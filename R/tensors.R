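#' @section Interaction tensors:
#' The Cartesian interaction tensor of multi-index alpha is the |alpha|-fold
#' derivative of the Coulomb kernel,
#'   T^\[alpha\](Ri, Rj) = d^alpha / dRj^alpha  1 / |Ri - Rj|,
#' the derivative being taken with respect to the second argument. Components
#' are generated by a closed-form recurrence on auxiliary kernels
#' R^m(r) = (-1)^m (2m-1)!! r^-(2m+1), for which
#'   d/dx R^m = x R^(m+1),  so  R^m_{t+1,u,v} = x R^(m+1)_{t,u,v} + t R^(m+1)_{t-1,u,v}
#' (McMurchie-Davidson style, specialized to the bare 1/r kernel). This is
#' numerically stable to high order and avoids symbolic differentiation.
#' @name interaction-tensors
#' @keywords internal
NULL

PE_SINGULAR_DIST <- 1e-6  # bohr; closer pairs are a hard error, no damping

double_factorial_odd <- function(m) {
  # (2m - 1)!! with (-1)!! = 1
  if (m == 0) return(1)
  prod(seq(1, 2 * m - 1, by = 2))
}

# cached integer matrices of (t, u, v) triples per total order; this sits on
# the innermost loop of every energy/derivative evaluation
.mi_cache <- new.env(parent = emptyenv())
mi_order_matrix <- function(k) {
  key <- as.character(k)
  if (!is.null(.mi_cache[[key]])) return(.mi_cache[[key]])
  m <- do.call(rbind, lapply(multiindices_of_order(k),
                             function(a) unclass(a)))
  storage.mode(m) <- "integer"
  .mi_cache[[key]] <- m
  m
}

#' Table of Cartesian derivatives of 1/r
#'
#' Computes d^(t,u,v) (1/|r|) for all t + u + v <= max_order at displacement
#' `r`, via the auxiliary-kernel recurrence described in
#' [interaction-tensors].
#'
#' @param r Numeric 3-vector displacement (bohr), must be non-zero.
#' @param max_order Highest total derivative order (supported well beyond 6).
#' @return A function `(t, u, v) -> scalar` backed by the precomputed table.
#' @keywords internal
coulomb_derivative_table <- function(r, max_order) {
  rnorm2 <- sum(r * r)
  if (sqrt(rnorm2) < PE_SINGULAR_DIST) {
    stop("interaction tensor is singular: points closer than ",
         PE_SINGULAR_DIST, " bohr")
  }
  K <- as.integer(max_order)
  A <- array(NA_real_, dim = c(K + 1, K + 1, K + 1, K + 1))
  rn <- sqrt(rnorm2)
  for (m in 0:K) {
    A[1, 1, 1, m + 1] <- (-1)^m * double_factorial_odd(m) / rn^(2 * m + 1)
  }
  if (K > 0) {
    for (d in 1:K) {
      idx <- mi_order_matrix(d)
      for (row in seq_len(nrow(idx))) {
        t <- idx[row, 1]; u <- idx[row, 2]; v <- idx[row, 3]
        for (m in 0:(K - d)) {
          if (t > 0) {
            val <- r[1] * A[t, u + 1, v + 1, m + 2]
            if (t > 1) val <- val + (t - 1) * A[t - 1, u + 1, v + 1, m + 2]
          } else if (u > 0) {
            val <- r[2] * A[t + 1, u, v + 1, m + 2]
            if (u > 1) val <- val + (u - 1) * A[t + 1, u - 1, v + 1, m + 2]
          } else {
            val <- r[3] * A[t + 1, u + 1, v, m + 2]
            if (v > 1) val <- val + (v - 1) * A[t + 1, u + 1, v - 1, m + 2]
          }
          A[t + 1, u + 1, v + 1, m + 1] <- val
        }
      }
    }
  }
  function(t, u, v) A[t + 1, u + 1, v + 1, 1]
}

#' Single interaction-tensor component
#'
#' @param R_i,R_j Numeric 3-vectors (bohr); the derivative is taken with
#'   respect to `R_j`.
#' @param alpha A [mi()] multi-index.
#' @return Scalar tensor component, atomic units of length^-(|alpha|+1).
#' @examples
#' interaction_tensor(c(0, 0, 0), c(2, 0, 0), mi(1, 0, 0))  # -0.25
#' @export
interaction_tensor <- function(R_i, R_j, alpha) {
  tab <- coulomb_derivative_table(R_j - R_i, mi_order(alpha))
  tab(alpha[1], alpha[2], alpha[3])
}

#' All interaction-tensor components of one order
#'
#' @inheritParams interaction_tensor
#' @param order Non-negative integer tensor order.
#' @return Object of class `tensor_block`: list with `R_i`, `R_j`, `order`,
#'   `indices` (the multi-indices, enumeration order) and `components`
#'   (numeric vector aligned with `indices`).
#' @export
tensor_block <- function(R_i, R_j, order) {
  if (order < 0) stop("order must be non-negative")
  tab <- coulomb_derivative_table(R_j - R_i, order)
  idx <- multiindices_of_order(order)
  comp <- vapply(idx, function(a) tab(a[1], a[2], a[3]), numeric(1))
  names(comp) <- vapply(idx, function(a) paste(unclass(a), collapse = ""),
                        character(1))
  structure(list(R_i = R_i, R_j = R_j, order = order,
                 indices = idx, components = comp),
            class = "tensor_block")
}

#' @export
print.tensor_block <- function(x, ...) {
  cat(sprintf("interaction tensor block, order %d (%d components)\n",
              x$order, length(x$components)))
  print(x$components)
  invisible(x)
}

# 3x3 matrix view of the order-2 block (dipole-dipole field tensor)
tensor_block_matrix2 <- function(r) {
  tab <- coulomb_derivative_table(r, 2)
  m <- matrix(0, 3, 3)
  e <- diag(3)
  for (i in 1:3) for (j in i:3) {
    a <- e[i, ] + e[j, ]
    m[i, j] <- m[j, i] <- tab(a[1], a[2], a[3])
  }
  m
}
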