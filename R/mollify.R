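#' Mollifier configuration
#'
#' The min-of-paraboloids potential has gradient discontinuities on basin
#' boundaries; the drift of the stochastic model uses a mollified (smoothed)
#' potential \eqn{\tilde F = F * \rho_\epsilon}, the convolution of `F` with a
#' kernel of radius `epsilon`. Two kernels are supported: `"gaussian"`
#' (standard deviation `epsilon`) and `"bump"` (compactly supported
#' \eqn{\exp(-1/(1-r^2))} mollifier on the disk of radius `epsilon`).
#'
#' The convolution integral is evaluated by tensor quadrature
#' (Gauss--Hermite for the gaussian kernel, weighted Gauss--Legendre for the
#' bump), which is exact for the piecewise-quadratic potential wherever a
#' single paraboloid covers the kernel support: there the gaussian-mollified
#' potential is `F + 2*a*epsilon^2` with unchanged gradient.
#'
#' @param epsilon kernel radius in landscape units (> 0).
#' @param kernel `"gaussian"` (default) or `"bump"`.
#' @param nodes quadrature nodes per axis (>= 3; default 5).
#' @return a `mollifier` object.
#' @export
mollifier <- function(epsilon, kernel = c("gaussian", "bump"), nodes = 5L) {
  kernel <- match.arg(kernel)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  nodes <- as.integer(nodes)
  if (nodes < 3L) stop("need at least 3 quadrature nodes per axis")
  if (kernel == "gaussian") {
    gh <- pracma::gaussHermite(nodes)
    sx <- sqrt(2) * epsilon * gh$x
    w1 <- gh$w / sqrt(pi)
    shift_u <- rep(sx, times = nodes)
    shift_v <- rep(sx, each = nodes)
    w <- rep(w1, times = nodes) * rep(w1, each = nodes)
  } else {
    gl <- pracma::gaussLegendre(nodes, -1, 1)
    xu <- rep(gl$x, times = nodes)
    xv <- rep(gl$x, each = nodes)
    ww <- rep(gl$w, times = nodes) * rep(gl$w, each = nodes)
    r2 <- xu^2 + xv^2
    keep <- r2 < 1
    dens <- exp(-1 / (1 - r2[keep]))
    w <- ww[keep] * dens
    w <- w / sum(w)
    shift_u <- epsilon * xu[keep]
    shift_v <- epsilon * xv[keep]
  }
  structure(list(kernel = kernel, epsilon = epsilon, nodes = nodes,
                 shift_u = shift_u, shift_v = shift_v, weights = w),
            class = "mollifier")
}

#' @export
print.mollifier <- function(x, ...) {
  cat("Mollifier:", x$kernel, "kernel, radius", format(x$epsilon),
      "(", length(x$weights), "quadrature nodes )\n")
  invisible(x)
}

#' Default mollifier radius for a landscape
#'
#' `epsilon = frac` times the diagonal of the landscape bounding box.
#'
#' @param land a [landscape()].
#' @param frac fraction of the bounding-box diagonal (default 0.05).
#' @param ... passed to [mollifier()].
#' @export
default_mollifier <- function(land, frac = 0.05, ...) {
  bb <- bounding_box(land)
  diag_len <- sqrt((bb["umax"] - bb["umin"])^2 + (bb["vmax"] - bb["vmin"])^2)
  mollifier(epsilon = unname(frac * diag_len), ...)
}

# Core quadrature evaluation of the mollified potential and/or its gradient.
# The gradient is the kernel average of the local paraboloid gradient
# 2 a_b (p - c_b) at the shifted points (valid a.e., dominated convergence).
moll_eval <- function(land, moll, u, v, want_value = TRUE, want_grad = TRUE) {
  M <- length(u)
  Q <- length(moll$weights)
  uq <- as.vector(outer(u, moll$shift_u, "+"))   # M*Q, point-major
  vq <- as.vector(outer(v, moll$shift_v, "+"))
  vals <- paraboloid_values(land, uq, vq)
  b <- max.col(-vals, ties.method = "first")
  out <- list()
  if (want_value) {
    Fq <- vals[cbind(seq_along(b), b)]
    out$value <- as.vector(matrix(Fq, nrow = M) %*% moll$weights)
  }
  if (want_grad) {
    a_b <- land$steepness[b]
    gu <- 2 * a_b * (uq - land$centers[b, 1])
    gv <- 2 * a_b * (vq - land$centers[b, 2])
    out$grad_u <- as.vector(matrix(gu, nrow = M) %*% moll$weights)
    out$grad_v <- as.vector(matrix(gv, nrow = M) %*% moll$weights)
  }
  out
}

#' Mollified potential and gradient
#'
#' @param land a [landscape()].
#' @param moll a [mollifier()].
#' @param u,v coordinates (vectors of equal length).
#' @return list with `value` (\eqn{\tilde F}), `grad_u`, `grad_v`.
#' @export
mollified_potential <- function(land, moll, u, v) {
  moll_eval(land, moll, u, v, want_value = TRUE, want_grad = TRUE)
}

# drift of the gradient system: (f, g) = -grad Ftilde
moll_drift <- function(land, moll, u, v) {
  g <- moll_eval(land, moll, u, v, want_value = FALSE, want_grad = TRUE)
  list(fu = -g$grad_u, fv = -g$grad_v)
}
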