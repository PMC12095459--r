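#' Stochastic reaction--diffusion simulation of the epigenetic field
#'
#' Integrates the two-component field \eqn{x(t,\xi) = (u(t,\xi), v(t,\xi))}
#' on the 1-D domain \eqn{[0, L]},
#' \deqn{dx = (A x + a(x))\,dt + dW,}
#' where \eqn{A = (d_1 \partial^2_\xi, d_2 \partial^2_\xi)} is the diffusion
#' operator, \eqn{a(x) = (\tilde f, \tilde g) = -\nabla \tilde F(u, v)} is the
#' pointwise mollified-landscape drift, and \eqn{dW} is additive white or
#' colored noise with magnitude \eqn{\sigma_1 = \sigma_2 = \sigma}. Time
#' stepping is semi-implicit Euler--Maruyama: the diffusion term is treated
#' implicitly (one tridiagonal solve per component per step under the chosen
#' boundary condition), drift and noise explicitly. White noise increments
#' are i.i.d. `Normal(0, sigma^2 dt / dxi)` per grid point per component
#' (the standard grid scaling of space-time white noise); colored noise uses
#' a truncated cosine/Fourier expansion with configurable per-mode weights.
#'
#' @param land a [landscape()].
#' @param moll a [mollifier()].
#' @param sigma noise magnitude.
#' @param start basin label/index, numeric `c(u, v)` (constant-in-space
#'   field), or a list `list(u =, v =)` of length-`N` vectors.
#' @param T time horizon.
#' @param dt time step (drift stability bound as in [simulate_sde()]).
#' @param N number of grid points (default 64).
#' @param L domain length (default 1).
#' @param d1,d2 diffusivities of the two components (default 0.01).
#' @param bc `"neumann"` (zero-flux, default) or `"periodic"`.
#' @param noise `"white"` (default) or `"colored"`.
#' @param modes,mode_weights for colored noise: number of spatial cosine
#'   modes and their weights (default `1/k`).
#' @param seed integer seed.
#' @param save_every save every k-th step (default chosen to keep ~200
#'   snapshots).
#' @return a `field_trajectory`: list with `times`, matrices `u`, `v`
#'   (snapshots x grid), grid `xi`, and the full configuration.
#' @export
simulate_spde <- function(land, moll, sigma, start, T, dt,
                          N = 64L, L = 1, d1 = 0.01, d2 = 0.01,
                          bc = c("neumann", "periodic"),
                          noise = c("white", "colored"),
                          modes = 8L, mode_weights = NULL,
                          seed = 1L, save_every = NULL) {
  bc <- match.arg(bc)
  noise <- match.arg(noise)
  check_dt(land, dt)
  if (N < 1L) stop("N must be >= 1")
  n_steps <- ceiling(T / dt)
  if (is.null(save_every)) save_every <- max(1L, n_steps %/% 200L)
  dxi <- L / N
  xi <- (seq_len(N) - 0.5) * dxi

  x0 <- field_start(land, start, N)
  ncfg <- noise_config(sigma, dt, dxi, N, L, xi, noise, modes, mode_weights)

  lap <- laplacian_matrix(N, dxi, bc)
  Ainv_u <- solve(diag(N) - dt * d1 * lap)
  Ainv_v <- solve(diag(N) - dt * d2 * lap)

  S <- n_steps %/% save_every + 1L
  U <- matrix(NA_real_, S, N); V <- matrix(NA_real_, S, N)
  times <- numeric(S)
  u <- x0$u; v <- x0$v
  U[1L, ] <- u; V[1L, ] <- v
  ri <- 1L
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      dr <- moll_drift(land, moll, u, v)
      u <- as.vector(Ainv_u %*% (u + dt * dr$fu + noise_increment(ncfg)))
      v <- as.vector(Ainv_v %*% (v + dt * dr$fv + noise_increment(ncfg)))
      if (any(!is.finite(u)) || any(!is.finite(v)))
        stop("numerical blow-up at step ", s, " (t = ", format(s * dt), ")")
      if (s %% save_every == 0L) {
        ri <- ri + 1L
        U[ri, ] <- u; V[ri, ] <- v; times[ri] <- s * dt
      }
    }
  })
  structure(list(times = times[seq_len(ri)],
                 u = U[seq_len(ri), , drop = FALSE],
                 v = V[seq_len(ri), , drop = FALSE], xi = xi,
                 config = list(sigma = sigma, T = T, dt = dt, N = N, L = L,
                               d1 = d1, d2 = d2, bc = bc, noise = noise,
                               modes = modes, seed = seed,
                               save_every = save_every,
                               mollifier = moll[c("kernel", "epsilon", "nodes")]),
                 labels = land$labels),
            class = "field_trajectory")
}

field_start <- function(land, start, N) {
  if (is.list(start) && !is.null(start$u)) {
    if (length(start$u) != N || length(start$v) != N)
      stop("explicit initial field must have length N per component")
    list(u = as.numeric(start$u), v = as.numeric(start$v))
  } else {
    x0 <- resolve_start(land, start)
    list(u = rep(x0[1], N), v = rep(x0[2], N))
  }
}

# second-difference operator with the chosen boundary handling
laplacian_matrix <- function(N, dxi, bc) {
  if (N == 1L) return(matrix(0, 1L, 1L))
  Lp <- matrix(0, N, N)
  for (i in seq_len(N)) {
    Lp[i, i] <- -2
    if (i > 1L) Lp[i, i - 1L] <- 1
    if (i < N) Lp[i, i + 1L] <- 1
  }
  if (bc == "neumann") {           # ghost-cell reflection: zero flux
    Lp[1L, 1L] <- -1
    Lp[N, N] <- -1
  } else {                         # periodic wrap
    Lp[1L, N] <- 1
    Lp[N, 1L] <- 1
  }
  Lp / dxi^2
}

#' Noise increment configuration and sampling
#'
#' `noise_config()` validates and precomputes the spatial structure of the
#' stochastic forcing; `noise_increment()` draws one increment vector (length
#' `N`) from the current RNG state. White noise: i.i.d.
#' `Normal(0, sigma^2 dt / dxi)` per grid point. Colored noise:
#' `sigma sqrt(dt) sum_k w_k eta_k phi_k(xi)` with L2-orthonormal cosine
#' modes `phi_k` and i.i.d. standard normal `eta_k`, giving spatially
#' correlated forcing whose spectrum is set by the weights.
#'
#' @param sigma,dt,dxi,N,L,xi discretisation parameters.
#' @param kind `"white"` or `"colored"`.
#' @param modes,mode_weights number of cosine modes and their weights
#'   (default `1/k`).
#' @return `noise_config()`: a config list; `noise_increment(cfg)`: numeric
#'   vector of length `N`.
#' @export
noise_config <- function(sigma, dt, dxi, N, L = N * dxi, xi = (seq_len(N) - 0.5) * dxi,
                         kind = c("white", "colored"), modes = 8L,
                         mode_weights = NULL) {
  kind <- match.arg(kind)
  cfg <- list(kind = kind, sigma = sigma, dt = dt, dxi = dxi, N = N)
  if (kind == "colored") {
    modes <- as.integer(modes)
    if (modes < 1L) stop("colored noise needs a non-empty mode spectrum")
    if (is.null(mode_weights)) mode_weights <- 1 / seq_len(modes)
    if (length(mode_weights) != modes) stop("mode_weights must have length modes")
    # cosine modes, orthonormal in L2([0, L]): integral phi_k^2 = 1
    Phi <- t(vapply(seq_len(modes),
                    function(k) sqrt(2 / L) * cos(k * pi * xi / L),
                    numeric(N)))
    cfg$Phi <- Phi
    cfg$weights <- as.numeric(mode_weights)
  }
  cfg
}

#' @rdname noise_config
#' @param cfg a `noise_config()` list.
#' @export
noise_increment <- function(cfg) {
  if (cfg$kind == "white") {
    stats::rnorm(cfg$N, sd = cfg$sigma * sqrt(cfg$dt / cfg$dxi))
  } else {
    eta <- stats::rnorm(length(cfg$weights))
    cfg$sigma * sqrt(cfg$dt) * as.vector(crossprod(cfg$Phi, cfg$weights * eta))
  }
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat("Field trajectory:", length(x$times), "snapshots, N =", x$config$N,
      "grid points, sigma =", format(x$config$sigma),
      ", noise =", x$config$noise, "\n")
  invisible(x)
}

#' @export
plot.field_trajectory <- function(x, component = c("u", "v"), ...) {
  component <- match.arg(component)
  z <- x[[component]]
  graphics::image(x$times, x$xi, z,
                  xlab = "t", ylab = expression(xi),
                  main = paste("field", component),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
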