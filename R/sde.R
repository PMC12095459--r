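#' Zero-dimensional stochastic simulation on the landscape
#'
#' Euler--Maruyama integration of the space-free reduction of the stochastic
#' epigenetic model,
#' \deqn{d(u, v) = -\nabla \tilde F(u, v)\,dt + \sigma\, dW,}
#' with two independent Wiener components and the mollified-potential drift.
#' This is the fast workhorse for exit-time and transition studies; the full
#' reaction--diffusion field is [simulate_spde()].
#'
#' @param land a [landscape()].
#' @param moll a [mollifier()].
#' @param sigma noise magnitude (>= 0).
#' @param start basin label, basin index, or numeric `c(u, v)`.
#' @param T time horizon.
#' @param dt time step; must satisfy the drift stability bound
#'   `dt * 4 * max(steepness) <= 1`.
#' @param seed integer seed (trajectories are reproducible bit for bit).
#' @param save_every save every k-th step (default 1).
#' @return an `sde_trajectory`: data.frame `t, u, v` with the configuration
#'   in attributes.
#' @export
simulate_sde <- function(land, moll, sigma, start, T, dt, seed = 1L,
                         save_every = 1L) {
  x0 <- resolve_start(land, start)
  check_dt(land, dt)
  n_steps <- ceiling(T / dt)
  keep <- seq(0L, n_steps, by = save_every)
  res <- with_seed(seed, sde_ensemble(land, moll, sigma,
                                      matrix(x0, nrow = 1L), n_steps, dt,
                                      record_every = save_every))
  out <- data.frame(t = keep * dt, u = res$U[, 1], v = res$V[, 1])
  structure(out, class = c("sde_trajectory", "data.frame"),
            config = list(sigma = sigma, T = T, dt = dt, seed = seed,
                          save_every = save_every, start = start,
                          mollifier = moll[c("kernel", "epsilon", "nodes")]),
            labels = land$labels)
}

#' @export
print.sde_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("SDE trajectory:", nrow(x), "snapshots, t in [0,",
      format(max(x$t)), "], sigma =", format(cfg$sigma), "\n")
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
plot.sde_trajectory <- function(x, land = NULL, ...) {
  if (!is.null(land)) {
    plot(land, ...)
    graphics::lines(x$u, x$v, col = "white", lwd = 0.8)
    graphics::points(x$u[1], x$v[1], pch = 4, col = "red")
  } else {
    graphics::plot(x$u, x$v, type = "l", xlab = "u", ylab = "v", ...)
  }
  invisible(x)
}

resolve_start <- function(land, start) {
  if (is.character(start)) {
    idx <- match(start, land$labels)
    if (is.na(idx)) stop("unknown basin label: ", start)
    land$centers[idx, ]
  } else if (length(start) == 1L && is.numeric(start)) {
    land$centers[as.integer(start), ]
  } else if (is.numeric(start) && length(start) == 2L) {
    as.numeric(start)
  } else stop("start must be a basin label, basin index, or c(u, v)")
}

check_dt <- function(land, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (dt * 4 * max(land$steepness) > 1)
    stop("dt = ", dt, " violates the drift stability bound ",
         "dt * 4 * max(steepness) <= 1 (max steepness ",
         format(max(land$steepness)), ")")
  invisible(TRUE)
}

# Vectorised Euler-Maruyama ensemble. X0 is an M x 2 matrix of starts. Caller
# manages the RNG state. Optional per-step basin recording and first-exit
# stopping (stop_basin: index to exit from; exited replicates are frozen).
sde_ensemble <- function(land, moll, sigma, X0, n_steps, dt,
                         record_every = 0L, record_basins = FALSE,
                         stop_basin = NULL, max_T = NULL) {
  M <- nrow(X0)
  u <- X0[, 1]; v <- X0[, 2]
  sdt <- sqrt(dt)
  rec <- record_every > 0L
  if (rec) {
    S <- n_steps %/% record_every + 1L
    U <- matrix(NA_real_, S, M); V <- matrix(NA_real_, S, M)
    U[1L, ] <- u; V[1L, ] <- v
    B <- if (record_basins) matrix(NA_integer_, S, M) else NULL
    if (record_basins) B[1L, ] <- classify_point(land, u, v)
    ri <- 1L
  } else { U <- V <- B <- NULL }
  stopping <- !is.null(stop_basin)
  if (stopping) {
    alive <- rep(TRUE, M)
    exit_time <- rep(NA_real_, M)
    exit_u <- rep(NA_real_, M); exit_v <- rep(NA_real_, M)
  }
  for (s in seq_len(n_steps)) {
    if (stopping && !any(alive)) break
    idx <- if (stopping) which(alive) else seq_len(M)
    dr <- moll_drift(land, moll, u[idx], v[idx])
    m <- length(idx)
    u[idx] <- u[idx] + dr$fu * dt + sigma * sdt * stats::rnorm(m)
    v[idx] <- v[idx] + dr$fv * dt + sigma * sdt * stats::rnorm(m)
    if (any(!is.finite(u[idx])) || any(!is.finite(v[idx])))
      stop("numerical blow-up at step ", s, " (t = ", format(s * dt), ")")
    if (stopping) {
      b <- classify_point(land, u[idx], v[idx])
      out <- b != stop_basin
      if (any(out)) {
        gone <- idx[out]
        exit_time[gone] <- s * dt
        exit_u[gone] <- u[gone]; exit_v[gone] <- v[gone]
        alive[gone] <- FALSE
      }
    }
    if (rec && s %% record_every == 0L) {
      ri <- ri + 1L
      U[ri, ] <- u; V[ri, ] <- v
      if (record_basins) B[ri, ] <- classify_point(land, u, v)
    }
  }
  out <- list(u = u, v = v, U = U, V = V, basins = B)
  if (stopping) {
    out$exit_time <- exit_time
    out$exit_u <- exit_u; out$exit_v <- exit_v
  }
  out
}
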