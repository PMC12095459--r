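#' Embed attractors into the plane
#'
#' Reduces each attractor's Boolean state (cycles are represented by their
#' mean bit vector) to 2-D coordinates with an exact t-distributed stochastic
#' neighbor embedding, so that attractors with similar activity patterns land
#' close together. The attractor counts involved here are small (tens), where
#' the exact algorithm is appropriate. Deterministic given `seed`.
#'
#' @param aset a (labelled) `attractor_set` from [find_attractors()].
#' @param perplexity t-SNE perplexity; must be smaller than the number of
#'   attractors (default `min(5, (k-1)/3)`).
#' @param iterations gradient-descent iterations (default 600).
#' @param seed integer seed for the random initial layout.
#' @return data.frame with columns `attractor_id, phenotype, u, v,
#'   basin_fraction`, suitable for [build_landscape()].
#' @export
embed_attractors <- function(aset, perplexity = NULL, iterations = 600L,
                             seed = 1L) {
  k <- length(aset)
  if (k < 2L) stop("need at least 2 attractors to embed")
  X <- t(vapply(aset$attractors, function(a) colMeans(a$states),
                numeric(length(aset$nodes))))
  if (is.null(perplexity)) perplexity <- max(1, min(5, (k - 1) / 3))
  if (perplexity >= k) stop("perplexity must be smaller than the number of attractors")
  Y <- with_seed(seed, tsne_exact(X, perplexity, iterations))
  df <- as.data.frame(aset)
  data.frame(attractor_id = df$attractor_id, phenotype = df$phenotype,
             u = Y[, 1], v = Y[, 2], basin_fraction = df$basin_fraction,
             stringsAsFactors = FALSE)
}

# Exact t-SNE for small item counts: conditional gaussian affinities with
# per-point precision calibrated to the target perplexity by bisection,
# symmetrised, then KL gradient descent with momentum and early exaggeration.
tsne_exact <- function(X, perplexity, iterations = 600L, eta = 50) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta_lo <- 1e-12; beta_hi <- 1e12; beta <- 1
    for (iter in 1:64) {
      w <- exp(-di * beta)
      s <- sum(w)
      if (s < .Machine$double.xmin) { H <- 0 } else {
        p <- w / s
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { beta_lo <- beta; beta <- if (beta_hi < 1e12) (beta + beta_hi) / 2 else beta * 2 }
      else { beta_hi <- beta; beta <- (beta + beta_lo) / 2 }
    }
    w <- exp(-di * beta)
    s <- sum(w)
    P[i, -i] <- if (s > 0) w / s else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)   # momentum accumulator
  for (it in seq_len(iterations)) {
    exag <- if (it <= 100L) 4 else 1
    mom <- if (it <= 250L) 0.5 else 0.8
    dy1 <- outer(Y[, 1], Y[, 1], "-")
    dy2 <- outer(Y[, 2], Y[, 2], "-")
    W <- 1 / (1 + dy1^2 + dy2^2); diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (exag * P - Q) * W
    grad <- 4 * cbind(rowSums(L * dy1), rowSums(L * dy2))
    G <- mom * G - eta * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}
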