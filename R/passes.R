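#' Locate mountain passes between basins
#'
#' A mountain pass of the landscape is the lowest point on the boundary
#' between two adjacent basins — the bottleneck through which small-noise
#' transitions occur. For a pair (i, j) the boundary set
#' \eqn{\{a_i r_i^2 = a_j r_j^2 \le a_k r_k^2\}} is the perpendicular
#' bisector of the centers when \eqn{a_i = a_j} and an Apollonius circle
#' otherwise; both are parameterised analytically, probed densely, restricted
#' to the arc actually owned by the pair (no third basin below), and the
#' minimiser is refined by 1-D local optimisation. The analytic candidate on
#' the inter-center segment (at distance \eqn{D\sqrt{a_j}/(\sqrt{a_i} +
#' \sqrt{a_j})} from center i, height \eqn{D^2 a_i a_j/(\sqrt{a_i} +
#' \sqrt{a_j})^2}) is always included as a probe.
#'
#' Pairs whose boundary never appears inside the bounding box (dominated
#' everywhere by other basins) are not adjacent and yield no pass.
#'
#' @param land a [landscape()] with at least 2 basins.
#' @param n_probe number of probe points per pair boundary (default 720).
#' @return a `mountain_passes` object: data.frame with columns
#'   `i, j, label_i, label_j, u, v, height`.
#' @export
find_passes <- function(land, n_probe = 720L) {
  if (land$n < 2L) stop("need at least 2 basins to have passes")
  bb <- bounding_box(land)
  span <- sqrt((bb["umax"] - bb["umin"])^2 + (bb["vmax"] - bb["vmin"])^2)
  res <- list()
  for (i in seq_len(land$n - 1L)) {
    for (j in (i + 1L):land$n) {
      p <- pair_pass(land, i, j, n_probe, span, bb)
      if (!is.null(p)) res[[length(res) + 1L]] <- p
    }
  }
  df <- if (length(res)) do.call(rbind, res) else
    data.frame(i = integer(), j = integer(), label_i = character(),
               label_j = character(), u = numeric(), v = numeric(),
               height = numeric(), stringsAsFactors = FALSE)
  structure(df, class = c("mountain_passes", "data.frame"))
}

#' @export
print.mountain_passes <- function(x, ...) {
  cat("Mountain passes (", nrow(x), " adjacent basin pairs )\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# The (i, j) boundary {a_i r_i^2 = a_j r_j^2} is parameterised in the frame
# of the inter-center axis: with x along c_i -> c_j and y transverse,
# (a_i - a_j)(x^2 + y^2) + 2 a_j D x - a_j D^2 = 0, giving for each y the
# branch(es) x(y) = (-a_j D +/- sqrt(a_i a_j D^2 - (a_i - a_j)^2 y^2)) /
# (a_i - a_j) (a single bisector branch x = D/2 when the steepness is
# equal). This stays well conditioned where the Apollonius circle becomes
# huge (a_i ~ a_j). The global minimum of max(F_i, F_j) sits at y = 0 (the
# on-segment candidate); when a third basin owns that point, the constrained
# minimiser is located by dense probing in y plus local refinement.
pair_pass <- function(land, i, j, n_probe, span, bb) {
  ci <- land$centers[i, ]; cj <- land$centers[j, ]
  ai <- land$steepness[i]; aj <- land$steepness[j]
  D <- sqrt(sum((cj - ci)^2))
  if (D == 0) stop("coincident centers for basins ", i, " and ", j)
  e1 <- (cj - ci) / D
  e2 <- c(-e1[2], e1[1])
  A <- ai - aj
  equal_a <- abs(A) < 1e-10 * max(ai, aj)

  to_plane <- function(x, y) {
    cbind(ci[1] + x * e1[1] + y * e2[1], ci[2] + x * e1[2] + y * e2[2])
  }
  branch_x <- function(y, sign) {
    if (equal_a) return(rep(D / 2, length(y)))
    disc <- ai * aj * D^2 - A^2 * y^2
    x <- rep(NA_real_, length(y))
    ok <- disc >= 0
    x[ok] <- (-aj * D + sign * sqrt(disc[ok])) / A
    x
  }

  y_max <- if (equal_a) span else min(span, D * sqrt(ai * aj) / abs(A))
  ys <- seq(-y_max, y_max, length.out = n_probe + 1L)
  ys <- sort(unique(c(ys, 0)))
  signs <- if (equal_a) 1 else c(1, -1)

  cand_y <- c(); cand_s <- c(); cand_h <- c(); cand_p <- NULL
  for (sg in signs) {
    xs <- branch_x(ys, sg)
    ok <- !is.na(xs)
    if (!any(ok)) next
    pts <- to_plane(xs[ok], ys[ok])
    inside <- pts[, 1] >= bb["umin"] & pts[, 1] <= bb["umax"] &
              pts[, 2] >= bb["vmin"] & pts[, 2] <= bb["vmax"]
    if (!any(inside)) next
    pts <- pts[inside, , drop = FALSE]
    yy <- ys[ok][inside]
    vals <- paraboloid_values(land, pts[, 1], pts[, 2])
    pair_val <- pmax(vals[, i], vals[, j])   # equal on the exact boundary
    others <- vals[, -c(i, j), drop = FALSE]
    owned <- if (ncol(others)) pair_val <= apply(others, 1L, min) * (1 + 1e-9) + 1e-12
             else rep(TRUE, nrow(pts))
    if (!any(owned)) next
    cand_y <- c(cand_y, yy[owned])
    cand_s <- c(cand_s, rep(sg, sum(owned)))
    cand_h <- c(cand_h, pair_val[owned])
    cand_p <- rbind(cand_p, pts[owned, , drop = FALSE])
  }
  if (!length(cand_h)) return(NULL)

  best <- which.min(cand_h)
  y0 <- cand_y[best]; sg <- cand_s[best]
  dy <- if (length(ys) > 1L) ys[2] - ys[1] else y_max
  obj <- function(y) {
    x <- branch_x(y, sg)
    if (is.na(x)) return(Inf)
    p <- to_plane(x, y)
    max(sum((p - ci)^2) * ai, sum((p - cj)^2) * aj)
  }
  y_disc <- if (equal_a) Inf else D * sqrt(ai * aj) / abs(A)
  opt <- stats::optimize(obj, lower = max(y0 - dy, -y_disc),
                         upper = min(y0 + dy, y_disc))
  p_ref <- to_plane(branch_x(opt$minimum, sg), opt$minimum)
  v_ref <- paraboloid_values(land, p_ref[1], p_ref[2])
  still_owned <- all(max(v_ref[i], v_ref[j]) <=
                       v_ref[-c(i, j)] * (1 + 1e-9) + 1e-12)
  if (is.finite(opt$objective) && still_owned && opt$objective < cand_h[best]) {
    p_best <- p_ref; h_best <- opt$objective
  } else {
    p_best <- cand_p[best, , drop = FALSE]; h_best <- cand_h[best]
  }
  data.frame(i = i, j = j, label_i = land$labels[i], label_j = land$labels[j],
             u = p_best[1], v = p_best[2], height = h_best,
             stringsAsFactors = FALSE)
}
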