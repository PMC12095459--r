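#' Epigenetic (Waddington) landscape as a minimum of paraboloids
#'
#' The potential is
#' \deqn{F(u,v) = \min_i \; a_i\,[(u-u_i)^2 + (v-v_i)^2],}
#' where \eqn{(u_i, v_i)} are basin centers, one per phenotype, and
#' \eqn{a_i > 0} are steepness parameters derived from basin-of-attraction
#' sizes. Every basin bottom sits at \eqn{F = 0}; barriers between basins are
#' the heights of the mountain passes on the pairwise boundaries.
#'
#' @param centers numeric matrix (n x 2) of basin centers, or data.frame with
#'   columns `u`, `v`.
#' @param steepness positive numeric vector of length n.
#' @param labels unique phenotype names, length n.
#' @param fractions optional basin fractions the steepness was derived from.
#' @param depth_rule,scale provenance of the steepness mapping (see
#'   [build_landscape()]).
#' @return an object of class `landscape`.
#' @export
landscape <- function(centers, steepness, labels,
                      fractions = NULL, depth_rule = "manual", scale = NA_real_) {
  if (is.data.frame(centers)) centers <- cbind(centers$u, centers$v)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  n <- nrow(centers)
  if (n < 1L) stop("a landscape needs at least one basin")
  if (length(steepness) != n || length(labels) != n)
    stop("centers, steepness and labels must have matching length")
  if (any(!is.finite(steepness)) || any(steepness <= 0))
    stop("all steepness values must be positive and finite")
  if (anyDuplicated(labels)) stop("basin labels must be unique")
  d <- as.matrix(stats::dist(centers))
  if (n > 1L && min(d[upper.tri(d)]) == 0) stop("basin centers must be pairwise distinct")
  colnames(centers) <- c("u", "v")
  structure(list(n = n, centers = centers, steepness = as.numeric(steepness),
                 labels = as.character(labels),
                 fractions = if (is.null(fractions)) NULL else as.numeric(fractions),
                 depth_rule = depth_rule, scale = scale),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("Epigenetic landscape:", x$n, "basins (min-of-paraboloids)\n")
  df <- data.frame(label = x$labels, u = x$centers[, 1], v = x$centers[, 2],
                   steepness = x$steepness)
  if (!is.null(x$fractions)) df$basin_fraction <- x$fractions
  print(df, row.names = FALSE)
  if (!identical(x$depth_rule, "manual"))
    cat("depth rule:", x$depth_rule, " scale:", format(x$scale), "\n")
  invisible(x)
}

#' @export
summary.landscape <- function(object, ...) {
  print(object)
  if (object$n >= 2) {
    p <- find_passes(object)
    cat("\nMountain passes:\n")
    print(as.data.frame(p), row.names = FALSE)
  }
  invisible(object)
}

#' Build a landscape from labelled, embedded attractors
#'
#' One basin per phenotype: the center is the centroid of that phenotype's
#' attractor coordinates and the steepness encodes the pooled basin fraction
#' through `depth_rule`. The default `"proportional"` rule sets
#' `a_i = scale * fraction_i`, so phenotypes with larger basins of attraction
#' get steeper wells and hence higher escape barriers; `"inverse"`
#' (`a_i = scale / fraction_i`) and `"log"` (`a_i = -scale / log(fraction_i)`,
#' for fractions < 1) are also registered.
#'
#' @param coords data.frame with columns `phenotype`, `u`, `v`,
#'   `basin_fraction` — one row per attractor (see [embed_attractors()]).
#' @param depth_rule `"proportional"` (default), `"inverse"` or `"log"`.
#' @param scale positive multiplier of the depth rule.
#' @return a [landscape()].
#' @export
build_landscape <- function(coords, depth_rule = c("proportional", "inverse", "log"),
                            scale = 1) {
  depth_rule <- match.arg(depth_rule)
  if (scale <= 0) stop("scale must be positive")
  need <- c("phenotype", "u", "v", "basin_fraction")
  if (!all(need %in% names(coords)))
    stop("coords must have columns: ", paste(need, collapse = ", "))
  if (any(coords$basin_fraction <= 0))
    stop("cannot size a basin with zero basin fraction")
  labs <- unique(coords$phenotype)
  agg <- lapply(labs, function(ph) {
    sub <- coords[coords$phenotype == ph, , drop = FALSE]
    c(u = mean(sub$u), v = mean(sub$v), frac = sum(sub$basin_fraction))
  })
  agg <- do.call(rbind, agg)
  frac <- agg[, "frac"]
  a <- switch(depth_rule,
              proportional = scale * frac,
              inverse = scale / frac,
              log = {
                if (any(frac >= 1)) stop("log depth rule needs fractions < 1")
                -scale / log(frac)
              })
  landscape(agg[, c("u", "v")], a, labs, fractions = frac,
            depth_rule = depth_rule, scale = scale)
}

#' Evaluate the landscape potential
#'
#' @param land a [landscape()].
#' @param u,v coordinates (vectors of equal length).
#' @return `F(u, v) = min_i a_i ((u-u_i)^2 + (v-v_i)^2)`, vectorised.
#' @export
potential <- function(land, u, v) {
  vals <- paraboloid_values(land, u, v)
  do.call(pmin, as.data.frame(vals))
}

# n_points x n_basins matrix of a_i * squared distance
paraboloid_values <- function(land, u, v) {
  du <- outer(u, land$centers[, 1], "-")
  dv <- outer(v, land$centers[, 2], "-")
  sweep(du * du + dv * dv, 2L, land$steepness, "*")
}

#' Assign points to basins
#'
#' Returns for each point the index of the paraboloid attaining the minimum
#' in the potential (ties broken toward the lowest index), i.e. the basin of
#' the multiplicatively weighted Voronoi partition induced by the landscape.
#'
#' @inheritParams potential
#' @return integer vector of basin indices.
#' @export
classify_point <- function(land, u, v) {
  vals <- paraboloid_values(land, u, v)
  max.col(-vals, ties.method = "first")
}

bounding_box <- function(land, pad_factor = 3) {
  pad <- if (land$n == 1L) pad_factor else 0.5 * max(stats::dist(land$centers))
  c(umin = min(land$centers[, 1]) - pad, umax = max(land$centers[, 1]) + pad,
    vmin = min(land$centers[, 2]) - pad, vmax = max(land$centers[, 2]) + pad)
}

max_pass_height <- function(land) {
  if (land$n < 2L) return(1)
  d <- as.matrix(stats::dist(land$centers))
  max(d)^2 * max(land$steepness)
}

#' Cluster basin centers by spatial proximity
#'
#' Single-linkage hierarchical clustering of the basin centers with a
#' largest-gap cutoff: the tree is cut where consecutive merge heights jump
#' the most, which separates well-spaced groups without a preset cluster
#' count. A fixed `k` can be forced instead.
#'
#' @param land a [landscape()].
#' @param k optional fixed number of clusters (overrides the gap rule).
#' @param method linkage method for [stats::hclust()] (default
#'   `"single"`).
#' @return list with `assignment` (integer per basin), `k`, and `clusters`
#'   (list of phenotype label vectors).
#' @export
cluster_centers <- function(land, k = NULL, method = "single") {
  if (land$n < 2L) {
    return(list(assignment = rep(1L, land$n), k = 1L,
                clusters = list(land$labels)))
  }
  d <- stats::dist(land$centers)
  if (max(d) < sqrt(.Machine$double.eps)) {
    return(list(assignment = rep(1L, land$n), k = 1L, clusters = list(land$labels)))
  }
  hc <- stats::hclust(d, method = method)
  if (is.null(k)) {
    h <- hc$height
    if (length(h) == 1L) {
      k <- 1L
    } else {
      # cut where consecutive merge heights jump the most on a log scale
      # (relative gap), which is insensitive to the absolute coordinate scale
      gaps <- diff(log(pmax(h, .Machine$double.eps)))
      cut_at <- which.max(gaps)
      k <- land$n - cut_at
      if (max(gaps) < log(1.5)) k <- 1L  # no dominant gap: one cluster
    }
  }
  assignment <- stats::cutree(hc, k = k)
  clusters <- split(land$labels, assignment)
  list(assignment = as.integer(assignment), k = as.integer(max(assignment)),
       clusters = unname(clusters))
}

#' Contour plot of the landscape
#'
#' Draws filled contours of the (optionally mollified) potential with basin
#' centers and labels overlaid. Purely a rendering aid; the optional
#' `render_offset` deepens each well by its steepness for visual relief and
#' never enters the dynamics.
#'
#' @param x a [landscape()].
#' @param grid_n grid resolution per axis.
#' @param mollifier optional [mollifier()] used for the plotted surface.
#' @param render_offset logical; subtract a per-basin depth offset for
#'   display.
#' @param ... passed to [graphics::image()].
#' @export
plot.landscape <- function(x, grid_n = 120L, mollifier = NULL,
                           render_offset = FALSE, ...) {
  bb <- bounding_box(x)
  us <- seq(bb["umin"], bb["umax"], length.out = grid_n)
  vs <- seq(bb["vmin"], bb["vmax"], length.out = grid_n)
  g <- expand.grid(u = us, v = vs)
  z <- if (is.null(mollifier)) potential(x, g$u, g$v)
       else mollified_potential(x, mollifier, g$u, g$v)$value
  if (render_offset) {
    b <- classify_point(x, g$u, g$v)
    z <- z - 0.5 * max_pass_height(x) * x$steepness[b] / max(x$steepness)
  }
  zm <- matrix(z, nrow = grid_n)
  graphics::image(us, vs, zm, col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "u", ylab = "v", ...)
  graphics::contour(us, vs, zm, add = TRUE, drawlabels = FALSE,
                    col = grDevices::grey(0.35))
  graphics::points(x$centers[, 1], x$centers[, 2], pch = 19, cex = 0.8)
  graphics::text(x$centers[, 1], x$centers[, 2], x$labels, pos = 3, cex = 0.7)
  invisible(x)
}
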