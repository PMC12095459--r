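#' Toy Boolean networks with known attractor structure
#'
#' Generators for small test networks whose attractors and basins are known
#' exactly (or checkable by exhaustive enumeration):
#' \describe{
#'   \item{`"toy3"`}{mutual-activation pair plus repressed reporter
#'     (`A <- B`, `B <- A`, `C <- NOT A`): two fixed points `001` and `110`
#'     with basins of 2 each, and one 2-cycle `010 <-> 101` with basin 4.}
#'   \item{`"ring"`}{a ring in which each node copies its predecessor and one
#'     link is negated (an odd negative feedback loop): the update map is a
#'     bijection, so there are no transient states and every attractor is a
#'     cycle whose basin is the cycle itself.}
#'   \item{`"random_k"`}{each node is driven by a random expression over `k`
#'     randomly chosen regulators; reproducible given `seed`.}
#' }
#'
#' @param type one of `"toy3"`, `"ring"`, `"random_k"`.
#' @param n node count (ring and random_k; default 5).
#' @param k regulators per node for random_k (default 2).
#' @param seed integer seed for random_k.
#' @return a [boolean_network()].
#' @export
make_toy_network <- function(type = c("toy3", "ring", "random_k"),
                             n = 5L, k = 2L, seed = 1L) {
  type <- match.arg(type)
  if (type == "toy3") {
    return(boolean_network(c("A", "B", "C"),
                           c(A = "B", B = "A", C = "NOT A")))
  }
  if (type == "ring") {
    if (n < 2L) stop("ring needs at least 2 nodes")
    nodes <- paste0("N", seq_len(n))
    prev <- c(n, seq_len(n - 1L))
    rules <- stats::setNames(nodes[prev], nodes)
    rules[1L] <- paste("NOT", rules[1L])
    return(boolean_network(nodes, rules))
  }
  # random_k
  if (k < 1L || k > n) stop("k must be in 1..n")
  nodes <- paste0("N", seq_len(n))
  rules <- with_seed(seed, vapply(seq_len(n), function(i) {
    regs <- sample(nodes, k)
    lits <- ifelse(stats::runif(k) < 0.4, paste("NOT", regs), regs)
    ops <- sample(c("AND", "OR"), max(k - 1L, 0L), replace = TRUE)
    expr <- lits[1L]
    if (k > 1L) for (j in 2L:k) expr <- paste0("(", expr, ") ", ops[j - 1L], " ", lits[j])
    expr
  }, character(1)))
  boolean_network(nodes, stats::setNames(rules, nodes))
}

# geometry of the packaged 13-phenotype reference landscape: five spatial
# clusters (one anti-tumoral holding M1 and M1M2d together with M0 and the
# M1-hybrid, four purely M2) with within-cluster center spacing well below
# the between-cluster spacing, and steepness values chosen so that the
# barrier ordering reproduces the canonical polarization routes
# (M1 -> M1M2d -> M2aM2d...; M0 -> M2d/M2bM2d cluster).
reference_geometry <- function() {
  g <- data.frame(
    label = c("M1", "M1M2d", "M1M2bM2cM2d", "M0",
              "M2bM2d", "M2d",
              "M2aM2d", "M2aM2bM2d",
              "M2a", "M2b", "M2aM2b",
              "M2c", "M2cM2d"),
    u = c(0.50, 0.84, 0.28, 1.26,
          1.95, 2.38,
          1.58, 2.08,
          3.05, 3.35, 3.28,
          3.30, 3.62),
    v = c(1.50, 1.50, 1.02, 1.78,
          2.48, 2.55,
          0.92, 0.78,
          0.50, 0.72, 0.28,
          2.85, 2.63),
    a = c(2.00, 1.30, 2.00, 1.44,
          0.09, 1.00,
          0.35, 0.60,
          1.20, 1.20, 1.20,
          1.20, 1.20),
    cluster = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L),
    stringsAsFactors = FALSE)
  g
}

#' The packaged 13-basin reference landscape
#'
#' A synthetic stand-in for the macrophage epigenetic landscape whose exact
#' geometry is not printed anywhere: it honors the published topology — 13
#' phenotype basins arranged in 5 spatial clusters, exactly one of which
#' (the anti-tumoral cluster) contains both M1 and M1M2d, the other four
#' containing only M2-compartment phenotypes — and a barrier ordering under
#' which the canonical noise-induced polarization routes (M1 into M1M2d and
#' onward to the M2aM2d cluster; the M0 monocyte into the M2d/M2bM2d
#' cluster) are the typical escape paths. Steepness values are recorded as a
#' proportional depth rule over per-basin fractions `a_i / sum(a)`.
#'
#' @param seed accepted for interface uniformity; the geometry is fixed, so
#'   every seed returns the same landscape.
#' @return a [landscape()] with 13 basins.
#' @export
make_reference_landscape <- function(seed = 1L) {
  g <- reference_geometry()
  land <- landscape(cbind(g$u, g$v), g$a, g$label,
                    fractions = g$a / sum(g$a),
                    depth_rule = "proportional", scale = sum(g$a))
  validate_reference(land, g$cluster)
  land
}

validate_reference <- function(land, expected_cluster) {
  if (land$n != 13L) stop("reference landscape must have 13 basins")
  cl <- cluster_centers(land)
  if (cl$k != 5L) stop("reference landscape must form 5 clusters (got ", cl$k, ")")
  anti <- cl$clusters[vapply(cl$clusters, function(x) "M1" %in% x, logical(1))]
  if (length(anti) != 1L || !"M1M2d" %in% anti[[1L]])
    stop("exactly one cluster must contain both M1 and M1M2d")
  pure_m2 <- vapply(cl$clusters, function(x)
    all(!grepl("M1", x) & x != "M0"), logical(1))
  if (sum(pure_m2) != 4L)
    stop("four clusters must contain only M2-compartment phenotypes")
  invisible(TRUE)
}

#' A calibrated symmetric double well
#'
#' Two basins of equal steepness `a` separated by `separation`, whose single
#' mountain pass sits at the midpoint with height
#' `a * separation^2 / 4`. The standard fixture for exit-time scaling
#' (Kramers/Freidlin--Wentzell checks) and pass-localization studies.
#'
#' @param steepness steepness of both wells (default 4).
#' @param separation center separation (default 1).
#' @return a [landscape()] with basins labelled `"left"`, `"right"`.
#' @export
make_double_well <- function(steepness = 4, separation = 1) {
  landscape(rbind(c(0, 0), c(separation, 0)),
            c(steepness, steepness), c("left", "right"))
}
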