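# shared fixtures and independent oracles for the test suite

toy3 <- function() make_toy_network("toy3")

# random small landscape with separated centers, for property tests
random_landscape <- function(n, seed) {
  set.seed(seed)
  repeat {
    centers <- cbind(runif(n, 0, 3), runif(n, 0, 3))
    if (n == 1 || min(dist(centers)) > 0.3) break
  }
  landscape(centers, runif(n, 0.3, 3), paste0("B", seq_len(n)))
}

# Brute-force mountain-pass oracle: scan a dense grid, find 4-neighbor cell
# pairs owned by different basins, and take the minimum of the pairwise
# boundary value max(F_i, F_j) over shared midpoints that really lie on the
# pair's owned boundary (no third basin below, up to the gradient-scaled
# grid slack). Returns per unordered pair the oracle height and a
# discretisation tolerance |grad F| * cell size to compare at.
brute_force_passes <- function(land, grid_n = 301L) {
  bb <- polarscape:::bounding_box(land)
  us <- seq(bb["umin"], bb["umax"], length.out = grid_n)
  vs <- seq(bb["vmin"], bb["vmax"], length.out = grid_n)
  cell <- max(us[2] - us[1], vs[2] - vs[1])
  g <- expand.grid(u = us, v = vs)
  own <- matrix(classify_point(land, g$u, g$v), nrow = grid_n)
  best <- new.env()
  consider <- function(i1, j1, i2, j2) {
    o1 <- own[cbind(i1, j1)]; o2 <- own[cbind(i2, j2)]
    sel <- which(o1 != o2)
    if (!length(sel)) return()
    mu <- (us[i1[sel]] + us[i2[sel]]) / 2
    mv <- (vs[j1[sel]] + vs[j2[sel]]) / 2
    a <- pmin(o1[sel], o2[sel]); b <- pmax(o1[sel], o2[sel])
    vals <- polarscape:::paraboloid_values(land, mu, mv)
    pv <- pmax(vals[cbind(seq_along(a), a)], vals[cbind(seq_along(b), b)])
    # local gradient bound 2 sqrt(a_max * F) * cell: reported as the
    # comparison tolerance for the discretisation error of the height.
    # Ownership is strict: midpoints where a third basin is already below
    # the pair are triple-junction artifacts, not (i, j) boundary.
    gtol <- 2 * sqrt(max(land$steepness) * pmax(pv, 1e-12)) * cell
    omin <- rep(Inf, length(a))
    if (land$n > 2) {
      for (kk in seq_len(land$n)) {
        mask <- kk != a & kk != b
        omin[mask] <- pmin(omin[mask], vals[mask, kk])
      }
    }
    keep <- which(pv <= omin)
    for (k in keep) {
      key <- paste(a[k], b[k], sep = "-")
      cur <- best[[key]]
      if (is.null(cur) || pv[k] < cur[1]) best[[key]] <- c(pv[k], gtol[k])
    }
  }
  idx <- seq_len(grid_n - 1L)
  # horizontal neighbors
  ii <- rep(idx, times = grid_n); jj <- rep(seq_len(grid_n), each = grid_n - 1L)
  consider(ii, jj, ii + 1L, jj)
  # vertical neighbors
  ii <- rep(seq_len(grid_n), times = grid_n - 1L); jj <- rep(idx, each = grid_n)
  consider(ii, jj, ii, jj + 1L)
  keys <- ls(best)
  if (!length(keys)) return(data.frame(i = integer(), j = integer(),
                                       height = numeric(), tol = numeric()))
  parts <- do.call(rbind, strsplit(keys, "-"))
  data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
             height = vapply(keys, function(k) best[[k]][1], numeric(1)),
             tol = vapply(keys, function(k) best[[k]][2], numeric(1)))
}

# quick occupancy profile builder from raw parts (for detector unit tests)
fake_profile <- function(times, fractions, labels,
                         mean_u = rep(0, length(times)),
                         mean_v = rep(0, length(times))) {
  structure(list(times = times, fractions = fractions,
                 mean_u = mean_u, mean_v = mean_v, labels = labels),
            class = "occupancy_profile")
}
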