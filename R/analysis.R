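#' Basin occupancy of a trajectory
#'
#' Classifies every grid point of every snapshot into its landscape basin and
#' returns the per-snapshot occupancy fractions (for the 0-D reduction the
#' fractions are the indicator of the current basin). Fractions sum to 1 at
#' every time.
#'
#' @param traj an `sde_trajectory` or `field_trajectory`.
#' @param land the [landscape()] the trajectory was simulated on.
#' @return an `occupancy_profile`: list with `times`, `fractions`
#'   (snapshots x basins, columns named by phenotype), and the spatial mean
#'   field `mean_u`, `mean_v` per snapshot.
#' @export
occupancy <- function(traj, land) {
  if (inherits(traj, "sde_trajectory")) {
    b <- classify_point(land, traj$u, traj$v)
    S <- nrow(traj)
    fr <- matrix(0, S, land$n, dimnames = list(NULL, land$labels))
    fr[cbind(seq_len(S), b)] <- 1
    prof <- list(times = traj$t, fractions = fr,
                 mean_u = traj$u, mean_v = traj$v, labels = land$labels)
  } else if (inherits(traj, "field_trajectory")) {
    S <- length(traj$times)
    N <- ncol(traj$u)
    fr <- matrix(0, S, land$n, dimnames = list(NULL, land$labels))
    for (s in seq_len(S)) {
      b <- classify_point(land, traj$u[s, ], traj$v[s, ])
      fr[s, ] <- tabulate(b, nbins = land$n) / N
    }
    prof <- list(times = traj$times, fractions = fr,
                 mean_u = rowMeans(traj$u), mean_v = rowMeans(traj$v),
                 labels = land$labels)
  } else stop("traj must be an sde_trajectory or field_trajectory")
  structure(prof, class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("Occupancy profile:", length(x$times), "snapshots,",
      ncol(x$fractions), "basins\n")
  dom <- dominant_basin(x, 0.5)
  occ <- table(factor(x$labels[pmax(dom, 1L)][dom > 0L], levels = x$labels))
  print(occ / length(x$times))
  invisible(x)
}

# index of the basin exceeding the dominance threshold at each snapshot;
# 0 = mixed (no basin dominant)
dominant_basin <- function(profile, dominance) {
  j <- max.col(profile$fractions, ties.method = "first")
  fmax <- profile$fractions[cbind(seq_along(j), j)]
  ifelse(fmax > dominance, j, 0L)
}

#' Detect basin-dominance transitions
#'
#' The dominant basin at a snapshot is the one whose occupancy fraction
#' exceeds `dominance` (otherwise the snapshot is "mixed" and emits no
#' events). An event is recorded whenever the dominant basin changes between
#' consecutive dominant snapshots: these are the noise-induced polarization
#' events. The crossing point is the spatial mean field at the flip snapshot.
#'
#' @param profile an [occupancy()] profile.
#' @param dominance dominance threshold in (0, 1] (default 0.5).
#' @return a `transition_events` data.frame: `time, source, target, u_cross,
#'   v_cross`.
#' @export
detect_transitions <- function(profile, dominance = 0.5) {
  if (dominance <= 0 || dominance > 1) stop("dominance must be in (0, 1]")
  dom <- dominant_basin(profile, dominance)
  keep <- which(dom > 0L)
  ev <- events_from_sequence(dom[keep], keep, profile)
  structure(ev, class = c("transition_events", "data.frame"))
}

events_from_sequence <- function(seq_dom, snap_idx, profile) {
  if (length(seq_dom) < 2L) {
    return(data.frame(time = numeric(), source = character(),
                      target = character(), u_cross = numeric(),
                      v_cross = numeric(), stringsAsFactors = FALSE))
  }
  flips <- which(diff(seq_dom) != 0L) + 1L
  data.frame(
    time = profile$times[snap_idx[flips]],
    source = profile$labels[seq_dom[flips - 1L]],
    target = profile$labels[seq_dom[flips]],
    u_cross = profile$mean_u[snap_idx[flips]],
    v_cross = profile$mean_v[snap_idx[flips]],
    stringsAsFactors = FALSE)
}

#' Polarization itinerary from transition events
#'
#' @param events a `transition_events` data.frame (time-sorted).
#' @param start label of the initial dominant basin, used when there are no
#'   events; inferred from the first event's source otherwise.
#' @return ordered character vector of visited basin labels (consecutive
#'   duplicates collapsed; revisits are kept).
#' @export
polarization_sequence <- function(events, start = NULL) {
  if (nrow(events) == 0L) {
    return(if (is.null(start)) character(0) else start)
  }
  seqs <- c(events$source[1L], events$target)
  if (!is.null(start) && start != seqs[1L]) seqs <- c(start, seqs)
  rle(seqs)$values
}

#' First-exit times versus noise magnitude
#'
#' For each noise magnitude, runs an ensemble of replicates started at a
#' basin center and records the first time the trajectory's basin (dominant
#' basin for the field model) differs from the starting basin; replicates
#' that never exit are censored at the horizon and excluded from the mean.
#' Mean exit time grows steeply as sigma decreases (exponentially in
#' `1/sigma^2`, with rate set by the pass height, in the small-noise limit).
#'
#' @param land a [landscape()].
#' @param moll a [mollifier()].
#' @param start basin label or index to start from (at its center).
#' @param sigmas numeric vector of noise magnitudes.
#' @param replicates ensemble size per sigma (>= 2).
#' @param T horizon.
#' @param dt time step.
#' @param seed integer seed.
#' @param mode `"sde"` (0-D reduction, default) or `"spde"` (full field;
#'   slower).
#' @param ... for `mode = "spde"`: arguments passed to [simulate_spde()].
#' @return an `exit_time_summary` data.frame with one row per sigma:
#'   `sigma, n, n_censored, mean, median, se`; per-replicate exit times and
#'   crossing points are in `attr(, "detail")`.
#' @export
exit_time_study <- function(land, moll, start, sigmas, replicates = 200L,
                            T = 100, dt = 0.01, seed = 1L,
                            mode = c("sde", "spde"), ...) {
  mode <- match.arg(mode)
  if (replicates < 2L) stop("need at least 2 replicates")
  x0 <- resolve_start(land, start)
  b0 <- classify_point(land, x0[1], x0[2])
  check_dt(land, dt)
  n_steps <- ceiling(T / dt)
  rows <- list(); detail <- list()
  for (k in seq_along(sigmas)) {
    sg <- sigmas[k]
    if (mode == "sde") {
      res <- with_seed(seed + k - 1L, sde_ensemble(
        land, moll, sg, matrix(rep(x0, each = replicates), ncol = 2L),
        n_steps, dt, stop_basin = b0))
      et <- res$exit_time
      eu <- res$exit_u; ev <- res$exit_v
    } else {
      et <- eu <- ev <- rep(NA_real_, replicates)
      for (r in seq_len(replicates)) {
        traj <- simulate_spde(land, moll, sigma = sg, start = start,
                              T = T, dt = dt, seed = seed + k * 100003L + r, ...)
        prof <- occupancy(traj, land)
        dom <- dominant_basin(prof, 0.5)
        hit <- which(dom > 0L & dom != b0)
        if (length(hit)) {
          et[r] <- prof$times[hit[1L]]
          eu[r] <- prof$mean_u[hit[1L]]; ev[r] <- prof$mean_v[hit[1L]]
        }
      }
    }
    ok <- !is.na(et)
    rows[[k]] <- data.frame(
      sigma = sg, n = replicates, n_censored = sum(!ok),
      mean = if (any(ok)) mean(et[ok]) else NA_real_,
      median = if (any(ok)) stats::median(et[ok]) else NA_real_,
      se = if (sum(ok) > 1L) stats::sd(et[ok]) / sqrt(sum(ok)) else NA_real_)
    detail[[k]] <- data.frame(sigma = sg, replicate = seq_len(replicates),
                              exit_time = et, u_exit = eu, v_exit = ev)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("exit_time_summary", "data.frame"),
            detail = do.call(rbind, detail),
            start = land$labels[b0], horizon = T, mode = mode, seed = seed)
}

#' @export
print.exit_time_summary <- function(x, ...) {
  cat("First-exit times from basin '", attr(x, "start"), "' (mode ",
      attr(x, "mode"), ", horizon ", format(attr(x, "horizon")), ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  cens <- x$n_censored == x$n
  if (any(cens))
    cat("note: all replicates censored at sigma =",
        paste(format(x$sigma[cens]), collapse = ", "), "\n")
  invisible(x)
}

#' Localize transition events at mountain passes
#'
#' Matches each event's crossing point against the mountain pass of its
#' (source, target) basin pair (unordered). In the small-noise limit
#' transitions concentrate at the passes, so the matched fraction tends to 1
#' and the distances shrink as sigma decreases. Events between basins with no
#' shared boundary (no pass) count as unmatched.
#'
#' @param events a `transition_events` data.frame (or the exit detail of an
#'   [exit_time_study()], with columns `source`/`target` supplied via
#'   `source_target`).
#' @param passes a [find_passes()] result on the same landscape.
#' @param tolerance matching radius in landscape units (> 0).
#' @return list with `fraction` (matched fraction; `NA` when there are no
#'   events) and `distances` (per-event distance to its pass, `NA` when the
#'   pair has none).
#' @export
pass_localization <- function(events, passes, tolerance) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (nrow(events) == 0L)
    return(list(fraction = NA_real_, distances = numeric(0)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pk <- key(passes$label_i, passes$label_j)
  ek <- key(events$source, events$target)
  idx <- match(ek, pk)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " event(s) between basins with no shared pass")
  d <- sqrt((events$u_cross - passes$u[idx])^2 +
            (events$v_cross - passes$v[idx])^2)
  matched <- !is.na(d) & d <= tolerance
  list(fraction = mean(matched), distances = d)
}

#' Ensemble polarization itineraries
#'
#' Runs an ensemble of 0-D trajectories from a basin center and summarises
#' each replicate's polarization itinerary: the ordered sequence of dominant
#' basins visited, the first transition, the set of basins reached, and the
#' final basin at the horizon. This is the ensemble view of the
#' noise-induced polarization runs behind the sigma-sweep figures.
#'
#' @param land a [landscape()].
#' @param moll a [mollifier()].
#' @param start basin label or index (started at its center).
#' @param sigma noise magnitude.
#' @param T horizon.
#' @param dt time step.
#' @param replicates ensemble size.
#' @param seed integer seed.
#' @param thin record the basin every `thin`-th step (default 10).
#' @return a `polarization_study`: list with `itineraries` (one label vector
#'   per replicate), `first_transition` (e.g. `"M1->M1M2d"`, `NA` if none),
#'   `final` (final basin label per replicate), and the run configuration.
#' @export
polarization_study <- function(land, moll, start, sigma, T, dt = 0.01,
                               replicates = 100L, seed = 1L, thin = 10L) {
  x0 <- resolve_start(land, start)
  check_dt(land, dt)
  n_steps <- ceiling(T / dt)
  res <- with_seed(seed, sde_ensemble(
    land, moll, sigma, matrix(rep(x0, each = replicates), ncol = 2L),
    n_steps, dt, record_every = thin, record_basins = TRUE))
  B <- res$basins
  itins <- lapply(seq_len(ncol(B)), function(r) land$labels[rle(B[, r])$values])
  first <- vapply(itins, function(it)
    if (length(it) > 1L) paste0(it[1L], "->", it[2L]) else NA_character_,
    character(1))
  final <- vapply(itins, function(it) it[length(it)], character(1))
  structure(list(itineraries = itins, first_transition = first, final = final,
                 config = list(start = start, sigma = sigma, T = T, dt = dt,
                               replicates = replicates, seed = seed,
                               thin = thin)),
            class = "polarization_study")
}

#' @export
print.polarization_study <- function(x, ...) {
  cfg <- x$config
  cat("Polarization study: start", cfg$start, ", sigma", format(cfg$sigma),
      ",", cfg$replicates, "replicates, T =", format(cfg$T), "\n")
  cat("first transitions:\n")
  print(sort(table(x$first_transition, useNA = "ifany"), decreasing = TRUE))
  cat("final basins:\n")
  print(sort(table(x$final), decreasing = TRUE))
  invisible(x)
}
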