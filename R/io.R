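#' Read and write package file formats
#'
#' Plain-text interchange formats for every domain object: Boolean networks
#' and landscapes as JSON, attractor tables / scan reports / transition
#' events / exit-time summaries as CSV, and trajectories as CSV with a JSON
#' provenance header line. All writers and readers round-trip: labels and
#' integers exactly, reals to full double precision.
#'
#' @param net,land,x objects to write.
#' @param path file path.
#' @name polarscape-io
NULL

FORMAT_VERSION <- "polarscape-1"

#' @rdname polarscape-io
#' @export
write_network_json <- function(net, path) {
  obj <- list(format = FORMAT_VERSION, type = "boolean_network",
              nodes = net$nodes,
              rules = as.list(stats::setNames(net$rules, net$nodes)))
  if (length(net$clamps)) obj$clamps <- as.list(net$clamps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_network_json <- function(path) {
  obj <- read_versioned_json(path, "boolean_network")
  clamps <- if (!is.null(obj$clamps)) unlist(obj$clamps) else NULL
  boolean_network(unlist(obj$nodes), unlist(obj$rules), clamps = clamps)
}

#' @rdname polarscape-io
#' @export
write_landscape_json <- function(land, path) {
  obj <- list(format = FORMAT_VERSION, type = "landscape",
              labels = land$labels,
              centers = unname(apply(land$centers, 1L, as.list)),
              steepness = land$steepness,
              depth_rule = land$depth_rule, scale = land$scale)
  if (!is.null(land$fractions)) obj$fractions <- land$fractions
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_landscape_json <- function(path) {
  obj <- read_versioned_json(path, "landscape")
  centers <- do.call(rbind, lapply(obj$centers, function(p) unlist(p)))
  landscape(centers, unlist(obj$steepness), unlist(obj$labels),
            fractions = if (!is.null(obj$fractions)) unlist(obj$fractions),
            depth_rule = if (!is.null(obj$depth_rule)) obj$depth_rule else "manual",
            scale = if (!is.null(obj$scale)) obj$scale else NA_real_)
}

read_versioned_json <- function(path, expected_type) {
  force(path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$format) || obj$format != FORMAT_VERSION)
    stop(path, ": unsupported or missing format version (expected ",
         FORMAT_VERSION, ")")
  if (!identical(obj$type, expected_type))
    stop(path, ": expected a ", expected_type, " file, found '",
         if (is.null(obj$type)) "?" else obj$type, "'")
  obj
}

#' @rdname polarscape-io
#' @param aset an `attractor_set`.
#' @export
write_attractors_csv <- function(aset, path) {
  utils::write.csv(as.data.frame(aset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_attractors_csv <- function(path) {
  df <- read_checked_csv(path,
    required = c("attractor_id", "state_sequence", "basin_size",
                 "basin_fraction", "phenotype"),
    numeric_cols = c("attractor_id", "basin_size", "basin_fraction"))
  df
}

#' @rdname polarscape-io
#' @param report a `scan_report`.
#' @export
write_scan_csv <- function(report, path) {
  utils::write.csv(report$rows, path, row.names = FALSE)
  agg_path <- sub("(\\.csv)?$", "_aggregates.csv", path)
  utils::write.csv(report$aggregates, agg_path, row.names = FALSE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_scan_csv <- function(path) {
  read_checked_csv(path,
    required = c("perturbation", "phenotype", "wt_fraction", "pert_fraction",
                 "pct_change", "category"),
    numeric_cols = c("wt_fraction", "pert_fraction"))
}

#' @rdname polarscape-io
#' @param events a `transition_events` data.frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_events_csv <- function(path) {
  df <- read_checked_csv(path,
    required = c("time", "source", "target", "u_cross", "v_cross"),
    numeric_cols = c("time", "u_cross", "v_cross"))
  structure(df, class = c("transition_events", "data.frame"))
}

#' @rdname polarscape-io
#' @param exits an `exit_time_summary`.
#' @export
write_exits_csv <- function(exits, path) {
  utils::write.csv(as.data.frame(exits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_exits_csv <- function(path) {
  read_checked_csv(path,
    required = c("sigma", "n", "n_censored", "mean", "median", "se"),
    numeric_cols = c("sigma", "n", "n_censored"))
}

#' @rdname polarscape-io
#' @param traj an `sde_trajectory` or `field_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(traj, "sde_trajectory")) {
    meta <- c(attr(traj, "config"), list(class = "sde_trajectory"))
    writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
    utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  } else if (inherits(traj, "field_trajectory")) {
    meta <- c(traj$config, list(class = "field_trajectory"))
    writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
    N <- ncol(traj$u)
    df <- data.frame(t = traj$times,
                     traj$u, traj$v, check.names = FALSE)
    names(df) <- c("t", paste0("u", seq_len(N)), paste0("v", seq_len(N)))
    utils::write.csv(df, con, row.names = FALSE)
  } else stop("not a trajectory object")
  invisible(path)
}

#' @rdname polarscape-io
#' @export
read_trajectory_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop(path, ": missing provenance header line")
  meta <- jsonlite::fromJSON(sub("^#", "", first))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (identical(meta$class, "sde_trajectory")) {
    meta$class <- NULL
    structure(df, class = c("sde_trajectory", "data.frame"), config = meta)
  } else if (identical(meta$class, "field_trajectory")) {
    N <- meta$N
    ucols <- paste0("u", seq_len(N)); vcols <- paste0("v", seq_len(N))
    missing <- setdiff(c("t", ucols, vcols), names(df))
    if (length(missing)) stop(path, ": missing column(s): ",
                              paste(utils::head(missing, 4L), collapse = ", "))
    meta$class <- NULL
    dxi <- meta$L / N
    structure(list(times = df$t,
                   u = as.matrix(df[, ucols]), v = as.matrix(df[, vcols]),
                   xi = (seq_len(N) - 0.5) * dxi, config = meta),
              class = "field_trajectory")
  } else stop(path, ": unknown trajectory class in header")
}

read_checked_csv <- function(path, required, numeric_cols = character(0)) {
  force(path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  for (cc in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(vals) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop(path, ": non-numeric value in column '", cc, "' at data row ",
           bad[1L])
    df[[cc]] <- vals
  }
  df
}
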