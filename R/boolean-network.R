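#' Boolean regulatory networks with synchronous dynamics
#'
#' A `boolean_network` holds an ordered node list, one logical update rule per
#' node (an expression over node names using `AND`, `OR`, `NOT` and
#' parentheses; the R operators `&`, `|`, `!` are also accepted), and an
#' optional set of clamp overrides. A clamped node ignores its rule and holds
#' the clamp value at every update, which is how sustained overexpression
#' (clamp to 1) and knockout (clamp to 0) perturbations are represented.
#'
#' Node order is part of the object: it fixes the bit order of states, so the
#' state `c(0, 1, 0)` assigns 0 to the first declared node, and bitstrings in
#' printed output read left to right in node order.
#'
#' @param nodes character vector of node identifiers (syntactic names).
#' @param rules named character vector or list of rule expressions, one per
#'   node. Names must match `nodes`; unnamed input is taken in node order.
#' @param clamps optional named numeric/integer vector of 0/1 clamp values.
#' @return an object of class `boolean_network`.
#' @examples
#' net <- boolean_network(c("A", "B", "C"),
#'                        c(A = "B", B = "A", C = "NOT A"))
#' step_state(net, c(0, 1, 0))
#' @export
boolean_network <- function(nodes, rules, clamps = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) stop("a network needs at least one node")
  if (anyDuplicated(nodes)) stop("duplicated node names: ",
                                 paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  bad <- nodes != make.names(nodes)
  if (any(bad)) stop("node names must be syntactic identifiers: ",
                     paste(nodes[bad], collapse = ", "))
  rules <- unlist(as.list(rules))
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    if (length(rules) != length(nodes)) stop("unnamed rules must match node count")
    names(rules) <- nodes
  }
  if (!setequal(names(rules), nodes)) {
    stop("rules must cover exactly the declared nodes; missing: ",
         paste(setdiff(nodes, names(rules)), collapse = ", "),
         "; unknown: ", paste(setdiff(names(rules), nodes), collapse = ", "))
  }
  rules <- rules[nodes]
  exprs <- lapply(rules, parse_rule, nodes = nodes)
  clamps <- validate_clamps(clamps, nodes)
  structure(list(nodes = nodes, rules = as.character(rules),
                 exprs = exprs, clamps = clamps),
            class = "boolean_network")
}

validate_clamps <- function(clamps, nodes) {
  if (is.null(clamps) || length(clamps) == 0L) return(integer(0))
  vals <- as.integer(unlist(clamps))
  nm <- names(clamps)
  if (is.null(nm) || any(!nzchar(nm))) stop("clamps must be a named 0/1 vector")
  unknown <- setdiff(nm, nodes)
  if (length(unknown)) stop("clamp refers to unknown node(s): ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(nm)) stop("duplicated clamp for node(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!all(vals %in% c(0L, 1L))) stop("clamp values must be 0 or 1")
  names(vals) <- nm
  vals
}

# Translate an AND/OR/NOT expression string into a parsed R expression and
# check that every identifier is a declared node (definition-time error).
parse_rule <- function(rule, nodes) {
  txt <- gsub("\\bAND\\b", "&", rule, ignore.case = FALSE)
  txt <- gsub("\\bOR\\b", "|", txt)
  txt <- gsub("\\bNOT\\b", "!", txt)
  ex <- tryCatch(str2lang(txt),
                 error = function(e) stop("cannot parse rule '", rule, "': ",
                                          conditionMessage(e), call. = FALSE))
  vars <- all.vars(ex)
  ops <- setdiff(all.names(ex), vars)
  bad_ops <- setdiff(ops, c("&", "|", "!", "(", "&&", "||"))
  if (length(bad_ops)) stop("rule '", rule, "' uses unsupported operator(s): ",
                            paste(bad_ops, collapse = ", "))
  if (!is.null(nodes)) {
    unknown <- setdiff(vars, nodes)
    if (length(unknown)) stop("rule '", rule, "' references undeclared node(s): ",
                              paste(unknown, collapse = ", "))
  }
  ex
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$nodes), "nodes (synchronous update)\n")
  for (i in seq_along(x$nodes)) {
    cl <- if (x$nodes[i] %in% names(x$clamps))
      paste0("  [clamped = ", x$clamps[[x$nodes[i]]], "]") else ""
    cat(sprintf("  %s <- %s%s\n", x$nodes[i], x$rules[i], cl))
  }
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

free_nodes <- function(net) setdiff(net$nodes, names(net$clamps))

# Vectorised synchronous update: `states` is an integer matrix with one row
# per state and one column per node (0/1). Returns the matrix of successors.
step_matrix <- function(net, states) {
  env <- new.env(parent = baseenv())
  for (j in seq_along(net$nodes)) {
    assign(net$nodes[j], states[, j] != 0L, envir = env)
  }
  out <- matrix(0L, nrow = nrow(states), ncol = ncol(states),
                dimnames = list(NULL, net$nodes))
  for (j in seq_along(net$nodes)) {
    nd <- net$nodes[j]
    if (nd %in% names(net$clamps)) {
      out[, j] <- net$clamps[[nd]]
    } else {
      out[, j] <- as.integer(eval(net$exprs[[j]], envir = env))
    }
  }
  out
}

#' Apply one synchronous update step
#'
#' Every non-clamped node takes the value of its rule evaluated on the input
#' state; clamped nodes take their clamp value.
#'
#' @param net a [boolean_network()].
#' @param state 0/1 vector in network node order.
#' @return the successor state as an integer 0/1 vector.
#' @export
step_state <- function(net, state) {
  if (length(state) != n_nodes(net)) stop("state length does not match network")
  drop(step_matrix(net, matrix(as.integer(state), nrow = 1L)))
}

# state codes <-> bit matrices; code enumerates only the given columns
# (free nodes), little-endian in column order, 0-based.
codes_to_matrix <- function(codes, n_bits) {
  m <- matrix(0L, nrow = length(codes), ncol = n_bits)
  for (b in seq_len(n_bits)) m[, b] <- bitwAnd(codes %/% (2L^(b - 1L)), 1L)
  m
}

matrix_to_codes <- function(m) {
  codes <- rep(0, nrow(m))
  for (b in seq_len(ncol(m))) codes <- codes + m[, b] * 2^(b - 1)
  codes
}

# lexicographic key of full states (first node most significant), used to
# pick the canonical rotation of a cycle
lex_key <- function(m) {
  key <- rep(0, nrow(m))
  n <- ncol(m)
  for (b in seq_len(n)) key <- key + m[, b] * 2^(n - b)
  key
}

#' Enumerate attractors and basins of a Boolean network
#'
#' Under synchronous update every state has a unique successor, so the state
#' space decomposes into basins, each draining into a fixed point or a cycle.
#' In `exhaustive` mode all `2^k` states over the free (non-clamped) nodes are
#' iterated to their attractor and basin sizes are exact; in `sampled` mode
#' `n_samples` random initial states are followed instead and basin fractions
#' are sample proportions (reproducible given `seed`).
#'
#' @param net a [boolean_network()].
#' @param mode `"exhaustive"` (default) or `"sampled"`.
#' @param n_samples number of random initial states for sampled mode.
#' @param seed integer seed for sampled mode.
#' @param max_nodes capacity cap for exhaustive mode (default 24 free nodes).
#' @return an `attractor_set`: a list of attractors, each with `states`
#'   (matrix, one row per cycle state, canonical rotation starting at the
#'   lexicographically smallest state), `basin_size`, `basin_fraction` and a
#'   `phenotype` slot (`NA` until labelled), plus enumeration metadata.
#' @examples
#' net <- boolean_network(c("A", "B", "C"), c(A = "B", B = "A", C = "NOT A"))
#' find_attractors(net)
#' @export
find_attractors <- function(net, mode = c("exhaustive", "sampled"),
                            n_samples = 10000L, seed = 1L, max_nodes = 24L) {
  mode <- match.arg(mode)
  free <- free_nodes(net)
  nf <- length(free)
  free_idx <- match(free, net$nodes)
  if (mode == "exhaustive") {
    if (nf > max_nodes) {
      stop("exhaustive enumeration capped at ", max_nodes,
           " free nodes (network has ", nf, "); use mode = 'sampled'")
    }
    M <- 2L^nf
    states <- matrix(0L, nrow = M, ncol = n_nodes(net),
                     dimnames = list(NULL, net$nodes))
    if (nf > 0) states[, free_idx] <- codes_to_matrix(0:(M - 1L), nf)
    for (nd in names(net$clamps)) states[, nd] <- net$clamps[[nd]]
    nxt <- step_matrix(net, states)
    succ <- as.integer(matrix_to_codes(nxt[, free_idx, drop = FALSE])) + 1L
    # iterate the successor map 2^ceil(log2 M) times by doubling: afterwards
    # every state has been mapped onto its attractor cycle
    s <- succ
    reps <- max(1L, ceiling(log2(max(M, 2L))))
    for (k in seq_len(reps)) s <- s[s]
    on_cycle <- sort(unique(s))
    cyc_id <- integer(M)           # 0 = not assigned
    cycles <- list()
    for (st in on_cycle) {
      if (cyc_id[st] > 0L) next
      path <- st
      cur <- succ[st]
      while (cur != st) { path <- c(path, cur); cur <- succ[cur] }
      cycles[[length(cycles) + 1L]] <- path
      cyc_id[path] <- length(cycles)
    }
    attr_id <- cyc_id[s]
    basin <- tabulate(attr_id, nbins = length(cycles))
    atts <- lapply(seq_along(cycles), function(i) {
      sm <- states[cycles[[i]], , drop = FALSE]
      sm <- canonical_rotation(sm)
      list(states = sm, basin_size = basin[i], basin_fraction = basin[i] / M,
           phenotype = NA_character_)
    })
    new_attractor_set(atts, net, mode, n_states = M, seed = NULL)
  } else {
    if (n_samples < 1L) stop("n_samples must be >= 1")
    M <- if (nf <= 52) 2^nf else Inf
    codes <- with_seed(seed, {
      if (nf <= 30) sample.int(2L^nf, n_samples, replace = TRUE) - 1L
      else floor(stats::runif(n_samples) * M)
    })
    tab <- table(codes)
    uniq <- as.numeric(names(tab))
    cnt <- as.integer(tab)
    start <- matrix(0L, nrow = length(uniq), ncol = n_nodes(net),
                    dimnames = list(NULL, net$nodes))
    if (nf > 0) start[, free_idx] <- codes_to_matrix(uniq, nf)
    for (nd in names(net$clamps)) start[, nd] <- net$clamps[[nd]]
    meet <- floyd_meet(net, start)
    # group samples by the attractor their meeting state belongs to
    keys <- vapply(seq_len(nrow(meet)), function(i) {
      cyc <- walk_cycle(net, meet[i, ])
      paste(apply(cyc, 1L, paste0, collapse = ""), collapse = ";")
    }, character(1))
    uk <- unique(keys)
    atts <- lapply(uk, function(k) {
      i <- which(keys == k)[1]
      cyc <- walk_cycle(net, meet[i, ])
      n_hit <- sum(cnt[keys == k])
      list(states = cyc, basin_size = n_hit, basin_fraction = n_hit / n_samples,
           phenotype = NA_character_)
    })
    new_attractor_set(atts, net, mode, n_states = n_samples, seed = seed)
  }
}

# vectorised Floyd cycle detection: returns, for each starting row, a state
# lying on its attractor cycle
floyd_meet <- function(net, start) {
  tort <- step_matrix(net, start)
  hare <- step_matrix(net, tort)
  active <- rowSums(tort != hare) > 0L
  guard <- 0L
  while (any(active)) {
    tort[active, ] <- step_matrix(net, tort[active, , drop = FALSE])
    hare[active, ] <- step_matrix(net, step_matrix(net, hare[active, , drop = FALSE]))
    active <- rowSums(tort != hare) > 0L
    guard <- guard + 1L
    if (guard > 2^min(n_nodes(net), 28L) + 16L) stop("cycle detection did not converge")
  }
  tort
}

# from a state known to lie on a cycle, collect the cycle in canonical form
walk_cycle <- function(net, state) {
  path <- matrix(as.integer(state), nrow = 1L, dimnames = list(NULL, net$nodes))
  cur <- step_state(net, state)
  while (!all(cur == state)) {
    path <- rbind(path, cur)
    cur <- step_state(net, cur)
  }
  canonical_rotation(path)
}

canonical_rotation <- function(sm) {
  if (nrow(sm) <= 1L) return(sm)
  k <- which.min(lex_key(sm))
  idx <- c(k:nrow(sm), seq_len(k - 1L))
  sm[idx, , drop = FALSE]
}

new_attractor_set <- function(atts, net, mode, n_states, seed) {
  # stable order: decreasing basin, then lexicographic first state
  key1 <- -vapply(atts, function(a) a$basin_size, numeric(1))
  key2 <- vapply(atts, function(a) lex_key(a$states)[1], numeric(1))
  atts <- atts[order(key1, key2)]
  structure(list(attractors = atts, nodes = net$nodes,
                 clamps = net$clamps, mode = mode,
                 n_states = n_states, seed = seed),
            class = "attractor_set")
}

#' @export
length.attractor_set <- function(x) length(x$attractors)

#' @export
print.attractor_set <- function(x, ...) {
  cat(length(x), "attractor(s) over", x$n_states,
      if (x$mode == "exhaustive") "states (exhaustive)\n" else "sampled states\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.attractor_set <- function(x, ...) {
  data.frame(
    attractor_id = seq_along(x$attractors),
    length = vapply(x$attractors, function(a) nrow(a$states), integer(1)),
    state_sequence = vapply(x$attractors, function(a)
      paste(apply(a$states, 1L, paste0, collapse = ""), collapse = ";"),
      character(1)),
    basin_size = vapply(x$attractors, function(a) a$basin_size, numeric(1)),
    basin_fraction = vapply(x$attractors, function(a) a$basin_fraction, numeric(1)),
    phenotype = vapply(x$attractors, function(a)
      if (is.na(a$phenotype)) NA_character_ else a$phenotype, character(1)),
    stringsAsFactors = FALSE)
}

#' Clamp a node to a fixed value (overexpression or knockout)
#'
#' Returns a copy of the network with the node clamped to 1 (sustained
#' overexpression) or 0 (knockout); an existing clamp on the same node is
#' replaced. The original network is unchanged.
#'
#' @param net a [boolean_network()].
#' @param node node identifier.
#' @param value 0 or 1.
#' @return a new `boolean_network`.
#' @export
perturb <- function(net, node, value) {
  if (!node %in% net$nodes) stop("unknown node: ", node)
  value <- as.integer(value)
  if (!value %in% c(0L, 1L)) stop("clamp value must be 0 or 1")
  cl <- net$clamps
  cl <- cl[setdiff(names(cl), node)]
  cl <- c(cl, stats::setNames(value, node))
  boolean_network(net$nodes, net$rules, clamps = cl)
}

run_with_seed <- function(seed, code) with_seed(seed, code)

# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
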