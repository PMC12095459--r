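#' Phenotype labelling rules for attractors
#'
#' A `phenotype_rules` object maps each polarization compartment (M1, M2a,
#' M2b, M2c, M2d) to a logical condition over node activities. An attractor is
#' labelled with the concatenation, in compartment order, of every compartment
#' whose condition holds on its activity vector; if none holds the label is
#' `"M0"` (unpolarized). For cyclic attractors a node counts as active under
#' `activity = "all"` iff it is ON in every cycle state (default) and under
#' `"any"` iff ON in at least one.
#'
#' @param conditions named character vector of conditions (AND/OR/NOT
#'   expressions over node names); names are the compartment labels, and their
#'   order is the concatenation order for hybrid labels.
#' @return a `phenotype_rules` object.
#' @seealso [macrophage_phenotype_rules()] for the canonical macrophage table.
#' @export
phenotype_rules <- function(conditions) {
  conditions <- unlist(as.list(conditions))
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("conditions must be named by compartment")
  exprs <- lapply(conditions, parse_rule, nodes = NULL)
  structure(list(labels = names(conditions),
                 conditions = as.character(conditions),
                 exprs = exprs),
            class = "phenotype_rules")
}

#' @export
print.phenotype_rules <- function(x, ...) {
  cat("Phenotype rules (", length(x$labels), " compartments; no match -> M0)\n",
      sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-4s : %s\n", x$labels[i], x$conditions[i]))
  invisible(x)
}

#' Canonical macrophage compartment conditions
#'
#' The standard conditions used to name macrophage polarization attractors:
#' M1 requires NFKB, STAT1, or TNFA together with AP1; M2a requires IL4 and
#' STAT6; M2b requires AP1 or ERK; M2c requires IL10 and STAT3; M2d requires
#' TLR4 with A2a, or HIF1A. Attractors activating several compartments get
#' hybrid labels (e.g. `"M1M2d"`); attractors activating none are `"M0"`.
#' Node names must match these identifiers in the network being labelled.
#'
#' @return a [phenotype_rules()] object.
#' @export
macrophage_phenotype_rules <- function() {
  phenotype_rules(c(
    M1  = "NFKB OR STAT1 OR (TNFA AND AP1)",
    M2a = "IL4 AND STAT6",
    M2b = "AP1 OR ERK",
    M2c = "IL10 AND STAT3",
    M2d = "(TLR4 AND A2a) OR HIF1A"))
}

#' Label one attractor with its phenotype
#'
#' @param attractor a single attractor (element of an `attractor_set`), or any
#'   list with a `states` 0/1 matrix whose columns are named by node.
#' @param rules a [phenotype_rules()] object.
#' @param activity `"all"` (node active iff ON in every cycle state, default)
#'   or `"any"` (ON in at least one).
#' @return the phenotype label string.
#' @export
classify_phenotype <- function(attractor, rules, activity = c("all", "any")) {
  activity <- match.arg(activity)
  sm <- attractor$states
  act <- if (activity == "all") apply(sm, 2L, function(z) all(z != 0L))
         else apply(sm, 2L, function(z) any(z != 0L))
  env <- new.env(parent = baseenv())
  for (nd in names(act)) assign(nd, act[[nd]], envir = env)
  hit <- vapply(rules$exprs, function(ex) {
    vars <- all.vars(ex)
    missing <- setdiff(vars, names(act))
    if (length(missing)) for (v in missing) assign(v, FALSE, envir = env)
    isTRUE(eval(ex, envir = env))
  }, logical(1))
  if (!any(hit)) "M0" else paste(rules$labels[hit], collapse = "")
}

#' Label every attractor in a set
#'
#' @param aset an `attractor_set` from [find_attractors()].
#' @inheritParams classify_phenotype
#' @return the `attractor_set` with `phenotype` filled in.
#' @export
label_attractors <- function(aset, rules, activity = c("all", "any")) {
  activity <- match.arg(activity)
  aset$attractors <- lapply(aset$attractors, function(a) {
    a$phenotype <- classify_phenotype(a, rules, activity)
    a
  })
  aset
}

# pooled basin fraction per phenotype label
phenotype_fractions <- function(aset) {
  df <- as.data.frame(aset)
  if (anyNA(df$phenotype)) stop("attractors are unlabelled; run label_attractors() first")
  tapply(df$basin_fraction, df$phenotype, sum)
}
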