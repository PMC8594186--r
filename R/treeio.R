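#' Read a sample of rooted trees from a newick file
#'
#' Reads one or more newick trees (one tree per line or concatenated, as
#' accepted by [ape::read.tree()]) and validates them as a coherent sample:
#' every tree must be rooted, strictly binary, have finite non-negative
#' branch lengths, and all trees must share the same tip-label set. A sample
#' of trees (for example posterior trees from a Bayesian phylogenetic run)
#' lets downstream likelihoods average over phylogenetic uncertainty.
#'
#' @param path Path to a newick file containing at least one tree. Branch
#'   lengths are interpreted as substitutions per site throughout the
#'   package.
#' @return A `tree_sample` object: a list of `phylo` trees with identical
#'   tip sets.
#' @seealso [tree_sample()], [write_tree_sample()], [check_ultrametric()]
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' ts <- read_tree_sample(f)
#' length(ts)
#' @export
read_tree_sample <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path)
  }
  trees <- withCallingHandlers(
    tryCatch(
      ape::read.tree(path),
      error = function(e) stop("newick parse failure in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(trees)) {
    stop("newick parse failure in '", path, "': no tree could be read",
         call. = FALSE)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_sample(trees)
}

#' Construct a validated tree sample
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A `tree_sample` object.
#' @export
tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1L) stop("a tree sample must contain at least one tree")
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) {
      stop("element ", i, " is not a 'phylo' tree")
    }
    .validate_tree(tr, index = i)
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different tip set from tree 1; ",
           "all trees in a sample must share the same tips")
    }
  }
  structure(trees, class = "tree_sample")
}

.validate_tree <- function(tr, index = NA) {
  lab <- if (is.na(index)) "tree" else paste0("tree ", index)
  if (is.null(tr$edge.length)) {
    stop(lab, " has no branch lengths")
  }
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop(lab, " has non-finite or negative branch lengths")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop(lab, " has duplicated tip labels")
  }
  # strictly binary: every internal node has exactly two children
  tab <- tabulate(tr$edge[, 1L], nbins = ape::Ntip(tr) + tr$Nnode)
  internal <- tab[(ape::Ntip(tr) + 1L):(ape::Ntip(tr) + tr$Nnode)]
  if (any(internal != 2L)) {
    stop(lab, " is not strictly binary (a rooted binary tree is required)")
  }
  invisible(tr)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample:", length(x), "tree(s),",
      ape::Ntip(x[[1L]]), "tips\n")
  invisible(x)
}

#' @export
`[.tree_sample` <- function(x, i) {
  tree_sample(unclass(x)[i])
}

#' Write a tree sample to a newick file
#'
#' One tree per line, branch lengths at full double precision so that a
#' write/read round trip reproduces the sample.
#'
#' @param sample A `tree_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(sample, path) {
  stopifnot(inherits(sample, "tree_sample"))
  txt <- vapply(unclass(sample), function(tr) {
    ape::write.tree(tr, digits = 17)
  }, character(1L))
  writeLines(txt, path)
  invisible(path)
}

#' Check whether a tree is ultrametric
#'
#' The BiSSE likelihood assumes all tips are sampled at the present, i.e. an
#' ultrametric tree. Posterior tree samples are ultrametric only up to
#' numerical slack, so the check is relative: the spread of root-to-tip path
#' lengths is compared against `rel_tol` times the tree depth.
#'
#' @param tree A `phylo` tree.
#' @param rel_tol Allowed spread of root-to-tip depths as a fraction of the
#'   maximum depth (default `1e-3`).
#' @return A list with `is_ultrametric` (logical), `max_deviation` (largest
#'   minus smallest root-to-tip depth, in branch-length units) and `depth`
#'   (maximum root-to-tip depth).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-3) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(depths) - min(depths)
  depth <- max(depths)
  ok <- if (depth == 0) dev == 0 else dev <= rel_tol * depth
  list(is_ultrametric = ok, max_deviation = dev, depth = depth)
}

#' Unit conversion between generations and substitutions/site
#'
#' All rates in the package are per substitution per site (the unit of the
#' tree branch lengths). Epoch boundaries and growth rates are more natural
#' in generations; the conversion is a per-generation substitution rate.
#'
#' @param subst_rate Substitutions per nucleotide per generation. The
#'   default, `2.5e-8`, is a standard human germline value.
#' @return A `unit_conversion` object.
#' @export
unit_conversion <- function(subst_rate = 2.5e-8) {
  if (!is.numeric(subst_rate) || length(subst_rate) != 1L ||
      !is.finite(subst_rate) || subst_rate <= 0) {
    stop("subst_rate must be a single positive finite number")
  }
  structure(list(subst_rate = subst_rate), class = "unit_conversion")
}

#' Convert times in generations to branch-length units
#'
#' @param g Time(s) in generations before present (non-negative).
#' @param conv A [unit_conversion()] object.
#' @return `g * subst_rate`, in substitutions/site.
#' @examples
#' generations_to_substitutions(140, unit_conversion())  # 3.5e-6
#' @export
generations_to_substitutions <- function(g, conv = unit_conversion()) {
  stopifnot(inherits(conv, "unit_conversion"))
  if (any(!is.finite(g)) || any(g < 0)) {
    stop("times in generations must be finite and non-negative")
  }
  g * conv$subst_rate
}

#' Construct a tip-state table
#'
#' Maps tip labels to a binary activity state (0 = low, 1 = high
#' retrotransposition activity) and/or a raw activity value expressed as a
#' percentage of the reference element L1_RP. Unknown states are allowed
#' (`NA`) and are treated as ambiguous in all likelihoods.
#'
#' @param tip_label Character vector of tip labels.
#' @param state Optional integer vector in `{0, 1, NA}`.
#' @param activity Optional non-negative numeric vector (percent of L1_RP).
#' @return A `tip_states` data frame with columns `tip_label`, `state` and
#'   (if given) `activity`.
#' @export
tip_states <- function(tip_label, state = NULL, activity = NULL) {
  tip_label <- as.character(tip_label)
  if (anyDuplicated(tip_label)) stop("duplicated tip labels in state table")
  n <- length(tip_label)
  if (is.null(state) && is.null(activity)) {
    stop("provide at least one of 'state' or 'activity'")
  }
  if (!is.null(activity)) {
    activity <- as.numeric(activity)
    stopifnot(length(activity) == n)
    if (any(activity < 0, na.rm = TRUE)) {
      stop("activity values must be non-negative")
    }
  }
  if (!is.null(state)) {
    state <- as.integer(state)
    stopifnot(length(state) == n)
    if (any(!state %in% c(0L, 1L, NA_integer_))) {
      stop("states must be 0, 1 or NA (unknown)")
    }
  } else {
    state <- rep(NA_integer_, n)
  }
  out <- data.frame(tip_label = tip_label, state = state,
                    stringsAsFactors = FALSE)
  if (!is.null(activity)) out$activity <- activity
  class(out) <- c("tip_states", "data.frame")
  out
}

#' Read a tip-state table from TSV
#'
#' Expects columns `tip_label` and at least one of `activity_percent`,
#' `state`.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `tip_states` object.
#' @export
read_tip_states <- function(path) {
  if (!file.exists(path)) stop("tip-state file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"tip_label" %in% names(df)) {
    stop("tip-state table must have a 'tip_label' column")
  }
  tip_states(df$tip_label,
             state = if ("state" %in% names(df)) df$state else NULL,
             activity = if ("activity_percent" %in% names(df))
               df$activity_percent else NULL)
}

#' Binarize raw retrotransposition activities
#'
#' Activities at or above `threshold` percent of the reference L1_RP are
#' classified as high (state 1), below as low (state 0). The tie at exactly
#' the threshold is classified high; the threshold is configurable. Tips
#' with missing activity become unknown (`NA`) and are treated as ambiguous
#' downstream.
#'
#' @param states A [tip_states()] object with an `activity` column.
#' @param threshold Percent-of-reference cutoff (default 25).
#' @return The same `tip_states` with `state` filled from `activity`.
#' @export
binarize_activity <- function(states, threshold = 25) {
  stopifnot(inherits(states, "tip_states"))
  if (is.null(states$activity)) {
    stop("binarize_activity requires raw activity values")
  }
  if (any(states$activity < 0, na.rm = TRUE)) {
    stop("activity values must be non-negative")
  }
  states$state <- ifelse(is.na(states$activity), NA_integer_,
                         as.integer(states$activity >= threshold))
  states
}

# Match a tip_states table against a tree; returns integer vector ordered by
# the tree's tip numbering with values 0, 1 or NA.
.states_for_tree <- function(tree, states) {
  stopifnot(inherits(states, "tip_states"))
  idx <- match(tree$tip.label, states$tip_label)
  if (anyNA(idx)) {
    stop("tip(s) missing from the state table: ",
         paste(utils::head(tree$tip.label[is.na(idx)], 5L), collapse = ", "))
  }
  states$state[idx]
}
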