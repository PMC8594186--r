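#' BiSSE parameter set
#'
#' The six rates of the binary-state speciation and extinction model, all in
#' units of per substitution per site (the branch-length unit): `lambda0`,
#' `lambda1` are the rates at which low/high-activity L1 lineages give rise
#' to new detectable insertions ("speciation"), `mu0`, `mu1` the rates at
#' which insertion lineages are removed ("extinction"), and `q01`, `q10` the
#' rates of transition from low to high and high to low activity.
#'
#' @param lambda0,lambda1,mu0,mu1,q01,q10 Non-negative finite rates.
#' @return A named numeric vector of class `bisse_params`.
#' @export
bisse_params <- function(lambda0, lambda1, mu0 = 0, mu1 = 0, q01 = 0,
                         q10 = 0) {
  p <- c(lambda0 = lambda0, lambda1 = lambda1, mu0 = mu0, mu1 = mu1,
         q01 = q01, q10 = q10)
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("all six BiSSE rates must be finite and non-negative")
  }
  structure(p, class = "bisse_params")
}

.as_bisse_params <- function(p) {
  if (inherits(p, "bisse_params")) return(p)
  p <- unlist(p)
  if (length(p) != 6L) stop("expected six BiSSE rates")
  nm <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  if (!is.null(names(p)) && all(nm %in% names(p))) p <- p[nm]
  do.call(bisse_params, as.list(unname(p)))
}

#' Change-point specification for epoch-varying speciation rates
#'
#' Epoch boundaries are times before present in generations, strictly
#' increasing; each boundary has a multiplier applied to both speciation
#' rates (`lambda0` and `lambda1` jointly) in the epoch older than that
#' boundary (and younger than the next). The most recent epoch, between the
#' present and the first boundary, always has multiplier 1. Extinction and
#' transition rates are unchanged across epochs.
#'
#' @param boundaries_gen Strictly increasing positive times before present,
#'   in generations.
#' @param multipliers One positive factor per boundary.
#' @return A `changepoint_spec` object.
#' @export
changepoint_spec <- function(boundaries_gen, multipliers) {
  boundaries_gen <- as.numeric(boundaries_gen)
  multipliers <- as.numeric(multipliers)
  if (length(boundaries_gen) != length(multipliers)) {
    stop("need exactly one multiplier per boundary")
  }
  if (length(boundaries_gen) == 0L) {
    stop("a change-point spec needs at least one boundary")
  }
  if (any(!is.finite(boundaries_gen)) || any(boundaries_gen < 0)) {
    stop("boundaries must be finite, non-negative generation counts")
  }
  if (is.unsorted(boundaries_gen, strictly = TRUE)) {
    stop("boundaries must be strictly increasing")
  }
  if (any(!is.finite(multipliers)) || any(multipliers <= 0)) {
    stop("multipliers must be finite and positive")
  }
  structure(list(boundaries_gen = boundaries_gen, multipliers = multipliers),
            class = "changepoint_spec")
}

#' Root-treatment options for the BiSSE likelihood
#'
#' How the two root partial likelihoods `D0`, `D1` are combined, and whether
#' the likelihood is conditioned on survival of both root lineages.
#' `"weighted"` (the default) weights each state by its relative partial
#' likelihood at the root; `"flat"` averages with weights 1/2;
#' `"equilibrium"` uses the stationary frequencies of the transition
#' process, `q10/(q01+q10)` and `q01/(q01+q10)`; `"fixed"` conditions on a
#' known root state.
#'
#' @param mode One of `"weighted"`, `"flat"`, `"equilibrium"`, `"fixed"`.
#' @param fixed_state Root state (0 or 1) when `mode = "fixed"`.
#' @param condition_on_survival Condition the likelihood on both lineages
#'   descending from the root leaving sampled descendants (default `FALSE`).
#' @return A `root_options` object.
#' @export
root_options <- function(mode = c("weighted", "flat", "equilibrium", "fixed"),
                         fixed_state = NULL,
                         condition_on_survival = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_state) || !fixed_state %in% c(0, 1)) {
      stop("mode 'fixed' requires fixed_state 0 or 1")
    }
  }
  structure(list(mode = mode, fixed_state = fixed_state,
                 condition_on_survival = isTRUE(condition_on_survival)),
            class = "root_options")
}

# Precompute everything the C++ pruning needs for one (tree, states) pair.
.bisse_prep <- function(tree, states, rel_tol = 1e-3, require_ultrametric = TRUE) {
  .validate_tree(tree)
  if (require_ultrametric) {
    um <- check_ultrametric(tree, rel_tol = rel_tol)
    if (!um$is_ultrametric) {
      stop("tree is not ultrametric within tolerance (deviation ",
           format(um$max_deviation), " on depth ", format(um$depth),
           "); the BiSSE likelihood requires an ultrametric tree")
    }
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  dist_root <- ape::node.depth.edgelength(tr)
  depth <- max(dist_root[seq_len(ntip)])
  node_time <- pmax(depth - dist_root, 0)
  node_time[seq_len(ntip)] <- 0  # tips sit at the present
  st <- .states_for_tree(tr, states)
  list(edge = tr$edge, edge_length = tr$edge.length, n_tip = ntip,
       tip_state = as.integer(st), node_time = node_time, depth = depth)
}

.stationary_freqs <- function(q01, q10) {
  s <- q01 + q10
  if (s <= 0) c(0.5, 0.5) else c(q10 / s, q01 / s)
}

# Core evaluation on a prepared tree. cp_sub: list(times, mult) already in
# branch-length units, or NULL.
.bisse_ll_prep <- function(prep, pars, root, cp_sub = NULL,
                           control = list()) {
  rtol <- control$rtol %||% 1e-10
  atol <- control$atol %||% 1e-14
  cp_times <- if (is.null(cp_sub)) numeric(0) else cp_sub$times
  cp_mult <- if (is.null(cp_sub)) numeric(0) else cp_sub$mult
  out <- bisse_pruning_cpp(prep$edge, prep$edge_length, prep$n_tip,
                           prep$tip_state, unname(unclass(pars)),
                           prep$node_time, cp_times, cp_mult, rtol, atol)
  if (!isTRUE(out$ok)) {
    stop("BiSSE ODE integration failed near node ", out$node,
         " (rates may be too extreme for the requested tolerance)")
  }
  D <- out$D
  E <- out$E
  if (sum(D) <= 0) return(-Inf)
  w <- switch(root$mode,
    weighted = D / sum(D),
    flat = c(0.5, 0.5),
    equilibrium = .stationary_freqs(pars[["q01"]], pars[["q10"]]),
    fixed = if (root$fixed_state == 0) c(1, 0) else c(0, 1))
  lik <- sum(w * D)
  if (lik <= 0) return(-Inf)
  ll <- log(lik) + out$logcomp
  if (root$condition_on_survival) {
    lam <- c(pars[["lambda0"]], pars[["lambda1"]]) * out$root_mult
    cond <- sum(w * lam * (1 - E)^2)
    if (cond <= 0) return(-Inf)
    ll <- ll - log(cond)
  }
  ll
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BiSSE log-likelihood of binary tip states on an ultrametric tree
#'
#' Computes the log-likelihood of the observed high/low activity states
#' under constant BiSSE rates by post-order pruning: along each branch the
#' extinction probabilities `E_i` and partial likelihoods `D_i` are
#' propagated by the standard BiSSE ordinary differential equations
#' (integrated with an adaptive embedded Runge-Kutta scheme), at each
#' internal node `D_i = lambda_i * D_i^left * D_i^right`, and at the root
#' the two states are combined per [root_options()]. Partial likelihoods are
#' renormalised at every node with a log-scale accumulator, so trees with
#' rates of order hundreds per unit branch length do not underflow.
#'
#' @param tree An ultrametric rooted binary `phylo` tree, branch lengths in
#'   substitutions/site.
#' @param states A [tip_states()] table covering every tip (states 0, 1 or
#'   `NA` for unknown; unknown tips contribute partial likelihood 1 for both
#'   states).
#' @param params A [bisse_params()] vector.
#' @param root A [root_options()] object.
#' @param rel_tol Ultrametricity tolerance passed to [check_ultrametric()].
#' @param control Optional list with integrator tolerances `rtol`, `atol`.
#' @return The log-likelihood (a single finite number, or `-Inf` for data
#'   impossible under the parameters).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' st <- tip_states(c("A", "B", "C"), state = c(0, 0, 1))
#' bisse_loglik(tr, st, bisse_params(1, 2, q01 = 0.1, q10 = 0.2))
#' @export
bisse_loglik <- function(tree, states, params, root = root_options(),
                         rel_tol = 1e-3, control = list()) {
  params <- .as_bisse_params(params)
  stopifnot(inherits(root, "root_options"))
  prep <- .bisse_prep(tree, states, rel_tol = rel_tol)
  .bisse_ll_prep(prep, params, root, cp_sub = NULL, control = control)
}

# Convert a changepoint_spec to branch-length units and check it against a
# tree depth; warns when a boundary is older than the root.
.cp_to_sub <- function(cp, conv, depth = NULL) {
  if (is.null(cp)) return(NULL)
  stopifnot(inherits(cp, "changepoint_spec"))
  times <- generations_to_substitutions(cp$boundaries_gen, conv)
  if (!is.null(depth) && any(times >= depth)) {
    warning("change-point boundary older than the tree root; ",
            "the corresponding multiplier cannot affect the likelihood")
  }
  list(times = times, mult = cp$multipliers)
}

#' BiSSE log-likelihood with piecewise-constant speciation rates
#'
#' As [bisse_loglik()], but both speciation rates are multiplied by a shared
#' epoch factor in epochs older than each change-point boundary (extinction
#' and transition rates are unchanged). Branches spanning a boundary are
#' integrated segment by segment with `E` and `D` continuous across the
#' boundary. With all multipliers equal to 1 this reduces exactly to the
#' constant-rate likelihood.
#'
#' @inheritParams bisse_loglik
#' @param cp A [changepoint_spec()] with boundaries in generations.
#' @param conv A [unit_conversion()] used to convert boundaries to
#'   branch-length units.
#' @return The log-likelihood.
#' @export
bisse_td_loglik <- function(tree, states, params, cp,
                            conv = unit_conversion(), root = root_options(),
                            rel_tol = 1e-3, control = list()) {
  params <- .as_bisse_params(params)
  stopifnot(inherits(root, "root_options"))
  prep <- .bisse_prep(tree, states, rel_tol = rel_tol)
  cp_sub <- .cp_to_sub(cp, conv, depth = prep$depth)
  .bisse_ll_prep(prep, params, root, cp_sub = cp_sub, control = control)
}

#' Pooled BiSSE log-likelihood over a tree sample
#'
#' Accounts for phylogenetic uncertainty by summing the per-tree likelihoods
#' over a sample of trees (e.g. posterior trees): the result is
#' `log(sum_i L_i)`, computed stably by log-sum-exp. Summing (rather than
#' averaging) shifts every model's log-likelihood by the same `log(N)`, so
#' AIC differences between models are unaffected.
#'
#' @param sample A [tree_sample()].
#' @inheritParams bisse_td_loglik
#' @param cp Optional [changepoint_spec()]; `NULL` for constant rates.
#' @return The pooled log-likelihood.
#' @export
pooled_loglik <- function(sample, states, params, cp = NULL,
                          conv = unit_conversion(), root = root_options(),
                          rel_tol = 1e-3, control = list()) {
  stopifnot(inherits(sample, "tree_sample"))
  params <- .as_bisse_params(params)
  ll <- vapply(seq_along(sample), function(i) {
    tryCatch({
      prep <- .bisse_prep(sample[[i]], states, rel_tol = rel_tol)
      cp_sub <- if (is.null(cp)) NULL else .cp_to_sub(cp, conv, depth = prep$depth)
      .bisse_ll_prep(prep, params, root, cp_sub = cp_sub, control = control)
    }, error = function(e) {
      stop("tree ", i, ": ", conditionMessage(e), call. = FALSE)
    })
  }, numeric(1L))
  .logsumexp(ll)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
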