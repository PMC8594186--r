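#' Transition probabilities of the two-state Markov (Mk2) model
#'
#' Closed-form solution of the two-state continuous-time Markov chain with
#' rates `q01` (low to high) and `q10` (high to low) over a branch of
#' length `t`:
#' `P00(t) = (q10 + q01 exp(-(q01+q10) t)) / (q01 + q10)` and complements.
#' With both rates zero the matrix is the identity. Rows sum to one.
#'
#' @param q01,q10 Non-negative transition rates (per substitution/site).
#' @param t Branch length (non-negative).
#' @return A 2x2 probability matrix, rows = starting state (low, high).
#' @examples
#' mk2_transition_probs(1, 3, 0.5)
#' @export
mk2_transition_probs <- function(q01, q10, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length t must be a single non-negative number")
  }
  if (q01 < 0 || q10 < 0) stop("transition rates must be non-negative")
  s <- q01 + q10
  if (s == 0) {
    return(matrix(c(1, 0, 0, 1), 2L, 2L,
                  dimnames = list(c("low", "high"), c("low", "high"))))
  }
  e <- exp(-s * t)
  p00 <- (q10 + q01 * e) / s
  p11 <- (q01 + q10 * e) / s
  matrix(c(p00, 1 - p11, 1 - p00, p11), 2L, 2L,
         dimnames = list(c("low", "high"), c("low", "high")))
}

# Precompute postorder structure for fast repeated Mk2 evaluations.
.mk2_prep <- function(tree, states) {
  .validate_tree(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  list(parent = tr$edge[, 1L], child = tr$edge[, 2L],
       el = tr$edge.length, n_tip = ape::Ntip(tr), n_node = tr$Nnode,
       tip_state = as.integer(.states_for_tree(tr, states)))
}

# Pruning likelihood on a prepared tree; root_freqs NULL = stationary.
.mk2_ll_prep <- function(prep, q01, q10, root_freqs = NULL) {
  s <- q01 + q10
  n_all <- prep$n_tip + prep$n_node
  L0 <- numeric(n_all)
  L1 <- numeric(n_all)
  ts <- prep$tip_state
  L0[seq_len(prep$n_tip)] <- ifelse(is.na(ts), 1, as.numeric(ts == 0L))
  L1[seq_len(prep$n_tip)] <- ifelse(is.na(ts), 1, as.numeric(ts == 1L))
  L0[(prep$n_tip + 1L):n_all] <- 1
  L1[(prep$n_tip + 1L):n_all] <- 1
  ex <- if (s > 0) exp(-s * prep$el) else rep(1, length(prep$el))
  logcomp <- 0
  for (e in seq_along(prep$el)) {
    child <- prep$child[e]
    par <- prep$parent[e]
    if (s > 0) {
      p00 <- (q10 + q01 * ex[e]) / s
      p11 <- (q01 + q10 * ex[e]) / s
    } else {
      p00 <- 1; p11 <- 1
    }
    v0 <- p00 * L0[child] + (1 - p00) * L1[child]
    v1 <- (1 - p11) * L0[child] + p11 * L1[child]
    a <- L0[par] * v0
    b <- L1[par] * v1
    m <- a + b
    if (m <= 0) return(-Inf)
    L0[par] <- a / m
    L1[par] <- b / m
    logcomp <- logcomp + log(m)
  }
  root <- prep$parent[length(prep$parent)]
  if (is.null(root_freqs)) root_freqs <- .stationary_freqs(q01, q10)
  lik <- root_freqs[1L] * L0[root] + root_freqs[2L] * L1[root]
  if (lik <= 0) return(-Inf)
  log(lik) + logcomp
}

#' Mk2 log-likelihood of binary tip states on a tree
#'
#' Felsenstein pruning with the closed-form Mk2 transition probabilities.
#' Unlike the BiSSE likelihood this places no ultrametricity requirement on
#' the tree, but it also ignores any effect of the character on branching.
#' The root is weighted by `root_freqs`, by default the stationary
#' frequencies `(q10, q01)/(q01+q10)` (uniform when both rates are zero),
#' under which the likelihood is invariant to re-rooting along a branch
#' (the chain is reversible at stationarity).
#'
#' @param tree A rooted binary `phylo` tree (any branch lengths).
#' @param states A [tip_states()] table (0, 1 or `NA`).
#' @param q01,q10 Non-negative transition rates.
#' @param root_freqs Optional length-2 non-negative weights for the root
#'   states (need not sum to 1 exactly; `NULL` = stationary).
#' @return The log-likelihood.
#' @export
mk2_loglik <- function(tree, states, q01, q10, root_freqs = NULL) {
  if (q01 < 0 || q10 < 0) stop("transition rates must be non-negative")
  if (!is.null(root_freqs)) {
    stopifnot(length(root_freqs) == 2L, all(root_freqs >= 0),
              sum(root_freqs) > 0)
  }
  prep <- .mk2_prep(tree, states)
  .mk2_ll_prep(prep, q01, q10, root_freqs)
}
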