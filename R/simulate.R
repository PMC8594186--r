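#' Configuration for a forward BiSSE simulation
#'
#' Describes one simulated dataset: the true rates, an optional change-point
#' spec (allowed only with a `max_time` stop rule, since its boundaries are
#' times before the present), a stop rule (a target number of extant tips,
#' or a fixed simulation time), and the root state.
#'
#' With `n_tips`, the simulation runs until a birth would raise the extant
#' lineage count past the target; the present is set to the time of that
#' birth (which is not applied). This avoids the bias of stopping exactly at
#' the n-th birth with zero-length tip branches.
#'
#' @param params True [bisse_params()].
#' @param cp Optional true [changepoint_spec()] (requires `max_time`).
#' @param n_tips Target number of extant tips (mutually exclusive with
#'   `max_time`).
#' @param max_time Simulation time from the root, in branch-length units.
#' @param root_state 0, 1 or `NULL` (draw from the stationary distribution
#'   of the transition process).
#' @param conv [unit_conversion()] used for change-point boundaries.
#' @param max_retries Retries allowed when the clade dies out before
#'   satisfying the stop rule.
#' @return A `sim_config` object.
#' @export
sim_config <- function(params, cp = NULL, n_tips = NULL, max_time = NULL,
                       root_state = NULL, conv = unit_conversion(),
                       max_retries = 100L) {
  params <- .as_bisse_params(params)
  if (is.null(n_tips) == is.null(max_time)) {
    stop("specify exactly one of n_tips or max_time")
  }
  if (!is.null(n_tips) && (n_tips < 2L || n_tips != round(n_tips))) {
    stop("n_tips must be an integer >= 2")
  }
  if (!is.null(max_time) && max_time <= 0) stop("max_time must be positive")
  if (!is.null(cp)) {
    stopifnot(inherits(cp, "changepoint_spec"))
    if (is.null(max_time)) {
      stop("a change-point truth requires the max_time stop rule ",
           "(boundaries are times before the present)")
    }
  }
  if (!is.null(root_state) && !root_state %in% c(0, 1)) {
    stop("root_state must be 0, 1 or NULL")
  }
  structure(list(params = params, cp = cp, n_tips = n_tips,
                 max_time = max_time, root_state = root_state, conv = conv,
                 max_retries = max_retries),
            class = "sim_config")
}

# multiplier at forward time t when the present is at `present`
.sim_mult <- function(t, present, cp_sub) {
  if (is.null(cp_sub)) return(1)
  tb <- present - t
  m <- 1
  for (k in seq_along(cp_sub$times)) {
    if (tb >= cp_sub$times[k]) m <- cp_sub$mult[k] else break
  }
  m
}

# One Gillespie run. Returns NULL if the clade dies out (or never reaches
# two survivors); otherwise a lineage table and the present time.
.sim_once <- function(cfg, cp_sub) {
  p <- cfg$params
  lam <- c(p[["lambda0"]], p[["lambda1"]])
  mu <- c(p[["mu0"]], p[["mu1"]])
  qq <- c(p[["q01"]], p[["q10"]])  # out-of-state rate by current state
  root_state <- cfg$root_state
  if (is.null(root_state)) {
    root_state <- stats::rbinom(1L, 1L, .stationary_freqs(qq[1L], qq[2L])[2L])
  }
  # change-point epochs in forward time (only with max_time)
  switch_times <- if (!is.null(cp_sub)) {
    sort(cfg$max_time - cp_sub$times)
  } else numeric(0)

  cap <- 10L * (if (!is.null(cfg$n_tips)) cfg$n_tips else 10L)
  grow <- function(v, n) c(v, rep(v[1L][NA], n))
  N <- 64L
  parent <- integer(N); t_birth <- numeric(N); t_end <- numeric(N)
  state <- integer(N); status <- character(N)
  parent[1L] <- 0L; t_birth[1L] <- 0; state[1L] <- root_state
  status[1L] <- "alive"
  n_lin <- 1L
  alive <- 1L
  t <- 0
  max_events <- 1000000L

  for (ev in seq_len(max_events)) {
    st <- state[alive]
    rate_i <- lam[st + 1L] * .sim_mult(t, cfg$max_time %||% Inf, cp_sub) +
      mu[st + 1L] + qq[st + 1L]
    total <- sum(rate_i)
    if (total <= 0) {
      if (!is.null(cfg$max_time)) { t <- cfg$max_time; break }
      return(NULL)  # stalled before reaching the tip target
    }
    dt <- stats::rexp(1L, total)
    # piecewise-constant rates: never step across an epoch boundary
    nxt_switch <- switch_times[switch_times > t]
    if (length(nxt_switch) > 0L && t + dt > nxt_switch[1L]) {
      t <- nxt_switch[1L]
      next
    }
    if (!is.null(cfg$max_time) && t + dt > cfg$max_time) {
      t <- cfg$max_time
      break
    }
    t <- t + dt
    i <- alive[sample.int(length(alive), 1L, prob = rate_i)]
    s <- state[i]
    m <- .sim_mult(t, cfg$max_time %||% Inf, cp_sub)
    u <- stats::runif(1L) * (lam[s + 1L] * m + mu[s + 1L] + qq[s + 1L])
    if (u < lam[s + 1L] * m) {
      # birth
      if (!is.null(cfg$n_tips) && length(alive) == cfg$n_tips) {
        break  # present is the time of the birth that would exceed the target
      }
      if (n_lin + 2L > length(parent)) {
        parent <- grow(parent, length(parent))
        t_birth <- grow(t_birth, length(t_birth))
        t_end <- grow(t_end, length(t_end))
        state <- grow(state, length(state))
        status <- grow(status, length(status))
      }
      status[i] <- "split"; t_end[i] <- t
      for (k in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- i; t_birth[n_lin] <- t
        state[n_lin] <- s; status[n_lin] <- "alive"
      }
      alive <- c(setdiff(alive, i), n_lin - 1L, n_lin)
    } else if (u < lam[s + 1L] * m + mu[s + 1L]) {
      status[i] <- "dead"; t_end[i] <- t
      alive <- setdiff(alive, i)
      if (length(alive) == 0L) return(NULL)
    } else {
      state[i] <- 1L - s
    }
    if (!is.null(cfg$n_tips) && n_lin > 50L * cfg$n_tips) {
      stop("simulation produced far more lineages than the tip target; ",
           "check the rates")
    }
    if (n_lin > 200000L) {
      stop("simulation exceeded 200000 lineages; the rates imply an ",
           "unmanageably large tree over this time span")
    }
  }
  if (length(alive) < 2L) return(NULL)
  status[alive] <- "extant"; t_end[alive] <- t
  idx <- seq_len(n_lin)
  list(lineages = data.frame(id = idx, parent = parent[idx],
                             t_birth = t_birth[idx], t_end = t_end[idx],
                             state = state[idx], status = status[idx],
                             stringsAsFactors = FALSE),
       present = t)
}

# Convert a lineage table to an ape phylo (complete tree incl. extinct tips).
.lineages_to_phylo <- function(lin) {
  is_tip <- lin$status %in% c("dead", "extant")
  tips <- lin$id[is_tip]
  splits <- lin$id[lin$status == "split"]
  if (length(splits) == 0L) stop("degenerate simulation: no branching event")
  if (lin$status[1L] != "split") stop("root lineage did not branch")
  n_tip <- length(tips)
  node_of <- integer(nrow(lin))
  node_of[tips] <- seq_len(n_tip)
  node_of[1L] <- n_tip + 1L  # crown root
  others <- setdiff(splits, 1L)
  node_of[others] <- n_tip + 1L + seq_along(others)
  children <- lin$id[lin$parent != 0L]
  edge <- cbind(node_of[lin$parent[children]], node_of[children])
  edge_length <- lin$t_end[children] - lin$t_birth[children]
  tr <- list(edge = edge, edge.length = edge_length,
             tip.label = paste0("t", tips), Nnode = length(splits),
             root.edge = lin$t_end[1L] - lin$t_birth[1L])
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Forward-simulate a BiSSE tree with tip states
#'
#' Gillespie simulation of the state-dependent birth-death-transition
#' process: each lineage in state `i` waits an exponential time with total
#' rate `lambda_i * m(t) + mu_i + q_ij` (with `m(t)` the epoch speciation
#' multiplier), and the event type is chosen proportionally. Extinct
#' lineages are pruned to give the reconstructed tree, which is ultrametric
#' by construction. Runs in which the clade dies out before satisfying the
#' stop rule are retried up to `cfg$max_retries` times.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the replicate is fully reproducible from it.
#' @return A list of class `bisse_sim` with elements `tree` (reconstructed,
#'   extant-only, ultrametric `phylo`), `states` ([tip_states()] for the
#'   reconstructed tips), `complete` (tree including extinct tips, with the
#'   stem as `root.edge`), `complete_states`, `present` (simulation time
#'   span) and `retries`.
#' @export
simulate_bisse <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  cp_sub <- .cp_to_sub(cfg$cp, cfg$conv)
  res <- NULL
  retries <- 0L
  for (k in seq_len(cfg$max_retries + 1L)) {
    res <- .sim_once(cfg, cp_sub)
    if (!is.null(res)) break
    retries <- retries + 1L
  }
  if (is.null(res)) {
    stop("clade died out in all ", cfg$max_retries + 1L, " attempts; the ",
         "extinction/speciation balance makes survival too unlikely")
  }
  lin <- res$lineages
  complete <- .lineages_to_phylo(lin)
  is_tip <- lin$status %in% c("dead", "extant")
  complete_states <- tip_states(paste0("t", lin$id[is_tip]),
                                state = lin$state[is_tip])
  dead_labels <- paste0("t", lin$id[lin$status == "dead"])
  tree <- if (length(dead_labels) > 0L) {
    ape::drop.tip(complete, dead_labels)
  } else {
    complete
  }
  tree$root.edge <- NULL
  keep <- complete_states$tip_label %in% tree$tip.label
  states <- complete_states[keep, , drop = FALSE]
  class(states) <- c("tip_states", "data.frame")
  structure(list(tree = tree, states = states, complete = complete,
                 complete_states = complete_states, present = res$present,
                 retries = retries, params = cfg$params, seed = seed),
            class = "bisse_sim")
}

#' Activity-generation model for simulated tips
#'
#' Conditional distributions of raw activity (percent of the reference
#' L1_RP) given the latent binary state. The defaults concentrate
#' low-activity draws well below the threshold (scaled Beta) and give
#' high-activity draws an exponential tail above it; both respect the
#' threshold by construction, so binarizing recovers the latent states
#' exactly.
#'
#' @param threshold Percent cutoff between low and high (default 25, the
#'   same value [binarize_activity()] uses).
#' @param rlow,rhigh Functions of `n` returning `n` draws for low / high
#'   tips. Defaults: `threshold * rbeta(n, 1.2, 4)` and
#'   `threshold * (1 + rexp(n, 1/2))`.
#' @return An `activity_model` object.
#' @export
activity_model <- function(threshold = 25, rlow = NULL, rhigh = NULL) {
  stopifnot(threshold > 0)
  if (is.null(rlow)) {
    rlow <- function(n) threshold * stats::rbeta(n, 1.2, 4)
  }
  if (is.null(rhigh)) {
    rhigh <- function(n) threshold * (1 + stats::rexp(n, 1 / 2))
  }
  structure(list(threshold = threshold, rlow = rlow, rhigh = rhigh),
            class = "activity_model")
}

#' Simulate raw activities consistent with binary states
#'
#' Draws a raw activity for every tip from the state-conditional
#' distributions of an [activity_model()]; values are clamped to the correct
#' side of the threshold so that [binarize_activity()] recovers the input
#' states exactly. Unknown states get `NA` activity.
#'
#' @param states A [tip_states()] table with binary states.
#' @param model An [activity_model()].
#' @param seed Optional integer seed.
#' @return The input `tip_states` with an `activity` column added.
#' @export
simulate_activities <- function(states, model = activity_model(),
                                seed = NULL) {
  stopifnot(inherits(states, "tip_states"), inherits(model, "activity_model"))
  if (!is.null(seed)) set.seed(seed)
  th <- model$threshold
  n <- nrow(states)
  act <- rep(NA_real_, n)
  lo <- which(!is.na(states$state) & states$state == 0L)
  hi <- which(!is.na(states$state) & states$state == 1L)
  if (length(lo) > 0L) {
    act[lo] <- pmin(pmax(model$rlow(length(lo)), 0), th * (1 - 1e-9))
  }
  if (length(hi) > 0L) {
    act[hi] <- pmax(model$rhigh(length(hi)), th)
  }
  states$activity <- act
  states
}

# multiplicative log-normal branch jitter with re-ultrametrization via the
# terminal branches (a cheap stand-in for posterior branch-length spread,
# NOT a posterior)
.jitter_ultrametric <- function(tree, sd) {
  if (sd == 0) return(tree)
  tr <- tree
  tr$edge.length <- tr$edge.length *
    exp(stats::rnorm(length(tr$edge.length), -sd^2 / 2, sd))
  ntip <- ape::Ntip(tr)
  d <- ape::node.depth.edgelength(tr)
  term <- match(seq_len(ntip), tr$edge[, 2L])
  base <- d[seq_len(ntip)] - tr$edge.length[term]
  target <- max(d[seq_len(ntip)])
  tr$edge.length[term] <- target - base
  tr
}

#' Write a synthetic fixture bundle emulating a posterior tree sample
#'
#' Simulates one dataset under `cfg`, then writes: a multi-tree newick file
#' of `n_trees` copies of the reconstructed tree with multiplicative
#' log-normal branch-length jitter (re-ultrametrized via the terminal
#' branches) emulating posterior spread — with `jitter_sd = 0` every copy
#' is the true tree; a tab-separated activity table (`tip_label`,
#' `activity_percent`, `true_state`); and a JSON file recording the true
#' parameters and the seed, for recovery tests. Re-running with the same
#' seed reproduces the bundle byte for byte.
#'
#' @param cfg A [sim_config()].
#' @param n_trees Number of jittered tree copies to write.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param jitter_sd Log-normal sigma for branch jitter (default 0.05).
#' @param act_model An [activity_model()].
#' @return Invisibly, a named list of the three file paths (`trees`,
#'   `activities`, `truth`).
#' @export
make_fixture_bundle <- function(cfg, n_trees, out_dir, seed = 1L,
                                jitter_sd = 0.05,
                                act_model = activity_model()) {
  stopifnot(inherits(cfg, "sim_config"), n_trees >= 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_bisse(cfg, seed = seed)
  # all remaining draws ride on the stream already seeded by simulate_bisse
  trees <- lapply(seq_len(n_trees), function(k) {
    .jitter_ultrametric(sim$tree, jitter_sd)
  })
  acts <- simulate_activities(sim$states, model = act_model)
  paths <- list(trees = file.path(out_dir, "trees.nwk"),
                activities = file.path(out_dir, "activities.tsv"),
                truth = file.path(out_dir, "truth.json"))
  write_tree_sample(tree_sample(trees), paths$trees)
  df <- data.frame(tip_label = acts$tip_label,
                   activity_percent = formatC(acts$activity, digits = 10,
                                              format = "g"),
                   true_state = acts$state, stringsAsFactors = FALSE)
  utils::write.table(df, paths$activities, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(params = as.list(unclass(sim$params)),
                cp = if (is.null(cfg$cp)) NULL else
                  list(boundaries_gen = cfg$cp$boundaries_gen,
                       multipliers = cfg$cp$multipliers),
                n_tips = cfg$n_tips, max_time = cfg$max_time,
                subst_rate = cfg$conv$subst_rate,
                seed = seed, jitter_sd = jitter_sd,
                threshold = act_model$threshold,
                synthetic = TRUE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
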