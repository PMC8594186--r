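MK2_MODELS <- c("free", "equal", "q01=0", "q10=0")

# free-rate names per model
.mk2_free_rates <- function(model) {
  switch(model,
         "free" = c("q01", "q10"),
         "equal" = "q",
         "q01=0" = "q10",
         "q10=0" = "q01")
}

# map (model, named free rates) to the (q01, q10) pair
.mk2_rates <- function(model, free_vals) {
  switch(model,
         "free" = c(free_vals[["q01"]], free_vals[["q10"]]),
         "equal" = c(free_vals[["q"]], free_vals[["q"]]),
         "q01=0" = c(0, free_vals[["q10"]]),
         "q10=0" = c(free_vals[["q01"]], 0))
}

#' Reversible-jump MCMC for the Mk2 transition rates over a tree sample
#'
#' Metropolis-Hastings sampling of the two activity transition rates, with
#' optional reversible jumps across the four rate constraints (both rates
#' free, equal rates, `q01 = 0`, `q10 = 0`; uniform prior over the four).
#' Rate moves are random walks on the log scale. Each iteration also
#' proposes a tree drawn uniformly from the sample and accepts it by the
#' likelihood ratio, which integrates over phylogenetic uncertainty in the
#' style of sampling trees from a posterior sample. Between-model moves
#' propose the new model's free rates from their priors, so the acceptance
#' ratio reduces to the likelihood ratio; this is simpler than split/merge
#' proposals but covers the same model set and leaves the correct posterior
#' invariant.
#'
#' Free rates carry independent exponential priors with mean
#' `priors$rate_mean` (default 100 per substitution/site, a weakly
#' informative scale for transition rates of order tens to hundreds).
#'
#' @param sample A [tree_sample()].
#' @param states A [tip_states()] table.
#' @param priors List with `rate_mean` (exponential prior mean per free
#'   rate).
#' @param n_iter Number of MCMC iterations (>= 1).
#' @param seed Integer seed; the whole trace is reproducible from it.
#' @param rj Enable between-model reversible jumps (default `TRUE`;
#'   otherwise the chain stays in the free-rates model).
#' @param proposal_sd Initial log-scale random-walk standard deviation;
#'   adapted toward ~30% acceptance during the first quarter of the chain,
#'   then frozen.
#' @param thin Keep every `thin`-th iteration (state at the start of the
#'   iteration), so the trace has `floor(n_iter / thin)` rows.
#' @param model_move_prob Per-iteration probability of attempting a
#'   between-model jump when `rj = TRUE` (default 0.3).
#' @param sample_prior If `TRUE` the likelihood is switched off and the
#'   chain targets the prior (used to validate the sampler).
#' @param root_freqs Root weighting passed to the Mk2 likelihood (`NULL` =
#'   stationary frequencies).
#' @return An `mcmc_trace` data frame with columns `iteration`, `model`,
#'   `q01`, `q10`, `tree_index`, `loglik`, and attributes `seed`,
#'   `settings` and `acceptance` (rate-move acceptance fraction).
#' @export
run_mcmc <- function(sample, states, priors = list(rate_mean = 100),
                     n_iter = 5000L, seed = 1L, rj = TRUE,
                     proposal_sd = 0.5, thin = 10L,
                     model_move_prob = 0.3, sample_prior = FALSE,
                     root_freqs = NULL) {
  stopifnot(inherits(sample, "tree_sample"), n_iter >= 1L, thin >= 1L)
  rate_mean <- priors$rate_mean %||% 100
  stopifnot(rate_mean > 0)
  preps <- lapply(unclass(sample), .mk2_prep, states = states)
  n_trees <- length(preps)
  ll_fun <- if (isTRUE(sample_prior)) {
    function(tree_idx, q01, q10) 0
  } else {
    function(tree_idx, q01, q10) {
      .mk2_ll_prep(preps[[tree_idx]], q01, q10, root_freqs)
    }
  }
  log_prior <- function(x) sum(stats::dexp(x, rate = 1 / rate_mean,
                                           log = TRUE))

  set.seed(seed)
  model <- "free"
  free_vals <- c(q01 = rate_mean, q10 = rate_mean)
  rates <- .mk2_rates(model, free_vals)
  tree_idx <- 1L
  ll <- ll_fun(tree_idx, rates[1L], rates[2L])

  n_keep <- n_iter %/% thin
  if (n_keep < 1L) n_keep <- 1L
  out_iter <- integer(n_keep); out_model <- character(n_keep)
  out_q01 <- numeric(n_keep); out_q10 <- numeric(n_keep)
  out_tree <- integer(n_keep); out_ll <- numeric(n_keep)
  keep <- 0L

  sd_now <- proposal_sd
  n_adapt <- floor(0.25 * n_iter)
  acc_n <- 0L; try_n <- 0L

  for (i in seq_len(n_iter)) {
    if ((i - 1L) %% thin == 0L && keep < n_keep) {
      keep <- keep + 1L
      out_iter[keep] <- i; out_model[keep] <- model
      out_q01[keep] <- rates[1L]; out_q10[keep] <- rates[2L]
      out_tree[keep] <- tree_idx; out_ll[keep] <- ll
    }

    # tree move (uniform proposal over the sample; symmetric)
    if (n_trees > 1L) {
      j <- sample.int(n_trees, 1L)
      if (j != tree_idx) {
        llj <- ll_fun(j, rates[1L], rates[2L])
        if (log(stats::runif(1L)) < llj - ll) {
          tree_idx <- j; ll <- llj
        }
      }
    }

    # rate move: log-scale random walk on each free rate in turn
    for (nm in names(free_vals)) {
      cur <- free_vals[[nm]]
      prop <- cur * exp(stats::rnorm(1L, 0, sd_now))
      fv2 <- free_vals; fv2[[nm]] <- prop
      r2 <- .mk2_rates(model, fv2)
      ll2 <- ll_fun(tree_idx, r2[1L], r2[2L])
      lacc <- (ll2 - ll) + (log_prior(prop) - log_prior(cur)) +
        (log(prop) - log(cur))  # Jacobian of the log-scale walk
      try_n <- try_n + 1L
      accepted <- is.finite(lacc) && log(stats::runif(1L)) < lacc
      if (accepted) {
        free_vals <- fv2; rates <- r2; ll <- ll2
        acc_n <- acc_n + 1L
      }
      if (i <= n_adapt) {
        sd_now <- sd_now * exp((as.numeric(accepted) - 0.3) / sqrt(10 + i))
        sd_now <- min(max(sd_now, 1e-3), 10)
      }
    }

    # between-model jump: born rates proposed from their priors, so the
    # prior and proposal densities cancel and the ratio is L'/L
    if (rj && stats::runif(1L) < model_move_prob) {
      m2 <- sample(setdiff(MK2_MODELS, model), 1L)
      fv2 <- stats::setNames(
        stats::rexp(length(.mk2_free_rates(m2)), rate = 1 / rate_mean),
        .mk2_free_rates(m2))
      r2 <- .mk2_rates(m2, fv2)
      ll2 <- ll_fun(tree_idx, r2[1L], r2[2L])
      if (is.finite(ll2) && log(stats::runif(1L)) < ll2 - ll) {
        model <- m2; free_vals <- fv2; rates <- r2; ll <- ll2
      }
    }
  }

  acc_rate <- if (try_n > 0L) acc_n / try_n else NA_real_
  if (!is.na(acc_rate) && (acc_rate < 0.05 || acc_rate > 0.9)) {
    warning("rate-move acceptance rate ", signif(acc_rate, 2),
            " is outside [0.05, 0.9]; consider adjusting proposal_sd")
  }
  tr <- data.frame(iteration = out_iter[seq_len(keep)],
                   model = out_model[seq_len(keep)],
                   q01 = out_q01[seq_len(keep)],
                   q10 = out_q10[seq_len(keep)],
                   tree_index = out_tree[seq_len(keep)],
                   loglik = out_ll[seq_len(keep)],
                   stringsAsFactors = FALSE)
  attr(tr, "seed") <- seed
  attr(tr, "settings") <- list(n_iter = n_iter, thin = thin, rj = rj,
                               rate_mean = rate_mean,
                               proposal_sd = proposal_sd,
                               model_move_prob = model_move_prob,
                               sample_prior = isTRUE(sample_prior))
  attr(tr, "acceptance") <- acc_rate
  class(tr) <- c("mcmc_trace", "data.frame")
  tr
}

#' Summarise an MCMC trace
#'
#' Drops a burn-in fraction, then reports posterior model probabilities and
#' model-averaged summaries of the two transition rates (means and central
#' 95% credible intervals; rates fixed at zero by a model contribute
#' zeros).
#'
#' @param trace An `mcmc_trace` from [run_mcmc()].
#' @param burnin Fraction of the trace discarded from the start (default
#'   0.25; must leave at least one row).
#' @return A list with `models` (data frame of posterior probabilities,
#'   summing to 1), `rates` (data frame with mean, 2.5% and 97.5% quantiles
#'   for `q01` and `q10`) and `n_samples`.
#' @export
posterior_summary <- function(trace, burnin = 0.25) {
  stopifnot(inherits(trace, "data.frame"), nrow(trace) >= 1L,
            burnin >= 0, burnin < 1)
  drop_n <- floor(burnin * nrow(trace))
  kept <- trace[(drop_n + 1L):nrow(trace), , drop = FALSE]
  if (nrow(kept) < 1L) stop("no samples left after burn-in")
  counts <- table(factor(kept$model, levels = MK2_MODELS))
  models <- data.frame(model = names(counts),
                       prob = as.numeric(counts) / nrow(kept),
                       stringsAsFactors = FALSE)
  qs <- function(x) c(mean = mean(x),
                      lower = unname(stats::quantile(x, 0.025)),
                      upper = unname(stats::quantile(x, 0.975)))
  rates <- rbind(q01 = qs(kept$q01), q10 = qs(kept$q10))
  rates <- data.frame(rate = rownames(rates), rates,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(models = models, rates = rates, n_samples = nrow(kept))
}

#' Write an MCMC trace as TSV
#'
#' @param trace An `mcmc_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
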