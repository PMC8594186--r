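PARAM_NAMES <- c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")

#' Define a parameter constraint on the BiSSE model
#'
#' A constraint is a set of equality ties among the six rates plus a set of
#' rates fixed to zero. The number of free parameters (`df`) is the number
#' of tie groups plus the number of untied, non-zero rates.
#'
#' @param id Short label for the constraint (used in tables).
#' @param ties A list of character vectors; the rates in each vector are
#'   constrained equal (e.g. `list(c("mu0", "mu1"))`).
#' @param zeros Character vector of rates fixed to zero.
#' @return A `model_constraint` object with fields `id`, `ties`, `zeros`,
#'   `df` and `free` (the names of the free parameters, one per tie group).
#' @export
model_constraint <- function(id, ties = list(), zeros = character(0)) {
  stopifnot(is.character(id), length(id) == 1L)
  zeros <- as.character(zeros)
  if (!all(zeros %in% PARAM_NAMES)) stop("unknown rate in 'zeros'")
  for (g in ties) {
    if (!all(g %in% PARAM_NAMES) || length(g) < 2L) {
      stop("each tie group must name at least two of the six rates")
    }
    if (any(g %in% zeros)) stop("a rate cannot be both tied and fixed to zero")
  }
  tied <- unlist(ties)
  if (anyDuplicated(tied)) stop("a rate appears in more than one tie group")
  free_single <- setdiff(PARAM_NAMES, c(zeros, tied))
  free <- c(vapply(ties, `[[`, character(1L), 1L), free_single)
  # keep canonical rate order for reproducible parameter vectors
  free <- PARAM_NAMES[PARAM_NAMES %in% free]
  df <- length(free)
  if (df < 1L) stop("a constraint must leave at least one free parameter")
  structure(list(id = id, ties = ties, zeros = zeros, df = df, free = free),
            class = "model_constraint")
}

# Expand a free-parameter vector (named by representative rates) to the full
# six-rate vector under a constraint.
.expand_params <- function(free_vals, constraint) {
  p <- stats::setNames(numeric(6L), PARAM_NAMES)
  p[constraint$free] <- free_vals
  for (g in constraint$ties) {
    rep_name <- PARAM_NAMES[PARAM_NAMES %in% g][1L]
    p[g] <- p[rep_name]
  }
  p[constraint$zeros] <- 0
  .as_bisse_params(p)
}

#' The built-in constraint set for the L1 diversification analysis
#'
#' Returns the nine constraint models compared in the analysis: the
#' unconstrained six-parameter model plus eight restricted variants (equal
#' extinction rates, equal speciation rates, equal transition rates, zero
#' extinction, zero low-activity speciation, zero low-to-high transition,
#' and the two three-parameter combinations).
#'
#' @return A named list of [model_constraint()] objects.
#' @examples
#' sapply(builtin_constraints(), function(m) m$df)
#' @export
builtin_constraints <- function() {
  cs <- list(
    model_constraint("unconstrained"),
    model_constraint("mu0=mu1", ties = list(c("mu0", "mu1"))),
    model_constraint("lambda0=lambda1", ties = list(c("lambda0", "lambda1"))),
    model_constraint("q01=q10", ties = list(c("q01", "q10"))),
    model_constraint("mu0=mu1=0", zeros = c("mu0", "mu1")),
    model_constraint("lambda0=0", zeros = "lambda0"),
    model_constraint("q01=0", zeros = "q01"),
    model_constraint("mu0=mu1=lambda0=0", zeros = c("mu0", "mu1", "lambda0")),
    model_constraint("mu0=mu1=q01=0", zeros = c("mu0", "mu1", "q01"))
  )
  stats::setNames(cs, vapply(cs, `[[`, character(1L), "id"))
}

# Cheap fingerprint of (sample, states) so model_table can refuse to rank
# fits obtained on different data.
.data_key <- function(sample, states) {
  c(n_trees = length(sample),
    n_tips = ape::Ntip(sample[[1L]]),
    total_length = round(sum(vapply(unclass(sample),
                                    function(tr) sum(tr$edge.length),
                                    numeric(1L))), 9),
    state_sum = sum(states$state, na.rm = TRUE),
    n_unknown = sum(is.na(states$state)))
}

# Shared optimisation driver. extra_free: names of additional log-scale
# parameters appended after the constrained rates (change-point multipliers).
.fit_driver <- function(sample, states, constraint, n_starts, seed, root,
                        cp_boundaries_sub = NULL, fix_multipliers = NULL,
                        extra_starts = list(), control = list(),
                        rel_tol = 1e-3) {
  stopifnot(inherits(sample, "tree_sample"),
            inherits(constraint, "model_constraint"),
            inherits(root, "root_options"), n_starts >= 1L)
  preps <- lapply(unclass(sample), .bisse_prep, states = states,
                  rel_tol = rel_tol)
  depth_max <- max(vapply(preps, `[[`, numeric(1L), "depth"))
  n_cp <- length(cp_boundaries_sub)
  mult_free <- if (n_cp > 0L && is.null(fix_multipliers)) n_cp else 0L
  n_free <- constraint$df + mult_free

  pooled <- function(pars, mult) {
    cp_sub <- if (n_cp > 0L) list(times = cp_boundaries_sub, mult = mult)
              else NULL
    ll <- vapply(preps, .bisse_ll_prep, numeric(1L), pars = pars,
                 root = root, cp_sub = cp_sub, control = control)
    .logsumexp(ll)
  }
  objective <- function(logp) {
    if (any(!is.finite(logp)) || any(abs(logp) > 50)) return(1e10)
    vals <- exp(logp)
    pars <- .expand_params(vals[seq_len(constraint$df)], constraint)
    mult <- if (mult_free > 0L) vals[constraint$df + seq_len(n_cp)]
            else fix_multipliers
    # rates implying thousands of expected events per lineage are
    # astronomically implausible and make the ODE integration arbitrarily
    # expensive; deflect the search with a sloped penalty instead
    scale <- max(pars * c(max(1, mult), max(1, mult), 1, 1, 1, 1)) * depth_max
    if (scale > 1000) return(1e9 * (1 + log10(scale / 1000)))
    ll <- tryCatch(pooled(pars, mult), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # starts: one moment-based heuristic + (n_starts - 1) log-uniform draws on
  # [1e-2, 1e4]; change-point multipliers start at 1
  set.seed(seed)
  n_tips <- preps[[1L]]$n_tip
  total_len <- sum(preps[[1L]]$edge_length)
  lam0 <- (n_tips - 1) / max(total_len, .Machine$double.eps)
  heuristic <- stats::setNames(rep(lam0, constraint$df), constraint$free)
  heuristic[grep("^mu", names(heuristic))] <- lam0 / 4
  heuristic[grep("^q", names(heuristic))] <- lam0 / 2
  starts <- list(log(heuristic))
  if (n_starts > 1L) {
    for (k in seq_len(n_starts - 1L)) {
      starts[[k + 1L]] <- stats::runif(constraint$df, log(1e-2), log(1e4))
    }
  }
  starts <- lapply(starts, function(s) c(s, rep(0, mult_free)))
  for (es in extra_starts) {
    es <- .as_bisse_params(es)
    free_vals <- pmax(unclass(es)[constraint$free], 1e-8)
    starts[[length(starts) + 1L]] <- c(log(free_vals), rep(0, mult_free))
  }

  runs <- lapply(starts, function(s0) {
    if (length(s0) == 1L) {
      return(stats::optim(s0, objective, method = "Brent", lower = -40,
                          upper = 40))
    }
    opt <- stats::optim(s0, objective, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-9))
    # one polishing pass from the NM optimum
    opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
    if (opt2$value < opt$value) opt <- opt2
    opt
  })
  vals <- vapply(runs, `[[`, numeric(1L), "value")
  if (all(vals >= 1e10)) {
    stop("all ", length(runs), " optimisation starts failed to reach a ",
         "finite likelihood")
  }
  best <- runs[[which.min(vals)]]
  est <- exp(best$par)
  pars_hat <- .expand_params(est[seq_len(constraint$df)], constraint)
  mult_hat <- if (mult_free > 0L) unname(est[constraint$df + seq_len(n_cp)])
              else fix_multipliers
  logL <- -best$value
  # a change-point model carries one parameter per boundary even when the
  # multiplier is pinned (a pinned multiplier is a spent, not reclaimed, df)
  df <- constraint$df + n_cp
  res <- list(
    constraint = constraint,
    params = pars_hat,
    loglik = logL,
    df = df,
    AIC = 2 * df - 2 * logL,
    multipliers = mult_hat,
    cp_boundaries_sub = cp_boundaries_sub,
    root = root,
    seed = seed,
    n_starts = length(starts),
    start_values = -vals,
    convergence = vapply(runs, `[[`, numeric(1L), "convergence"),
    data_key = .data_key(sample, states),
    diagnostics = list(
      unidentifiable_boundaries =
        if (n_cp > 0L) which(cp_boundaries_sub >= depth_max) else integer(0))
  )
  class(res) <- "fit_result"
  res
}

#' Maximum-likelihood fit of a constrained BiSSE model
#'
#' Maximises the pooled log-likelihood ([pooled_loglik()]) over the free
#' parameters of a constraint. Optimisation is over log-transformed rates
#' (so the non-negativity constraint is implicit and conditioning is
#' better), with a deterministic multi-start strategy: one moment-based
#' start plus `n_starts - 1` log-uniform draws on `[1e-2, 1e4]`, all seeded.
#' Non-finite likelihoods during the search are penalised, not fatal.
#'
#' @param sample A [tree_sample()].
#' @param states A [tip_states()] table.
#' @param constraint A [model_constraint()].
#' @param n_starts Number of optimisation starts (default 10).
#' @param seed Integer seed controlling the random starts.
#' @param root A [root_options()] object.
#' @param extra_starts Optional list of full six-rate vectors used as
#'   additional starts (e.g. the optimum of a nested model).
#' @param control Integrator control list, see [bisse_loglik()].
#' @param rel_tol Ultrametricity tolerance.
#' @return A `fit_result` with the ML [bisse_params()], the pooled
#'   log-likelihood, `df`, `AIC = 2*df - 2*logLik`, per-start diagnostics,
#'   the root options used and the seed.
#' @export
fit_model <- function(sample, states, constraint, n_starts = 10L, seed = 1L,
                      root = root_options(), extra_starts = list(),
                      control = list(), rel_tol = 1e-3) {
  .fit_driver(sample, states, constraint, n_starts, seed, root,
              extra_starts = extra_starts, control = control,
              rel_tol = rel_tol)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("BiSSE fit [", x$constraint$id, "]  df =", x$df, "\n")
  cat("  logLik =", format(x$loglik, digits = 8),
      "  AIC =", format(x$AIC, digits = 8), "\n")
  cat("  rates:", paste(names(x$params),
                        format(unclass(x$params), digits = 4),
                        sep = "=", collapse = ", "), "\n")
  if (!is.null(x$multipliers)) {
    cat("  epoch multipliers:",
        paste(format(x$multipliers, digits = 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' AIC comparison table for a set of fits
#'
#' Ranks fits of different constraint models on the same data by AIC
#' (ascending). Ties are broken by fewer free parameters, then by constraint
#' id. Refuses to rank fits whose data fingerprints differ.
#'
#' @param fits A list of `fit_result` objects (at least one).
#' @return A data frame with columns `constraint`, `df`, `loglik`, `AIC`,
#'   `dAIC` and `best`, sorted by AIC.
#' @export
model_table <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1L), "fit_result")))
  keys <- lapply(fits, `[[`, "data_key")
  if (length(unique(vapply(keys, paste, character(1L), collapse = "|"))) > 1L) {
    stop("fits were obtained on different data and cannot be ranked together")
  }
  tab <- data.frame(
    constraint = vapply(fits, function(f) f$constraint$id, character(1L)),
    df = vapply(fits, `[[`, numeric(1L), "df"),
    loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
    AIC = vapply(fits, `[[`, numeric(1L), "AIC"),
    stringsAsFactors = FALSE)
  ord <- order(tab$AIC, tab$df, tab$constraint)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  tab
}

#' Fit a change-point BiSSE model
#'
#' Jointly maximises the constrained base rates and one speciation-rate
#' multiplier per change-point boundary; each boundary adds one parameter,
#' so `df = df_base + n_boundaries` (a multiplier pinned via
#' `fix_multipliers` still counts as a spent parameter). A boundary older
#' than every tree root is flagged as unidentifiable in the diagnostics.
#'
#' @inheritParams fit_model
#' @param base_constraint The [model_constraint()] for the six rates.
#' @param cp_boundaries_gen Change-point times before present, in
#'   generations (strictly increasing).
#' @param conv A [unit_conversion()].
#' @param fix_multipliers Optional numeric vector: fix the multipliers at
#'   these values instead of estimating them (they then add no df).
#' @return A `fit_result` with `multipliers` and boundary diagnostics.
#' @export
fit_changepoint <- function(sample, states, base_constraint,
                            cp_boundaries_gen, conv = unit_conversion(),
                            n_starts = 10L, seed = 1L,
                            root = root_options(), fix_multipliers = NULL,
                            extra_starts = list(), control = list(),
                            rel_tol = 1e-3) {
  cp_boundaries_gen <- as.numeric(cp_boundaries_gen)
  if (length(cp_boundaries_gen) < 1L ||
      is.unsorted(cp_boundaries_gen, strictly = TRUE) ||
      any(cp_boundaries_gen < 0)) {
    stop("cp_boundaries_gen must be strictly increasing, non-negative")
  }
  if (!is.null(fix_multipliers) &&
      length(fix_multipliers) != length(cp_boundaries_gen)) {
    stop("fix_multipliers must match the number of boundaries")
  }
  boundaries_sub <- generations_to_substitutions(cp_boundaries_gen, conv)
  res <- .fit_driver(sample, states, base_constraint, n_starts, seed, root,
                     cp_boundaries_sub = boundaries_sub,
                     fix_multipliers = fix_multipliers,
                     extra_starts = extra_starts, control = control,
                     rel_tol = rel_tol)
  res$cp_boundaries_gen <- cp_boundaries_gen
  if (length(res$diagnostics$unidentifiable_boundaries) > 0L) {
    warning("boundary ",
            paste(res$diagnostics$unidentifiable_boundaries, collapse = ", "),
            " lies beyond every tree root; its multiplier is unidentifiable")
  }
  res
}

#' Write a fit result as JSON
#'
#' Serialises the ML parameters, log-likelihood, df, AIC, any epoch
#' multipliers, the root options and the optimiser diagnostics.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(
    constraint = fit$constraint$id,
    params = as.list(unclass(fit$params)),
    loglik = fit$loglik,
    df = fit$df,
    AIC = fit$AIC,
    multipliers = fit$multipliers,
    cp_boundaries_gen = fit$cp_boundaries_gen,
    root = list(mode = fit$root$mode,
                condition_on_survival = fit$root$condition_on_survival),
    seed = fit$seed,
    n_starts = fit$n_starts,
    start_logliks = fit$start_values,
    convergence = fit$convergence,
    diagnostics = fit$diagnostics
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a model comparison table to TSV
#'
#' @param tab A table from [model_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
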