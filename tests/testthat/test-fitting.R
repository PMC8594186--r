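test_that("the built-in constraint set matches the published model list", {
  cs <- builtin_constraints()
  expect_length(cs, 9L)
  dfs <- vapply(cs, `[[`, numeric(1L), "df")
  expect_equal(unname(dfs),
               c(6, 5, 5, 5, 4, 5, 5, 3, 3))
  expect_equal(cs[["mu0=mu1=0"]]$df, 4)
  expect_equal(cs[["unconstrained"]]$df, 6)
  expect_equal(cs[["mu0=mu1=lambda0=0"]]$df, 3)
  expect_equal(cs[["mu0=mu1=q01=0"]]$df, 3)
})

test_that("constraint construction validates its inputs", {
  expect_error(model_constraint("bad", zeros = "lambda9"), "unknown rate")
  expect_error(model_constraint("bad", ties = list("mu0")), "at least two")
  expect_error(model_constraint("bad", ties = list(c("mu0", "mu1")),
                                zeros = "mu0"), "both tied and fixed")
  expect_error(model_constraint("bad", zeros = PARAM_NAMES_ALL <-
                                  c("lambda0", "lambda1", "mu0", "mu1",
                                    "q01", "q10")), "at least one free")
  m <- model_constraint("yule", ties = list(c("lambda0", "lambda1")),
                        zeros = c("mu0", "mu1", "q01", "q10"))
  expect_equal(m$df, 1L)
})

test_that("Yule data recover the analytic lambda MLE", {
  set.seed(61)
  tr <- ape::rcoal(20)
  st <- tip_states(tr$tip.label, state = rep(0L, 20))
  ts <- tree_sample(list(tr))
  yule <- model_constraint("yule", ties = list(c("lambda0", "lambda1")),
                           zeros = c("mu0", "mu1", "q01", "q10"))
  fit <- fit_model(ts, st, yule, n_starts = 3, seed = 2)
  lam_hat <- fit$params[["lambda0"]]
  lam_analytic <- (20 - 1) / sum(tr$edge.length)
  expect_equal(lam_hat, lam_analytic, tolerance = 1e-4)
  expect_equal(fit$params[["lambda0"]], fit$params[["lambda1"]])
  expect_equal(fit$params[["mu0"]], 0)
  # AIC identity holds exactly
  expect_identical(fit$AIC, 2 * fit$df - 2 * fit$loglik)
})

test_that("fitting is deterministic given the seed", {
  set.seed(71)
  sim <- simulate_bisse(sim_config(bisse_params(4, 8, 0, 0, 1, 2),
                                   n_tips = 25), seed = 5)
  ts <- tree_sample(list(sim$tree))
  cs <- builtin_constraints()
  f1 <- fit_model(ts, sim$states, cs[["mu0=mu1=0"]], n_starts = 3, seed = 7)
  f2 <- fit_model(ts, sim$states, cs[["mu0=mu1=0"]], n_starts = 3, seed = 7)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("nested constraints never beat the more general model", {
  set.seed(73)
  sim <- simulate_bisse(sim_config(bisse_params(4, 10, 0, 0, 1.5, 3),
                                   n_tips = 40), seed = 9)
  ts <- tree_sample(list(sim$tree))
  cs <- builtin_constraints()
  f_zero <- fit_model(ts, sim$states, cs[["mu0=mu1=0"]], n_starts = 3,
                      seed = 11)
  f_tied <- fit_model(ts, sim$states, cs[["mu0=mu1"]], n_starts = 3,
                      seed = 11, extra_starts = list(f_zero$params))
  f_full <- fit_model(ts, sim$states, cs[["unconstrained"]], n_starts = 3,
                      seed = 11, extra_starts = list(f_tied$params))
  expect_lte(f_zero$loglik, f_tied$loglik + 1e-6)
  expect_lte(f_tied$loglik, f_full$loglik + 1e-6)
  for (f in list(f_zero, f_tied, f_full)) {
    expect_identical(f$AIC, 2 * f$df - 2 * f$loglik)
  }
  # best-fit parameters satisfy the constraint exactly
  expect_identical(f_zero$params[["mu0"]], 0)
  expect_identical(f_zero$params[["mu1"]], 0)
  expect_identical(f_tied$params[["mu0"]], f_tied$params[["mu1"]])

  tab <- model_table(list(f_zero, f_tied, f_full))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$AIC) >= 0))
  expect_equal(tab$dAIC[1L], 0)
  expect_true(tab$best[1L])
})

test_that("model table arithmetic and safety checks", {
  fake_fit <- function(id, df, loglik, key = c(a = 1)) {
    structure(list(constraint = model_constraint(id),
                   params = bisse_params(1, 1), loglik = loglik, df = df,
                   AIC = 2 * df - 2 * loglik, data_key = key),
              class = "fit_result")
  }
  # equal logLik, df 4 vs 6: delta AIC = 4 in favour of the smaller model
  tab <- model_table(list(fake_fit("big", 6, -100), fake_fit("small", 4, -100)))
  expect_equal(tab$constraint[1L], "small")
  expect_equal(tab$dAIC[2L], 4)
  # a single fit is a one-row table
  tab1 <- model_table(list(fake_fit("only", 5, -10)))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$dAIC, 0)
  # ties broken by fewer df
  tab2 <- model_table(list(fake_fit("a6", 6, -101), fake_fit("b4", 4, -103)))
  expect_equal(tab2$constraint[1L], "b4")
  # different data refuse to rank
  expect_error(model_table(list(fake_fit("x", 4, -1, key = c(a = 1)),
                                fake_fit("y", 4, -1, key = c(a = 2)))),
               "different data")
})

test_that("fit results and model tables export to JSON and TSV", {
  set.seed(79)
  tr <- ape::rcoal(15)
  st <- tip_states(tr$tip.label, state = rep(0L, 15))
  yule <- model_constraint("yule", ties = list(c("lambda0", "lambda1")),
                           zeros = c("mu0", "mu1", "q01", "q10"))
  fit <- fit_model(tree_sample(list(tr)), st, yule, n_starts = 2, seed = 3)
  fj <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  back <- jsonlite::read_json(fj)
  expect_equal(back$constraint, "yule")
  expect_equal(back$AIC, fit$AIC, tolerance = 1e-12)
  expect_equal(back$params$lambda0, fit$params[["lambda0"]],
               tolerance = 1e-12)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(model_table(list(fit)), ft)
  tab <- utils::read.table(ft, header = TRUE, sep = "\t")
  expect_equal(tab$AIC, fit$AIC, tolerance = 1e-9)
})

test_that("a change-point multiplier pinned at 1 costs exactly one df", {
  set.seed(83)
  sim <- simulate_bisse(sim_config(bisse_params(5, 9, 0, 0, 1, 2),
                                   n_tips = 25), seed = 13)
  ts <- tree_sample(list(sim$tree))
  cs <- builtin_constraints()
  depth <- check_ultrametric(sim$tree)$depth
  b_gen <- 0.4 * depth / unit_conversion()$subst_rate
  base <- fit_model(ts, sim$states, cs[["mu0=mu1=0"]], n_starts = 3,
                    seed = 17)
  pinned <- fit_changepoint(ts, sim$states, cs[["mu0=mu1=0"]], b_gen,
                            n_starts = 3, seed = 17, fix_multipliers = 1)
  expect_equal(pinned$loglik, base$loglik, tolerance = 1e-6)
  expect_equal(pinned$df, base$df + 1L)
  expect_equal(pinned$AIC, base$AIC + 2, tolerance = 1e-5)
})

test_that("a boundary beyond every root is flagged as unidentifiable", {
  set.seed(89)
  sim <- simulate_bisse(sim_config(bisse_params(5, 9, 0, 0, 1, 2),
                                   n_tips = 20), seed = 19)
  ts <- tree_sample(list(sim$tree))
  depth <- check_ultrametric(sim$tree)$depth
  conv <- unit_conversion()
  b_gen <- c(0.4 * depth, 5 * depth) / conv$subst_rate
  suppressWarnings(
    fit <- fit_changepoint(ts, sim$states,
                           builtin_constraints()[["mu0=mu1=0"]], b_gen,
                           n_starts = 2, seed = 23)
  )
  expect_equal(fit$diagnostics$unidentifiable_boundaries, 2L)
  expect_equal(fit$df, 4L + 2L)
})

test_that("a true pre-boundary speciation multiplier is recovered", {
  # simulate with both speciation rates 1.6x higher before a known boundary
  conv <- unit_conversion()
  max_t <- 1
  b_sub <- 0.5 * max_t
  cp_true <- changepoint_spec(b_sub / conv$subst_rate, 1.6)
  p <- bisse_params(1.5, 3, 0, 0, 0.3, 0.6)
  sims <- list(); k <- 0L
  for (s in 1:20) {
    sim <- try(simulate_bisse(sim_config(p, cp = cp_true, max_time = max_t),
                              seed = 100 + s), silent = TRUE)
    if (!inherits(sim, "try-error") && ape::Ntip(sim$tree) >= 20 &&
        ape::Ntip(sim$tree) <= 120) {
      k <- k + 1L; sims[[k]] <- sim
    }
    if (k == 3L) break
  }
  expect_gte(k, 1L)
  mults <- sapply(sims, function(sim) {
    ts <- tree_sample(list(sim$tree))
    fit <- fit_changepoint(ts, sim$states,
                           builtin_constraints()[["mu0=mu1=0"]],
                           b_sub / conv$subst_rate, n_starts = 3, seed = 29,
                           extra_starts = list(p))
    fit$multipliers
  })
  # point estimates are noisy tree by tree; demand the right direction and
  # a sane magnitude on the median
  expect_gt(median(mults), 1.0)
  expect_lt(median(mults), 4.0)
})
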