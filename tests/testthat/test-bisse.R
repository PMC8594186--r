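test_that("pure-birth closed forms are reproduced", {
  # 2-tip cherry, both tips low, mu = q = 0: L = lambda * exp(-2 lambda t)
  tr <- ape::read.tree(text = "(A:0.8,B:0.8);")
  st <- tip_states(c("A", "B"), state = c(0, 0))
  lam <- 0.7
  ll <- bisse_loglik(tr, st, bisse_params(lam, lam))
  expect_equal(ll, log(lam) - 2 * lam * 0.8, tolerance = 1e-8)

  # Yule closed form on a larger tree: (n-1) log(lambda) - lambda * T
  set.seed(5)
  tr2 <- ape::rcoal(12)
  st2 <- tip_states(tr2$tip.label, state = rep(0L, 12))
  lam2 <- 0.9
  expected <- 11 * log(lam2) - lam2 * sum(tr2$edge.length)
  expect_equal(bisse_loglik(tr2, st2, bisse_params(lam2, lam2)), expected,
               tolerance = 1e-8)
})

test_that("likelihood is symmetric under label swap for symmetric rates", {
  set.seed(9)
  cs <- random_case(10)
  p <- bisse_params(2, 2, 0.5, 0.5, 1.2, 1.2)
  ll <- bisse_loglik(cs$tree, cs$states, p)
  swapped <- cs$states
  swapped$state <- 1L - swapped$state
  expect_equal(bisse_loglik(cs$tree, swapped, p), ll, tolerance = 1e-10)
})

test_that("likelihood is invariant to tip enumeration order", {
  set.seed(31)
  cs <- random_case(8)
  p <- bisse_params(3, 6, 0.4, 0.2, 0.9, 1.7)
  ll <- bisse_loglik(cs$tree, cs$states, p)
  perm <- cs$states[sample(nrow(cs$states)), , drop = FALSE]
  class(perm) <- c("tip_states", "data.frame")
  expect_equal(bisse_loglik(cs$tree, perm, p), ll, tolerance = 1e-12)
  # and to ladderization (child reordering)
  rot <- ape::ladderize(cs$tree)
  expect_equal(bisse_loglik(rot, cs$states, p), ll, tolerance = 1e-8)
})

test_that("adaptive integrator matches the fixed-step RK4 oracle", {
  set.seed(101)
  # includes the high-rate regime typical of L1 trees (rates ~ hundreds per
  # unit branch length on short trees)
  cs <- random_case(10)
  cs$tree$edge.length <- cs$tree$edge.length * 0.01
  p_hi <- bisse_params(10, 412, 0, 0, 31, 360)
  ll <- bisse_loglik(cs$tree, cs$states, p_hi)
  ll_o <- oracle_bisse_loglik(cs$tree, cs$states, p_hi)
  expect_equal(ll, ll_o, tolerance = 1e-6)

  for (k in 1:10) {
    cs <- random_case(10)
    p <- bisse_params(exp(runif(1, -1, 1.5)), exp(runif(1, -1, 1.5)),
                      exp(runif(1, -3, 0)), exp(runif(1, -3, 0)),
                      exp(runif(1, -2, 1)), exp(runif(1, -2, 1)))
    ll <- bisse_loglik(cs$tree, cs$states, p)
    ll_o <- oracle_bisse_loglik(cs$tree, cs$states, p)
    expect_equal(ll, ll_o, tolerance = 1e-6,
                 label = paste("draw", k, "loglik"))
  }
})

test_that("unknown tip states behave as sums over resolved states", {
  set.seed(17)
  cs <- random_case(6)
  p <- bisse_params(2, 5, 0.3, 0.1, 0.8, 2)
  # flat root combination is linear in the tip initialisation, so a tip with
  # unknown state must give L(unknown) = L(tip = 0) + L(tip = 1)
  root <- root_options("flat")
  s_na <- cs$states; s_na$state[1] <- NA_integer_
  s0 <- cs$states; s0$state[1] <- 0L
  s1 <- cs$states; s1$state[1] <- 1L
  l_na <- bisse_loglik(cs$tree, s_na, p, root = root)
  l0 <- bisse_loglik(cs$tree, s0, p, root = root)
  l1 <- bisse_loglik(cs$tree, s1, p, root = root)
  expect_equal(exp(l_na), exp(l0) + exp(l1), tolerance = 1e-8)
})

test_that("extinction enters through the exact birth-death closed form", {
  # a monomorphic cherry under state-independent rates is a plain
  # birth-death tree: L = lambda * p1(t)^2 with
  # p1(t) = (lambda-mu)^2 e^{-(lambda-mu) t} / (lambda - mu e^{-(lambda-mu) t})^2
  tr <- ape::read.tree(text = "(A:1,B:1);")
  st <- tip_states(c("A", "B"), state = c(0L, 0L))
  lam <- 1
  lls <- sapply(c(0, 0.2, 0.5, 0.9), function(mu) {
    ll <- bisse_loglik(tr, st, bisse_params(lam, lam, mu, mu))
    r <- lam - mu
    p1 <- r^2 * exp(-r) / (lam - mu * exp(-r))^2
    expect_equal(ll, log(lam * p1^2), tolerance = 1e-8,
                 label = paste("BD closed form, mu =", mu))
    ll
  })
  # in this observed-survivors regime the likelihood falls with extinction
  expect_true(all(diff(lls) < 0))
})

test_that("non-ultrametric trees are rejected", {
  tr <- ape::read.tree(text = "((A:1,B:1.5):1,C:2);")
  st <- tip_states(c("A", "B", "C"), state = c(0, 1, 0))
  expect_error(bisse_loglik(tr, st, bisse_params(1, 1)), "ultrametric")
  # but tolerated within the requested slack
  expect_silent(bisse_loglik(tr, st, bisse_params(1, 1), rel_tol = 0.5))
})

test_that("change-point likelihood degenerates correctly", {
  set.seed(41)
  cs <- random_case(10)
  cs$tree$edge.length <- cs$tree$edge.length * 0.01
  p <- bisse_params(10, 412, 0, 0, 31, 360)
  conv <- unit_conversion()
  depth <- check_ultrametric(cs$tree)$depth
  ll0 <- bisse_loglik(cs$tree, cs$states, p)

  # all multipliers 1 -> constant model
  cp1 <- changepoint_spec(0.5 * depth / conv$subst_rate, 1)
  expect_equal(bisse_td_loglik(cs$tree, cs$states, p, cp1), ll0,
               tolerance = 1e-12)

  # boundary at the present with factor f -> lambda pre-scaled by f
  cp2 <- changepoint_spec(1e-12, 1.6)
  p_scaled <- bisse_params(10 * 1.6, 412 * 1.6, 0, 0, 31, 360)
  expect_equal(bisse_td_loglik(cs$tree, cs$states, p, cp2),
               bisse_loglik(cs$tree, cs$states, p_scaled),
               tolerance = 1e-10)

  # boundary older than the root warns and leaves the likelihood unchanged
  cp3 <- changepoint_spec(2 * depth / conv$subst_rate, 3)
  expect_warning(ll3 <- bisse_td_loglik(cs$tree, cs$states, p, cp3),
                 "older than the tree root")
  expect_equal(ll3, ll0, tolerance = 1e-12)
})

test_that("change-point likelihood matches the segment-wise RK4 oracle", {
  set.seed(43)
  cs <- random_case(20)
  cs$tree$edge.length <- cs$tree$edge.length * 0.01
  p <- bisse_params(10, 412, 0, 0, 31, 360)
  conv <- unit_conversion()
  depth <- check_ultrametric(cs$tree)$depth
  b_sub <- 0.5 * depth
  cp <- changepoint_spec(b_sub / conv$subst_rate, 1.6)
  ll <- bisse_td_loglik(cs$tree, cs$states, p, cp)
  ll_o <- oracle_bisse_loglik(cs$tree, cs$states, p,
                              cp_times = b_sub, cp_mult = 1.6)
  expect_equal(ll, ll_o, tolerance = 1e-6)
})

test_that("pooling sums per-tree likelihoods on the log scale", {
  set.seed(47)
  cs <- random_case(8)
  p <- bisse_params(2, 4, 0.2, 0.1, 0.7, 1.1)
  ll1 <- bisse_loglik(cs$tree, cs$states, p)

  # N identical trees: pooled = single + log(N)
  ts5 <- tree_sample(rep(list(cs$tree), 5))
  expect_equal(pooled_loglik(ts5, cs$states, p), ll1 + log(5),
               tolerance = 1e-10)
  # a sample of one equals the single-tree likelihood
  expect_equal(pooled_loglik(tree_sample(list(cs$tree)), cs$states, p), ll1,
               tolerance = 1e-12)

  # distinct trees: log-sum-exp of the per-tree values
  trees <- lapply(1:3, function(i) ape::rcoal(8))
  for (i in 2:3) trees[[i]]$tip.label <- trees[[1]]$tip.label
  st <- tip_states(trees[[1]]$tip.label, state = rbinom(8, 1, 0.5))
  lls <- sapply(trees, function(tr) bisse_loglik(tr, st, p))
  pooled <- pooled_loglik(tree_sample(trees), st, p)
  expect_equal(pooled, log(sum(exp(lls))), tolerance = 1e-10)
  # order invariance
  expect_equal(pooled_loglik(tree_sample(trees[c(3, 1, 2)]), st, p), pooled,
               tolerance = 1e-12)
})

test_that("root treatment options change the combination as documented", {
  set.seed(53)
  cs <- random_case(6)
  p <- bisse_params(2, 3, 0, 0, 0.5, 0.9)
  l_w <- bisse_loglik(cs$tree, cs$states, p, root = root_options("weighted"))
  l_f <- bisse_loglik(cs$tree, cs$states, p, root = root_options("flat"))
  l_0 <- bisse_loglik(cs$tree, cs$states, p,
                      root = root_options("fixed", fixed_state = 0))
  l_1 <- bisse_loglik(cs$tree, cs$states, p,
                      root = root_options("fixed", fixed_state = 1))
  # flat combination is the average of the two fixed-state likelihoods
  expect_equal(exp(l_f), 0.5 * (exp(l_0) + exp(l_1)), tolerance = 1e-10)
  # weighted-by-D lies between the fixed-state extremes
  expect_gte(l_w, min(l_0, l_1) - 1e-10)
  expect_lte(l_w, max(l_0, l_1) + 1e-10)
  # conditioning on survival shifts the likelihood
  l_c <- bisse_loglik(cs$tree, cs$states, p,
                      root = root_options("weighted",
                                          condition_on_survival = TRUE))
  expect_false(isTRUE(all.equal(l_c, l_w)))
})
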