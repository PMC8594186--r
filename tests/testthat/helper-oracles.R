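# Independent fixed-step RK4 pruning oracle for the BiSSE likelihood.
# Deliberately separate from the package implementation: recursive
# traversal, fixed-step classical RK4 per branch, same model definition.

oracle_bisse_loglik <- function(tree, states, pars, cp_times = numeric(0),
                                cp_mult = numeric(0), steps_scale = 80,
                                root_mode = c("weighted", "flat", "fixed0")) {
  root_mode <- match.arg(root_mode)
  pars <- unclass(pars)
  l0 <- pars[["lambda0"]]; l1 <- pars[["lambda1"]]
  m0 <- pars[["mu0"]]; m1 <- pars[["mu1"]]
  q01 <- pars[["q01"]]; q10 <- pars[["q10"]]
  rate_scale <- max(l0, l1) * max(1, cp_mult, 1) + m0 + m1 + q01 + q10 + 1

  ntip <- ape::Ntip(tree)
  dr <- ape::node.depth.edgelength(tree)
  depth <- max(dr[seq_len(ntip)])
  node_time <- pmax(depth - dr, 0)
  node_time[seq_len(ntip)] <- 0
  st <- states$state[match(tree$tip.label, states$tip_label)]

  mult_at <- function(t) {
    m <- 1
    for (k in seq_along(cp_times)) {
      if (t >= cp_times[k]) m <- cp_mult[k] else break
    }
    m
  }
  dydt <- function(y, m) {
    la <- l0 * m; lb <- l1 * m
    c(m0 - (la + m0 + q01) * y[1] + q01 * y[2] + la * y[1]^2,
      m1 - (lb + m1 + q10) * y[2] + q10 * y[1] + lb * y[2]^2,
      -(la + m0 + q01) * y[3] + q01 * y[4] + 2 * la * y[1] * y[3],
      -(lb + m1 + q10) * y[4] + q10 * y[3] + 2 * lb * y[2] * y[4])
  }
  rk4_segment <- function(y, len, m) {
    if (len <= 0) return(y)
    n <- max(50L, ceiling(len * rate_scale * steps_scale))
    h <- len / n
    for (i in seq_len(n)) {
      k1 <- dydt(y, m)
      k2 <- dydt(y + h / 2 * k1, m)
      k3 <- dydt(y + h / 2 * k2, m)
      k4 <- dydt(y + h * k3, m)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  integrate_branch <- function(y, t0, t1) {
    cur <- t0
    while (cur < t1 - 1e-300) {
      nxt <- t1
      for (b in cp_times) if (b > cur && b < nxt) nxt <- b
      y <- rk4_segment(y, nxt - cur, mult_at(cur))
      cur <- nxt
    }
    y
  }

  children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  edge_len <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  visit <- function(node) {
    if (node <= ntip) {
      s <- st[node]
      d <- if (is.na(s)) c(1, 1) else if (s == 0) c(1, 0) else c(0, 1)
      return(list(y = c(0, 0, d), logf = 0))
    }
    kids <- children_of[[as.character(node)]]
    parts <- lapply(kids, function(ch) {
      r <- visit(ch)
      r$y <- integrate_branch(r$y, node_time[ch], node_time[node])
      r
    })
    m <- mult_at(node_time[node])
    E <- (parts[[1]]$y[1:2] + parts[[2]]$y[1:2]) / 2
    D <- c(l0 * m, l1 * m) * parts[[1]]$y[3:4] * parts[[2]]$y[3:4]
    logf <- parts[[1]]$logf + parts[[2]]$logf
    tot <- sum(D)
    list(y = c(E, D / tot), logf = logf + log(tot))
  }
  res <- visit(ntip + 1L)
  D <- res$y[3:4]
  lik <- switch(root_mode,
                weighted = sum(D^2) / sum(D),
                flat = 0.5 * sum(D),
                fixed0 = D[1])
  log(lik) + res$logf
}

# random ultrametric test tree with binary states
random_case <- function(n_tips, p_high = 0.4) {
  tr <- ape::rcoal(n_tips)
  st <- tip_states(tr$tip.label,
                   state = stats::rbinom(n_tips, 1L, p_high))
  list(tree = tr, states = st)
}
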