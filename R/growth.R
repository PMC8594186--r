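#' Build the 2x2 L1 abundance dynamics matrix
#'
#' The fitted diversification rates define a linear system for the expected
#' numbers of low- and high-activity L1 insertions, `x = (x_low, x_high)`:
#' `dx/dt = M x` with
#' `M = [[lambda0 - mu0 - q01, q10], [q01, lambda1 - mu1 - q10]]`,
#' in units of per substitution per site. Off-diagonal entries are the
#' transition rates and hence non-negative, so the dominant eigenvalue is
#' real.
#'
#' @param params A [bisse_params()] vector (or a `fit_result`, whose ML
#'   parameters are used).
#' @return A 2x2 numeric matrix with dimnames `c("low", "high")`.
#' @examples
#' dynamics_matrix(bisse_params(10, 412, 0, 0, 31, 360))
#' @export
dynamics_matrix <- function(params) {
  if (inherits(params, "fit_result")) params <- params$params
  p <- .as_bisse_params(params)
  m <- matrix(c(p[["lambda0"]] - p[["mu0"]] - p[["q01"]], p[["q10"]],
                p[["q01"]], p[["lambda1"]] - p[["mu1"]] - p[["q10"]]),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("low", "high"), c("low", "high")))
  m
}

#' Asymptotic L1 growth rate, equilibrium activity mix and doubling time
#'
#' Solves the 2x2 eigenproblem of the dynamics matrix in closed form (the
#' quadratic of the characteristic polynomial, for exactness): the dominant
#' eigenvalue is the asymptotic rate of increase of L1 insertions per
#' nucleotide substitution, and the associated non-negative eigenvector,
#' normalised to sum 1, gives the stationary fractions of low- and
#' high-activity elements. The per-generation growth rate is the eigenvalue
#' times the substitution rate, and the doubling time is `ln(2)` over the
#' per-generation rate (infinite when growth is non-positive).
#'
#' @param m A matrix from [dynamics_matrix()] (off-diagonals must be
#'   non-negative).
#' @param conv A [unit_conversion()].
#' @return A `dynamics_result` list: `r_sub` (per substitution),
#'   `fraction_low`, `fraction_high`, `r_gen` (per generation),
#'   `doubling_gen` (generations; `Inf` when `r_gen <= 0`), and `matrix`.
#' @examples
#' m <- dynamics_matrix(bisse_params(10, 412, 0, 0, 31, 360))
#' res <- asymptotic_growth(m)
#' round(res$r_sub)  # insertions per nucleotide substitution
#' @export
asymptotic_growth <- function(m, conv = unit_conversion()) {
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (m[1L, 2L] < 0 || m[2L, 1L] < 0) {
    stop("off-diagonal entries must be non-negative (transition rates)")
  }
  a <- m[1L, 1L]; b <- m[1L, 2L]; cc <- m[2L, 1L]; d <- m[2L, 2L]
  disc2 <- (a - d)^2 + 4 * b * cc
  if (disc2 < 0) stop("internal error: complex dominant pair")
  disc <- sqrt(disc2)
  r <- (a + d + disc) / 2
  if (b == 0 && cc == 0) {
    frac_high <- if (a > d) 0 else if (d > a) 1 else 0.5
  } else {
    v <- c(b, r - a)
    if (sum(v) <= 0) v <- c(r - d, cc)
    frac_high <- v[2L] / sum(v)
  }
  r_gen <- r * conv$subst_rate
  structure(list(
    r_sub = r,
    fraction_low = 1 - frac_high,
    fraction_high = frac_high,
    r_gen = r_gen,
    doubling_gen = doubling_time(r_gen),
    matrix = m,
    subst_rate = conv$subst_rate
  ), class = "dynamics_result")
}

#' Doubling time of an exponentially growing quantity
#'
#' @param r_gen Per-generation growth rate.
#' @return `log(2) / r_gen` in generations; `Inf` when `r_gen <= 0`.
#' @export
doubling_time <- function(r_gen) {
  ifelse(r_gen > 0, log(2) / r_gen, Inf)
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat("Asymptotic L1 dynamics\n")
  cat("  growth rate:", round(x$r_sub),
      "insertions per nucleotide substitution\n")
  cat("  per generation:", signif(x$r_gen, 2), "\n")
  if (is.finite(x$doubling_gen)) {
    cat("  doubling time:", signif(x$doubling_gen, 2), "generations\n")
  } else {
    cat("  doubling time: undefined (non-positive growth)\n")
  }
  cat("  equilibrium mix:", signif(100 * x$fraction_low, 3), "% low /",
      signif(100 * x$fraction_high, 3), "% high activity\n")
  invisible(x)
}

#' Forward-integrate the L1 abundance dynamics
#'
#' Numerically solves `dx/dt = M x` from a non-negative initial abundance
#' vector. To avoid overflow at large times the system is integrated in
#' log-total/composition form: `d log S/dt = 1' M p`,
#' `dp/dt = M p - (1' M p) p` with `S` the total abundance and `p` the
#' composition. The long-run slope of `log S` recovers the dominant
#' eigenvalue and the composition converges to the stationary fractions,
#' which makes this an independent check of [asymptotic_growth()].
#'
#' @param m A 2x2 dynamics matrix.
#' @param x0 Non-negative initial abundances `(low, high)`, not both zero.
#' @param t_max End time (same units as the rates' inverse).
#' @param n_steps Number of output points (default 200).
#' @return A data frame with columns `time`, `log_total`, `fraction_low`,
#'   `fraction_high`.
#' @export
forward_integrate <- function(m, x0, t_max, n_steps = 200L) {
  stopifnot(is.matrix(m), all(dim(m) == 2L), length(x0) == 2L,
            all(x0 >= 0), sum(x0) > 0, t_max >= 0)
  p0 <- x0 / sum(x0)
  y0 <- c(logS = log(sum(x0)), p1 = p0[1L])
  rhs <- function(t, y, parms) {
    p <- c(y[2L], 1 - y[2L])
    mp <- parms %*% p
    growth <- sum(mp)
    list(c(growth, mp[1L] - growth * p[1L]))
  }
  times <- seq(0, t_max, length.out = max(2L, n_steps))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = m,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  data.frame(time = sol[, 1L],
             log_total = sol[, 2L],
             fraction_low = sol[, 3L],
             fraction_high = 1 - sol[, 3L])
}
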