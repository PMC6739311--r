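#' Joint in/out-degree distributions for the percolation theory
#'
#' The generating-function predictions take a joint distribution
#' `P(q_in, q_out)`. Two representations are supported: independent
#' Poisson marginals with common mean `c` (the directed ER case), held
#' symbolically and truncated only when sums are evaluated, and an
#' explicit finite table. Correlated tables are accepted but flagged
#' experimental: the branching equations assume an uncorrelated network.
#'
#' @param mean_degree common mean of the Poisson in- and out-degree.
#' @param q_max truncation cutoff for evaluated sums; defaults to
#'   `max(50, ceiling(mean_degree + 12 * sqrt(mean_degree)))`, whose
#'   Poisson tail mass is far below 1e-10 for the regimes studied here.
#' @return an object of class `joint_degree_dist`.
#' @export
poisson_degree_dist <- function(mean_degree, q_max = NULL) {
  if (mean_degree < 0) stop("`mean_degree` must be >= 0", call. = FALSE)
  if (is.null(q_max))
    q_max <- max(50L, as.integer(ceiling(mean_degree + 12 * sqrt(mean_degree))))
  structure(list(type = "poisson", mean = mean_degree, q_max = q_max),
            class = "joint_degree_dist")
}

#' @rdname poisson_degree_dist
#' @param P numeric matrix; `P[i, j]` is the probability of
#'   `q_in = i - 1`, `q_out = j - 1`. Must sum to 1 (tolerance 1e-8) and
#'   have equal in- and out-degree means (directed-network consistency).
#' @export
table_degree_dist <- function(P) {
  P <- as.matrix(P)
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8)
    stop("`P` must be a probability table summing to 1", call. = FALSE)
  qin <- seq_len(nrow(P)) - 1
  qout <- seq_len(ncol(P)) - 1
  m_in <- sum(qin * rowSums(P))
  m_out <- sum(qout * colSums(P))
  if (abs(m_in - m_out) > 1e-6 * max(1, m_in))
    stop(sprintf("mean in-degree (%.6g) != mean out-degree (%.6g)",
                 m_in, m_out), call. = FALSE)
  independent <- max(abs(P - outer(rowSums(P), colSums(P)))) < 1e-10
  if (!independent)
    warning("correlated joint degree table: branching theory is experimental here",
            call. = FALSE)
  structure(list(type = "table", P = P, mean = m_in,
                 q_max = max(nrow(P), ncol(P)) - 1L),
            class = "joint_degree_dist")
}

# truncated probability table (rows q_in = 0..q_max, cols q_out) with a
# tail-mass precision warning
dist_table <- function(dist) {
  if (dist$type == "table") return(dist$P)
  q <- 0:dist$q_max
  marg <- stats::dpois(q, dist$mean)
  if (sum(marg) < 1 - 1e-10)
    warning(sprintf(
      "q_max = %d truncates tail mass %.3g > 1e-10; increase q_max",
      dist$q_max, 1 - sum(marg)), call. = FALSE)
  outer(marg, marg)
}

#' Finite-component branching probabilities
#'
#' Solves the self-consistency equations for `x_c`, the probability that
#' an in-link comes from a finite in-component, and `y_c`, the
#' probability that an out-link leads to a finite out-component. For an
#' uncorrelated network the link-follow equations are
#' `x = sum_q (q_out / <q>) P(q_in, q_out) x^q_in` and
#' `y = sum_q (q_in / <q>) P(q_in, q_out) y^q_out`; for independent
#' Poisson(c) marginals both reduce to the single equation
#' `u = exp(-c (1 - u))`, whose smallest root in `[0, 1]` is returned
#' (u = 1 for `c <= 1`: no giant component). The solver iterates from 0
#' (plain iteration is monotone towards the smallest fixed point) and
#' falls back to bisection; the residual must be below 1e-12.
#'
#' @param dist a [poisson_degree_dist()] or [table_degree_dist()].
#' @param tol residual tolerance (default 1e-13).
#' @param max_iter iteration budget.
#' @return object of class `branching_probabilities`: list with `x_c`,
#'   `y_c` and `residual`.
#' @examples
#' solve_branching_probabilities(poisson_degree_dist(1.5))
#' @export
solve_branching_probabilities <- function(dist, tol = 1e-13,
                                          max_iter = 100000L) {
  stopifnot(inherits(dist, "joint_degree_dist"))
  if (dist$type == "poisson") {
    # solved in s = 1 - u space, s = -expm1(-c s), which keeps full
    # relative precision arbitrarily close to the critical point c = 1
    c0 <- dist$mean
    u <- 1 - solve_poisson_giant_fraction(c0, tol, max_iter)
    res <- abs(u - exp(-c0 * (1 - u)))
    out <- list(x_c = u, y_c = u, residual = res)
  } else {
    P <- dist$P
    qin <- seq_len(nrow(P)) - 1
    qout <- seq_len(ncol(P)) - 1
    mq <- dist$mean
    if (mq == 0) {
      out <- list(x_c = 1, y_c = 1, residual = 0)
    } else {
      wx <- colSums(t(P) * qout) / mq  # P weighted by q_out, by q_in value
      wy <- colSums(P * qin) / mq      # P weighted by q_in, by q_out value
      x <- solve_scalar_fixed_point(function(x) sum(wx * x^qin), tol, max_iter)
      y <- solve_scalar_fixed_point(function(y) sum(wy * y^qout), tol, max_iter)
      out <- list(x_c = x, y_c = y,
                  residual = max(abs(x - sum(wx * x^qin)),
                                 abs(y - sum(wy * y^qout))))
    }
  }
  if (out$residual > 1e-12)
    stop(sprintf("branching solver did not converge: residual %.3g",
                 out$residual), call. = FALSE)
  structure(out, class = "branching_probabilities")
}

# giant-component fraction s solving s = -expm1(-c s): 0 for c <= 1,
# else the unique positive root. Iteration from s = 1 is monotone
# decreasing towards it; uniroot (bisection-based) polishes slow
# convergence near criticality
solve_poisson_giant_fraction <- function(c0, tol, max_iter) {
  if (c0 <= 1) return(0)
  g <- function(s) -expm1(-c0 * s) - s
  if (g(1e-12) <= 0) return(0)  # root below fp resolution of c - 1
  s <- 1
  for (i in seq_len(max_iter)) {
    s_new <- -expm1(-c0 * s)
    if (abs(s_new - s) < tol) return(s_new)
    s <- s_new
  }
  stats::uniroot(g, c(1e-12, 1), tol = .Machine$double.eps)$root
}

# smallest fixed point of an increasing map f on [0, 1]; iteration from 0
# is monotone increasing towards it, bisection polishes slow convergence
# near criticality
solve_scalar_fixed_point <- function(f, tol, max_iter) {
  u <- 0
  for (i in seq_len(max_iter)) {
    u_new <- f(u)
    if (abs(u_new - u) < tol) return(u_new)
    u <- u_new
  }
  g <- function(v) v - f(v)
  if (g(1 - 1e-12) <= 0) return(1)  # subcritical: only fixed point is 1
  stats::uniroot(g, c(u - tol, 1 - 1e-12), tol = .Machine$double.eps)$root
}

#' Theoretical fraction of SOURCE nodes
#'
#' A randomly chosen node is a SOURCE when it has `q_in = 0` and at
#' least one of its out-links leads into the giant component:
#' `N_SOURCE / N = sum_{q_out} P(q_in = 0, q_out) (1 - y_c^q_out)`.
#' For independent Poisson(c) this closes to `exp(-c) * (1 - y_c)`.
#'
#' @inheritParams solve_branching_probabilities
#' @param branching optional precomputed
#'   [solve_branching_probabilities()] result.
#' @return fraction in `[0, 1]` (0 below percolation).
#' @examples
#' source_fraction_theory(poisson_degree_dist(1.5))  # ~ 0.130
#' @export
source_fraction_theory <- function(dist, branching = NULL) {
  if (is.null(branching)) branching <- solve_branching_probabilities(dist)
  y <- branching$y_c
  if (dist$type == "poisson") return(exp(-dist$mean) * (1 - y))
  P <- dist_table(dist)
  qout <- seq_len(ncol(P)) - 1
  sum(P[1, ] * (1 - y^qout))
}

#' Theoretical number of IN-CORE links
#'
#' Expected count of links from IN nodes into the CORE:
#' `L_IN-CORE = N sum_{q_in, q_out} q_in x_c P(q_in, q_out)
#' (1 - y_c^q_out) (1 - x_c^(q_in - 1))`, evaluated as a truncated double
#' sum. The normalized form `L_IN-CORE / L` divides by `N <q_in>`.
#'
#' @inheritParams source_fraction_theory
#' @param n_nodes network size `N` multiplying the per-node expectation.
#' @return expected link count (0 below percolation).
#' @export
in_core_links_theory <- function(dist, n_nodes = 1, branching = NULL) {
  if (is.null(branching)) branching <- solve_branching_probabilities(dist)
  x <- branching$x_c
  y <- branching$y_c
  if (x == 1 || y == 1) return(0)
  P <- dist_table(dist)
  qin <- seq_len(nrow(P)) - 1
  qout <- seq_len(ncol(P)) - 1
  inner <- qin * x * (1 - x^pmax(qin - 1, 0))  # q_in = 0 term vanishes
  outer_f <- 1 - y^qout
  n_nodes * as.numeric(inner %*% P %*% outer_f)
}

#' Theoretical CORE fraction
#'
#' A node belongs to the CORE when it is reached from the giant
#' in-component and reaches the giant out-component:
#' `N_CORE / N = (1 - sum_q P x_c^q_in)(1 - sum_q P y_c^q_out)`,
#' which for independent Poisson(c) equals `(1 - y_c)^2`
#' (0 for `c <= 1`).
#'
#' @inheritParams source_fraction_theory
#' @return fraction in `[0, 1]`.
#' @examples
#' core_fraction_theory(poisson_degree_dist(1.5))  # ~ 0.340
#' @export
core_fraction_theory <- function(dist, branching = NULL) {
  if (is.null(branching)) branching <- solve_branching_probabilities(dist)
  x <- branching$x_c
  y <- branching$y_c
  if (dist$type == "poisson") return((1 - x) * (1 - y))
  P <- dist_table(dist)
  qin <- seq_len(nrow(P)) - 1
  qout <- seq_len(ncol(P)) - 1
  xhat <- as.numeric((x^qin) %*% P %*% rep(1, ncol(P)))
  yhat <- as.numeric(rep(1, nrow(P)) %*% P %*% (y^qout))
  (1 - xhat) * (1 - yhat)
}

#' Emergence point of the giant CORE (Poisson family)
#'
#' Locates, by bisection on the mean degree, the infimum of `c` for
#' which the theoretical CORE fraction `(1 - u)^2` with
#' `u = exp(-c (1 - u))` is positive. Analytically this is the directed
#' percolation point `c = 1`; the function recovers it numerically from
#' the theory itself.
#'
#' @param lower,upper bracketing mean degrees (CORE absent at `lower`,
#'   present at `upper`).
#' @param tol bisection tolerance on `c`.
#' @return the threshold mean in-degree.
#' @export
core_emergence_point <- function(lower = 0.5, upper = 2, tol = 1e-9) {
  positive <- function(c0)
    core_fraction_theory(poisson_degree_dist(c0)) > 0
  if (positive(lower) || !positive(upper))
    stop("bracket does not straddle the emergence point", call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (positive(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Theory curves over a mean-degree grid
#'
#' @param c_grid mean in-degree values.
#' @return `data.frame` with columns `c`, `x_c`, `source_frac`,
#'   `core_frac`, `in_core_over_l` (`L_IN-CORE / L`).
#' @export
theory_curve <- function(c_grid) {
  rows <- lapply(c_grid, function(c0) {
    d <- poisson_degree_dist(c0)
    b <- solve_branching_probabilities(d)
    data.frame(
      c = c0, x_c = b$x_c,
      source_frac = source_fraction_theory(d, b),
      core_frac = core_fraction_theory(d, b),
      in_core_over_l = if (c0 > 0)
        in_core_links_theory(d, 1, b) / c0 else 0)
  })
  do.call(rbind, rows)
}
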