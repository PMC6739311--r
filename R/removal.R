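#' Remove a random fraction of IN nodes
#'
#' Samples `floor(f * N_IN)` nodes (at least one when `f > 0` and the IN
#' component is nonempty) uniformly without replacement from the
#' partition's original IN set and deletes all their links. Node ids are
#' kept stable: removed nodes remain as isolated vertices, which leaves
#' every measured subset (notably the CORE, whose SCC cannot be broken
#' by removing IN nodes) addressable with its original ids.
#'
#' @param net a [directed_network()].
#' @param partition the matching [bowtie_decompose()] result.
#' @param f fraction of IN nodes to remove, in `[0, 1]`.
#' @param seed integer seed for the uniform draw.
#' @return a `directed_network` with attribute `removed_nodes`.
#' @export
remove_in_fraction <- function(net, partition, f, seed) {
  stopifnot(inherits(net, "directed_network"),
            inherits(partition, "bowtie_partition"))
  if (partition$n_nodes != net$n_nodes)
    stop("partition is not consistent with this network", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop("`f` must be a fraction in [0, 1]", call. = FALSE)
  in_set <- partition$in_set
  n_rm <- floor(f * length(in_set))
  if (f > 0 && n_rm == 0 && length(in_set) >= 1) n_rm <- 1L
  if (n_rm == 0) {
    out <- net
    attr(out, "removed_nodes") <- integer(0)
    return(out)
  }
  removed <- with_seed(seed, sort(sample(in_set, n_rm)))
  keep <- !(net$tail %in% removed | net$head %in% removed)
  out <- directed_network(net$n_nodes, net$tail[keep], net$head[keep],
                          check = FALSE)
  attr(out, "removed_nodes") <- removed
  out
}

#' Sweep the removed IN fraction and measure CORE ordering
#'
#' For every fraction `f` on the grid and every seed: remove that
#' fraction of IN nodes uniformly at random, run the chosen dynamics on
#' the remnant, and record the steady-state CORE ordering (time-averaged
#' `r_CORE` for Kuramoto, time-averaged `|m_CORE|` for Ising) together
#' with the pair-correlation function (`C_CORE` or `chi_CORE`).
#' Measurements always use the ORIGINAL pre-removal CORE node set, so
#' the observable does not silently change meaning along the sweep.
#'
#' @param net a [directed_network()].
#' @param partition the matching [bowtie_decompose()] result.
#' @param dynamics `"kuramoto"` or `"ising"`.
#' @param f_grid increasing removal fractions (default
#'   `seq(0, 1, 0.05)`).
#' @param params named list of dynamics parameters. Kuramoto: `K`
#'   (required), optional `dt`, `t_transient`, `t_observe`,
#'   `sample_every`. Ising: `temperature` (required), optional
#'   `sweeps_transient`, `sweeps_observe`.
#' @param seeds integer vector; each seed drives one removal draw plus
#'   one dynamics run per grid point.
#' @return object of class `removal_sweep_result`: list with the
#'   `data.frame` `curve` (columns `f`, `order_mean`, `order_se`,
#'   `pc_mean`, `pc_se`), `dynamics`, `n_seeds`, `core_size`, and
#'   `f_critical` from [detect_critical_fraction()].
#' @export
removal_sweep <- function(net, partition, dynamics = c("kuramoto", "ising"),
                          f_grid = seq(0, 1, by = 0.05), params = list(),
                          seeds = 0:9) {
  dynamics <- match.arg(dynamics)
  stopifnot(inherits(net, "directed_network"),
            inherits(partition, "bowtie_partition"))
  f_grid <- as.numeric(f_grid)
  if (is.unsorted(f_grid, strictly = TRUE))
    stop("`f_grid` must be strictly increasing", call. = FALSE)
  core <- partition$core
  if (length(core) < 2)
    stop("CORE too small to measure ordering", call. = FALSE)

  rows <- lapply(f_grid, function(f) {
    ord <- pc <- numeric(length(seeds))
    for (k in seq_along(seeds)) {
      s <- as.integer(seeds[k])
      net_f <- remove_in_fraction(net, partition, f, seed = derive_seed(s, 11))
      if (dynamics == "kuramoto") {
        if (is.null(params$K)) stop("params$K is required", call. = FALSE)
        sim <- simulate_kuramoto(
          oscillator_system(net_f, K = params$K),
          dt = params$dt,
          t_transient = params$t_transient %||% 200,
          t_observe = params$t_observe %||% 200,
          sample_every = params$sample_every %||% 0.5,
          subsets = list(core = core), seed = derive_seed(s, 23))
        ord[k] <- mean(sim$r[, "core"])
        pc[k] <- pair_correlation_C(sim, "core")
      } else {
        if (is.null(params$temperature))
          stop("params$temperature is required", call. = FALSE)
        sim <- simulate_ising(
          spin_system(net_f, params$temperature),
          sweeps_transient = params$sweeps_transient %||% 1000,
          sweeps_observe = params$sweeps_observe %||% 1000,
          subsets = list(core = core), seed = derive_seed(s, 23))
        ord[k] <- mean(abs(sim$m[, "core"]))
        pc[k] <- pair_correlation_chi(sim, "core")
      }
    }
    data.frame(f = f, order_mean = mean(ord), order_se = se_mean(ord),
               pc_mean = mean(pc), pc_se = se_mean(pc))
  })
  curve <- do.call(rbind, rows)
  res <- structure(list(curve = curve, dynamics = dynamics,
                        n_seeds = length(seeds), core_size = length(core),
                        f_critical = NA_real_),
                   class = "removal_sweep_result")
  if (nrow(curve) >= 5) res$f_critical <- detect_critical_fraction(res)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.removal_sweep_result <- function(x, ...) {
  cat(sprintf("<removal_sweep_result> %s dynamics, CORE of %d nodes, %d seeds\n",
              x$dynamics, x$core_size, x$n_seeds))
  print(x$curve, row.names = FALSE, digits = 4)
  if (is.na(x$f_critical)) cat("  critical fraction: none detected\n")
  else cat(sprintf("  critical fraction f_IN^C = %.3g\n", x$f_critical))
  invisible(x)
}

#' Locate the critical removed fraction from the pair-correlation peak
#'
#' Returns the grid location of an interior maximum of the
#' pair-correlation curve that exceeds BOTH endpoint values by at least
#' 2 pooled standard errors (so small sampling bumps do not trigger),
#' or `NA` when no such peak exists (the already-ordered case, where
#' the curve decays monotonically).
#'
#' @param sweep a [removal_sweep()] result, or a `data.frame` with
#'   columns `f`, `pc_mean`, `pc_se`.
#' @param prominence_se required prominence in pooled standard errors
#'   (default 2).
#' @return the critical fraction, or `NA_real_` ("none").
#' @examples
#' tent <- data.frame(f = c(0, .25, .5, .75, 1),
#'                    pc_mean = c(1, 2, 5, 2, 1), pc_se = 1e-6)
#' detect_critical_fraction(tent)  # 0.5
#' @export
detect_critical_fraction <- function(sweep, prominence_se = 2) {
  curve <- if (inherits(sweep, "removal_sweep_result")) sweep$curve else sweep
  stopifnot(all(c("f", "pc_mean", "pc_se") %in% names(curve)))
  k <- nrow(curve)
  if (k < 5) stop("need at least 5 grid points", call. = FALSE)
  interior <- 2:(k - 1)
  i <- interior[which.max(curve$pc_mean[interior])]
  se <- curve$pc_se
  se[is.na(se)] <- 0
  ok <- function(j) curve$pc_mean[i] - curve$pc_mean[j] >=
    prominence_se * sqrt(se[i]^2 + se[j]^2)
  if (ok(1) && ok(k)) curve$f[i] else NA_real_
}
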