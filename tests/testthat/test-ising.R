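test_that("heat-bath single-site law matches the Gibbs probabilities", {
  # follower with one in-link from a frozen +1 spin at T = 2:
  # stationary P(up) = 1 / (1 + exp(-1)) ~ 0.7311; successive heat-bath
  # draws are independent of the current state, so recorded spins are iid
  net <- directed_network(2, tail = 0L, head = 1L)
  sys <- spin_system(net, temperature = 2, spins = c(1L, 1L))
  n_sweeps <- 5000
  sim <- simulate_ising(sys, sweeps_transient = 10, sweeps_observe = n_sweeps,
                        subsets = list(b = 1L), seed = 1, update_sites = 1L)
  p_hat <- mean(sim$m[, "b"] == 1)
  p_true <- 1 / (1 + exp(-1))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n_sweeps))

  # T -> 0 with h = +3: up with probability 1
  net3 <- directed_network(4, tail = c(0L, 1L, 2L), head = c(3L, 3L, 3L))
  sys3 <- spin_system(net3, temperature = 0, spins = c(1L, 1L, 1L, -1L))
  sim3 <- simulate_ising(sys3, sweeps_transient = 5, sweeps_observe = 50,
                         subsets = list(d = 3L), seed = 2,
                         update_sites = 3L)
  expect_true(all(sim3$m[, "d"] == 1))
})

test_that("source spins flip a fair coin at any temperature", {
  # in-degree 0 => h = 0 => up with probability 1/2 regardless of T
  net <- directed_network(2, tail = 0L, head = 1L)
  for (Tv in c(0, 1.7)) {
    sim <- simulate_ising(spin_system(net, Tv, spins = c(1L, -1L)),
                          sweeps_transient = 0, sweeps_observe = 4000,
                          subsets = list(src = 0L), seed = 3,
                          update_sites = 0L)
    expect_lt(abs(mean(sim$m[, "src"])), 3 / sqrt(4000))
  }
})

test_that("the aligned CORE at T = 0 is absorbing", {
  net <- generate_directed_er(500, 2.0, seed = 4)
  core_net <- induced_subnetwork(net, bowtie_decompose(net)$core)
  sys <- spin_system(core_net, temperature = 0,
                     spins = rep(1L, core_net$n_nodes))
  sim <- simulate_ising(sys, sweeps_transient = 10, sweeps_observe = 50,
                        seed = 5)
  expect_true(all(sim$m[, "all"] == 1))
})

test_that("an imported 2-cycle fully orders as T -> 0", {
  f <- tempfile()
  writeLines(c("0 1", "1 0"), f)
  net <- read_edge_list(f)
  expect_equal(attr(net, "reciprocal_pairs"), 1L)
  sim <- simulate_ising(spin_system(net, temperature = 0.05),
                        sweeps_transient = 100, sweeps_observe = 200,
                        seed = 6)
  expect_equal(mean(abs(sim$m[, "all"])), 1, tolerance = 1e-6)
})

test_that("trajectories negate exactly under global spin reversal", {
  net <- generate_directed_er(120, 1.8, seed = 7)
  s0 <- with(list(), {set.seed(8); ifelse(runif(120) < 0.5, 1L, -1L)})
  a <- simulate_ising(spin_system(net, 0.9, spins = s0),
                      sweeps_transient = 20, sweeps_observe = 50, seed = 9,
                      symmetric_draw = TRUE)
  b <- simulate_ising(spin_system(net, 0.9, spins = -s0),
                      sweeps_transient = 20, sweeps_observe = 50, seed = 9,
                      symmetric_draw = TRUE)
  expect_identical(a$m, -b$m)
  expect_identical(a$spins_final, -b$spins_final)
})

test_that("direct and symmetric draws sample the same equilibrium", {
  net <- directed_network(2, tail = 0L, head = 1L)
  sys <- spin_system(net, temperature = 2, spins = c(1L, 1L))
  sim <- simulate_ising(sys, sweeps_transient = 10, sweeps_observe = 4000,
                        subsets = list(b = 1L), seed = 10,
                        update_sites = 1L, symmetric_draw = FALSE)
  p_hat <- mean(sim$m[, "b"] == 1)
  p_true <- 1 / (1 + exp(-1))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
})

test_that("sweeps are reproducible and resumable", {
  net <- generate_directed_er(80, 1.5, seed = 11)
  a <- simulate_ising(spin_system(net, 1), 5, 20, seed = 12)
  b <- simulate_ising(spin_system(net, 1), 5, 20, seed = 12)
  expect_identical(a$m, b$m)

  sys <- spin_system(net, 1, spins = a$spins_final)
  set.seed(1)
  stepped <- heat_bath_sweep(sys, sweeps = 3)
  expect_true(all(stepped$spins %in% c(-1L, 1L)))
  expect_error(heat_bath_sweep(spin_system(net, 1)), "spins")
})

test_that("pair correlation chi is the scaled time variance of m", {
  fake <- structure(list(
    m = cbind(x = rep(c(-0.1, 0.1), 8)), subset_sizes = c(x = 50L)),
    class = "magnetization_series")
  expect_equal(pair_correlation_chi(fake, "x"), 50 * 0.01)
  fake$m <- cbind(x = rep(0.3, 5))
  expect_equal(pair_correlation_chi(fake, "x"), 0)
  fake$m <- cbind(x = 0.3)
  expect_error(pair_correlation_chi(fake, "x"), "2 samples")
})

test_that("T_C grows with CORE density and shrinks when IN is restored", {
  n <- 1e4
  t_grid <- seq(0.25, 4, by = 0.25)
  tc_of <- function(net, subset) estimate_critical_temperature(
    net, subset, t_grid, sweeps_transient = 300, sweeps_observe = 300,
    seeds = 0:2)

  net_hi <- generate_directed_er(n, 2.0, seed = 13)
  part_hi <- bowtie_decompose(net_hi)
  bare_hi <- remove_in_fraction(net_hi, part_hi, 1, seed = 14)
  tc_hi <- tc_of(bare_hi, part_hi$core)

  net_lo <- generate_directed_er(n, 1.2, seed = 15)
  part_lo <- bowtie_decompose(net_lo)
  bare_lo <- remove_in_fraction(net_lo, part_lo, 1, seed = 16)
  tc_lo <- tc_of(bare_lo, part_lo$core)

  # denser CORE supports ordering over a wider temperature range
  expect_gt(tc_hi$T_c, tc_lo$T_c)

  # restoring the IN component lowers the CORE's critical temperature
  tc_full <- tc_of(net_hi, part_hi$core)
  expect_lt(tc_full$T_c, tc_hi$T_c)

  # a grid entirely in the frozen phase: chi still rising at the upper
  # boundary, so the transition lies outside the grid
  expect_error(
    estimate_critical_temperature(bare_hi, part_hi$core, c(0.05, 0.1, 0.15),
                                  sweeps_transient = 100,
                                  sweeps_observe = 100, seeds = 0),
    "outside grid")
})
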