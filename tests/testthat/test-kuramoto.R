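test_that("order parameter matches hand values and is shift-invariant", {
  expect_equal(order_parameter(c(0.3, 0.3, 0.3)), 1)
  expect_equal(order_parameter(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2)), 1 / sqrt(2))
  th <- runif(20, -pi, pi)
  expect_equal(order_parameter(th), order_parameter(th + 1.234))
  expect_equal(order_parameter(th, subset = c(0, 3, 5)),
               order_parameter(th[c(1, 4, 6)]))
  expect_error(order_parameter(th, subset = integer(0)), "nonempty")
})

test_that("a free oscillator advances exactly at its natural frequency", {
  # constant derivative: RK4 is exact up to roundoff
  net <- directed_network(1, integer(), integer())
  sys <- oscillator_system(net, K = 5, omega = 2, theta0 = 0.25)
  sim <- simulate_kuramoto(sys, dt = 0.01, t_transient = 0, t_observe = 10,
                           sample_every = 1)
  expect_equal(sim$theta_final, 0.25 + 2 * 10, tolerance = 1e-10)
  expect_equal(sim$Omega, 2, tolerance = 1e-8)
  expect_true(all(abs(sim$r[, "all"] - 1) < 1e-12))
})

test_that("a driven follower locks at the closed-form phase lag", {
  # theta_b' = omega_b + K sin(theta_a - theta_b) with omega_a = 0:
  # stationary lag theta_a - theta_b = -asin(omega_b / K)
  net <- directed_network(2, tail = 0L, head = 1L)
  sys <- oscillator_system(net, K = 10, omega = c(0, 0.5), theta0 = c(0, 0))
  sim <- simulate_kuramoto(sys, dt = 0.005, t_transient = 50, t_observe = 10,
                           sample_every = 1)
  lag <- sim$theta_final[2] - sim$theta_final[1]
  lag <- atan2(sin(lag), cos(lag))
  expect_equal(lag, asin(0.05), tolerance = 1e-6)
  expect_equal(asin(0.05), 0.0500, tolerance = 1e-3)
})

test_that("the synchronized manifold is invariant", {
  net <- generate_directed_er(50, 1.5, seed = 2)
  sys <- oscillator_system(net, K = 3, omega = rep(0.7, 50),
                           theta0 = rep(1.1, 50))
  sim <- simulate_kuramoto(sys, t_transient = 5, t_observe = 5,
                           sample_every = 0.5)
  expect_true(all(abs(sim$r[, "all"] - 1) < 1e-12))
})

test_that("r samples are invariant under a change of rotating frame", {
  # shifting every natural frequency by a constant Omega rigidly rotates
  # the phases and must leave every r_X sample unchanged
  net <- generate_directed_er(100, 1.7, seed = 3)
  om <- with(list(), {set.seed(11); rnorm(100)})
  th0 <- with(list(), {set.seed(12); runif(100, -pi, pi)})
  base <- simulate_kuramoto(oscillator_system(net, 10, om, th0),
                            dt = 0.002, t_transient = 10, t_observe = 10)
  shifted <- simulate_kuramoto(oscillator_system(net, 10, om + 2.5, th0),
                               dt = 0.002, t_transient = 10, t_observe = 10)
  expect_equal(base$r, shifted$r, tolerance = 1e-4)
  expect_equal(shifted$Omega - base$Omega, 2.5, tolerance = 1e-3)
})

test_that("simulation is reproducible and guarded", {
  net <- generate_directed_er(100, 1.5, seed = 5)
  sys <- oscillator_system(net, K = 10)
  a <- simulate_kuramoto(sys, t_transient = 5, t_observe = 5, seed = 9)
  b <- simulate_kuramoto(sys, t_transient = 5, t_observe = 5, seed = 9)
  expect_identical(a$r, b$r)
  expect_error(simulate_kuramoto(sys, dt = 0.05, t_transient = 1,
                                 t_observe = 1, seed = 9),
               "stability guard")
  expect_error(simulate_kuramoto(sys, t_transient = 5, t_observe = 5),
               "seed")
})

test_that("pair correlation C is the scaled time variance of r", {
  fake <- structure(list(
    r = cbind(x = rep(c(0.2, 0.4), 10)), subset_sizes = c(x = 100L)),
    class = "order_parameter_series")
  expect_equal(pair_correlation_C(fake, "x"), 100 * 0.01)
  fake$r <- cbind(x = rep(0.37, 10))
  expect_equal(pair_correlation_C(fake, "x"), 0)
  fake$r <- cbind(x = 0.4)
  expect_error(pair_correlation_C(fake, "x"), "2 samples")
})

test_that("an isolated CORE locks near the mean natural frequency", {
  # CORE-only network at c = 2: at large K the locked group rotates at
  # a frequency within 3 standard errors of <omega> = 0
  net <- generate_directed_er(2000, 2.0, seed = 21)
  core <- bowtie_decompose(net)$core
  core_net <- induced_subnetwork(net, core)
  sim <- suppressWarnings(simulate_kuramoto(
    oscillator_system(core_net, K = 10), dt = 0.003,
    t_transient = 50, t_observe = 50, seed = 22))
  expect_gt(mean(sim$r[, "all"]), 0.8)  # fully/near-fully locked
  expect_lt(abs(sim$Omega), 3 / sqrt(core_net$n_nodes))
})

test_that("synchronization saturates with K on a fixed topology", {
  net <- generate_directed_er(500, 1.9, seed = 31)
  rk <- vapply(c(0.5, 5, 15), function(K)
    mean(suppressWarnings(simulate_kuramoto(
      oscillator_system(net, K = K), dt = 0.002, t_transient = 60,
      t_observe = 60, seed = 32))$r[, "all"]), numeric(1))
  expect_gt(rk[2], rk[1])          # coupling orders the network...
  expect_gt(rk[3], rk[1])
  expect_lt(abs(rk[3] - rk[2]), 0.15)  # ...but topology caps the gain
  expect_true(all(rk <= 1))
})
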