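test_that("remove_in_fraction follows the floor rule on the original IN set", {
  net <- cycle_with_feeder()
  part <- bowtie_decompose(net)

  same <- remove_in_fraction(net, part, 0, seed = 1)
  expect_equal(n_links(same), n_links(net))
  expect_length(attr(same, "removed_nodes"), 0)

  # 3-cycle + 2 feeders, f = 0.5 -> floor(0.5 * 2) = 1 removed
  net2 <- directed_network(5, c(0, 1, 2, 3, 4), c(1, 2, 0, 0, 1))
  part2 <- bowtie_decompose(net2)
  expect_equal(sort(part2$in_set), c(3L, 4L))
  for (seed in 1:5) {
    rem <- remove_in_fraction(net2, part2, 0.5, seed = seed)
    expect_length(attr(rem, "removed_nodes"), 1)
    expect_true(attr(rem, "removed_nodes") %in% c(3L, 4L))
    expect_equal(n_links(rem), 4)
  }

  # at least one node removed whenever f > 0 and IN is nonempty
  rem <- remove_in_fraction(net2, part2, 0.1, seed = 1)
  expect_length(attr(rem, "removed_nodes"), 1)

  # complete removal leaves the CORE intact under re-decomposition
  rem1 <- remove_in_fraction(net2, part2, 1, seed = 2)
  expect_equal(bowtie_decompose(rem1)$core, part2$core)

  expect_error(remove_in_fraction(net2, part2, 1.2, seed = 1), "fraction")
  expect_error(remove_in_fraction(net2, bowtie_decompose(net), 0.5, seed = 1),
               "consistent")
})

test_that("the pre-removal CORE survives any partial removal", {
  for (seed in 1:10) {
    net <- generate_directed_er(300, 1.5, seed = 400 + seed)
    part <- bowtie_decompose(net)
    if (length(part$in_set) == 0) next
    for (f in c(0.3, 0.7, 1)) {
      rem <- remove_in_fraction(net, part, f, seed = seed)
      expect_true(all(part$core %in% bowtie_decompose(rem)$core))
    }
  }
})

test_that("critical-fraction detection needs an interior prominent peak", {
  tent <- data.frame(f = c(0, 0.25, 0.5, 0.75, 1),
                     pc_mean = c(1, 2, 5, 2, 1), pc_se = 1e-6)
  expect_equal(detect_critical_fraction(tent), 0.5)

  decay <- data.frame(f = seq(0, 1, 0.25), pc_mean = c(5, 4, 3, 2, 1),
                      pc_se = 1e-6)
  expect_true(is.na(detect_critical_fraction(decay)))

  # a bump within the noise must not trigger
  noisy <- data.frame(f = seq(0, 1, 0.25), pc_mean = c(1, 1.1, 1.2, 1.1, 1),
                      pc_se = 0.5)
  expect_true(is.na(detect_critical_fraction(noisy)))

  expect_error(detect_critical_fraction(tent[1:4, ]), "5 grid points")
})

test_that("Ising removal sweep: ordering grows with f_IN, peak marks onset", {
  net <- generate_directed_er(2000, 1.4, seed = 21)
  part <- bowtie_decompose(net)
  sweep <- removal_sweep(net, part, "ising", f_grid = seq(0, 1, 0.1),
                         params = list(temperature = 0,
                                       sweeps_transient = 1000,
                                       sweeps_observe = 1000),
                         seeds = 0:9)
  cur <- sweep$curve

  # two-point consequence: complete removal maximizes CORE ordering
  expect_gt(cur$order_mean[nrow(cur)], cur$order_mean[1])
  expect_gt(cur$order_mean[nrow(cur)], 0.9)

  # stochastic monotonicity within 2 pooled standard errors
  for (i in seq_len(nrow(cur) - 1)) {
    slack <- 2 * sqrt(cur$order_se[i]^2 + cur$order_se[i + 1]^2)
    expect_gt(cur$order_mean[i + 1], cur$order_mean[i] - slack)
  }

  # an interior chi peak exists below the full removal (ordering sets in
  # before the IN component is gone) ...
  expect_false(is.na(sweep$f_critical))
  expect_gt(sweep$f_critical, 0)
  expect_lt(sweep$f_critical, 1)

  # ... and coincides with the steepest rise of the ordering curve
  d <- diff(cur$order_mean)
  steepest <- (cur$f[which.max(d)] + cur$f[which.max(d) + 1]) / 2
  expect_lt(abs(sweep$f_critical - steepest), 0.1 + 1e-9)
})

test_that("Kuramoto removal sweep at c > 1.5: linear enhancement, no peak", {
  net <- generate_directed_er(1000, 1.7, seed = 31)
  part <- bowtie_decompose(net)
  sweep <- suppressWarnings(
    removal_sweep(net, part, "kuramoto", f_grid = seq(0, 1, 0.2),
                  params = list(K = 10, dt = 0.003,
                                t_transient = 60, t_observe = 60),
                  seeds = 0:2))
  cur <- sweep$curve
  # already partially synchronized: removal enhances r_CORE ...
  expect_gt(cur$order_mean[nrow(cur)], cur$order_mean[1])
  for (i in seq_len(nrow(cur) - 1)) {
    slack <- 2 * sqrt(cur$order_se[i]^2 + cur$order_se[i + 1]^2)
    expect_gt(cur$order_mean[i + 1], cur$order_mean[i] - slack)
  }
  # ... and the pair correlation decays without an interior peak
  expect_true(is.na(sweep$f_critical))
  expect_lt(cur$pc_mean[nrow(cur)], cur$pc_mean[1])
})
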