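test_that("clustered builder produces block-structured coupling", {
  net <- clustered_network(4, 15, J_k = 0.025, inter_edges_per_pair = 0)
  J <- net$coupling$J
  expect_equal(dim(J), c(60, 60))
  expect_equal(net$coupling$gamma, 0.025)
  expect_equal(net$coupling$gamma_prime, 0.025)
  blk <- matrix(1, 15, 15) - diag(15)
  for (c in 1:4) {
    rows <- 1:15 + (c - 1) * 15
    expect_identical(J[rows, rows], blk)
  }
  expect_true(all(J[1:15, 16:60] == 0))   # no inter-cluster edges requested

  single <- clustered_network(1, 60, J_k = 0.05)
  expect_identical(single$coupling$J, matrix(1, 60, 60) - diag(60))

  trivial <- clustered_network(1, 1)
  expect_identical(trivial$coupling$J, matrix(0, 1, 1))
})

test_that("sparse inter-cluster links are seeded and symmetric", {
  net <- clustered_network(2, 5, inter_edges_per_pair = 2, seed = 9)
  net2 <- clustered_network(2, 5, inter_edges_per_pair = 2, seed = 9)
  expect_identical(net$coupling$J, net2$coupling$J)
  J <- net$coupling$J
  expect_identical(J, t(J))
  expect_gt(sum(J[1:5, 6:10] != 0), 0)
})

test_that("pump assignment orders cluster firing rates descending", {
  P <- assign_pump_spread(60, 4)
  expect_length(P, 60)
  cl <- rep(1:4, each = 15)
  mean_omega <- tapply(omega_spiking(P), cl, mean)
  expect_true(all(diff(mean_omega) < 0))      # A fastest ... D slowest
  expect_identical(unique(assign_pump_spread(8, 4, P_tilde_spread = 0)),
                   seq(0.6, 1.8, length.out = 4))
  expect_error(assign_pump_spread(8, 4, P_tilde_centers = c(0.5, 1, 2, 2.9)),
               "spiking domain")
})

test_that("Ising encoding couples only the v-DOPOs with zero bias", {
  inst <- ferro_pair_instance()
  net <- ising_network(inst, J_k = 0.25)
  expect_equal(net$coupling$gamma, 0.25)
  expect_identical(net$coupling$gamma_prime, 0)
  expect_identical(net$params$I_ext, c(0, 0))
  expect_identical(net$coupling$J, inst$J)
  un <- ising_network(inst, J_k = 0)
  expect_identical(un$coupling$gamma, 0)
})

test_that("random instances are symmetric, seeded, and near target density", {
  a <- random_ising_instance(150, 0.5, seed = 3)
  b <- random_ising_instance(150, 0.5, seed = 3)
  expect_identical(a$J, b$J)
  expect_identical(a$J, t(a$J))
  expect_identical(diag(a$J), rep(0, 150))
  # binomial sampling error around density 0.5 over C(150,2) edges
  expect_lt(abs(a$density - 0.5), 3 * sqrt(0.25 / choose(150, 2)) + 0.01)
  expect_true(all(a$J[a$J != 0] %in% c(-1, 1)))
  u <- random_ising_instance(20, 0.5, weights = "uniform", seed = 1)
  expect_true(all(abs(u$J) <= 1))
})

test_that("instances round-trip through the edge-list file format", {
  inst <- random_ising_instance(12, 0.4, seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ising_instance(inst, path)
  back <- read_ising_instance(path)
  expect_identical(back$J, inst$J)
  expect_identical(back$n, inst$n)
  # comment lines are tolerated
  writeLines(c("# a comment", readLines(path)), path)
  expect_identical(read_ising_instance(path)$J, inst$J)
})

test_that("malformed instance files are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 2", "1 2 1.0"), path)
  expect_error(read_ising_instance(path), "promises")
  writeLines(c("3 1", "1 4 1.0"), path)
  expect_error(read_ising_instance(path), "out of range")
})

test_that("relabelling neurons within a cluster conjugates the dynamics", {
  net <- clustered_network(2, 4, J_k = 0.05, inter_edges_per_pair = 1,
                           seed = 2)
  n <- 8
  perm <- c(2, 3, 4, 1, 5:8)            # rotate cluster A labels
  x0 <- cbind(stats::rnorm(n, sd = 1e-3), stats::rnorm(n, sd = 1e-3))
  cfg <- sim_config(duration = 100, record_stride = 10L)
  base <- dopo_simulate(net$params, net$coupling, cfg, init = x0)

  Jp <- net$coupling$J[perm, perm]
  cp <- network_coupling(Jp, net$coupling$gamma, net$coupling$gamma_prime)
  pp <- neuron_params(n, P = net$params$P[perm],
                      J_vw = net$params$J_vw, J_wv = net$params$J_wv)
  permuted <- dopo_simulate(pp, cp, cfg, init = x0[perm, ])
  r_base <- order_parameter(to_polar(base)$theta)$global
  r_perm <- order_parameter(to_polar(permuted)$theta)$global
  expect_equal(r_perm, r_base, tolerance = 1e-10)
})
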