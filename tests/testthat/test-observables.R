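test_that("order parameter matches hand-computed configurations", {
  expect_equal(order_parameter(rep(1.3, 7)), 1)
  expect_equal(order_parameter(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-15)
  expect_equal(order_parameter(c(0, pi / 2)), sqrt(2) / 2)
  expect_error(order_parameter(numeric()), "empty")
})

test_that("order parameter is bounded and phase-shift invariant", {
  set.seed(42)
  for (k in 1:20) {
    th <- stats::runif(10, -10, 10)
    r <- order_parameter(th)
    expect_gte(r, 0)
    expect_lte(r, 1)
    expect_equal(order_parameter(th + 2.1), r, tolerance = 1e-12)
  }
})

test_that("per-cluster order parameters use only their members", {
  th <- matrix(c(0, 0, 0, pi, 0, pi), 3, 2)   # neurons x time
  op <- order_parameter(th, membership = c("a", "a", "b"))
  expect_equal(op$cluster["a", ], c(1, 0), tolerance = 1e-15)
  expect_equal(op$cluster["b", ], c(1, 1))
  expect_equal(dim(op$cluster), c(2L, 2L))
})

test_that("winding detector counts clean rotations exactly", {
  times <- seq(0, 20 * pi, length.out = 4001)
  pol <- structure(list(times = times,
                        theta = matrix(times, 1),
                        R = matrix(1, 1, length(times)),
                        omega0 = 1),
                   class = "dopo_polar")
  sp <- detect_spikes(pol)
  expect_equal(sp$counts, 10L)
  expect_equal(sp$rate, 1.0, tolerance = 1e-9)
  expect_equal(sp$spike_times[[1]], 2 * pi * (1:10), tolerance = 1e-6)

  pol$theta <- matrix(1.5, 1, length(times))
  still <- detect_spikes(pol)
  expect_equal(still$counts, 0L)
  expect_identical(still$rate, 0)
})

test_that("measured firing rate matches the closed-form frequency", {
  np <- neuron_params(1, P_tilde = 1)
  pol <- simulate_polar(np, J_k = 0,
                        config = sim_config(duration = 300, seed = 7), R0 = 1)
  rate <- detect_spikes(trim_polar(pol))$rate
  expect_equal(rate, 0.93541, tolerance = 0.02)
})

test_that("phase increments report the advance per window", {
  times <- seq(0, 100, by = 0.1)
  pol <- structure(list(times = times, theta = matrix(0.7 * times, 1),
                        R = matrix(1, 1, length(times)), omega0 = 0.7),
                   class = "dopo_polar")
  pi_out <- phase_increment(pol, window = 5)
  expect_equal(as.vector(pi_out$delta_theta), rep(0.7 * 5, 20),
               tolerance = 1e-9)
  pol$theta <- matrix(0, 1, length(times))
  expect_equal(as.vector(phase_increment(pol, 5)$delta_theta), rep(0, 20))
  expect_error(phase_increment(pol, 200), "longer than")
})

test_that("strong intra-cluster coupling induces phase stalling", {
  net <- clustered_network(1, 10, J_k = 0.075, P_tilde_centers = 2.2,
                           P_tilde_spread = 0.1)
  cfg <- sim_config(duration = 300, record_stride = 10L, seed = 3)
  coupled <- dopo_simulate(net$params, net$coupling, cfg)
  free <- dopo_simulate(net$params, network_coupling(net$coupling$J, 0, 0),
                        cfg)
  stall_frac <- function(tr) {
    d <- phase_increment(trim_polar(to_polar(tr)), window = 2)$delta_theta
    mean(abs(d) < 0.1 * 1 * 2)
  }
  expect_gt(stall_frac(coupled), stall_frac(free))
})

test_that("Ising and local energies obey their defining identities", {
  expect_identical(ising_energy(ferro_pair_instance()$J, c(1, 1)), -1)
  expect_identical(ising_energy(triangle_instance()$J, c(1, 1, -1)), -1)
  set.seed(8)
  for (k in 1:10) {
    inst <- random_ising_instance(10, 0.6, seed = k)
    s <- sample(c(-1, 1), 10, replace = TRUE)
    E <- ising_energy(inst$J, s)
    El <- local_energy(inst$J, s)
    expect_equal(E, sum(El) / 2, tolerance = 1e-12)
    expect_equal(ising_energy(inst$J, -s), E)   # global flip symmetry
    # single-flip energy change is -2 * E_loc of the flipped spin
    for (i in sample(10, 3)) {
      s2 <- s; s2[i] <- -s2[i]
      expect_equal(ising_energy(inst$J, s2) - E, -2 * El[i],
                   tolerance = 1e-12)
    }
  }
  expect_error(ising_energy(diag(0, 2), c(1, 0)), "must be -1 or \\+1")
})

test_that("spin readout takes the sign of v with +1 tie-break", {
  tr <- structure(list(times = c(0, 1),
                       v = matrix(c(0.3, -1.2, 0, 5), 2),
                       w = matrix(0, 2, 2),
                       params = neuron_params(2)),
                  class = "dopo_trajectory")
  expect_identical(spin_readout(tr, 0), c(1L, -1L))
  expect_identical(spin_readout(tr, 1), c(1L, 1L))
  expect_error(spin_readout(tr, 2), "outside")
})

test_that("renormalized pump formulas evaluate as printed", {
  expect_identical(renormalized_pump(0.7, 0, 15, 0.075), 0.7)
  expect_equal(renormalized_pump(0, 1, 15, 0.075), 1.05)
  expect_identical(renormalized_pump_ising(1.2, 0.25, 0), 1.2)
  expect_equal(renormalized_pump_ising(1, 0.2, c(-2, 4)), c(1.2, 0.6))
})

test_that("firing/energy correlation flags degenerate inputs", {
  flat <- firing_vs_local_energy(rep(3, 5), c(1, 2, 3, 4, 5))
  expect_true(flat$undefined)
  expect_true(is.na(flat$rank_correlation))
  ranked <- firing_vs_local_energy(1:6, (1:6) * 2 - 3)
  expect_equal(ranked$rank_correlation, 1)
  expect_equal(ranked$linear_correlation, 1)
})
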