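test_that("below threshold the neuron decays to the origin", {
  np <- neuron_params(1, P = -1, I_ext = 0)   # p = 0
  tr <- dopo_simulate(np, config = sim_config(duration = 50, seed = 3,
                                              init_noise = 1e-2))
  m <- ncol(tr$v)
  expect_lt(abs(tr$v[1, m]), 1e-6)
  expect_lt(abs(tr$w[1, m]), 1e-6)
})

test_that("trajectories are sign-inversion equivariant at zero bias", {
  np <- neuron_params(2, P_tilde = c(0.8, 1.4))
  J <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  cp <- network_coupling(J, gamma = 0.05, gamma_prime = 0.05)
  cfg <- sim_config(duration = 30, dt = 1e-3)
  x0 <- cbind(c(0.02, -0.013), c(0.007, 0.019))
  a <- dopo_simulate(np, cp, cfg, init = x0)
  b <- dopo_simulate(np, cp, cfg, init = -x0)
  expect_equal(b$v, -a$v, tolerance = 1e-8)
  expect_equal(b$w, -a$w, tolerance = 1e-8)
})

test_that("uncoupled network equals independent single-neuron runs", {
  np <- neuron_params(3, P_tilde = c(0.5, 1.0, 1.5))
  cfg <- sim_config(duration = 40)
  x0 <- cbind(c(0.01, -0.02, 0.005), c(-0.004, 0.013, 0.02))
  multi <- dopo_simulate(np, config = cfg, init = x0)
  for (i in 1:3) {
    si <- neuron_params(1, P_tilde = dimensionless(np)$P_tilde[i])
    single <- dopo_simulate(si, config = cfg,
                            init = matrix(x0[i, ], 1, 2))
    expect_equal(multi$v[i, ], single$v[1, ], tolerance = 1e-12)
    expect_equal(multi$w[i, ], single$w[1, ], tolerance = 1e-12)
  }
})

test_that("the fixed-step integrator converges at fourth order", {
  np <- neuron_params(1, P_tilde = 1)
  x0 <- matrix(c(0.1, 0), 1, 2)
  final_at <- function(dt) {
    tr <- dopo_simulate(np, config = sim_config(duration = 10, dt = dt),
                        init = x0)
    c(tr$v[1, ncol(tr$v)], tr$w[1, ncol(tr$w)])
  }
  f1 <- final_at(0.02); f2 <- final_at(0.01); f3 <- final_at(0.005)
  e1 <- sqrt(sum((f1 - f2)^2))
  e2 <- sqrt(sum((f2 - f3)^2))
  expect_gt(e1 / e2, 8)   # ~16 expected for a 4th-order scheme
})

test_that("fixed-step trajectories agree with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  np <- neuron_params(1, P_tilde = 1.5)
  x0 <- matrix(c(0.05, -0.02), 1, 2)
  tr <- dopo_simulate(np, config = sim_config(duration = 30, dt = 1e-3),
                      init = x0)
  ref <- deSolve::ode(
    c(v = 0.05, w = -0.02), c(0, 30),
    function(t, y, p) list(c(1.5 * y[1] - y[1]^3 - y[2],
                             1.5 * y[2] - y[2]^3 + y[1])),
    NULL, rtol = 1e-11, atol = 1e-12)
  m <- ncol(tr$v)
  expect_equal(tr$v[1, m], unname(ref[2, "v"]), tolerance = 1e-6)
  expect_equal(tr$w[1, m], unname(ref[2, "w"]), tolerance = 1e-6)
})

test_that("constant and degenerate-ramp schedules reduce to the static run", {
  np <- neuron_params(1, P_tilde = 1.2, I_ext_tilde = 0.1)
  cfg <- sim_config(duration = 20, seed = 5)
  base <- dopo_simulate(np, config = cfg)
  const <- dopo_simulate(np, config = cfg,
                         pump_schedule = schedule_constant(np$P),
                         bias_schedule = schedule_constant(np$I_ext))
  ramp <- dopo_simulate(np, config = cfg,
                        pump_schedule = schedule_linear(np$P, np$P))
  expect_identical(const$v, base$v)
  expect_identical(ramp$v, base$v)
  expect_equal(unique(as.vector(base$schedules$P)), np$P)
})

test_that("a pump ramp across the spiking region starts and stops firing", {
  np <- neuron_params(1)
  cfg <- sim_config(duration = 500, record_stride = 10L, seed = 2)
  tr <- dopo_simulate(np, config = cfg,
                      pump_schedule = schedule_linear(-0.5, 3.2))
  sp <- detect_spikes(to_polar(tr))
  st <- sp$spike_times[[1]]
  expect_gt(length(st), 5)
  # pump crosses 0 at t ~ 68 and leaves the spiking region at t ~ 450
  expect_gt(st[1], 50)
  expect_lt(st[length(st)], 470)
})

test_that("mismatched shapes and undefined schedules are rejected", {
  np <- neuron_params(2, P_tilde = 1)
  cp <- network_coupling(matrix(0, 3, 3))
  expect_error(dopo_simulate(np, cp, sim_config(duration = 1)),
               "3 neurons")
  expect_error(
    dopo_simulate(np, config = sim_config(duration = 10),
                  pump_schedule = schedule_table(c(0, 5), c(1, 1))),
    "cover")
})

test_that("runs are reproducible from the seed", {
  np <- neuron_params(4, P_tilde = 1)
  cfg <- sim_config(duration = 10, seed = 11)
  a <- dopo_simulate(np, config = cfg)
  b <- dopo_simulate(np, config = cfg)
  expect_identical(a$v, b$v)
})
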