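test_that("brute-force oracle handles the canonical small cases", {
  pair <- brute_force_ground_state(ferro_pair_instance())
  expect_identical(pair$energy, -1)
  expect_identical(pair$sigma[1], pair$sigma[2])
  expect_identical(pair$degeneracy, 1L)

  tri <- brute_force_ground_state(triangle_instance())
  expect_identical(tri$energy, -1)
  expect_identical(tri$degeneracy, 3L)

  empty <- brute_force_ground_state(ising_instance(matrix(0, 4, 4)))
  expect_identical(empty$energy, 0)
  expect_identical(empty$degeneracy, 8L)   # all 2^(n-1) configurations

  expect_error(brute_force_ground_state(random_ising_instance(30, 0.5)),
               "guard")
})

test_that("oracle minimum is reproduced by re-evaluating its configuration", {
  inst <- random_ising_instance(12, 0.5, seed = 21)
  gs <- brute_force_ground_state(inst)
  expect_identical(ising_energy(inst$J, gs$sigma), gs$energy)
})

test_that("a ferromagnetic pair anneals to the aligned ground state", {
  inst <- ferro_pair_instance()
  aligned <- vapply(1:20, function(s) {
    a <- run_anneal(inst, anneal_schedule(J_k = 0.25), seed = s)
    a$final_sigma[1] == a$final_sigma[2]
  }, logical(1))
  expect_gte(sum(aligned), 18)
})

test_that("the frustrated triangle reaches its exact minimum", {
  inst <- triangle_instance()
  best <- vapply(1:20, function(s)
    run_anneal(inst, anneal_schedule(J_k = 0.25), seed = s)$best_energy,
    numeric(1))
  expect_gte(sum(best <= -1 + 1e-9), 18)
})

test_that("anneal trials never beat the exact oracle (soundness)", {
  inst <- random_ising_instance(10, 0.5, seed = 13)
  gs <- brute_force_ground_state(inst)
  for (s in 1:5) {
    a <- run_anneal(inst, anneal_schedule(J_k = 0.25), seed = s)
    expect_gte(a$best_energy, gs$energy)
    expect_gte(min(a$energy_trace), a$best_energy)   # best is the trace min
    expect_lte(a$best_energy, a$final_energy)
  }
})

test_that("uncoupled ramp stops firing before the ramp ends", {
  inst <- random_ising_instance(5, 0.9, seed = 2)
  a <- run_anneal(inst, anneal_schedule(J_k = 0), seed = 1)
  expect_true(all(a$firing_counts > 5))
  # re-derive spike times to check the last one precedes the ramp end
  net <- ising_network(inst, 0)
  cfg <- sim_config(duration = 500, dt = 1e-2, record_stride = 10L, seed = 1)
  tr <- dopo_simulate(net$params, net$coupling, cfg,
                      pump_schedule = schedule_linear(-0.5, 3.2))
  sp <- detect_spikes(to_polar(tr))
  last <- max(unlist(sp$spike_times))
  expect_lt(last, 470)
})

test_that("trial batches report success against the oracle", {
  inst <- ferro_pair_instance()
  batch <- run_trials(inst, anneal_schedule(J_k = 0.25), n_trials = 5,
                      base_seed = 3)
  expect_equal(batch$reference_energy, -1)
  expect_equal(batch$success_probability, 1)
  expect_length(batch$conf_int, 2)
  expect_identical(batch$trials$best_energy, rep(-1, 5))
  # a reference above every achievable energy gives probability 1
  easy <- run_trials(inst, anneal_schedule(J_k = 0.25), n_trials = 3,
                     base_seed = 3, reference_energy = 10)
  expect_equal(easy$success_probability, 1)
})

test_that("trial batches are reproducible from the base seed", {
  inst <- random_ising_instance(8, 0.5, seed = 4)
  a <- run_trials(inst, anneal_schedule(J_k = 0.2), n_trials = 3,
                  base_seed = 7)
  b <- run_trials(inst, anneal_schedule(J_k = 0.2), n_trials = 3,
                  base_seed = 7)
  expect_identical(a$trials, b$trials)
})
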