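#' Pump-ramp annealing schedule
#'
#' Node-independent pump ramped linearly with time. The default starts below
#' the oscillation threshold (P_tilde = -0.5), crosses the spiking region,
#' and ends beyond its sqrt(8) edge (P_tilde = 3.2) so the dynamics freeze
#' into a readout state by the end of the run.
#'
#' @param P_tilde_start,P_tilde_end ramp endpoints (dimensionless pump).
#' @param duration ramp duration in units of 1/omega0 (default 500).
#' @param J_k coupling strength used by [run_anneal()].
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(P_tilde_start = -0.5, P_tilde_end = 3.2,
                            duration = 500, J_k = 0.25) {
  stopifnot(duration > 0, is.finite(P_tilde_start), is.finite(P_tilde_end),
            is.finite(J_k))
  structure(list(P_tilde_start = P_tilde_start, P_tilde_end = P_tilde_end,
                 duration = duration, J_k = J_k),
            class = "anneal_schedule")
}

#' Run one pump-ramp annealing trial
#'
#' Encodes the instance with [ising_network()] (couplings only between
#' v-DOPOs, `gamma = -J_k`, zero bias), ramps the pump linearly per the
#' schedule, and records the spin configuration `sigma(t) = sign(v(t))` at
#' every stored sample. During the ramp, neurons sitting on energetically
#' unstable configurations receive extra effective gain
#' (`P' = P0 - J_k E_loc / 2`), fire faster, and preferentially flip — the
#' self-tuning heuristic that relaxes the network toward low Ising energy.
#' The headline output is the best (minimum) energy seen anywhere along the
#' trace, not just the final state.
#'
#' @param instance an `ising_instance`.
#' @param schedule an [anneal_schedule()].
#' @param dt integration step (default 1e-2).
#' @param record_stride steps between stored samples (default 10).
#' @param seed seed for the initial noise.
#' @param init_noise initial noise amplitude (default 1e-3).
#' @param omega0 natural frequency (default 1).
#' @return An object of class `dopo_anneal`: `energy_times`, `energy_trace`,
#'   `best_energy`, `best_sigma`, `final_sigma`, `final_E_loc`,
#'   `firing_counts`, `seed`, `schedule`, `instance`.
#' @export
run_anneal <- function(instance, schedule = anneal_schedule(), dt = 1e-2,
                       record_stride = 10L, seed = 1, init_noise = 1e-3,
                       omega0 = 1) {
  stopifnot(inherits(instance, "ising_instance"),
            inherits(schedule, "anneal_schedule"))
  net <- ising_network(instance, J_k = schedule$J_k, omega0 = omega0)
  cfg <- sim_config(duration = schedule$duration, dt = dt,
                    record_stride = record_stride, seed = seed,
                    init_noise = init_noise)
  ramp <- schedule_linear(schedule$P_tilde_start * omega0,
                          schedule$P_tilde_end * omega0)
  tr <- dopo_simulate(net$params, net$coupling, cfg, pump_schedule = ramp)

  S <- sign(t(tr$v))            # samples x n
  S[S == 0] <- 1
  E <- -0.5 * rowSums((S %*% instance$J) * S)
  best <- which.min(E)
  sigma_final <- as.integer(S[nrow(S), ])
  counts <- detect_spikes(to_polar(tr))$counts

  structure(list(energy_times = tr$times, energy_trace = E,
                 best_energy = E[best], best_sigma = as.integer(S[best, ]),
                 final_sigma = sigma_final,
                 final_energy = E[length(E)],
                 final_E_loc = local_energy(instance$J, sigma_final),
                 firing_counts = counts, seed = seed,
                 schedule = schedule, instance = instance),
            class = "dopo_anneal")
}

#' @export
print.dopo_anneal <- function(x, ...) {
  cat(sprintf(
    "Pump-ramp anneal: %d spins, J_k~ = %g, best E = %g (final %g)\n",
    x$instance$n, x$schedule$J_k, x$best_energy, x$final_energy))
  invisible(x)
}

#' @export
plot.dopo_anneal <- function(x, ...) {
  graphics::plot(x$energy_times, x$energy_trace, type = "l",
                 xlab = "time (1/omega0)", ylab = "Ising energy", ...)
  graphics::abline(h = x$best_energy, lty = 2, col = "red")
  invisible(x)
}

#' Batch of seeded annealing trials
#'
#' Runs `n_trials` independent trials (seeds `base_seed + 1 .. + n_trials`)
#' and reports success statistics against a reference energy (typically the
#' exact minimum from [brute_force_ground_state()]). A trial succeeds when
#' its best-seen energy is <= the reference. The success probability carries
#' an exact binomial confidence interval.
#'
#' @param instance an `ising_instance`.
#' @param schedule an [anneal_schedule()].
#' @param n_trials number of trials (>= 1).
#' @param base_seed base for the per-trial seeds.
#' @param reference_energy success threshold; if NULL and the instance is
#'   small enough, the brute-force minimum is used; otherwise the
#'   probability is omitted.
#' @param ... passed on to [run_anneal()].
#' @return An object of class `dopo_anneal_batch`: `trials` (data frame:
#'   seed, best_energy, final_energy, success), `best_energy`,
#'   `success_probability`, `conf_int`, `reference_energy`.
#' @export
run_trials <- function(instance, schedule = anneal_schedule(), n_trials = 20,
                       base_seed = 1, reference_energy = NULL, ...) {
  stopifnot(n_trials >= 1)
  if (is.null(reference_energy) && instance$n <= 24)
    reference_energy <- brute_force_ground_state(instance)$energy
  res <- lapply(seq_len(n_trials), function(k)
    run_anneal(instance, schedule, seed = base_seed + k, ...))
  best <- vapply(res, `[[`, numeric(1), "best_energy")
  fin <- vapply(res, `[[`, numeric(1), "final_energy")
  trials <- data.frame(seed = base_seed + seq_len(n_trials),
                       best_energy = best, final_energy = fin)
  out <- list(trials = trials, results = res,
              best_energy = min(best),
              reference_energy = reference_energy,
              schedule = schedule)
  if (!is.null(reference_energy)) {
    succ <- best <= reference_energy + 1e-9
    bt <- stats::binom.test(sum(succ), n_trials)
    out$trials$success <- succ
    out$success_probability <- mean(succ)
    out$conf_int <- as.numeric(bt$conf.int)
  }
  structure(out, class = "dopo_anneal_batch")
}

#' @export
print.dopo_anneal_batch <- function(x, ...) {
  cat(sprintf("Anneal batch: %d trials, best energy %g\n",
              nrow(x$trials), x$best_energy))
  if (!is.null(x$success_probability))
    cat(sprintf("  success vs reference %g: %.0f%% (95%% CI %.0f-%.0f%%)\n",
                x$reference_energy, 100 * x$success_probability,
                100 * x$conf_int[1], 100 * x$conf_int[2]))
  invisible(x)
}

#' Exact ground state by exhaustive enumeration
#'
#' Enumerates the 2^(n-1) spin configurations with sigma_1 fixed to +1
#' (global flip symmetry) in chunks, returning the exact minimum energy, one
#' minimizing configuration, and the degeneracy (number of distinct minima
#' up to the global flip). Refuses instances above `max_n` spins.
#'
#' @param instance an `ising_instance`.
#' @param max_n enumeration guard (default 24).
#' @return An object of class `ising_oracle`: `energy`, `sigma`,
#'   `degeneracy`.
#' @export
brute_force_ground_state <- function(instance, max_n = 24) {
  stopifnot(inherits(instance, "ising_instance"))
  n <- instance$n
  if (n > max_n)
    stop(sprintf("instance has %d spins; enumeration guard is %d", n, max_n))
  J <- instance$J
  total <- 2^(n - 1)
  chunk <- min(total, 2^16)
  best_e <- Inf
  best_sigma <- NULL
  degeneracy <- 0L
  done <- 0
  while (done < total) {
    m <- min(chunk, total - done)
    codes <- done + seq_len(m) - 1
    # bits of the code give spins 2..n; spin 1 fixed at +1
    S <- matrix(1, m, n)
    for (b in seq_len(n - 1))
      S[, b + 1] <- ifelse(bitwAnd(codes, 2^(b - 1)) > 0, -1, 1)
    E <- -0.5 * rowSums((S %*% J) * S)
    mn <- min(E)
    if (mn < best_e - 1e-12) {
      best_e <- mn
      best_sigma <- as.integer(S[which.min(E), ])
      degeneracy <- sum(E < mn + 1e-12)
    } else if (mn < best_e + 1e-12) {
      degeneracy <- degeneracy + sum(E < best_e + 1e-12)
    }
    done <- done + m
  }
  structure(list(energy = best_e, sigma = best_sigma,
                 degeneracy = as.integer(degeneracy)),
            class = "ising_oracle")
}

#' @export
print.ising_oracle <- function(x, ...) {
  cat(sprintf("Exact ground state: E = %g, degeneracy %d (up to global flip)\n",
              x$energy, x$degeneracy))
  invisible(x)
}
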