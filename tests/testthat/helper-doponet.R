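# shared fixtures built in code

# drop the first `frac` of a polar trajectory (transient discard)
trim_polar <- function(pol, frac = 0.25) {
  keep <- pol$times >= frac * max(pol$times)
  pol$times <- pol$times[keep]
  pol$theta <- pol$theta[, keep, drop = FALSE]
  if (!is.null(pol$R)) pol$R <- pol$R[, keep, drop = FALSE]
  if (!is.null(pol$undefined))
    pol$undefined <- pol$undefined[, keep, drop = FALSE]
  pol
}

# steady firing rate of a single full-model neuron
steady_rate <- function(P_tilde, duration = 300, dt = 1e-2, seed = 1) {
  np <- neuron_params(1, P_tilde = P_tilde)
  tr <- dopo_simulate(np, config = sim_config(duration = duration, dt = dt,
                                              seed = seed))
  detect_spikes(trim_polar(to_polar(tr)))$rate
}

# the frustrated triangle: every pair antiferromagnetic
triangle_instance <- function() {
  J <- matrix(-1, 3, 3)
  diag(J) <- 0
  ising_instance(J)
}

ferro_pair_instance <- function() {
  ising_instance(matrix(c(0, 1, 1, 0), 2, 2))
}
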