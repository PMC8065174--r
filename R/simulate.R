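#' Simulate a network of paired-DOPO neurons
#'
#' Integrates the full two-variable amplitude dynamics of a DOPO neural
#' network with a fixed-step scheme:
#' \deqn{\dot v_i = P_i v_i - v_i^3 + J_{vw} w_i
#'       + \gamma \sum_j J_{ij} v_j + I_{ext,i}}
#' \deqn{\dot w_i = P_i w_i - w_i^3 + J_{wv} v_i
#'       + \gamma' \sum_j J_{ij} w_j}
#' where \eqn{P_i = -1 + p_i} is the effective pump. Initial conditions are
#' i.i.d. zero-mean Gaussian noise of standard deviation
#' `config$init_noise` (seeded), unless `init` is supplied.
#'
#' Pump and bias may be time dependent via [schedule_constant()],
#' [schedule_linear()] or [schedule_table()]; constant schedules reduce
#' exactly to the static parameters in `params`.
#'
#' @param params a [neuron_params()] object.
#' @param coupling a [network_coupling()] object, or NULL for an uncoupled
#'   network.
#' @param config a [sim_config()] object.
#' @param pump_schedule,bias_schedule optional `dopo_schedule` objects
#'   overriding `params$P` / `params$I_ext` over time.
#' @param init optional 2 x n or n x 2 matrix (columns/rows v, w) of exact
#'   initial values, bypassing the seeded noise draw.
#' @return An object of class `dopo_trajectory`: list with `times` (length m),
#'   `v`, `w` (n x m matrices), `params`, `coupling`, `config`, and
#'   `schedules` (the per-sample P and I_ext actually applied, n x m).
#' @examples
#' np <- neuron_params(1, P_tilde = 1)
#' tr <- dopo_simulate(np, config = sim_config(duration = 100, seed = 1))
#' summary(tr)
#' @export
dopo_simulate <- function(params, coupling = NULL, config,
                          pump_schedule = NULL, bias_schedule = NULL,
                          init = NULL) {
  stopifnot(inherits(params, "dopo_params"), inherits(config, "dopo_config"))
  n <- params$n_neurons
  if (is.null(coupling)) {
    coupling <- network_coupling(matrix(0, n, n))
  }
  stopifnot(inherits(coupling, "dopo_coupling"))
  if (coupling$n_neurons != n)
    stop(sprintf("coupling is for %d neurons but params has %d",
                 coupling$n_neurons, n))

  pk <- resolve_schedule(pump_schedule, n, config$duration, params$P)
  bk <- resolve_schedule(bias_schedule, n, config$duration, params$I_ext)

  if (is.null(init)) {
    x0 <- with_seed(config$seed, stats::rnorm(2 * n, sd = config$init_noise))
    v0 <- x0[seq_len(n)]
    w0 <- x0[n + seq_len(n)]
  } else {
    init <- as.matrix(init)
    if (nrow(init) == 2 && n != 2) init <- t(init)
    if (!identical(dim(init), c(n, 2L)) && !(n == 2 && all(dim(init) == 2)))
      stopifnot(nrow(init) == n, ncol(init) == 2)
    v0 <- init[, 1]
    w0 <- init[, 2]
  }

  nsteps <- max(1L, as.integer(round(config$duration / config$dt)))
  res <- .sim_cartesian_cpp(
    v0, w0, coupling$J, coupling$gamma, coupling$gamma_prime,
    params$J_vw, params$J_wv,
    pk$times, pk$values, bk$times, bk$values,
    config$dt, nsteps, config$record_stride,
    config$integrator == "euler",
    any(coupling$J != 0) && (coupling$gamma != 0 || coupling$gamma_prime != 0))

  times <- res$times
  st <- res$state
  structure(
    list(times = times,
         v = st[seq_len(n), , drop = FALSE],
         w = st[n + seq_len(n), , drop = FALSE],
         params = params, coupling = coupling, config = config,
         schedules = list(P = eval_schedule_knots(pk, times),
                          I_ext = eval_schedule_knots(bk, times))),
    class = "dopo_trajectory")
}

#' @export
print.dopo_trajectory <- function(x, ...) {
  cat("DOPO trajectory:", nrow(x$v), "neuron(s),", length(x$times),
      "samples over t = [0,", format(max(x$times)), "]\n")
  invisible(x)
}

#' @export
summary.dopo_trajectory <- function(object, ...) {
  n <- nrow(object$v)
  pol <- to_polar(object)
  sp <- detect_spikes(pol)
  out <- data.frame(
    neuron = seq_len(n),
    v_final = object$v[, ncol(object$v)],
    w_final = object$w[, ncol(object$w)],
    amplitude_max = apply(abs(object$v), 1, max),
    spikes = vapply(sp$spike_times, length, integer(1)),
    rate = sp$rate)
  class(out) <- c("summary.dopo_trajectory", class(out))
  out
}

#' @export
plot.dopo_trajectory <- function(x, neurons = NULL, ...) {
  n <- nrow(x$v)
  if (is.null(neurons)) neurons <- seq_len(min(n, 5L))
  graphics::matplot(x$times, t(x$v[neurons, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (1/omega0)", ylab = "v amplitude",
                    ...)
  invisible(x)
}
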