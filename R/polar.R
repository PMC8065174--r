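#' Polar view of a DOPO trajectory
#'
#' Rewrites the paired amplitudes through \eqn{\sqrt{R_i} e^{i\theta_i} =
#' v_i + i w_i}: the phase \eqn{\theta_i = \arg(v_i + i w_i)} and squared
#' amplitude \eqn{R_i = v_i^2 + w_i^2}. Phases are unwrapped continuously
#' along time. Samples where `R` falls below `R_min` have an ill-defined
#' phase; their theta is carried forward from the last defined value and the
#' affected samples are flagged in the `undefined` matrix.
#'
#' @param trajectory a `dopo_trajectory`.
#' @param R_min floor below which the phase is treated as undefined
#'   (default 1e-12).
#' @return An object of class `dopo_polar`: `times`, `theta` (unwrapped,
#'   n x m), `R` (n x m), `undefined` (logical n x m), `omega0`.
#' @export
to_polar <- function(trajectory, R_min = 1e-12) {
  stopifnot(inherits(trajectory, "dopo_trajectory"))
  v <- trajectory$v
  w <- trajectory$w
  R <- v^2 + w^2
  n <- nrow(v)
  theta <- matrix(0, n, ncol(v))
  undef <- R < R_min
  for (i in seq_len(n)) {
    th <- atan2(w[i, ], v[i, ])
    bad <- undef[i, ]
    if (any(bad) && !all(bad)) {
      # carry phase forward through ill-defined stretches before unwrapping
      idx <- cummax(ifelse(bad, 0L, seq_along(th)))
      idx[idx == 0L] <- which(!bad)[1]
      th <- th[idx]
    }
    theta[i, ] <- unwrap_phase(th)
  }
  structure(list(times = trajectory$times, theta = theta, R = R,
                 undefined = undef, omega0 = trajectory$params$omega0,
                 params = trajectory$params),
            class = "dopo_polar")
}

#' Cartesian view of a polar trajectory
#'
#' Inverse of [to_polar()]: `v = sqrt(R) cos(theta)`,
#' `w = sqrt(R) sin(theta)`. Metadata (params, coupling, config) is carried
#' over when present.
#'
#' @param polar a `dopo_polar` object with an `R` component.
#' @return a `dopo_trajectory` (with empty coupling/config metadata when the
#'   polar object was built directly rather than converted).
#' @export
from_polar <- function(polar) {
  stopifnot(inherits(polar, "dopo_polar"))
  if (is.null(polar$R)) stop("phase-only trajectory: amplitude R is absent")
  sq <- sqrt(polar$R)
  structure(list(times = polar$times,
                 v = sq * cos(polar$theta),
                 w = sq * sin(polar$theta),
                 params = polar$params %||%
                   neuron_params(nrow(polar$theta)),
                 coupling = NULL, config = NULL, schedules = NULL),
            class = "dopo_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# continuous unwrapping: remove 2*pi jumps along a phase series
unwrap_phase <- function(th) {
  if (length(th) < 2) return(th)
  d <- diff(th)
  jumps <- round(d / (2 * pi))
  th - c(0, cumsum(jumps)) * 2 * pi
}

#' Simulate the reduced phase-amplitude dynamics
#'
#' Integrates the polar form of the network equations under uniform
#' all-to-all coupling `J_k`:
#' \deqn{\dot\theta_i = \omega_0 - J_k \sum_{j\ne i} \epsilon_{ij}
#'       \sin(\theta_i-\theta_j) + (R_i/4)\sin 4\theta_i}
#' \deqn{\dot R_i = 2 P_i R_i + 2 J_k R_i \sum_{j\ne i} \epsilon_{ij}
#'       \cos(\theta_i-\theta_j) - (R_i^2/2)(\cos 4\theta_i + 3)}
#' with amplitude-ratio weights \eqn{\epsilon_{ij} = \sqrt{R_j/R_i}}
#' recomputed at every step. `R` is floored at `R_floor` (the phase is
#' ill-defined at zero amplitude); floored runs are flagged.
#'
#' @param params a [neuron_params()] object (pump per neuron; bias unused in
#'   this reduction).
#' @param J_k uniform all-to-all coupling strength.
#' @param config a [sim_config()] object.
#' @param pump_schedule optional `dopo_schedule` for a time-dependent pump.
#' @param theta0,R0 optional explicit initial conditions; defaults are
#'   seeded uniform phases on (-pi, pi] and `R0 = max(init_noise^2, 1e-8)`.
#' @param R_floor amplitude floor (default 1e-12).
#' @return a `dopo_polar` object (with `params` and `config` attached).
#' @export
simulate_polar <- function(params, J_k = 0, config, pump_schedule = NULL,
                           theta0 = NULL, R0 = NULL, R_floor = 1e-12) {
  stopifnot(inherits(params, "dopo_params"), inherits(config, "dopo_config"))
  n <- params$n_neurons
  pk <- resolve_schedule(pump_schedule, n, config$duration, params$P)
  if (is.null(theta0))
    theta0 <- with_seed(config$seed, stats::runif(n, -pi, pi))
  if (is.null(R0)) R0 <- rep(max(config$init_noise^2, 1e-8), n)
  theta0 <- rep_len(theta0, n)
  R0 <- rep_len(R0, n)
  if (any(R0 <= 0)) stop("R0 must be > 0")

  nsteps <- max(1L, as.integer(round(config$duration / config$dt)))
  res <- .sim_polar_cpp(theta0, R0, params$omega0, J_k,
                        pk$times, pk$values,
                        config$dt, nsteps, config$record_stride,
                        config$integrator == "euler", R_floor)
  st <- res$state
  R <- st[n + seq_len(n), , drop = FALSE]
  structure(list(times = res$times,
                 theta = st[seq_len(n), , drop = FALSE],
                 R = R,
                 undefined = R <= R_floor,
                 omega0 = params$omega0,
                 params = params, config = config, J_k = J_k),
            class = "dopo_polar")
}

#' Simulate the Kuramoto phase model
#'
#' All-to-all coupled phase oscillators,
#' \eqn{\dot\theta_i = \omega_i - J_k \sum_j \sin(\theta_i - \theta_j)},
#' used as the reference model for synchronization behaviour. The returned
#' object is phase-only (`R` is NULL).
#'
#' @param omegas per-oscillator natural frequencies.
#' @param J_k coupling strength.
#' @param config a [sim_config()] object.
#' @param theta0 optional initial phases (default: seeded uniform).
#' @return a `dopo_polar` object with `R = NULL`.
#' @export
simulate_kuramoto <- function(omegas, J_k = 0, config, theta0 = NULL) {
  stopifnot(inherits(config, "dopo_config"))
  omegas <- as.numeric(omegas)
  n <- length(omegas)
  stopifnot(n >= 1, all(is.finite(omegas)))
  if (is.null(theta0))
    theta0 <- with_seed(config$seed, stats::runif(n, -pi, pi))
  theta0 <- rep_len(theta0, n)
  nsteps <- max(1L, as.integer(round(config$duration / config$dt)))
  res <- .sim_kuramoto_cpp(theta0, omegas, J_k, config$dt, nsteps,
                           config$record_stride,
                           config$integrator == "euler")
  structure(list(times = res$times,
                 theta = res$state,
                 R = NULL, undefined = NULL, omega0 = NA_real_,
                 config = config, J_k = J_k),
            class = "dopo_polar")
}

#' @export
print.dopo_polar <- function(x, ...) {
  cat("DOPO polar trajectory:", nrow(x$theta), "neuron(s),",
      length(x$times), "samples",
      if (is.null(x$R)) "(phase only)" else "", "\n")
  invisible(x)
}

#' @export
plot.dopo_polar <- function(x, neurons = NULL, ...) {
  n <- nrow(x$theta)
  if (is.null(neurons)) neurons <- seq_len(min(n, 8L))
  graphics::matplot(x$times, t(x$theta[neurons, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (1/omega0)",
                    ylab = expression(theta ~ "(unwrapped, rad)"), ...)
  invisible(x)
}
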