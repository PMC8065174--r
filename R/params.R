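#' Per-neuron DOPO parameters
#'
#' Bundles the single-neuron parameters of the paired-DOPO neuron model: the
#' effective pump \eqn{P_i = -1 + p_i}, the external bias \eqn{I_{ext,i}}, and
#' the internal v-w coupling coefficients \eqn{J_{vw}}, \eqn{J_{wv}}. The
#' natural spiking frequency is \eqn{\omega_0 = \sqrt{-J_{vw} J_{wv}}}, which
#' requires antisymmetric internal coupling (\eqn{J_{vw} J_{wv} < 0}).
#'
#' Parameters may be given either in raw units (`P`, `I_ext`) or in the
#' dimensionless tilde convention (`P_tilde` = P / omega0,
#' `I_ext_tilde` = I_ext / omega0^(3/2)); exactly one of each pair.
#' With the default internal coupling (`J_vw = -1`, `J_wv = 1`) omega0 = 1 and
#' the two conventions coincide.
#'
#' @param n_neurons number of neurons.
#' @param P,P_tilde effective pump amplitude per neuron (scalar recycled).
#' @param I_ext,I_ext_tilde external bias per neuron (scalar recycled).
#' @param J_vw,J_wv internal coupling coefficients; must satisfy
#'   `J_vw * J_wv < 0`.
#' @return An object of class `dopo_params`: a list with elements
#'   `n_neurons`, `P`, `p` (= 1 + P), `I_ext`, `J_vw`, `J_wv`, `omega0`.
#' @seealso [dimensionless()], [network_coupling()], [dopo_simulate()]
#' @examples
#' np <- neuron_params(1, P_tilde = 1)
#' dimensionless(np)$P_tilde
#' @export
neuron_params <- function(n_neurons, P = NULL, I_ext = NULL,
                          P_tilde = NULL, I_ext_tilde = NULL,
                          J_vw = -1, J_wv = 1) {
  stopifnot(is.numeric(n_neurons), length(n_neurons) == 1, n_neurons >= 1)
  n_neurons <- as.integer(n_neurons)
  if (!is.finite(J_vw) || !is.finite(J_wv) || J_vw * J_wv >= 0)
    stop("antisymmetric internal coupling required: J_vw * J_wv must be < 0")
  omega0 <- sqrt(-J_vw * J_wv)

  if (!is.null(P) && !is.null(P_tilde))
    stop("give either `P` or `P_tilde`, not both")
  if (is.null(P)) P <- if (is.null(P_tilde)) 0 else P_tilde * omega0
  if (!is.null(I_ext) && !is.null(I_ext_tilde))
    stop("give either `I_ext` or `I_ext_tilde`, not both")
  if (is.null(I_ext))
    I_ext <- if (is.null(I_ext_tilde)) 0 else I_ext_tilde * omega0^1.5

  P <- rep_len(as.numeric(P), n_neurons)
  I_ext <- rep_len(as.numeric(I_ext), n_neurons)
  if (!all(is.finite(P)) || !all(is.finite(I_ext)))
    stop("P and I_ext must be finite")

  structure(
    list(n_neurons = n_neurons, P = P, p = 1 + P, I_ext = I_ext,
         J_vw = J_vw, J_wv = J_wv, omega0 = omega0),
    class = "dopo_params")
}

#' Dimensionless (tilde) view of neuron parameters
#'
#' Converts raw parameters to the tilde convention: `P_tilde = P / omega0`,
#' `I_ext_tilde = I_ext / omega0^(3/2)`. The conversion is exactly
#' self-inverse with [neuron_params()].
#'
#' @param params a `dopo_params` object.
#' @return list with `P_tilde`, `I_ext_tilde`, `omega0`.
#' @export
dimensionless <- function(params) {
  stopifnot(inherits(params, "dopo_params"))
  list(P_tilde = params$P / params$omega0,
       I_ext_tilde = params$I_ext / params$omega0^1.5,
       omega0 = params$omega0)
}

#' @export
print.dopo_params <- function(x, ...) {
  cat("DOPO neuron parameters\n")
  cat("  neurons:", x$n_neurons, "\n")
  cat("  omega0 :", format(x$omega0), sprintf("(J_vw = %g, J_wv = %g)\n",
                                              x$J_vw, x$J_wv))
  cat("  P~     :", .range_str(x$P / x$omega0), "\n")
  cat("  I_ext~ :", .range_str(x$I_ext / x$omega0^1.5), "\n")
  invisible(x)
}

.range_str <- function(v) {
  if (length(unique(v)) == 1) format(v[1])
  else sprintf("[%s, %s] (n = %d)", format(min(v)), format(max(v)), length(v))
}

#' Synaptic coupling of a DOPO network
#'
#' Wraps the symmetric synaptic matrix `J` together with the scaling factors
#' `gamma` (applied to the v-equations) and `gamma_prime` (w-equations).
#' Kuramoto-style clustered networks use `gamma == gamma_prime == J_k`;
#' Ising-encoded networks use `gamma == -J_k`, `gamma_prime == 0`.
#'
#' @param J n x n real symmetric matrix with zero diagonal.
#' @param gamma scaling of `J` in the v-equations.
#' @param gamma_prime scaling of `J` in the w-equations.
#' @param quantize_bits optional integer; if given, J entries are rounded to a
#'   signed fixed-point grid with this many bits over \[-max|J|, max|J|\]
#'   (mirrors finite connection-weight resolution in hardware). Off by default.
#' @return An object of class `dopo_coupling`.
#' @export
network_coupling <- function(J, gamma = 0, gamma_prime = 0, quantize_bits = NULL) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("J must be square")
  if (any(!is.finite(J))) stop("J must be finite")
  if (max(abs(J - t(J))) > 1e-12) stop("J must be symmetric")
  if (any(diag(J) != 0)) stop("J must have zero diagonal")
  if (!is.finite(gamma) || !is.finite(gamma_prime))
    stop("gamma and gamma_prime must be finite")
  if (!is.null(quantize_bits)) {
    stopifnot(quantize_bits >= 2)
    m <- max(abs(J))
    if (m > 0) {
      levels <- 2^(quantize_bits - 1) - 1
      J <- round(J / m * levels) / levels * m
    }
  }
  structure(list(n_neurons = nrow(J), J = J, gamma = gamma,
                 gamma_prime = gamma_prime),
            class = "dopo_coupling")
}

#' @export
print.dopo_coupling <- function(x, ...) {
  nz <- sum(x$J[upper.tri(x$J)] != 0)
  cat("DOPO network coupling\n")
  cat("  neurons     :", x$n_neurons, "\n")
  cat("  edges       :", nz, "\n")
  cat("  gamma       :", format(x$gamma), "\n")
  cat("  gamma_prime :", format(x$gamma_prime), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Fixed-step integration settings shared by all simulators. Times are in
#' units of 1/omega0.
#'
#' @param duration total integrated time (> 0).
#' @param dt integration step (default 1e-2).
#' @param integrator `"rk4"` (classical 4th order, default) or `"euler"`.
#' @param record_stride store every this-many steps (>= 1).
#' @param seed integer seed for the initial-condition noise (optional).
#' @param init_noise standard deviation of the zero-mean initial v, w values
#'   (default 1e-3, emulating growth from amplified vacuum noise).
#' @return An object of class `dopo_config`.
#' @export
sim_config <- function(duration, dt = 1e-2, integrator = c("rk4", "euler"),
                       record_stride = 1L, seed = NULL, init_noise = 1e-3) {
  integrator <- match.arg(integrator)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(duration) || duration < dt) stop("duration must be >= dt")
  record_stride <- as.integer(record_stride)
  if (record_stride < 1) stop("record_stride must be >= 1")
  if (init_noise < 0) stop("init_noise must be >= 0")
  structure(list(duration = duration, dt = dt, integrator = integrator,
                 record_stride = record_stride, seed = seed,
                 init_noise = init_noise),
            class = "dopo_config")
}

# seeded RNG evaluation without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
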