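#' Kuramoto order parameter
#'
#' \eqn{r = |N^{-1}\sum_j e^{i\theta_j}|}: 1 for phase-locked ensembles, ~0
#' for incoherent ones. Accepts a phase vector (one sample), a phase matrix
#' (neurons x time, returning a trace), or a `dopo_polar` object. With a
#' `membership` factor, per-group traces are returned alongside the global
#' one.
#'
#' @param theta phase vector, n x m phase matrix, or `dopo_polar`.
#' @param membership optional factor/vector of group labels (length n).
#' @return For a vector: scalar r. For a matrix/polar object: list with
#'   `global` (length-m trace) and, when membership is given, `cluster`
#'   (group x m matrix).
#' @examples
#' order_parameter(c(0, pi / 2))   # sqrt(2)/2
#' @export
order_parameter <- function(theta, membership = NULL) {
  if (inherits(theta, "dopo_polar")) theta <- theta$theta
  if (is.null(dim(theta))) {
    if (length(theta) < 1) stop("empty phase set")
    return(Mod(mean(exp(1i * theta))))
  }
  if (nrow(theta) < 1) stop("empty phase set")
  global <- Mod(colMeans(exp(1i * theta)))
  if (is.null(membership)) return(list(global = global))
  membership <- as.factor(membership)
  if (length(membership) != nrow(theta))
    stop("membership must have one label per neuron")
  cl <- t(vapply(levels(membership), function(g) {
    rows <- which(membership == g)
    Mod(colMeans(exp(1i * theta[rows, , drop = FALSE])))
  }, numeric(ncol(theta))))
  rownames(cl) <- levels(membership)
  list(global = global, cluster = cl)
}

#' Detect spikes and firing rates
#'
#' Default definition (`"winding"`): one spike per full 2*pi advance of the
#' unwrapped phase, timestamped by linear interpolation of the level
#' crossing. Rotation below an amplitude floor (`R < min_R`) carries no
#' spike energy and is ignored — this keeps subthreshold decay, which still
#' rotates at omega0, from being counted. The alternative (`"peak"`)
#' definition takes local maxima of |v| above `peak_threshold`.
#'
#' The firing rate is reported as an angular frequency,
#' `2*pi * (count - 1) / (t_last - t_first)` for two or more spikes, else 0,
#' directly comparable with the closed-form spiking frequency.
#'
#' @param polar a `dopo_polar` object (theta unwrapped). For the `"peak"`
#'   definition a `dopo_trajectory` is also accepted.
#' @param definition `"winding"` (default) or `"peak"`.
#' @param min_R amplitude-squared floor for winding spikes (default 1e-3;
#'   ignored for phase-only trajectories).
#' @param peak_threshold |v| threshold for the peak definition (default 0.2).
#' @return An object of class `spike_train`: list with `spike_times` (list of
#'   numeric vectors), `rate` (per neuron), `counts`, `definition`.
#' @export
detect_spikes <- function(polar, definition = c("winding", "peak"),
                          min_R = 1e-3, peak_threshold = 0.2) {
  definition <- match.arg(definition)
  if (definition == "peak") {
    tr <- if (inherits(polar, "dopo_trajectory")) polar else from_polar(polar)
    times <- tr$times
    st <- lapply(seq_len(nrow(tr$v)), function(i) {
      a <- abs(tr$v[i, ])
      m <- length(a)
      if (m < 3) return(numeric())
      pk <- which(a[2:(m - 1)] > a[1:(m - 2)] & a[2:(m - 1)] >= a[3:m] &
                    a[2:(m - 1)] > peak_threshold) + 1
      times[pk]
    })
  } else {
    stopifnot(inherits(polar, "dopo_polar"))
    times <- polar$times
    n <- nrow(polar$theta)
    st <- lapply(seq_len(n), function(i) {
      th <- polar$theta[i, ]
      if (!is.null(polar$R)) {
        low <- polar$R[i, ] < min_R
        if (all(low)) return(numeric())
        if (any(low)) {
          # freeze the phase while the amplitude is below the floor
          idx <- cummax(ifelse(low, 0L, seq_along(th)))
          idx[idx == 0L] <- which(!low)[1]
          th <- th[idx]
        }
      }
      adv <- th - th[1]
      s <- sign(adv[length(adv)])
      if (s == 0) return(numeric())
      adv <- s * adv
      k_end <- floor(max(cummax(adv)) / (2 * pi))
      if (k_end < 1) return(numeric())
      vapply(seq_len(k_end), function(k) {
        lev <- 2 * pi * k
        j <- which(adv >= lev)[1]
        if (j == 1) return(times[1])
        f <- (lev - adv[j - 1]) / (adv[j] - adv[j - 1])
        times[j - 1] + f * (times[j] - times[j - 1])
      }, numeric(1))
    })
  }
  counts <- vapply(st, length, integer(1))
  rate <- vapply(st, function(s) {
    if (length(s) >= 2) 2 * pi * (length(s) - 1) / (s[length(s)] - s[1]) else 0
  }, numeric(1))
  structure(list(spike_times = st, rate = rate, counts = counts,
                 definition = definition),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike trains (", x$definition, " definition): ",
      length(x$spike_times), " neuron(s)\n", sep = "")
  cat("  counts:", .range_str(x$counts), "\n")
  cat("  rate  :", .range_str(round(x$rate, 4)), "\n")
  invisible(x)
}

#' Phase advance per reporting window
#'
#' Finite differences of the unwrapped phase over consecutive windows of
#' length `window` (the analogue of the phase change per a fixed number of
#' cavity circulations). Stretches of near-zero increments signal class-I
#' stalling near unstable stationary points.
#'
#' @param polar a `dopo_polar` object.
#' @param window window length in time units (> 0, at most the trace span).
#' @return list with `window_times` (right edges) and `delta_theta`
#'   (neurons x windows matrix).
#' @export
phase_increment <- function(polar, window) {
  stopifnot(inherits(polar, "dopo_polar"), window > 0)
  span <- max(polar$times) - min(polar$times)
  if (window > span) stop("window longer than the recorded trace")
  edges <- seq(min(polar$times), max(polar$times), by = window)
  if (length(edges) < 2) stop("window longer than the recorded trace")
  n <- nrow(polar$theta)
  th_at <- vapply(edges, function(tt) {
    j <- findInterval(tt, polar$times, all.inside = TRUE)
    f <- (tt - polar$times[j]) / (polar$times[j + 1] - polar$times[j])
    polar$theta[, j] + f * (polar$theta[, j + 1] - polar$theta[, j])
  }, numeric(n))
  th_at <- matrix(th_at, nrow = n)
  list(window_times = edges[-1],
       delta_theta = th_at[, -1, drop = FALSE] -
         th_at[, -ncol(th_at), drop = FALSE])
}

#' Ising and local energies
#'
#' \eqn{E_{Ising} = -\sum_{i<j} J_{ij}\sigma_i\sigma_j} and
#' \eqn{E_{loc,i} = -\sum_j J_{ij}\sigma_i\sigma_j}, related by
#' \eqn{E_{Ising} = \frac{1}{2}\sum_i E_{loc,i}}. Exact (integer) for
#' integer weights.
#'
#' @param J symmetric coupling matrix (zero diagonal).
#' @param sigma spin vector with entries in \{-1, +1\}.
#' @return `ising_energy()`: scalar; `local_energy()`: per-spin vector.
#' @export
ising_energy <- function(J, sigma) {
  check_spins(J, sigma)
  -0.5 * drop(sigma %*% J %*% sigma)
}

#' @rdname ising_energy
#' @export
local_energy <- function(J, sigma) {
  check_spins(J, sigma)
  -sigma * drop(J %*% sigma)
}

check_spins <- function(J, sigma) {
  if (!all(sigma %in% c(-1, 1))) stop("sigma entries must be -1 or +1")
  if (length(sigma) != nrow(J)) stop("sigma length must match J")
  invisible(TRUE)
}

#' Spin readout from a trajectory
#'
#' The Ising spin of neuron i is the binary phase state of its v-DOPO:
#' `sigma_i = sign(v_i(time))`, with zero mapped to +1.
#'
#' @param trajectory a `dopo_trajectory`.
#' @param time readout time (default: end of the run).
#' @return integer vector of -1/+1 spins.
#' @export
spin_readout <- function(trajectory, time = NULL) {
  stopifnot(inherits(trajectory, "dopo_trajectory"))
  if (is.null(time)) time <- max(trajectory$times)
  if (time < min(trajectory$times) || time > max(trajectory$times))
    stop("readout time outside the recorded trace")
  j <- which.min(abs(trajectory$times - time))
  s <- sign(trajectory$v[, j])
  s[s == 0] <- 1
  as.integer(s)
}

#' Renormalized pump amplitude
#'
#' Coherent input from synchronized neighbours acts as extra gain. In a
#' cluster of N all-to-all coupled neurons with order parameter r the
#' effective pump is \eqn{P' = P + r(N-1)J_k} (amplitude-ratio weights
#' approximated by 1); in the Ising encoding it is
#' \eqn{P' = P_0 - \frac{1}{2} J_k E_{loc,i}}, so energetically unstable
#' spins (high local energy) receive more gain and fire faster.
#'
#' @param P,P0 bare pump amplitude.
#' @param r order parameter in \[0, 1\].
#' @param N cluster size (>= 1).
#' @param J_k coupling strength.
#' @param E_loc local energy (vectorized).
#' @return effective pump P'.
#' @export
renormalized_pump <- function(P, r, N, J_k) {
  stopifnot(all(r >= 0 & r <= 1), N >= 1)
  P + r * (N - 1) * J_k
}

#' @rdname renormalized_pump
#' @export
renormalized_pump_ising <- function(P0, J_k, E_loc) {
  P0 - 0.5 * J_k * E_loc
}

#' Firing count versus local energy
#'
#' Per-neuron association between total firing count and the local energy of
#' the readout configuration. Both the rank (Spearman) and linear (Pearson)
#' coefficients are reported; zero-variance inputs give an `undefined` flag
#' rather than a zero.
#'
#' @param counts per-neuron firing counts (or a `spike_train`).
#' @param E_loc per-neuron local energies.
#' @return list with `table` (data frame: neuron, count, E_loc),
#'   `rank_correlation`, `linear_correlation`, `undefined`.
#' @export
firing_vs_local_energy <- function(counts, E_loc) {
  if (inherits(counts, "spike_train")) counts <- counts$counts
  stopifnot(length(counts) == length(E_loc))
  undefined <- stats::sd(counts) == 0 || stats::sd(E_loc) == 0
  list(table = data.frame(neuron = seq_along(counts), count = counts,
                          E_loc = E_loc),
       rank_correlation = if (undefined) NA_real_ else
         stats::cor(counts, E_loc, method = "spearman"),
       linear_correlation = if (undefined) NA_real_ else
         stats::cor(counts, E_loc, method = "pearson"),
       undefined = undefined)
}
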