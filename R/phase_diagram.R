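#' Scan the single-neuron phase diagram
#'
#' Maps the spiking frequency of one DOPO neuron over a grid of
#' dimensionless pump and bias values. Each cell is simulated from seeded
#' noise with the full two-variable model; the firing rate is measured from
#' the last 75% of the run (transient discarded) with the winding-number
#' spike detector. Each cell's equilibria are located and classified with
#' [find_equilibria()], and bifurcation boundary points are tagged on edges
#' between spiking and quiescent cells:
#' * Andronov-Hopf (AH, class-II onset): the quiescent neighbour has a
#'   single focus-type equilibrium — spiking starts at finite frequency.
#' * Saddle-node on a limit cycle (SNLC, class-I offset): the quiescent
#'   neighbour holds saddle/node pairs born on the former cycle — the
#'   period diverges smoothly.
#'
#' @param P_tilde_range,I_ext_tilde_range length-2 ranges of the
#'   dimensionless pump and bias.
#' @param n_P,n_I grid resolution (default 15 x 5).
#' @param omega0 natural frequency (default 1).
#' @param duration,dt simulation length and step per cell.
#' @param seed seed for the per-cell initial noise.
#' @param rate_tol cells with measured rate below this count as quiescent
#'   (default 1e-3).
#' @return An object of class `dopo_phase_diagram`: `grid` (data frame with
#'   P_tilde, I_ext_tilde, omega_tilde, n_equilibria, stable_exists,
#'   has_saddle), `ah_boundary`, `snlc_boundary` (data frames of midpoints),
#'   plus the scan settings.
#' @export
scan_phase_diagram <- function(P_tilde_range = c(-0.5, 3.5),
                               I_ext_tilde_range = c(-0.3, 0.3),
                               n_P = 15, n_I = 5, omega0 = 1,
                               duration = 200, dt = 1e-2, seed = 1,
                               rate_tol = 1e-3) {
  stopifnot(length(P_tilde_range) == 2, length(I_ext_tilde_range) == 2,
            n_P >= 2, n_I >= 1)
  Pg <- seq(P_tilde_range[1], P_tilde_range[2], length.out = n_P)
  Ig <- seq(I_ext_tilde_range[1], I_ext_tilde_range[2], length.out = n_I)
  grid <- expand.grid(P_tilde = Pg, I_ext_tilde = Ig)
  cfg <- sim_config(duration = duration, dt = dt, record_stride = 2L,
                    seed = seed)
  omega_t <- numeric(nrow(grid))
  n_eq <- integer(nrow(grid))
  stable <- logical(nrow(grid))
  saddle <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    np <- neuron_params(1, P_tilde = grid$P_tilde[k],
                        I_ext_tilde = grid$I_ext_tilde[k],
                        J_vw = -omega0, J_wv = omega0)
    tr <- dopo_simulate(np, config = cfg)
    omega_t[k] <- measure_rate(tr, discard = 0.25) / omega0
    st <- find_equilibria(grid$P_tilde[k] * omega0,
                          I_ext = grid$I_ext_tilde[k] * omega0^1.5,
                          omega0 = omega0)
    n_eq[k] <- st$n_equilibria
    stable[k] <- any(st$classifications %in% c("stable-focus", "stable-node"))
    saddle[k] <- any(st$classifications == "saddle")
  }
  grid$omega_tilde <- pmax(0, omega_t)
  grid$omega_tilde[grid$omega_tilde < rate_tol] <- 0
  grid$n_equilibria <- n_eq
  grid$stable_exists <- stable
  grid$has_saddle <- saddle

  ah <- list()
  snlc <- list()
  idx <- function(ip, ii) (ii - 1) * n_P + ip
  tag_edge <- function(a, b) {
    # a spiking, b quiescent
    if (grid$has_saddle[b] || grid$n_equilibria[b] >= 3) "snlc"
    else if (grid$n_equilibria[b] >= 1) "ah"
    else NA_character_
  }
  for (ii in seq_len(n_I)) for (ip in seq_len(n_P - 1)) {
    a <- idx(ip, ii); b <- idx(ip + 1, ii)
    sa <- grid$omega_tilde[a] > 0; sb <- grid$omega_tilde[b] > 0
    if (sa == sb) next
    if (!sa) { tmp <- a; a <- b; b <- tmp }
    tag <- tag_edge(a, b)
    pt <- data.frame(P_tilde = mean(grid$P_tilde[c(a, b)]),
                     I_ext_tilde = grid$I_ext_tilde[a])
    if (identical(tag, "ah")) ah[[length(ah) + 1]] <- pt
    else if (identical(tag, "snlc")) snlc[[length(snlc) + 1]] <- pt
  }
  structure(list(grid = grid,
                 ah_boundary = do.call(rbind, ah) %||%
                   data.frame(P_tilde = numeric(), I_ext_tilde = numeric()),
                 snlc_boundary = do.call(rbind, snlc) %||%
                   data.frame(P_tilde = numeric(), I_ext_tilde = numeric()),
                 omega0 = omega0, n_P = n_P, n_I = n_I),
            class = "dopo_phase_diagram")
}

#' @export
print.dopo_phase_diagram <- function(x, ...) {
  cat("DOPO phase diagram:", x$n_P, "x", x$n_I, "cells;",
      sum(x$grid$omega_tilde > 0), "spiking\n")
  cat("  AH boundary points  :", nrow(x$ah_boundary), "\n")
  cat("  SNLC boundary points:", nrow(x$snlc_boundary), "\n")
  invisible(x)
}

#' @export
plot.dopo_phase_diagram <- function(x, ...) {
  Pg <- sort(unique(x$grid$P_tilde))
  Ig <- sort(unique(x$grid$I_ext_tilde))
  z <- matrix(x$grid$omega_tilde, length(Pg), length(Ig))
  graphics::image(Pg, Ig, z, xlab = expression(tilde(P)),
                  ylab = expression(tilde(I)[ext]),
                  col = grDevices::hcl.colors(32, "viridis"), ...)
  if (nrow(x$ah_boundary))
    graphics::points(x$ah_boundary, col = "red", pch = 19)
  if (nrow(x$snlc_boundary))
    graphics::points(x$snlc_boundary, col = "blue", pch = 19)
  invisible(x)
}

# firing rate (angular) of neuron 1 of a trajectory after a transient
measure_rate <- function(trajectory, discard = 0.25, neuron = 1L) {
  keep <- trajectory$times >= discard * max(trajectory$times)
  sub <- trajectory
  sub$times <- trajectory$times[keep]
  sub$v <- trajectory$v[, keep, drop = FALSE]
  sub$w <- trajectory$w[, keep, drop = FALSE]
  detect_spikes(to_polar(sub))$rate[neuron]
}
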