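#' Closed-form spiking frequency and period
#'
#' In the reduced single-neuron phase equation
#' \eqn{\dot\theta = \omega_0 + (P/\sqrt{8})\sin 4\theta} (obtained by
#' replacing R with its steady value \eqn{\sqrt 2 P}), the rotation period is
#' \deqn{T = \int_{-\pi}^{\pi} \frac{d\theta}{\omega_0 +
#'   (P/\sqrt 8)\sin 4\theta} = \frac{2\pi}{\sqrt{\omega_0^2 - P^2/8}},}
#' so the spiking frequency is
#' \eqn{\omega(P) = \omega_0\sqrt{1 - P^2 / (8\omega_0^2)}}, valid for
#' \eqn{0 \le P/\omega_0 \le \sqrt 8}. At the upper edge the period diverges
#' (saddle-node on the limit cycle) and `omega_spiking()` returns 0.
#'
#' @param P effective pump amplitude (vectorized).
#' @param omega0 natural frequency (default 1).
#' @return `omega_spiking()`: angular spiking frequency;
#'   `spiking_period()`: the period `2*pi/omega(P)` (requires
#'   `P/omega0 < sqrt(8)`).
#' @examples
#' omega_spiking(0)           # 1
#' omega_spiking(sqrt(8))     # 0 at the spiking-region edge
#' @export
omega_spiking <- function(P, omega0 = 1) {
  stopifnot(omega0 > 0)
  Pt <- P / omega0
  if (any(Pt < 0 | Pt > sqrt(8) + 1e-12))
    stop("P/omega0 must lie in [0, sqrt(8)]")
  w2 <- pmax(0, 1 - Pt^2 / 8)
  omega0 * sqrt(w2)
}

#' @rdname omega_spiking
#' @export
spiking_period <- function(P, omega0 = 1) {
  stopifnot(omega0 > 0)
  if (any(P / omega0 >= sqrt(8)))
    stop("period diverges at P/omega0 >= sqrt(8)")
  2 * pi / omega_spiking(P, omega0)
}

#' Steady-state squared amplitude
#'
#' The amplitude equation balances pump gain against saturation; averaging
#' over one rotation gives
#' \deqn{R = \frac{2P}{\pi}\int_{-\pi}^{\pi}\frac{d\theta}{3+\cos 4\theta}
#'       = \sqrt 2\, P,}
#' i.e. the circulating photon number grows linearly with pump. The
#' quadrature route evaluates the integral numerically and is exposed for
#' cross-checking against the closed form.
#'
#' @param P effective pump (>= 0; negative P is below threshold and returns 0
#'   with a warning).
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return steady R value(s).
#' @export
steady_radius <- function(P, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (any(P < 0)) {
    warning("P < 0 is below threshold; steady R is 0 there")
    P <- pmax(P, 0)
  }
  if (method == "closed") return(sqrt(2) * P)
  vapply(P, function(p) {
    q <- stats::integrate(function(th) 1 / (3 + cos(4 * th)), -pi, pi,
                          rel.tol = 1e-12, abs.tol = 0)$value
    2 * p / pi * q
  }, numeric(1))
}

#' Measured rotation frequency of the reduced phase equation
#'
#' Integrates the scalar reduced phase ODE
#' \eqn{\dot\theta = \omega_0 + (P/\sqrt 8)\sin 4\theta} with the
#' fixed-step RK4 scheme and reports the mean rotation rate over an integer
#' number of revolutions. Serves as the simulation-side counterpart of
#' [omega_spiking()].
#'
#' @param P effective pump (scalar).
#' @param omega0 natural frequency.
#' @param revolutions number of full turns to time (default 20).
#' @param dt integration step (default 1e-3).
#' @return measured angular frequency (2*pi / mean period).
#' @export
phase_ode_frequency <- function(P, omega0 = 1, revolutions = 20, dt = 1e-3) {
  stopifnot(omega0 > 0, P >= 0, P / omega0 < sqrt(8))
  a <- P / sqrt(8)
  f <- function(th) omega0 + a * sin(4 * th)
  th <- 0
  t <- 0
  target <- 2 * pi * revolutions
  # RK4 until the phase has advanced `revolutions` turns, then interpolate
  repeat {
    k1 <- f(th)
    k2 <- f(th + 0.5 * dt * k1)
    k3 <- f(th + 0.5 * dt * k2)
    k4 <- f(th + dt * k3)
    step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (th + step >= target) {
      t <- t + dt * (target - th) / step
      break
    }
    th <- th + step
    t <- t + dt
    if (t > 1e7) stop("phase failed to complete the requested revolutions")
  }
  target / t
}

#' Linear stability at an equilibrium
#'
#' Assembles the single-neuron Jacobian
#' \deqn{M = \begin{pmatrix} P - 3v_e^2 & -\omega_0 \\ \omega_0 &
#'   P - 3w_e^2\end{pmatrix}}
#' at an equilibrium `(v_e, w_e)` and classifies it from the exact 2x2
#' eigenvalues. At the origin the eigenvalues are exactly
#' \eqn{\lambda = P \pm i\omega_0}: the focus loses stability at P = 0
#' (Andronov-Hopf threshold).
#'
#' @param P effective pump.
#' @param omega0 natural frequency.
#' @param equilibrium numeric length-2 vector `(v_e, w_e)`; must satisfy the
#'   equilibrium conditions to residual < `tol`.
#' @param I_ext external bias (default 0).
#' @param tol equilibrium residual tolerance (default 1e-8).
#' @param marginal_tol |Re lambda| below this is classified "marginal"
#'   (default 1e-9).
#' @return list with `equilibrium`, `M`, `lambda` (complex pair),
#'   `classification` (one of stable-focus, unstable-focus, saddle,
#'   stable-node, unstable-node, marginal).
#' @export
linearize_at <- function(P, omega0, equilibrium, I_ext = 0,
                         tol = 1e-8, marginal_tol = 1e-9) {
  ve <- equilibrium[1]
  we <- equilibrium[2]
  res <- c(P * ve - ve^3 - omega0 * we + I_ext,
           P * we - we^3 + omega0 * ve)
  if (max(abs(res)) > tol)
    stop(sprintf("not an equilibrium: residual %.3e exceeds %.1e",
                 max(abs(res)), tol))
  M <- matrix(c(P - 3 * ve^2, omega0, -omega0, P - 3 * we^2), 2, 2)
  tr <- M[1, 1] + M[2, 2]
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  disc <- tr^2 / 4 - det
  lambda <- if (disc < 0) {
    complex(real = tr / 2, imaginary = c(1, -1) * sqrt(-disc))
  } else {
    as.complex(tr / 2 + c(1, -1) * sqrt(disc))
  }
  re <- Re(lambda)
  im <- Im(lambda)
  classification <-
    if (all(abs(re) < marginal_tol)) "marginal"
    else if (any(im != 0)) {
      if (re[1] < 0) "stable-focus" else "unstable-focus"
    } else if (prod(re) < 0) "saddle"
    else if (all(re < 0)) "stable-node"
    else "unstable-node"
  list(equilibrium = c(v = ve, w = we), M = M, lambda = lambda,
       classification = classification)
}

#' Locate and classify all equilibria of a single DOPO neuron
#'
#' Finds the real equilibria of the cubic system
#' \eqn{P v - v^3 - \omega_0 w + I_{ext} = 0},
#' \eqn{P w - w^3 + \omega_0 v = 0}
#' by Newton polishing from a fixed deterministic grid of starts over
#' \eqn{[-3\sqrt{1+|P|}, 3\sqrt{1+|P|}]^2} (the cubic nullclines confine all
#' equilibria to this box), merging duplicates within 1e-6, and classifies
#' each via [linearize_at()]. For large pump, equilibria appear near
#' \eqn{(\pm\sqrt{P/3}, \mp 2P\sqrt P/3\omega_0)} with real positive
#' eigenvalues — the saddle-node pairs of the SNLC regime.
#'
#' @param P effective pump.
#' @param I_ext external bias (default 0).
#' @param omega0 natural frequency (default 1).
#' @param grid_n starts per axis (default 13).
#' @return An object of class `dopo_stability`: list with `equilibria`
#'   (list of [linearize_at()] entries), `P`, `I_ext`, `omega0`, and
#'   convenience fields `n_equilibria`, `classifications`.
#' @export
find_equilibria <- function(P, I_ext = 0, omega0 = 1, grid_n = 13) {
  stopifnot(is.finite(P), is.finite(I_ext), omega0 > 0)
  Ffun <- function(x) c(P * x[1] - x[1]^3 - omega0 * x[2] + I_ext,
                        P * x[2] - x[2]^3 + omega0 * x[1])
  Jfun <- function(x) matrix(c(P - 3 * x[1]^2, omega0,
                               -omega0, P - 3 * x[2]^2), 2, 2)
  L <- 3 * sqrt(1 + abs(P))
  starts <- as.matrix(expand.grid(v = seq(-L, L, length.out = grid_n),
                                  w = seq(-L, L, length.out = grid_n)))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    x <- starts[k, ]
    ok <- FALSE
    for (it in 1:60) {
      Fx <- Ffun(x)
      if (max(abs(Fx)) < 1e-12) { ok <- TRUE; break }
      Jx <- Jfun(x)
      step <- tryCatch(solve(Jx, Fx), error = function(e) NULL)
      if (is.null(step)) break
      # damped Newton keeps the iterates inside the confinement box
      if (max(abs(step)) > L) step <- step * L / max(abs(step))
      x <- x - step
      if (max(abs(x)) > 4 * L) break
    }
    if (!ok) next
    dup <- any(vapply(roots, function(r) max(abs(r - x)) < 1e-6, logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- x
  }
  entries <- lapply(roots, function(r)
    linearize_at(P, omega0, r, I_ext = I_ext, tol = 1e-8))
  structure(list(equilibria = entries, P = P, I_ext = I_ext, omega0 = omega0,
                 n_equilibria = length(entries),
                 classifications = vapply(entries, `[[`, "",
                                          "classification")),
            class = "dopo_stability")
}

#' @export
print.dopo_stability <- function(x, ...) {
  cat(sprintf("Stability report at P = %g, I_ext = %g, omega0 = %g\n",
              x$P, x$I_ext, x$omega0))
  for (e in x$equilibria)
    cat(sprintf("  (%+.4f, %+.4f)  lambda = %s  %s\n",
                e$equilibrium[1], e$equilibrium[2],
                paste(format(e$lambda, digits = 4), collapse = ", "),
                e$classification))
  if (x$n_equilibria == 0) cat("  no equilibria found\n")
  invisible(x)
}

#' Critical pump of the saddle-node-on-limit-cycle transition
#'
#' Bisection on the existence of a finite-amplitude equilibrium of the
#' uncoupled polar system: an equilibrium with R > 0 requires
#' \eqn{R = 4P/(3+\cos 4\theta)} from the amplitude equation, and
#' substituting into the phase equation leaves
#' \eqn{\omega_0 + P\sin 4\theta/(3+\cos 4\theta) = 0}, which first admits a
#' solution when \eqn{P = \sqrt 8\,\omega_0}. The routine locates the edge
#' numerically (it does not use the analytic value).
#'
#' @param omega0 natural frequency.
#' @param tol bisection tolerance on P (default 1e-6).
#' @return the smallest P > 0 with an on-cycle equilibrium.
#' @export
snlc_threshold <- function(omega0 = 1, tol = 1e-6) {
  stopifnot(omega0 > 0)
  has_eq <- function(P) {
    g <- function(th) omega0 + P * sin(4 * th) / (3 + cos(4 * th))
    # min over one quarter period of the 4-fold symmetric drive
    opt <- stats::optimize(g, c(-pi / 4, pi / 4), tol = 1e-12)
    opt$objective <= 0
  }
  lo <- omega0      # below: pure rotation, no equilibrium
  hi <- 8 * omega0  # far above the edge
  if (has_eq(lo) || !has_eq(hi)) stop("bisection bracket failure")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_eq(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
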