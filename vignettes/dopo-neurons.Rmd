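---
title: "Spiking dynamics of paired-DOPO neurons: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking dynamics of paired-DOPO neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doponet)
```

## The model

A degenerate optical parametric oscillator (DOPO) locks its phase to 0 or
$\pi$ relative to its pump, so its in-phase amplitude is a continuous,
sign-bistable variable. An artificial spiking neuron is built from a pair of
such oscillators — a $v$-DOPO and a $w$-DOPO — coupled antisymmetrically.
The network dynamics integrated by `dopo_simulate()` are

$$\dot v_i = P_i v_i - v_i^3 + J_{vw} w_i + \gamma \sum_j J_{ij} v_j + I_{ext},$$
$$\dot w_i = P_i w_i - w_i^3 + J_{wv} v_i + \gamma' \sum_j J_{ij} w_j,$$

where $P_i = -1 + p_i$ is the pump measured from the oscillation threshold,
$J_{vw} J_{wv} < 0$ so that the pair rotates at the natural frequency
$\omega_0 = \sqrt{-J_{vw} J_{wv}}$, $J_{ij}$ is the symmetric synaptic
matrix, and $\gamma, \gamma'$ scale its effect on the two quadratures.
Each full $2\pi$ rotation of the pair in the $(v, w)$ plane is one spike.

**Units.** Internally the package defaults to $J_{vw} = -1$, $J_{wv} = +1$,
hence $\omega_0 = 1$, and all user-facing quantities follow the
dimensionless convention $\tilde X = X/\omega_0$ (and
$\tilde I_{ext} = I_{ext}/\omega_0^{3/2}$). The sign split ($J_{vw}$
negative) is deliberate: it is the convention under which the linearization
at the origin is $M = \begin{pmatrix} P & -\omega_0 \\ \omega_0 &
P\end{pmatrix}$ and the polar-form phase velocity is $+\omega_0$, so phases
advance and windings are positive.

## Excitability classes and the bifurcation structure

With $I_{ext} = 0$ the origin has eigenvalues exactly $P \pm i\omega_0$
(`linearize_at()`): for $P < 0$ the neuron is a stable focus (quiescent),
and at $P = 0$ it loses stability in an Andronov–Hopf (AH) bifurcation —
firing starts at the finite frequency $\omega_0$, the class-II signature.

In polar coordinates $\sqrt{R_i} e^{i\theta_i} = v_i + i w_i$
(`to_polar()`, `simulate_polar()`) the same dynamics read

$$\dot\theta_i = \omega_0 - J_k \sum_{j\ne i} \varepsilon_{ij}
  \sin(\theta_i - \theta_j) + \tfrac{R_i}{4}\sin 4\theta_i, \qquad
  \dot R_i = 2 P_i R_i + 2 J_k R_i \sum_{j\ne i} \varepsilon_{ij}
  \cos(\theta_i - \theta_j) - \tfrac{R_i^2}{2}(\cos 4\theta_i + 3),$$

with amplitude-ratio weights $\varepsilon_{ij} = \sqrt{R_j / R_i}$. Setting
$\dot R = 0$ and averaging gives the steady amplitude $R = \sqrt{2} P$
(`steady_radius()`, with the defining quadrature
$\tfrac{2P}{\pi}\int_{-\pi}^{\pi} d\theta / (3 + \cos 4\theta)$ exposed for
cross-checking) and the single-neuron phase equation
$\dot\theta = \omega_0 + (P/\sqrt 8) \sin 4\theta$, whose period integral
yields the frequency law

$$\omega(P) = \omega_0 \sqrt{1 - P^2 / (8\omega_0^2)}, \qquad
  0 \le \tilde P \le \sqrt 8 .$$

As $\tilde P \to \sqrt 8$ the $\sin 4\theta$ drive overcomes $\omega_0$,
equilibria appear on the cycle, and the period diverges — a saddle-node
bifurcation on the limit cycle (SNLC), the class-I signature.
`snlc_threshold()` locates this edge by bisection on equilibrium existence
rather than by the analytic value, so it doubles as a numerical check that
the edge is $\sqrt 8\,\omega_0$. `find_equilibria()` confirms the same
structure in the full model: beyond the edge, saddle/node pairs appear near
$(\pm\sqrt{P/3}, \mp 2P\sqrt P / 3\omega_0)$.

**How far the closed form holds.** $\omega(P)$ is derived from the polar
system under the steady-amplitude approximation. Integrating the reduced
phase ODE reproduces it essentially exactly (the frequency-law check in
`scripts/acceptance.R` reports the worst-case error over
$\tilde P \in \{0.5, \dots, 2.5\}$ at the $10^{-7}$ % level), but the full
two-variable model rotates systematically slower as the SNLC edge is
approached: the same check measures a worst-case deviation of order 10% at
$\tilde P = 2.5$ (about 2% at $\tilde P = 1$), and the simulated spiking
edge sits slightly below $\sqrt 8$. This is a property of the
approximation, not of the integrator — the polar simulation, an exact
change of variables, tracks the full model to better than 0.1%.

## Observables

* `detect_spikes()` — the spike definition is one full $2\pi$ winding of
  the unwrapped phase. The $\sin 4\theta$ potential has four-fold symmetry,
  so quarter-turn definitions would be ambiguous; the full revolution is the
  rotation the frequency law describes, and the detector tag is stored with
  every train. Windings are only counted while $R$ exceeds an amplitude
  floor (`min_R`, default $10^{-3}$): subthreshold decay still rotates at
  $\omega_0$ but carries no spike energy, and ungated counting would report
  firing from a quiescent neuron. Firing rates are angular
  ($2\pi \times$ revolutions per unit time), directly comparable to
  $\omega(P)$. An amplitude-peak detector is available as an alternative.
* `order_parameter()` — $r = |N^{-1}\sum_j e^{i\theta_j}|$, per cluster and
  global.
* `phase_increment()` — phase advance per fixed reporting window; stretches
  with $\Delta\theta \approx 0$ expose class-I stalling near the saddle
  ghosts.
* `ising_energy()`, `local_energy()` — $E_{Ising} = -\sum_{i<j} J_{ij}
  \sigma_i \sigma_j$ and $E_{loc,i} = -\sum_j J_{ij}\sigma_i\sigma_j$ with
  $E_{Ising} = \tfrac12 \sum_i E_{loc,i}$ exact.

## Self-tuning synchronization

In a cluster of $N$ all-to-all coupled neurons
($\gamma = \gamma' = J_k$), coherent input renormalizes the pump:
$P' = P + r (N - 1) J_k$ under $\varepsilon_{ij} \approx 1$
(`renormalized_pump()`). Since $\omega(P)$ decreases with pump,
synchronization slows the whole cluster down and pushes it from class-II
toward class-I — the firing rate becomes a collective variable.

`sync_experiment()` reproduces this protocol with 4 clusters of 15 neurons.
Defaults a practitioner should know:

* **Pump assignment** (`assign_pump_spread()`): the per-cluster pump values
  are not published for the original experiment, so the builder exposes
  them as explicit configuration with a documented default — cluster
  centres evenly spaced over $\tilde P \in [0.6, 1.8]$ with a within-cluster
  spread of 0.22, evenly spaced per neuron. This keeps every neuron safely
  inside the spiking domain at zero coupling, gives clearly separated
  cluster rates (the intrinsic spread), and places the slowest cluster
  close enough to the SNLC edge that the strongest default coupling
  ($\tilde J_k = 0.075$, where $r (N-1) J_k \approx 1$) drives it into
  stalling — the regime where intermittent global synchronization appears.
* **Inter-cluster topology**: "sparsely connected" is realized as a seeded
  default of 2 random edges per cluster pair at the intra-cluster weight;
  both knobs are configuration.
* **Measurement**: the first 25% of each run is discarded as transient;
  rates and order parameters are computed from the remainder of a
  600-time-unit run (about 90 natural periods).

## Ising annealing

`ising_network()` encodes a symmetric instance on the $v$-DOPOs only
($\gamma' = 0$, $I_{ext} = 0$); the spin is the binary sign of $v$
(`spin_readout()`). The v-feedback is applied with gain $+J_k J_{ij}$ —
the sign for which a ferromagnetic pair freezes aligned and the
rotating-frame average of the coupling gives
$P' = P_0 - \tfrac12 J_k E_{loc,i}$ (`renormalized_pump_ising()`).
Descriptions of measurement-and-feedback hardware sometimes quote this gain
with the opposite sign because the injected feedback is measured with an
inverted convention; with the model equations as written above, a negative
gain demonstrably maximizes the energy instead (the package's two-spin test
makes this check explicit).

Because rotation is repeated sign flipping, the renormalized pump makes
energetically unstable neurons (high $E_{loc}$) fire faster while stable
ones freeze first — a selective spin-flip heuristic akin to extremal
optimization. `run_anneal()` ramps a node-independent pump linearly from
$\tilde P = -0.5$ (below threshold, so the state grows from seeded noise)
to $3.2$ (beyond the $\sqrt 8$ edge, so the dynamics freeze into a readout
state) over 500 time units; the headline statistic is the best energy seen
anywhere along the trace, since the energy is monitored continuously.
`run_trials()` batches seeded trials (seed = base + trial index) and scores
them against the exact minimum from `brute_force_ground_state()`
(exhaustive enumeration up to 24 spins, global flip symmetry halved).

In the deterministic, noiseless simulation the firing-count/local-energy
rank correlation is already positive at weak coupling
($\tilde J_k \approx 0.08$) because rank correlation registers even a tiny
systematic rate differential; it vanishes only as $\tilde J_k \to 0$.
Hardware measurements of the same quantity at weak coupling sit near zero,
plausibly because physical noise swamps that small effect — a caveat when
comparing the simulated correlation against measured ones.

## Numerical choices

* **Integrator**: fixed-step classical RK4 (explicit Euler available),
  default $dt = 10^{-2}/\omega_0$; the equations are smooth and non-stiff,
  and a fixed step keeps every run bit-reproducible from its seed. A
  convergence test verifies the fourth-order error scaling.
* **Initial conditions**: i.i.d. zero-mean Gaussian noise, default
  amplitude $10^{-3}$, emulating growth from amplified vacuum noise without
  modelling quantum statistics; the integration itself is deterministic.
* **Polar amplitude floor**: $R$ is floored at $10^{-12}$ during polar
  integration (the phase is undefined at zero amplitude) and affected
  samples are flagged.
* **Equilibrium search**: damped Newton from a fixed $13 \times 13$ grid
  over $[-3\sqrt{1+|P|}, 3\sqrt{1+|P|}]^2$ (the cubic nullclines confine
  all equilibria), duplicates merged at $10^{-6}$; $|\mathrm{Re}\,\lambda| <
  10^{-9}$ is classified "marginal" to avoid mislabelling the AH threshold.
* **Phase-diagram scan**: each cell is simulated for 200 time units and the
  rate measured on the last 75%; boundary edges between spiking and
  quiescent cells are tagged AH when the quiescent side holds a single
  focus, SNLC when it holds saddle/node pairs.
* **Problem sizes**: the test suite and acceptance script use the
  experiment's own cluster geometry (4 × 15 neurons, 600 time units) and
  scale the annealing benchmark to 16 spins at density 0.5 with 20 trials
  per coupling, where the exact oracle is available; the original 150-spin
  benchmark instance is unpublished and out of scope.

## What the simulations do and do not show

The synthetic networks reproduce the model's collective phenomena:
within-cluster rate collapse under weak coupling, monotone rate decrease
with coupling strength, intermittent global synchronization, and the
coupling-dependent annealing quality and firing/energy correlation. They do
not emulate the photonic hardware: no cavity round trips (coupling acts
continuously, not via discrete measurement-and-feedback), no quantum or
detector noise, no pump depletion or gain saturation beyond the cubic term,
and no quadrature components. Agreement of a property here is therefore
evidence about the model, not about any particular physical realization;
an optional 8-bit weight quantization (`network_coupling(quantize_bits =
8)`) is provided for fidelity experiments but is off by default.
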