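---
title: "Sampling, inference, and ring-attractor dynamics in spike-coding networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling, inference, and ring-attractor dynamics in spike-coding networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ringsampler)
```

# The model

`ringsampler` simulates spike-coding networks (SCNs): recurrent spiking
networks whose spikes greedily minimize the error between a low-dimensional
signal and its linear readout `zhat = D r`, where `r` are leaky filtered
spike trains (`r' = -lambda r + o`) and `D` is a fixed M-by-N decoding
matrix.  The greedy rule gives each neuron a threshold
`T_i = (nu lambda + mu lambda^2 + |D_i|^2)/2`, a fast balancing
connectivity `Omega_f = -D^T D` that delivers each spike's readout jump to
every voltage (the diagonal carries the effective reset; there is no
separate reset), and a slow connectivity that imposes the desired readout
dynamics.

Three layers of dynamics are built on this substrate:

1. **Langevin sampling.**  For a polynomial energy `U(z)` with
   `P(z) = exp(-U)/Z`, the readout follows the overdamped Langevin equation
   `dz = -(1/tau_s) grad U(z) dt + sqrt(2/tau_s) dW`.  In the network this
   becomes a voltage drift `D^T(-(1/tau_s) grad U(zhat) + lambda zhat)`
   plus voltage noise `sqrt(2/tau_s) D^T xi`.  Because `grad U` of a
   polynomial is itself polynomial, the drift can be written as per-degree
   Kronecker-structured slow weights acting on powers of `r`
   (`build_slow_weights()` materializes them); at simulation time the
   package computes the drift unfactored in readout space and lifts it by
   `D^T`, which is numerically identical and unambiguous.
2. **Sampling-based inference.**  When the stimulus is observed only
   through noisy counts `sigma` from a sensory population with rate kernel
   `phi(z)`, the posterior under a flat prior has
   `grad U(z) = sum_i grad phi_i(z) (1 - sigma_i / phi_i(z))` (Poisson), so
   the same machinery samples the posterior.  Exponential kernels give an
   exactly implementable drift; linear and logistic kernels are handled by
   truncated expansions of `1/phi` whose order `K` is a population
   parameter, with the exact gradient available for validation.  The
   Bernoulli, binomial, and geometric families use the logistic kernel
   value as their success probability.
3. **Head-direction (HD) tracking.**  Heading is represented in Cartesian
   coordinates `(x, y)` to avoid wrap-around, with a soft ring prior that
   acts as an attractor.  Angular velocity enters through a Poisson
   population whose per-step count mean is `exp(beta_i omega dt)` (count 1
   at rest).  A Bayesian-filter step combines the previous estimate with
   the current observation; the derived normalizer
   `alpha = 1 + dt beta^T beta` is the weight of the prior relative to one
   observation.  The resulting per-step update is a rotation
   `(dt/alpha) beta^T(sigma - 1) (-y, x)`, an attractor term
   `-(gamma dt/alpha) z (x^2+y^2 - 2 rho^2)`, and noise
   `sqrt(2 dt/alpha) xi`.  The same dynamics can run as an explicit
   8-neuron spiking network (`build_hd_network()`).

# Parameters that matter

* `lambda` (1/s): voltage and filtered-train leak.  Default 10 for
  tracking and head-direction runs; the slow-leak regime (0.5) is the
  delocalized-bump condition studied by the leak-manipulation analysis.
* `dt` (s): Euler-Maruyama step.  1e-4 for networks, 1e-3 for behavioral
  signals and encoders (a tenfold separation of timescales).  Stability
  needs `lambda dt << 1`; sampler accuracy needs
  `dt * max|U''| / tau_s << 1` (see Numerical choices).
* `tau_s` (s): sampling timescale.  0.01 for free sampling; 0.1 for
  posterior inference, where posteriors are much sharper than the
  free-sampling targets.
* `nu`, `mu`: linear and quadratic spike costs; zero by default (they
  raise thresholds and, for `mu`, damp individual rates).
* Decoders: `line_decoder(N, a)` uses columns of both signs so a 1-D
  readout can move both ways (default `a = 0.1`, N = 20);
  `ring_decoder(N, rho)` places columns at angles `2 pi i / N` with norm
  `rho / N`.  The per-spike readout jump equals the column norm, so both
  quantization and the tracking friction shrink as `1/N`.
* Encoder gain: `hd_config()` defaults to `Np = 10` neurons with
  alternating gains of `+/-100` at `dt = 1e-3`, i.e.
  `beta^T beta dt = 100` and `alpha = 101`.  Two properties motivated
  this choice: the per-step observation gain `beta^T beta dt / alpha`
  must be close to 1 for velocities to integrate without systematic
  shrinkage, and the antisymmetric arrangement cancels the even-order
  bias of the exponential kernel (the residual relative bias is
  `(b omega dt)^2/6`, under 3% at 4 rad/s).  Lower gain means less
  informative spikes; the drift analysis uses `b = 30` as its
  high-noise condition.
* `gamma`: attractor strength, default 4.  In the low-dimensional map the
  attractor is divided by `alpha`, as the filter derivation requires.  In
  the spiking network the attractor enters the voltage equation at full
  strength: with `alpha ~ 100` the scaled-down version cannot hold the
  readout on the ring against spike quantization and the bump collapses,
  while the full-strength term (which leaves the fixed point unchanged)
  sustains it.  Both conventions are implemented where they belong.
* Ring prior: the stated prior `exp[-(x^2+y^2)(x^2+y^2-2 rho^2)]` has its
  true gradient proportional to `(x^2+y^2-rho^2)`, stabilizing radius
  `rho`, while the published update uses the factor `(x^2+y^2-2 rho^2)`,
  stabilizing `sqrt(2) rho`.  Both are exposed (`mode = "literal"` /
  `"exact"`), each pinned to its own fixed point in the tests; no intent
  is guessed.

# What the generators emulate — and what they do not

`make_trajectory()` produces constant, piecewise, Ornstein-Uhlenbeck, and
sinusoidal angular-velocity profiles with wrapped integration; the OU kind
is the "naturalistic" stand-in (default timescale 0.5 s, stationary sd
2 rad/s).  `emit_spikes()` and `encode_velocity()` draw independent counts
per step from the configured family.  Real heading data differ in ways
these generators do not capture: velocity statistics are neither stationary
nor Gaussian, sensory neurons are correlated and adapt, and landmarks are
not a single Poisson channel fixed at angle zero.  Passing tests therefore
demonstrate the internal consistency of the model at its stated
conditions — correct sampling, inference, integration, and reset under its
own noise model — not performance on biological recordings.

# Numerical choices

* Explicit Euler-Maruyama throughout, Wiener increments scaled by
  `sqrt(dt)`.  The discrete stationary variance of a linearized sampler is
  inflated by roughly `1/(1 - U'' dt / (2 tau_s))`; the inference default
  `tau_s = 0.1` keeps this bias near 2% for posteriors with curvature
  ~50, and the free-sampling default 0.01 does the same for the wide
  test energies.
* At most one spike per step, the neuron with the largest threshold
  violation, ties to the lowest index.  A brute-force cost oracle in the
  tests confirms the greedy choice never increases the instantaneous
  reconstruction error.
* Thinning: distributional tests thin Langevin output at interval
  `tau_s` (recorded in outputs) to blunt autocorrelation.
* Divergence guards: samplers abort when `|z|` exceeds ten times the
  outermost stationary point of `U`; head-direction maps and networks
  carry analogous bounds.  Odd-degree energies are refused before
  sampling (`check_normalizable()`).
* Normalizability for `M > 1` is decided numerically (energy growth on
  expanding direction shells plus a stabilizing grid integral), since no
  simple leading-coefficient rule exists in several variables.
* Degenerate inputs: zero readouts decode to an `NA` angle with radius 0;
  unvisited tuning bins are reported as `NA`, never interpolated; empty
  spike trains yield flagged `NA` correlation rows.
* Initial conditions: `init_trains_at()` places the readout at a target
  point by a clipped ridge pseudo-inverse, rescaled after clipping
  (filtered trains are non-negative, which otherwise halves the readout).

# Design choices where the design was open

* The two published filtered-train conventions differ only by a fixed
  rescaling of `r`; the default follows the explicit simulation form
  (`r' = -lambda r + o`, `zhat = D r`), with the alternative available as
  `filter_variant = "methods"`.
* The linear-term bookkeeping of the slow weights (whether the leak enters
  with `+lambda` or `-lambda`) is resolved by computing the drift
  unfactored from the voltage equation, which is unambiguous; the
  materialized weights follow the same composition and are verified by a
  contraction oracle.
* The rotational term is oriented so that a positive encoded velocity
  advances the decoded angle counter-clockwise, consistent with the 1-D
  update (the small-angle identity in Cartesian coordinates is
  `sin(th_t - th_{t-1}) = y_t x_{t-1} - x_t y_{t-1}`).
* The logistic-kernel expansion uses the Taylor forms of the kernel
  derivative (`A(1/4 - (Az)^2/16)`) and of its reciprocal
  (`1 + exp(-Az)`), validated against exact gradients by finite
  differences.
* Head-direction analyses measure bump velocity on the low-dimensional
  sampler when skewness is at issue: the count-driven skew
  (`~0.04` at 4 rad/s under the default encoder) is an order of magnitude
  below the spike-quantization noise floor of the 8-neuron network, and
  only the map resolves its sign at feasible run lengths.  Mirror
  symmetry of the +/- velocity distributions holds in both
  implementations.
* The landmark sits at angle 0 at distance `sqrt(2) rho` (on the
  literal-mode attractor circle), with Poisson gain `c = 20`; the reset
  term is implemented literally, including its `-2 sigma` factor.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
every statistic is resolvable at its stated tolerance: 60 s sampler runs
(6e5 steps) for moment and KS checks, 10 s head-direction runs per
velocity condition, 20 repetitions for drift and reset ensembles, 300 s
of the low-D map for velocity-distribution statistics, and 150 s of
noise-free map time for the slowly relaxing (`gamma/alpha ~ 0.04`)
attractor transient.

# Known limitations

* Inference networks integrate dynamic count streams only for the
  exponential kernel; linear/logistic kernels support static (single
  observation) posteriors through their polynomial form.
* The truncated logistic gradient is one-dimensional, as the parabola
  approximation is stated for scalar stimuli.
* Quadrature densities and posteriors cover one and two dimensions;
  higher-dimensional targets would need importance sampling.
* The visual-remapping plasticity that would let a landmark population
  learn its angular offset is out of scope; the landmark is hard-wired
  at angle 0.
* With very few neurons and coarse decoder norms the self-referential
  readout loses radius through spike quantization; the defaults
  (`norm = rho/N`, network step ten times finer than the encoder step)
  were chosen so an 8-neuron ring tracks within a few percent, and the
  vignette section on parameters explains the trade-off.
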