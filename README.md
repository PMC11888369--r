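# ringsampler

Spike-coding networks that sample, infer, and track head direction.

`ringsampler` is a simulation and analysis toolkit for computational
neuroscientists studying how spiking networks can perform probabilistic
computation.  It implements three connected ideas:

1. **Langevin sampling with spikes.**  A spike-coding network (SCN)
   represents a signal z ∈ R^M through a linear readout ẑ = D r of leaky
   filtered spike trains (ṙ = −λr + o).  Spikes are emitted greedily —
   neuron i fires when its voltage exceeds T_i = ‖D_i‖²/2 — which yields
   fast balancing weights Ω_f = −DᵀD and slow computational weights.
   Setting the slow drift to Dᵀ(−(1/τ_s)∇U(ẑ) + λẑ) with voltage noise
   √(2/τ_s) Dᵀξ makes the readout follow overdamped Langevin dynamics,

       dz = −(1/τ_s) ∇U(z) dt + √(2/τ_s) dW,

   whose stationary law is P(z) ∝ e^{−U(z)} for any normalizable
   polynomial energy U.  The polynomial gradient maps onto per-degree
   Kronecker-structured multiplicative synapses (Ω_s^{(d)} = Dᵀ A_d D^{⊗d}).
2. **Sampling-based inference.**  When a stimulus is seen only through
   noisy counts σ from a sensory population with rate kernel φ(z)
   (Poisson, Bernoulli, binomial, or geometric), the flat-prior posterior
   has ∇U(z) = Σ_i ∇φ_i(z)(1 − σ_i/φ_i(z)), so the same network samples
   the posterior over the stimulus — the readout is a stream of posterior
   samples, carrying the full uncertainty.
3. **A head-direction ring network.**  Heading is held in Cartesian
   coordinates with a soft ring prior acting as an attractor
   (−γ z(‖z‖² − 2ρ²)), angular velocity arrives as Poisson counts with
   per-step mean exp(β_i ω dt), and a Bayesian-filter update with
   normalizer α = 1 + dt βᵀβ combines the previous estimate with each
   observation.  The result — inference, integration, and attractor
   dynamics in one 8-neuron spiking network — reproduces a rotating
   activity bump, heading-tuned neurons, velocity-dependent bump
   statistics, noise-dependent drift, and landmark-driven resets.

The package ships a compiled Euler–Maruyama engine (Rcpp), a direct
(non-spiking) Langevin reference sampler, synthetic trajectory and
spike-train generators, and analysis routines for subthreshold
cross-correlations, two-timescale spike correlations, tuning curves,
bump-velocity statistics, and drift curves.  See the vignette
(`vignettes/ring-sampling-methods.Rmd`) for the model assumptions,
parameter choices, and numerical details.

## Worked example

Sample from the bimodal double-well density P(z) ∝ exp(−z⁴ + 2z²) with a
20-neuron spiking network, and compare against trapezoid quadrature:

```r
library(ringsampler)

U <- bimodal_energy()                       # U(z) = z^4 - 2 z^2
params <- scn_params(lambda = 10, dt = 1e-4, tau_s = 0.01)
net <- build_sampler_network(U, line_decoder(20, 0.1), params)
sim <- simulate_network(net, duration = 20, seed = 1)
#> <scn_sim> 200000 steps, 20 neurons, 155848 spikes

th <- thin_samples(sim$readout[, 1], 1e-4, 0.01, burn_in = 0.5)
cmp <- compare_samples(th, density_quadrature(U, -3, 3, 1201))
round(cmp$moments, 3)
#>          mean   var skewness kurtosis
#> sample -0.003 0.788   -0.018    1.649
#> target  0.000 0.833    0.000    1.561
cmp$ks
#> [1] 0.03
```

The thinned readout reproduces the target's moments (variance within 6%,
skewness near zero, the platykurtic two-mode shape) with a
Kolmogorov–Smirnov distance of 0.03.

Track a constant 4 rad/s turn with the 8-neuron head-direction network:

```r
cfg <- hd_config()               # 10 encoder neurons, gains +/-100, alpha = 101
traj <- make_trajectory("constant", list(omega = 4), duration = 10,
                        dt = cfg$dt)
rec <- encode_velocity(traj, cfg, seed = 2)
D <- ring_decoder(8, 1)
net <- build_hd_network(cfg, D, scn_params(lambda = 10, dt = 1e-4, tau_s = 1),
                        rec)
sim <- simulate_network(net, seed = 3, r0 = init_trains_at(D, c(sqrt(2), 0)))
dec <- decode_angle(sim)
mean(wrap_diff(dec$theta_hat)) / 1e-4   # decoded mean angular velocity
#> [1] 4.017
mean(dec$radius)                        # readout stays on the ring
#> [1] 1.412
```

The decoded heading advances at 4.017 rad/s (0.4% from the true 4 rad/s)
while the readout holds the attractor radius √2·ρ ≈ 1.414.

End-to-end experiments (sampling, inference, darkness tracking, landmark
reset, prediction statistics) run from a YAML/JSON config via
`run_experiment()`, or from the shell through the thin wrapper
`inst/cli/ringsampler.R`.

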