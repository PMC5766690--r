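# phasebayes

Bayesian estimation of coupled phase-oscillator dynamics from
multi-neuronal spike times.

Populations of rhythmically firing neurons — and coupled limit-cycle
oscillators generally — can be reduced to phase variables obeying

    dφ_i/dt = ω_i + Σ_{j≠i} Γ_ij(φ_i − φ_j) + ξ_i(t),

with natural frequencies ω_i (rad/ms), 2π-periodic interaction functions
Γ_ij, and white phase noise of intensity D_i (rad²/ms).  Extracting
ω̂_i, Γ_ij and D_i directly from data reveals the locked states,
synchronization properties, and effective connectivity of the circuit
without ever fitting a biophysical model.  In electrophysiology the
catch is that only **spike times** are recorded, not continuous phases.
`phasebayes` is for experimenters and modelers who have multi-unit spike
trains of autonomously firing neurons and want the reduced phase model
behind them.

The method: each spike is phase zero and the phase is linearly
interpolated in between; on a uniform grid the phase increments become a
linear regression on Fourier terms cos(mΔφ_ij), sin(mΔφ_ij) of the
pairwise phase differences.  A conjugate normal-inverse-gamma prior
yields the joint posterior of all coefficients and the noise variance
(σ² = 2D/Δt) in closed form, and the harmonic count M ∈ {1,…,5} is
selected by the closed-form model evidence.  Synaptic connectivity is
then inferred by thresholding the summed Fourier power
P_ij = Σ_m (a_ij^(m)² + b_ij^(m)²) with Otsu's method and scored with
Matthews' correlation coefficient; binned coherence
κ_ij = Σ x_i x_j / √(Σ x_i Σ x_j) characterizes the network state.  A
bundled simulator generates ground-truth oscillator networks so the
whole pipeline is testable end to end, and a phase-response-curve module
(including an adjoint solver for user-supplied limit-cycle ODEs) derives
the theoretical Γ the estimates should match.

## Worked example

Simulate 1000 firing cycles of an 8-neuron inhibitory network (3 random
in-edges per neuron, 10% frequency dispersion, phase noise
4×10⁻⁴ rad²/ms), then recover the model from the spikes alone:

```r
library(phasebayes)

cfg <- synth_config(n_units = 8, k_in = 3, seed = 42)
net <- generate_network(cfg)
ds  <- simulate_phases(net, cycles_to_duration(net, 1000), seed = 43)
ds
#> <spike_dataset> 8 units on [ 0 , 23947.2 ] ms; 7997 spikes (median 995 per unit)

fit <- fit_network(ds)
fit$fits[["1"]]
#> <phase_fit> receiver 1 - M = 1 , omega_hat = 0.28555 rad/ms ,
#>             D_hat = 0.0001826 rad^2/ms, T = 1995
```

The evidence selected one harmonic (the generating coupling is a pure
sine), and the effective frequency 0.286 rad/ms is receiver 1's natural
frequency plus the mean inhibitory drive.  The estimated interaction
from a true presynaptic partner matches the ground truth:

```r
coupling_estimate(fit$fits[["1"]], 3)        # estimated, rad/ms
#>   a: -0.00225
#>   b: -0.005971
coupling_of(net, 1, 3)                       # simulated truth
#>   a: 0
#>   b: -0.006

interaction_credible_band(fit$fits[["1"]], 3, pi / 2)
#>       dphi         mean           lo          hi
#> 1 1.570796 -0.005970853 -0.006584726 -0.00535698
```

Connectivity inference over all 56 ordered pairs recovers the graph
almost perfectly at this data length:

```r
infer_connections(fit, truth = net$adjacency)
#> <connectivity_inference> threshold = 0.428 ; 23 edges inferred
#>   MCC = 0.964

median(l2_distance_table(fit, net)$distance)
#> [1] 0.000711      # rad/ms, against couplings of magnitude 0.006
```

A command-line front end wrapping the same functions (subcommands
`simulate`, `estimate`, `connections`, `evaluate`, `coherence`,
`prc-gamma`, `scenario`) is installed at
`system.file("cli/phasebayes.R", package = "phasebayes")`.

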