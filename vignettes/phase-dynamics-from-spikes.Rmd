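---
title: "Estimating coupled phase-oscillator dynamics from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating coupled phase-oscillator dynamics from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasebayes)
```

## The model

A population of rhythmically firing neurons (or any weakly coupled
limit-cycle oscillators) is reduced to phases $\phi_i$ obeying

$$\frac{d\phi_i}{dt} \;=\; \omega_i \;+\; \sum_{j \ne i}
  \Gamma_{ij}(\phi_i - \phi_j) \;+\; \xi_i(t),$$

where $\omega_i$ is the natural frequency (rad/ms), $\Gamma_{ij}$ is the
$2\pi$-periodic interaction function describing how sender $j$ accelerates
or delays receiver $i$ as a function of their phase difference, and
$\xi_i$ is white noise with intensity $D_i$
($\langle\xi_i(t)\xi_i(s)\rangle = 2D_i\,\delta(t-s)$, rad²/ms).  Each
interaction function is a finite Fourier series of $M_i$ harmonics; the
constant term of each series is not separable from $\omega_i$ and is
absorbed into the effective frequency $\hat\omega_i$.

The package estimates $\hat\omega_i$, $D_i$, and all $\Gamma_{ij}$ of a
receiver **from spike times alone**.  A spike marks phase zero; between
consecutive spikes the phase is interpolated linearly
($\phi$ gains $2\pi$ per interspike interval).  On a uniform grid of step
$\Delta t$ the phase increments $\delta(\tau) =
(\phi_i(\tau{+}1)-\phi_i(\tau))/\Delta t$ form a linear regression on an
intercept plus $\cos(m\,\Delta\phi_{ij})$, $\sin(m\,\Delta\phi_{ij})$
columns, with noise variance $\sigma^2 = 2D_i/\Delta t$.  A conjugate
normal-inverse-gamma prior over (coefficients, $\sigma^2$) gives the
posterior and the model evidence in closed form; the harmonic count
$M_i \in \{1,\dots,5\}$ is chosen by maximizing the evidence, ties going
to the smaller count.

Downstream, connectivity is inferred from the summed Fourier power
$P_{ij} = \sum_m (a_{ij}^{(m)2} + b_{ij}^{(m)2})$ of each estimated
interaction: powers are normalized by their maximum, split by Otsu's
threshold (exhaustive over the observed values), and scored against a
known network with Matthews' correlation coefficient.  Synchrony of the
raw spike trains is summarized by the binned coherence
$\kappa_{ij} = \sum_n x_i x_j/\sqrt{\sum_n x_i \sum_n x_j}$.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dt` | mean ISI / 2 | ms | phase sampling interval (see below) |
| `m_range` | 1–5 | – | candidate harmonic counts |
| `prior_scale` | $10^3$ | – | coefficient prior scale ($\Sigma = 10^6 I$) |
| `alpha0`, `beta0` | $10^{-3}$ | – | vague inverse-gamma on $\sigma^2$ |
| `period_mean` | 25 | ms | generator: mean natural period (40 spikes/s) |
| `sigma_rel` | 0.1 | – | generator: relative SD of $\omega_i$ |
| `D` | $4\times10^{-4}$ | rad²/ms | generator: phase-noise intensity |
| `coupling_scale` | 0.006 | rad/ms | generator: per-edge coupling magnitude |
| `k_in` | 8 (of 64) | – | generator: in-degree |
| `h` | period/1000 | ms | generator: integration step |

**Why `dt` is half the mean interspike interval.**  Linear interpolation
makes the phase piecewise linear between spikes, so each cycle contributes
essentially one independent increment; the within-cycle samples of
$\delta$ are copies of the same ISI average.  Sampling much faster than
the firing rate therefore multiplies the *apparent* sample count without
adding information, and the evidence — which assumes independent
residuals — becomes overconfident by roughly the oversampling factor.  In
practice that overconfidence makes it select the maximal harmonic count
even for single-harmonic couplings, and the weakly constrained high
harmonics of slowly drifting pairs then take on arbitrarily large values.
Two samples per mean cycle keep the independence violation mild while
still resolving the within-cycle curvature of the phase differences
(harmonic resolution in $\Delta\phi$ comes from the slow drift of phase
differences across many cycles, not from fast sampling within a cycle).
`dt` remains configurable for sensitivity analyses.

**Why `coupling_scale` defaults to 0.006 rad/ms.**  The generator
emulates an inhibitory network whose units fire at 40 spikes/s in
isolation ($\omega = 2\pi/25 \approx 0.251$ rad/ms) and are slowed to a
~31 ms period by 8 inhibitory synapses.  That slowdown fixes the mean
per-synapse drive at $(2\pi/31 - 2\pi/25)/8 \approx -0.006$ rad/ms, and
we take the harmonic amplitude to be of the same order.  The ratio of
coupling to frequency dispersion is the critical quantity: at this scale
a 10% spread of natural frequencies keeps the network asynchronous, which
is precisely the regime in which phase differences sweep their full range
and the regression is identifiable.  Couplings several times stronger
entrain the whole network, phase differences freeze, and estimation
degenerates — reproducing that transition is itself one of the package's
test properties rather than something to be avoided by construction.

## The synthetic-data generator

`generate_network()` draws natural frequencies
$\omega_i = (2\pi/\bar T)(1+\nu_i)$, $\nu_i \sim N(0, \sigma_{rel}^2)$
(redrawn while $\omega_i \le 0$, which deviates from normality only at
large `sigma_rel`), and a random directed graph with exactly `k_in`
in-edges per unit.  All edges share one coupling template: `in_phase`
($b_1 = -s$; a symmetric pair locks at phase difference 0) or `bistable`
($b_1 = -0.2s$, $b_2 = -s$; locked states at both 0 and $\pi$).
`simulate_phases()` integrates the stochastic phase equation by
Euler–Maruyama at step `h = period_mean/1000` and emits a spike at the
linearly interpolated crossing of each multiple of $2\pi$; everything is
deterministic given the seed.  `scale_network_config()` doubles the size
and in-degree while halving the coupling, the convention used for
network-size scaling experiments.

What the generator does *not* emulate: conductance-based membrane
dynamics (spike shapes, ionic currents, synaptic kinetics), rate
adaptation, non-stationarity, and unequal synaptic weights.  Passing
tests on these data therefore demonstrates correctness of the estimator
for data that truly follow the phase equation; on real recordings the
additional model mismatch (e.g. amplitude effects and bursting) is
untested territory.

## Numerical choices

* Posterior updates use Cholesky factorizations with a single
  diagonal-jitter retry ($10^{-10}$ of the diagonal scale); a genuinely
  singular system — synchronous data — raises an error instead of
  returning an unstable posterior.
* Root finding for locked states scans a 512-point grid, bisects each
  sign change to tolerance, and classifies stability by the analytic
  derivative of the sine series; slopes within $10^{-9}$ of zero are
  labelled `degenerate` rather than guessed.
* PRC averaging integrates $Z(\tau)\,k(\tau - \Delta\phi\,T/2\pi)$ by the
  trapezoidal rule after shifting the kernel's wrap discontinuity to the
  integration boundary (the substitution keeps the rule $O(h^2)$); delta
  kernels are evaluated in closed form.
* The adjoint PRC solver refines the period on a Poincaré section
  orthogonal to the flow (transversal by construction), interpolates the
  cycle with periodic splines, and iterates backward integration of
  $\dot Z = -J^\top Z$ with per-period renormalization until the solution
  is periodic; the convention $Z \cdot f = 2\pi/T$ is enforced at the
  initial point and verified pointwise in the tests.
* Otsu's threshold is found by exhaustive search over splits of the
  sorted observed values (exact for the few hundred pairs arising here),
  ties toward the smaller threshold.
* The L2 coefficient distance takes the square root by default (making it
  a metric); `squared = TRUE` gives the plain sum of squares for
  comparison with conventions that omit the root.

## Design choices that were genuinely open

* **Shared grid.**  All units are interpolated on one uniform grid
  anchored at the common window start, so $\Delta\phi_{ij}(\tau)$ is
  well defined across units; per-interval sample counts need not be
  integers because interpolation is analytic in $t$.
* **One $M$ per receiver.**  The harmonic count is shared by all senders
  of a receiver (per-edge counts are out of scope).
* **Pointwise bands.**  The 95% band of an interaction function is the
  pointwise scaled Student-$t$ interval of $g(\Delta\phi)^\top c$ with
  $2\alpha$ degrees of freedom, not a simultaneous band.
* **Units.**  Interaction functions are reported in rad/ms throughout.
* **Noise recovery convention.**  $\hat D = E[\sigma^2]\,\Delta t/2$
  follows the regression convention $\sigma^2 = 2D/\Delta t$.  Because
  interpolation discards within-cycle diffusion, the residual variance
  reflects cycle-level jitter only, so $\hat D$ recovers roughly
  $D \cdot \Delta t/\mathrm{ISI}$ rather than $D$; the tests pin down
  this attenuation instead of pretending it away.  Comparisons across
  conditions (e.g. noise sweeps) remain valid since the attenuation
  factor is fixed by `dt`.

## Problem sizes used in the validation suite

The test suite exercises 8-unit ($k_{in}=3$) networks over 100–1000
cycles for coupling recovery, 16-unit ($k_{in}=4$) networks for
connectivity inference and the synchrony failure mode, and directed pairs
for harmonic selection — desk-scale versions of the 64-unit/8-synapse
study design with the per-edge coupling kept at its derived per-synapse
strength.  A 1000-cycle, 16-unit dataset contains ~16k spikes and, at
two samples per mean cycle, ~2000 regression rows per receiver; a full
network fit takes a few seconds.

## Known limitations

* **Coefficient-level coverage fails at long data lengths.**  The
  linear-interpolation bias (each $\delta$ is an ISI average of
  $\Gamma$ over the phase-difference arc swept during that cycle) is a
  fixed systematic error of a few percent of the coefficient, while the
  posterior SD shrinks as $T^{-1/2}$; beyond a few hundred cycles the
  truth therefore sits many posterior SDs from the posterior mean even
  though the absolute error is small.  Credible bands should be read as
  describing estimator uncertainty, not calibrated frequentist coverage.
* **Connectivity inference is not infallible at 1000 cycles.**  On
  16-unit networks with 25% connection density the Otsu split
  misclassifies a pair or two in some realizations (MCC 0.85–1.0);
  near-perfect classification needs either longer data or sparser
  networks.
* **Globally synchronized networks are unidentifiable** — phase
  differences freeze, the design matrix degenerates, and the package
  (deliberately) reports large errors or raises conditioning errors
  rather than silently extrapolating.
* Weak, unequal synaptic weights, per-edge harmonic counts, sparsity
  priors, and time-delayed coupling are out of scope.
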