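---
title: "Noise-enhanced coding in phasic neurons: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-enhanced coding in phasic neurons: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasic)
```

# The scientific problem

Phasic (Class III) neurons carry a subthreshold negative feedback — in
biophysical models usually a low-threshold K⁺ current — that makes them
high-pass: a slow depolarizing input of any amplitude fails to evoke spikes
because the feedback tracks it and cancels it. With broadband noise added,
however, these cells fire and their spikes lock to the slow signal. The
package implements two levels of description of this effect and
cross-validates them:

* a **two-dimensional stochastic FitzHugh–Nagumo (FN) model** whose
  recovery variable has a voltage-dependent timescale, and
* a **reduced two-barrier renewal ("hazard") model** that makes the
  mechanism analytically tractable.

# The FitzHugh–Nagumo level

## Equations and parameters

$$\tau_v \dot v = v(0.1 - v)(v - 1) - w + A\sin(2\pi\varphi t)
  + \sqrt{2D}\,\xi(t), \qquad \dot w = \varepsilon(v)\,v,$$

with $\langle\xi(t)\xi(t')\rangle = \delta(t - t')$. The $w$-nullcline is
vertical, so the rest state $(0,0)$ is stable for any constant input — the
defining phasic property. Two variants:

* **ε(v)-model**: $\varepsilon(v) = \dfrac{0.1 + 0.03\,
  e^{(v-0.15)/0.03}}{1 + e^{(v-0.15)/0.03}}$ — feedback ~3× faster near
  rest (ε ≈ 0.1) than during a spike (ε ≈ 0.03). Computed in the logistic
  form `eps_lo + (eps_hi - eps_lo) * plogis(-(v - v_half)/v_slope)`, which
  cannot overflow.
* **ε-model**: constant ε = 0.03.

Spikes are upward crossings of $w$ through $w_c$ (0.14 for the ε(v)-model,
0.15 for the ε-model), located by linear interpolation between bracketing
samples; a sample exactly at $w_c$ counts only if the previous sample is
strictly below, which also enforces a subthreshold sample between
consecutive spikes. Detecting on $w$ rather than $v$ makes the count robust
to noise-induced chatter near the voltage threshold.

Integration is Euler–Maruyama at `dt = 0.01` ms (time unit: milliseconds
throughout this level). The per-step noise increment has variance
$2D\,dt/\tau_v^2$. Each cell of an ensemble draws from an independent
xoshiro256++ stream keyed by `(seed, cell_id)`, so results are bit-for-bit
reproducible and independent of scheduling order — a property R's single
global RNG stream cannot provide, which is why the integrator carries its
own generator.

## The membrane time constant and the rate anchors

$\tau_v$ is exposed as a parameter with default **1 ms**. Two external
anchors exist for calibrating it: the ε(v)-model at $D = 0.03$ and the
ε-model at $D = 0.069$ should both fire at ν ≈ 0.0045/ms. Under the
literal reading ($\tau_v = 1$, equations exactly as above) the package
obtains ν ≈ 0.030 and ≈ 0.024 respectively — the *pairing* of the two
noise levels reproduces (the two variants' rates coincide to ~12% of their
common value, and the ε(v)-model is the more noise-sensitive one,
qualitatively as expected), but the absolute scale is ~6.7× the anchor
value. We verified with an independent plain-R integrator and with halved
`dt` that this is not an implementation or discretization artifact, and we
scanned $\tau_v \in [1, 50]$: no single $\tau_v$ reconciles both anchors
(they would require ~55 and ~13 ms respectively), nor does a pure
rescaling of $D$. Because the paired structure — the strongest
implementation-independent check — holds at $\tau_v = 1$, the package
keeps that default and treats the absolute rate anchors as *calibration
checks that currently fail*, most plausibly due to an unstated time- or
noise-units convention in the original study's code. The acceptance tests
assert both the absolute anchors (red under this reading) and the pairing
(green); `scripts/acceptance.R` reports the computed rates.

## The deterministic no-spike property

At $D = 0$ and $\varphi = 0.005$/ms the model is silent for subthreshold
amplitudes: verified for $A = 0.01$ and $A = 0.1$. At $A = 0.5$ the slow
ramp outruns the feedback (the quasi-static fold margin of the cubic is
only ~0.0024, while the tracking lag is $\dot I/0.65 \approx 0.024$) and a
genuine spike excursion occurs — confirmed with RK4 at `dt = 0.001` ms. The
"no spikes at any amplitude" statement therefore requires $\varphi$ to
shrink as $A$ grows; the acceptance test keeps the $A = 0.5$ leg as stated
and it fails honestly.

## Spike metrics

* **Vector strength** is computed from raw spike phases (sum of unit
  vectors), eliminating binning bias; the histogram route exists for
  plotting and cross-checks. Phases are expressed in time units on
  $[0, T = 1/\varphi)$.
* **Spike-triggered average**: the noise path is stored as per-step
  increments divided by $\sqrt{dt}$ (an estimate of $\xi$); window default
  100 ms pre / 20 ms post. For long runs the accumulation is done online in
  the integrator with a ring buffer — the result is sample-identical to the
  stored-path computation (tested) without the memory cost.
* **Power spectra**: Welch averaging with 50% overlap and a Hann taper,
  normalized so the one-sided density integrates to the sample variance
  (Parseval within 1%). Exact estimator choice is not load-bearing for any
  quantitative claim.
* **Smoothing**: three successive centered moving averages
  ("pseudo-Gaussian"); edge windows shrink symmetrically so constants pass
  through unchanged.

# The phase-plane level

The separatrix $v^*(w)$ is found per $w$ by bisecting the initial $v$
between a non-spiking and a spiking initial condition, with the spike
classifier re-using the trajectory detector at the variant's $w_c$
(RK4, horizon 150 ms — long enough for non-spiking paths to demonstrably
decay; halving the horizon or the step does not move the classification at
the default tolerance 1e-5). Two facts about this vector field shaped the
defaults:

* the *non-spiking* bracket endpoint is the rest-basin interior ($v = 0$),
  not a far-left value: strongly hyperpolarized starts rebound into a
  spike;
* the spike branch of the separatrix only exists for $w$ below the cubic's
  local maximum (~0.12): above it $\dot v < 0$ for every $v > 0$ and no
  initial condition can spike, so the default grid covers
  $w \in [-0.05, 0.1]$ and the distance trace signals rather than
  extrapolates outside it.

The distance trace $\Delta U(t) = v^*(w(t)) - v(t)$ from the
hyperpolarized start $(-0.2, 0)$ dips well below its rest value and rings
back — the geometric fact the reduced model's moving barrier caricatures.

# The two-barrier renewal level

## Model

Large fluctuations either cross a left barrier $\Delta U_L = 0.9$
(recruiting the feedback) or a right barrier (a spike, reset to the
origin). Rates follow $H(\Delta U, D) = 5 e^{-3\Delta U^{1.5}/D}$, bounded
by γ = 5. After any reset the right barrier relaxes along
$\Delta U_R(t) = 1.5 - 1.4\sin(0.8\pi(t+0.15))\,e^{-0.8(t+0.25)}$, dipping
to a global minimum ≈ 0.676 at $t ≈ 0.352$ (found by grid scan plus local
refinement — the transient is oscillatory, so a bare 1-D optimizer can land
in the wrong trough). Variants: **phasic** (left barrier active, both event
types reset the clock), **right_moving** (no left barrier), **classic**
(constant barrier; classical stochastic resonance). A weak slow sinusoid
($A \ll v_R$, default $A = 0.1$, $\varphi = 0.1$) lowers both barriers
quasi-statically.

## The Fourier renewal solve

With exit kernels $J_R = H_R S$, $J_L = H_L S$,
$S = e^{-\int_0^t (H_L + H_R)}$, the ISI density solves
$f = J_R + J_L * f$, i.e. $\hat f = \hat J_R / (1 - \hat J_L)$. Numerical
choices, each of which was selected against the constant-barrier closed
form ($f = H_R e^{-H_R t}$ for any $H_L$):

* transforms are trapezoid-corrected DFTs,
  $\hat J = dt\,(\mathrm{fft}(J) - J(0)/2)$ — measured max-normalized error
  ~1e-8 versus ~1e-4 for the plain rectangle DFT at the same grid;
* the $t = 0$ sample of the inverse is repaired to the exact boundary value
  $f(0) = J_R(0)$;
* negative FFT ringing is clipped at $-10^{-6}\max f$ and reported; beyond
  that it signals a too-coarse grid. (The clip floor matches the solver's
  actual tail error of 1e-8–1e-7 of $\max f$; a much tighter floor would
  reject correct output.)
* `dt` resolves the fastest model feature: the moving-barrier oscillation
  (≥64 points/period), the sinusoid period (≥64 points), and the fastest
  total hazard (≥50 points per mean escape);
* `t_max` starts from the kernel-survivor rule (integrated hazard > ~14)
  and **doubles until the solved density's own tail mass is < 1e-8**. The
  phasic $f$ decays far more slowly than its kernels, and because the
  FFT solve is circular, a short grid aliases the tail back into the
  density without hurting its normalization — the tail check is the only
  reliable guard. `n_t` is a power of two in $[2^{14}, 2^{22}]$.

The hazard-ratio extreme (large $H_L/H_R$) amplifies quadrature error by
$1/(1-\hat J_L(0))$; the constant-barrier reduction test therefore runs on
a $2^{21}$ grid where the measured error is below 1e-6. An independent
time-domain oracle — direct summation of the convolution series to 8 terms
— matches the Fourier solution to within its own truncation mass
$a b^9/(1-b)$ (computed, not assumed) plus quadrature tolerance.

## Phases: kernel, fixed point, and the sinusoid clock

The spike-phase kernel $g(\psi|\psi_0) \propto \sum_k f(kT + \psi -
\psi_0 \mid \psi_0)$ is built by folding the ISI density's mass into phase
bins on its own fine time grid (mass-preserving aggregation with trapezoid
end-weights), then renormalizing each column to integrate to one — the
normalization the kernel must satisfy, enforced directly rather than
through a prefactor whose printed form is dimensionally inconsistent with
it. The wrap truncation `k_max` spans the entire time grid, so enlarging it
adds only zeros; the mass beyond `k_max` periods is checked explicitly.
Two further choices matter numerically:

* the **ψ grid points are bin centers**: a kernel column stands for its
  whole bin, and midpoint evaluation keeps the discretized phase chain
  second-order accurate (with left-edge evaluation the stationary vector
  strength converges only first-order and overshoots by ~0.007 at
  $n_\psi = 128$);
* $n_\psi = 128$ (not 64): the phasic kernel inherits the sharp reset
  transient (width ~0.3 time units against a 64-bin width of 0.156), which
  at 64 bins leaves ~1% column-mass defect at high $D$.

The stationary phase density is the fixed point of the column-stochastic
phase map, found by power iteration from the uniform density (L1 tolerance
1e-10, every iterate renormalized, residual returned). With $A = 0$ the
kernel is exactly circulant and fixes the uniform density; the vector
strength then vanishes to round-off.

The convolution theorem requires kernels stationary in time-since-reset,
so the theory references the sinusoid to the most recent reset with offset
$\psi_0$ (the quasi-static bookkeeping), and the phase recorded at a spike
advances by the full interval. The thinning Monte Carlo implements three
clocks: `absolute` (physically realistic, default), `per_reset` (mirrors
the theory's bookkeeping exactly — the right comparator for validating the
numerics), and `endogenous` (fixed offset after every reset, making ISIs
i.i.d. — the right comparator for distribution-level tests). The
`absolute`-vs-`per_reset` gap *is* the quasi-static approximation error and
is visible in the validation tables (at $D = 1$, $A = 0.1$: r ≈ 0.35
absolute vs ≈ 0.16 per-reset).

## Monte Carlo

Thinning with bound $2\gamma$ is exact because each hazard is bounded by
γ — no discretization enters. Standard errors: the firing rate uses the
delta method on the mean ISI; the vector strength uses batch means of the
resultant components (20 consecutive batches) with the delta method, which
tolerates the weak serial dependence of phases.

# What the generators emulate, and what they do not

All data in the package are synthetic, produced by the two simulators under
the study conditions (FN: `dt = 0.01` ms ensembles; reduced model: the
constants above). They emulate stationary background noise, a single slow
sinusoid, and uncoupled identical cells. They do **not** emulate
heterogeneous populations, synaptic (colored, conductance) noise,
adaptation or non-renewal serial ISI correlations, coupled networks, or
biophysical (Hodgkin–Huxley-type) spike generation — so green tests here
demonstrate internal consistency of models and theory, not fidelity to any
particular recorded neuron.

# Problem sizes

Defaults used by the tests and the acceptance script: FN rate checks use
20 cells × 100 s (2×10⁶ ms of ensemble time, ~6×10⁴ spikes at the checked
noise level); the STA shares that run; theory–MC validation uses ≥10⁴
spikes per noise level; theory grids are $2^{14}$–$2^{18}$ time points in
routine use and $2^{21}$ for the closed-form reduction check. These sizes
put Monte Carlo standard errors well below the effect sizes being asserted.

# Known limitations

* The FN absolute firing-rate anchors fail under the literal parameter
  reading (see above); only the cross-variant pairing is reproduced.
* The quasi-static phase theory assumes $\varphi \ll 1$ and
  $A \ll v_R$; the package does not attempt to locate its breakdown, and
  the `absolute` clock's deviation quantifies it only pointwise.
* The deterministic no-spike property has a finite amplitude range at fixed
  $\varphi$ (see the $A = 0.5$ discussion).
* The separatrix is a per-$w$ bisection construction, not an invariant
  manifold continuation; it is defined only where a spiking initial
  condition exists.
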