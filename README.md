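# phasic

Simulation and semi-analytic theory of **noise-enhanced coding in phasic
(Class III) neurons**.

Phasic neurons — common in the auditory brainstem, spinal cord and
cerebellum — carry a subthreshold negative feedback (typically a
low-threshold K⁺ conductance) that suppresses spiking to slow or sustained
inputs: deterministically they are high-pass filters and will not fire to a
slow sinusoid of *any* amplitude. Yet with moderate broadband noise their
spike trains lock well to exactly those slow signals. This package provides
the modelling stack to study that effect quantitatively, for computational
neuroscientists working on stochastic excitable dynamics:

1. **`fn_simulator`** — a stochastic FitzHugh–Nagumo model with a vertical
   w-nullcline and a voltage-dependent recovery timescale,

   τ_v dv/dt = v(0.1 − v)(v − 1) − w + A sin(2πφt) + √(2D) ξ(t),
   dw/dt = ε(v) v,

   with ε(v) = (0.1 + 0.03 e^{(v−0.15)/0.03}) / (1 + e^{(v−0.15)/0.03})
   (the *ε(v)-model*; faster feedback when hyperpolarized) or constant
   ε = 0.03 (the *ε-model*). Ensembles of uncoupled cells are integrated by
   Euler–Maruyama in C++; spikes are upward crossings of w through w_c.
2. **`spike_metrics`** — firing rate ν, cycle histogram p(ψ), vector
   strength r = |∫p(ψ)e^{2πiφψ}dψ|, the coding measure **q = ν·r**,
   spike-triggered averages ⟨ξ(t)|t_spike⟩, Welch power spectra, and a
   pseudo-Gaussian smoother.
3. **`phase_plane`** — numerical separatrix v*(w) by bisection and the
   distance-to-threshold trace ΔU(t) = v*(w(t)) − v(t), showing how a
   hyperpolarizing excursion transiently lowers the effective spike
   threshold.
4. **`barrier_theory`** — the reduced two-barrier renewal model: Arrhenius
   hazards H(ΔU, D) = 5 e^{−3ΔU^{1.5}/D} for a static left barrier
   (ΔU_L = 0.9, feedback recruitment) and a moving right barrier
   ΔU_R(t) = 1.5 − 1.4 sin(0.8π(t+0.15)) e^{−0.8(t+0.25)} (spike
   threshold, reset by both event types). The interspike-interval density
   solves f = J_R + J_L ∗ f, solved in the Fourier domain as
   f̂ = Ĵ_R/(1 − Ĵ_L); a slow sinusoid enters quasi-statically, and the
   stationary spike-phase density is the fixed point of the phase map,
   giving semi-analytic ν, r and q for three variants (phasic /
   right-moving-boundary / classic stochastic resonance).
5. **`barrier_mc`** — an exact thinning (rejection) simulator of the same
   point process, the independent oracle for the theory.
6. **`cli_io`** — JSON-configured experiment drivers
   (`run_experiment()`, `inst/cli/phasic.R`) with reproducible seeds and
   byte-stable CSV output.

## Worked example

A slow sinusoid (period 200 ms) that evokes *no* spikes deterministically is
encoded once noise is added, best at intermediate noise:

```r
library(phasic)

# deterministically silent
p0 <- fn_params("voltage_dependent", D = 0, A = 0.05, phi = 0.005,
                duration = 400)
sum(sapply(simulate_fn(p0)$trains, function(t) length(t$times)))
#> [1] 0

for (D in c(0.0005, 0.001, 0.002, 0.005)) {
  params <- fn_params("voltage_dependent", D = D, A = 0.05, phi = 0.005,
                      duration = 20000, n_cells = 10, seed = 42)
  sim <- simulate_fn(params)
  nu <- firing_rate(sim$trains)
  r  <- vector_strength(sim$trains, phi = params$phi)
  cat(sprintf("D=%.4f: nu = %.4f /ms, r = %.3f, q = %.5f\n",
              D, nu, r, q_value(nu, r)))
}
#> D=0.0005: nu = 0.0031 /ms, r = 0.647, q = 0.00200
#> D=0.0010: nu = 0.0079 /ms, r = 0.399, q = 0.00316
#> D=0.0020: nu = 0.0144 /ms, r = 0.226, q = 0.00326
#> D=0.0050: nu = 0.0211 /ms, r = 0.128, q = 0.00269
```

The firing rate ν grows with D while the locking r decays — their product q
peaks at intermediate noise. The reduced theory reproduces its own exact
Monte Carlo to within sampling error:

```r
spec <- barrier_spec("phasic", D = 1, A = 0.1, phi = 0.1)
th <- theory_metrics(spec)
mc <- mc_metrics(simulate_barrier_process(spec, 5e4, seed = 1,
                                          sinusoid_clock = "per_reset"))
sprintf("theory: nu = %.4f, r = %.4f, q = %.5f", th$nu, th$r, th$q)
#> [1] "theory: nu = 0.2143, r = 0.1621, q = 0.03473"
sprintf("MC:     nu = %.4f +- %.4f, r = %.4f +- %.4f",
        mc$nu, mc$nu_se, mc$r, mc$r_se)
#> [1] "MC:     nu = 0.2158 +- 0.0030, r = 0.1569 +- 0.0085"
```

At the same noise level the phasic variant encodes the slow signal with a
~6× larger q than the classic (static-barrier) stochastic-resonance model —
the package's central quantitative statement.

See `vignettes/phasic-coding.Rmd` for the model assumptions, numerical
choices and known limitations (including the calibration status of the
stochastic FitzHugh–Nagumo firing-rate anchors).

## Command-line driver

```sh
Rscript inst/cli/phasic.R theory-scan --config cfg.json --out outdir
```

with subcommands `fn-run`, `fn-scan`, `theory-scan`, `mc-validate`,
`phase-plane`; the config file carries the model, grid and scan sections
(unknown keys are rejected), and each run echoes its resolved configuration
and seed beside the CSV outputs.
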