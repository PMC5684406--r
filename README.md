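# excitondelay

Time-delayed coherent feedback dynamics of an excitonic dimer coupled to a
phonon bath.

## What problem this solves, and for whom

Femtosecond spectroscopy of photosynthetic pigment–protein complexes (the
FMO complex being the standard testbed) shows population and coherence
beatings that outlive naive decoherence estimates. One candidate mechanism
is *coherent feedback*: a chromophore pair — reduced in the weak-excitation
limit to an effective two-level system — couples to its vibrational
environment at two spatial points, so an emitted excitation re-interacts
with the system after a travel-time delay τ, with no measurement involved.
This package is for researchers in open quantum systems / quantum biology
who want a small, fully tested simulator of that mechanism: how delay and
feedback phase control beating, coherence lifetime, and excitation
trapping, and how strong the bath coupling needs to be for oscillations to
appear.

## The model

The two-point bath coupling has spectral density

    J(ω) = (γ₀/π) (1 + cos(ωτ + φ)),   ω > 0,

whose inverse Fourier transform is a three-delta dissipation kernel at lags
{−τ, 0, +τ}. In the single-excitation sector the bath integrates out
exactly and the amplitude obeys the linear delay differential equation
(rotating frame, detuning δ₀)

    dc/dt = −iδ₀ c(t) − γ₀ c(t) − θ(t−τ) γ₀ e^{−iφ} c(t−τ),   c(0) = c₀.

Key exact facts the package computes and tests:

- **Trapping**: for φ = π (destructive interference), |c(t)| → 1/(1+γ₀τ);
  for any other phase, |c(t)| → 0.
- **Characteristic roots**: s_k = −iδ₀ − γ₀ + W_k(−γ₀τ e^{−iφ}
  e^{(iδ₀+γ₀)τ})/τ over Lambert-W branches; at φ = π a root sits exactly
  at 0.
- **Piecewise closed form**: c(t) = Σₙ (−b)ⁿ e^{−a(t−nτ)} (t−nτ)ⁿ/n!
  with a = iδ₀+γ₀, b = γ₀e^{−iφ} — the independent oracle for the solver.

The solver is classical RK4 with the method of steps (C++ core), with the
step dividing τ exactly so the propagated derivative kinks fall on grid
nodes. A general N-site memory-kernel engine (Heun + trapezoidal history
quadrature) provides an independent route through the full Volterra
equation and the bridge to user-defined spectral densities.

## Worked example

```r
library(excitondelay)

fc <- feedback_coupling(530, tau = 50, phi = pi, gamma0_unit = "cm-1")
fc
#> Feedback coupling (two-point bath coupling with delay)
#>   gamma0 = 0.0998335 fs^-1  (530 cm^-1)
#>   tau    = 50 fs
#>   phi    = 3.14159 rad (= 1 pi)
#>   delta0 = 0 fs^-1

traj <- solve_amplitude(fc, t_max = 2000)
tail(population(traj)$value, 1)   # donor population at 2000 fs
#> [1] 0.02785497
steady_state_amplitude(fc)^2      # analytic trapped population (1/(1+γ₀τ))²
#> [1] 0.02785501

beating_metrics(population(traj))$period   # beating period, fs
#> [1] 58.09848

characteristic_roots(fc, -2:2)
#>   branch                       root     residual
#> 1      0  0.00000e+00+2.040511e-18i 3.851860e-34
#> 2     -1 -7.13488e-03-1.083976e-01i 9.714451e-17
#> 3      1 -7.13488e-03+1.083976e-01i 7.473417e-17
#> 4     -2 -1.76499e-02-2.268626e-01i 1.185719e-16
#> 5      2 -1.76499e-02+2.268626e-01i 1.475229e-16
```

At 530 cm⁻¹ and τ = 50 fs the destructive-interference phase traps ≈ 2.8 %
of the donor population indefinitely (the root at s = 0), the population
beats with a period slightly above the delay, and every other mode decays.
Increasing τ lengthens the beating period and lifetime; at τ → 0 no
oscillations occur for any realistic coupling.

A command-line front end wraps the same functions:

```sh
Rscript exec/excitondelay simulate --gamma0 530 --gamma0-unit cm-1 \
    --tau 50 --phi pi --t-max 2000 -o out.csv
Rscript exec/excitondelay steady-state --gamma0 0.02 --tau 50 --phi pi
#> 0.5
```

Subcommands: `simulate`, `dimer`, `sweep`, `roots`, `steady-state`; see
`?run_cli`. The methods vignette
(`vignettes/delayed-feedback-dimer.Rmd`) documents the model, unit
conventions, numerical design and limitations.

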