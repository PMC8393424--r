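# sdnn — stimulus-dependent attractor neural networks

Classical Hebbian attractor networks recognize a pattern by relaxing
into a stored memory's basin of attraction, which limits them to a load
of about α = p/N ≈ 0.14 stored patterns per neuron: beyond that, the
crosstalk from the other memories drowns the signal. This package
implements a different operating mode, aimed at computational
neuroscientists and statistical physicists studying associative memory:
a persistent external field κηᵢ — a stimulus that stays on during the
whole relaxation — is calibrated against the crosstalk noise, and
recognition is read off from the overlap gap between a
memory-correlated and an orthogonal stimulus. In this mode the network
recognizes patterns at loads a hundred times the classical capacity.

The model: N binary neurons σᵢ = ±1, Hebbian couplings
Jᵢⱼ = (1/N) Σ_μ ξᵢ^μ ξⱼ^μ over p = αN random ±1 patterns, local field

    hᵢ = Σ_{j≠i} Jᵢⱼ σⱼ + κ ηᵢ,

zero-temperature sequential dynamics σᵢ ← sign(hᵢ). The stimulus η
agrees per-site with a target memory ρ with probability γ ∈ [1/2, 1],
or is drawn orthogonal (on average) to all memories. The crosstalk
noise on an aligned neuron has variance ≈ α, so the calibrated
intensity is located near √α; operationally it is the argmax over κ of

    Δm(κ) = |⟨m_ρ⟩ − ⟨m_⊥⟩|,

where m_ρ is the overlap retrieved under the correlated stimulus and
m_⊥ under the orthogonal one. The package provides:

* pattern/stimulus generators, including exact-count correlated
  companions and piecewise-constant stimulus schedules;
* a compiled zero-temperature dynamics engine (overlap-refactored
  fields, exact integer arithmetic; asymmetric synaptic dilution
  supported);
* replica-symmetric mean-field solvers at T = 0 and finite temperature,
  with Maxwell branch selection and the classical-capacity bisection;
* experiment drivers: `kappa_scan()`, `correlated_scan()`,
  `dilution_scan()`, `noise_variance_empirical()`, `time_course()`,
  `theory_vs_simulation()`, all returning tibbles with `glance()` and
  `autoplot()` methods;
* a small CLI (`inst/cli/sdnn.R`, or `run_cli()`) writing CSV results
  with JSON sidecars for bit-reproducible reruns.

## Worked example

```r
library(sdnn)

scan <- kappa_scan(N = 2000, alpha = 1, gamma = 1,
                   kappa_grid = seq(0.5, 1.5, by = 0.05),
                   realizations = 20, seed = 1)
glance(scan)
#> # A tibble: 1 × 7
#>   kappa_c max_delta_m     N alpha gamma realizations     d
#>     <dbl>       <dbl> <dbl> <dbl> <dbl>        <dbl> <dbl>
#> 1    0.95       0.368  2000     1     1           20     0
```

At α = 1 — seven times the classical capacity — the overlap gap peaks at
κ_c = 0.95, right at the analytic noise-width estimate √α = 1 (the
simulated value sits a few percent below it). At that intensity the scan
row shows `m_rho = 0.861`: the network retrieves the stimulated memory
with 86% overlap, while the orthogonal baseline `m_perp = 0.493` confirms
that an unrelated stimulus of the same strength is *not* mistaken for a
memory. `autoplot(scan)` draws the three curves with κ_c marked.

The mean-field side reproduces the classical result in one line:

```r
round(critical_capacity(kappa = 0, gamma = 1), 2)
#> [1] 0.14
```

and `mf_solve_T0(alpha, kappa, gamma)` /
`mf_solve_orthogonal_T0(alpha, kappa)` give the theoretical overlap
curves that `theory_vs_simulation()` lays against the simulation.

See the vignette (`vignettes/stimulus-calibrated-retrieval.Rmd`) for
the model, the numerical choices, and what the desk-scale defaults do
and do not establish.

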