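# erscaling

Tools for studying how morphogen gradients scale with tissue size through
**expansion–repression (ER) feedback** when the expander molecule is
*position dependent*. The package is aimed at quantitative developmental
biologists and modellers who want to simulate the circuit, measure
position-resolved patterning quality, and map trade-offs across parameter
space.

## The model

A morphogen `M` and an expander `E` react and diffuse on `x ∈ [0, L]`
with zero-flux boundaries:

    ∂t M = DM ∂x² M − k M / (1 + E/ξ) + νM θ(wM − x)
    ∂t E = DE ∂x² E − μ E / (1 + E/ζ) + νE mʰ / (mʰ + Mʰ)

The expander suppresses morphogen degradation (threshold `ξ`), the
morphogen represses expander production (Hill threshold `m`, coefficient
`h`), and — the modification that makes position-dependent expanders
compatible with scaling — the expander also suppresses its *own*
degradation (threshold `ζ`). The source width `wM = βL` scales with the
tissue by default; fixed-width and boundary-flux variants are available.

On top of the stiff method-of-lines solver the package provides:

* **Closed-form limits** (`sdd_steady_profile()`) — the exact no-feedback
  steady state used as the solver oracle, plus analytic scaling and
  robustness baselines for feedback-free exponential gradients.
* **Position-dependent metrics** — scaling `S_M(r) = 1 − |ρ_L − r|`
  between tissue lengths `L1 = 50` and `L2 = 100` µm, robustness `R_M(r)`
  under ±1.5-fold production changes, precision
  `P_M(r) = 1 − sqrt(M/(d (∂rM)²))` with cell size `d = 1` µm, expander
  summaries (dynamic range `f_E`, half-decay length `λ_E`, source width
  `w_E`, integrated degradation `μ̄`), gradient-shape classification
  (exponential vs power law), and useful-patterning regions
  (`min(S,R,P) > 0.95`).
* **A seeded parameter sweep** — log-uniform sampling, admissibility
  filters (convergence, monotone informative gradients, active feedback
  `E > ξ` for `r ≥ 0.1`), relaxation timing after perturbations, and
  figure-level aggregation (binned metric profiles by `f_E` and
  high-scaling position, probability histograms, rank correlations).

## Worked example

```r
library(erscaling)

p <- model_params(DM = 2, DE = 100, k = 0.5, mu = 2, nuM = 1, nuE = 0.5,
                  xi = 0.01, zeta = 1, m = 0.2, h = 4, beta = 0.1, L = 50)
opts <- solver_options(Nx = 501)
ps1 <- solve_steady_state(p, opts)            # steady state at L1 = 50 um
ps2 <- solve_steady_state(with_length(p, 100), opts)

expander_summaries(ps1, p)
#> expander_summary: f_E = 0.927, lambda_E = 28.47 um, w_E = 28.87 um, mu_bar = 85.57

S <- scaling_profile(ps1, ps2)
classify_scaling(S, target_region = c(0.1, 1))
#> $kind
#> [1] "local"
#> $local_position
#> [1] 0.1
```

The expander is strongly position dependent (`f_E ≈ 0.93`: it collapses
toward the morphogen source), and the system scales *locally*, best right
at the source edge (`r = 0.1`): the morphogen concentration found there
sits at the same relative position at both tissue lengths, with scaling
quality decaying further into the target tissue.

A command-line wrapper (`inst/scripts/erscaling`) exposes `steady`,
`perturb`, `metrics`, `sweep`, `aggregate` and `fixtures` subcommands over
YAML configs and TSV profiles; see `?cli_main`.

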