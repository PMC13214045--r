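---
title: "Morphogen gradient scaling with position-dependent expanders"
author: "erscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphogen gradient scaling with position-dependent expanders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erscaling)
```

## The model

Developmental patterns scale with tissue size even though the morphogen
gradients that organise them are set by dimensional rates and
diffusivities. The expansion-repression (ER) motif explains gradient
scaling through a second diffusing molecule, the *expander*, which
suppresses morphogen degradation while the morphogen represses expander
production. In its classical form the motif requires a spatially uniform
expander; measured expander profiles, however, are often strongly
position-dependent. This package implements a modified ER circuit in which
the expander additionally represses its own degradation, which allows the
expander profile itself to scale with tissue length, and with it the
morphogen gradient — even when the expander is far from uniform.

The two species obey, on $x \in [0, L]$,

$$
\partial_t M = D_M \partial_x^2 M - \frac{k}{1 + E/\xi}\, M
  + \nu_M\, \theta(w_M - x), \qquad
\partial_t E = D_E \partial_x^2 E - \frac{\mu}{1 + E/\zeta}\, E
  + \nu_E \frac{m^h}{m^h + M^h},
$$

with zero diffusive flux at both ends. $k$ and $\mu$ are *upper limits* of
the two degradation rates; the expander concentration scales $\xi$ and
$\zeta$ set where the two repressive feedbacks become effective, and the
Hill term (threshold $m$, coefficient $h$) confines expander production to
regions of low morphogen. The morphogen source occupies $[0, w_M]$ with
$w_M = \beta L$ by default, so the source grows with the tissue; a fixed
source width and a constant boundary influx are available as variants
(`source_mode`), and the boundary-flux variant is numerically equivalent to
a narrow fixed source of equal strength.

A useful summary of an expander profile is its *dynamic range*
$f_E = (E(L) - E(w_M))/E(L)$: 0 for a uniform expander (the classical
regime, exponential morphogen gradients), 1 for an expander that vanishes
at the source edge (power-law-like morphogen gradients with a sharp decay
at the source boundary).

## Numerics

The equations are discretised by the method of lines on a uniform grid
(default `Nx = 1001`; the sweep uses 501) with ghost-node reflection for
the zero-flux boundaries, and integrated by a stiff solver (deSolve's
`lsodar`; the Jacobian is banded with half-bandwidth 2 because the state
is interleaved). The right-hand side is compiled C; a reference R
implementation (`assemble_rhs()`) backs the contract tests. Three
numerical choices deserve a note:

* **Source discretisation.** The Heaviside source indicator is weighted by
  the overlap of each node's control volume with $[0, w_M]$, so total
  production varies continuously as $w_M$ crosses nodes and discrete
  conservation (total rate of change = production − degradation + influx)
  holds to round-off.
* **Steady-state detection.** Steady state is declared when the normalised
  residual $\max_i |\partial_t C_i| / (\max_i C_i + \text{atol})$ of both
  species falls below `ss_tol` ($10^{-8}$ by default, with
  `rtol = 10^{-8}`, `atol = 10^{-10}`). The criterion is monitored
  continuously through the integrator's root-finding rather than at a
  fixed cadence. The integration horizon defaults to $50/\min(k_{\rm
  eff}, \mu_{\rm eff})$ evaluated at the expander's saturation
  concentration; when expander production exceeds its degradation ceiling
  $\mu\zeta$ no steady state exists and the run is cut off by the horizon
  or the overflow guard ($10^{12}$ concentration units) and flagged.
  Steady states are found by time-marching, which is robust for the
  strongly nonlinear feedback; a Newton polish was considered and not
  needed at the tolerances used.
* **Units.** Lengths are in µm, times in model time units and
  concentrations in arbitrary solver units; no nondimensionalisation is
  imposed. The precision formula below therefore inherits the solver's
  concentration scale — a deliberate, literal convention.

Verification rests on closed forms: with expander production switched off
and the feedback thresholds pushed to infinity the morphogen equation
degenerates to the linear source–diffusion–degradation (SDD) problem,
whose steady state `sdd_steady_profile()` evaluates exactly (matched
hyperbolic-cosine branches; overflow-safe for $L/\lambda$ in the
hundreds). The solver reproduces it to better than $10^{-4}$ relative
error at `Nx = 2001`, converges at second order in the grid spacing, and
closes the mass balance below $10^{-5}$.

## Position-dependent metrics

All metrics are functions of the relative position $r = x/L$ on a default
grid of 101 points, and all are bounded above by 1.

**Scaling** compares one system at two lengths ($L_1 = 50$, $L_2 =
100$ µm by default): $S_M(r) = 1 - |\rho_L - r|$ where $\rho_L$ is the
relative position in the longer tissue carrying the concentration
$M(r; L_1)$ — absolute concentrations, not normalised ones.
**Robustness** applies the same construction to a $\pm 1.5$-fold change of
the morphogen production rate at fixed length, averaging the positive and
negative shifts. **Precision** is the deterministic noise estimate
$\sigma_r(r) = \sqrt{M(r) / (d\, (\partial_r M)^2)}$ with effective cell
size $d = 0.02\,L_1 = 1$ µm, and $P_M = 1 - \sigma_r$ floored at zero;
$\sigma_r \sim M(0)^{-1/2}$, so dim gradients are imprecise even where
they are steep.

Threshold inversion interpolates linearly in log concentration (exact for
exponential decay) and operates on the profile's non-increasing branch
from its maximum: strong-feedback systems can peak slightly *inside* the
source region, where degradation is maximal because the expander is
lowest. Positions that fall outside the tissue are clamped to $[0, 1]$
and flagged rather than dropped, so the metrics stay defined tissue-wide;
flat plateaus make the precision denominator vanish and are flagged as
divergent with $P_M = 0$.

A system scales *globally* when $S_M \ge 0.98$ (a boundary shift below
2 %) at every evaluated position of the target tissue $r \in (\beta, 1]$,
and *locally* when the threshold is met only around some position. The
*useful patterning region* is where $\min(S_M, R_M, P_M) > 0.95$; interval
edges are located by interpolating the threshold crossing.

The expander half-decay length $\lambda_E$ is measured from the far edge
to the last position where $E$ falls to $E(L)/2$ — the absolute half
level, not the range midpoint. The two conventions coincide for the
full-dynamic-range systems the quantity is used for ($E(w_M) \approx 0$),
and the absolute convention degrades gracefully to a "not reached"
sentinel for flat profiles.

## Shape classification

The limiting solutions of the circuit motivate two shape families for a
steady gradient: exponential $A e^{-x/\lambda}$ (uniform expander) and
power law $B (x + c)^{-\alpha}$ (full-range expander). Two details make
the discrimination meaningful:

* With an unbounded offset the power-law family *nests* the exponential
  ($c \to \infty$ at fixed $\alpha/c$), so the offset is bounded by the
  start of the fit window — the power law's divergence point must lie
  near the source, as it does in the limiting solutions.
* Under zero-flux boundaries a uniform-expander gradient is exactly
  $A \cosh((L - x)/\lambda)$: an exponential with a far-boundary plateau.
  The exponential family is therefore fit in both the pure and the
  cosh form and the better one kept. Without this, the plateau's convex
  log-shape is systematically absorbed by the power law and the
  classification loses most of its discriminating power.

Fits are least squares on log concentration over $r \in [\beta + 0.05,
0.95]$ (avoiding the source and the far plateau), with nonlinear inner
parameters found by nested 1D search. The signed preference
$(\mathrm{rss}_{\exp} - \mathrm{rss}_{\rm pl}) / (\mathrm{rss}_{\exp} +
\mathrm{rss}_{\rm pl})$ is $-1$ on exact exponentials and $+1$ on exact
power laws.

## The parameter sweep

`sweep_config()` fixes the study conditions: parameters are drawn
log-uniformly and independently, with per-system seeds derived from the
campaign seed so any record is reproducible in isolation. The default
ranges — diffusivities $[0.1, 100]$ µm²/t, rates $[10^{-3}, 10]$ /t,
production rates and feedback thresholds $[10^{-3}, 10]$, $h \in \{2, 4,
8\}$, $\beta = 0.1$ — span morphogen decay lengths from far below to far
above $L_1 = 50$ µm and were chosen once, as the realistic window around
the tissue scale; they are configurable but the defaults are the
conditions under which all reported properties are measured.

Each system is solved at both lengths and under both production
perturbations; admissibility filters are applied in order (convergence,
no blow-up, monotone gradient over the target tissue, informative
gradient $M(L)/M(0) < 0.5$, and active feedback $E > \xi$ for all
$r \ge 0.1$ at both lengths — systems whose feedback dies inside the
target tissue revert to effectively constant degradation and are
excluded). The monotonicity and informativeness filters are this
package's concrete reading of "biologically relevant" gradients; their
thresholds are configurable and logged. Relaxation timing after each
perturbation (time of the extremum of $\int M\,dx$ and time to the new
steady state) is computed for passing systems.

At the default scale used by the tests and the acceptance script (200 and
2000 systems at `Nx = 501`) roughly one system in five passes all
filters. The emergent properties are stable at this scale: the
exponential-to-power-law preference tracks $f_E$ (Spearman $\approx
0.95$), relaxation time anticorrelates with the integrated expander
degradation rate, the useful-patterning probability mass moves toward the
source as $f_E$ grows, and every populated dynamic-range bin improves on
the no-feedback robustness baseline. *Global* scaling, by contrast, is a
fine-tuned phenotype: it requires the expander profile itself to scale
and the feedback to deactivate exactly within the source so that the
amplitude stays put while the shape scales. In sweeps of a few thousand
systems, typically no sampled system clears the 0.98 threshold at every
target-tissue position (the best reach $\min_r S_M \approx 0.93$, with
near-global behaviour concentrated at high $f_E$), so the global-scaler
assertions hold vacuously at this scale; recovering a populated
global-scaling set is expected to require sampling depths orders of
magnitude beyond what these budgets admit.

## What the generator does and does not emulate

The synthetic systems are deterministic steady states of the 1D circuit
on a static domain. Tissue growth enters only quasi-statically (two
independent lengths), readout noise only through the deterministic
precision formula, and there is no stochastic gene expression, no 2D/3D
geometry, no advection or dilution, and no feedback through the
diffusivities. Passing tests therefore validate the circuit's
steady-state patterning logic, not the dynamics of any real growing
tissue.

## Known limitations

* The steady-state criterion is relative; a species growing linearly at
  very large amplitude can satisfy it. Such systems (expander production
  above its degradation ceiling) are nonetheless excluded by the
  admissibility filters, which is where the question belongs.
* $\lambda_E$ is undefined (sentinel) for near-uniform expanders; summary
  statistics that use it are restricted to systems where it exists.
* The precision formula mixes concentration and length units by design
  (see above); comparisons should stay within one concentration
  convention.

## A worked example

```{r example, eval = FALSE}
p <- model_params(DM = 2, DE = 100, k = 0.5, mu = 2, nuM = 1, nuE = 0.5,
                  xi = 0.01, zeta = 1, m = 0.2, h = 4, beta = 0.1, L = 50)
opts <- solver_options(Nx = 501)
ps1 <- solve_steady_state(p, opts)
ps2 <- solve_steady_state(with_length(p, 100), opts)

S <- scaling_profile(ps1, ps2)
expander_summaries(ps1, p)
classify_scaling(S, target_region = c(0.1, 1))
```
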