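---
title: "Modelling Aedes aegypti control by genetically modified male releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Aedes aegypti control by genetically modified male releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedesgm)
```

## The model

`aedesgm` simulates the spatial population dynamics of *Aedes aegypti* under
releases of genetically modified (GM) males carrying a dominant lethal gene
(the RIDL/OX513A strategy: offspring of GM males and wild females die before
adulthood). Five density fields (mosquitoes/m²) live on a rectangular grid of
house-block and street cells: eggs $E$, the aquatic phase $A$ (larvae and
pupae), reproductive females $F$, wild males $M$ and GM males $G$:

$$
\begin{aligned}
\partial_t E &= \alpha\,\beta F M - e E,\\
\partial_t A &= e\Bigl(1 - \frac{A}{k}\Bigr) E - (\eta_a + \mu_a) A,\\
\partial_t F &= \nabla\cdot(D_m \nabla F) - \mu_f F + r \eta_a A,\\
\partial_t M &= \nabla\cdot(D_m \nabla M) - \mu_m M + (1-r) \eta_a A,\\
\partial_t G &= \nabla\cdot(D_g \nabla G) - \mu_g G + l,
\end{aligned}
$$

where $\alpha = M/(M+G)$ (taken as 1 when $M = G = 0$) dilutes the mating
success of wild males as GM males accumulate, $k$ is the aquatic carrying
capacity of the local cell, and $l(x,y,t)$ is the GM release rate. Only $k$
is heterogeneous (houses offer far more breeding sites than streets); the
remaining coefficients are environment-independent. Eggs carry no capacity
(females skip-oviposit across sites) and no mortality (the egg stage is
extremely durable); adults carry no capacity. The model assumes optimal
temperature, food and humidity throughout — none of the coefficients depend
on weather or season, which bounds what quantitative claims it can support.

The variable domain $0 \le E, F, M, G < \infty$, $0 \le A \le k$ is
invariant under the flow (each right-hand side points inward at the
boundary), and the solver enforces it numerically (see below).

### Parameters

`default_parameters()` carries the literature estimates, per day: egg
production $\beta = 34$ (m²/day), hatching $e = 0.24$, emergence
$\eta_a = 0.5596$, mortalities $\mu_a = 0.025$, $\mu_f = \mu_m = 0.1177$,
$\mu_g = 0.62$, female fraction $r = 0.5$, and diffusion $D_m = 111$,
$D_g = 331.4062$ m²/day. Diffusion coefficients come from inverting the
spreading-radius relation $R(t) = \sqrt{4Dt}\,\mathrm{erf}^{-1}(0.9)$ — the
radius of the band holding 90% of a point release along an axis — with the
observed lifetime dispersal (65 m over 7 days for wild adults):
`fit_diffusion(65, 7)` ≈ 111.5 m²/day. Two deliberate quirks are kept
because they reflect the tabulated values used in the reference
simulations: the GM
coefficient is 331.4062 rather than the ≈385.7 implied by the underlying
67.3 m/2.17 d inputs, and adult mortality is 0.1177 rather than the
$-\ln(0.9) \approx 0.105$ implied by a 10%-per-day loss.

## The single-cell reduction and its equilibria

Integrating the system over one isolated grid cell (no-flux faces, area
$S$) yields a five-dimensional ODE system for total populations. One subtlety
deserves emphasis: because $\beta$ multiplies a *product* of densities, the
cell-integrated egg source is $\alpha\beta \mathbf{F}\mathbf{M}/S$, not
$\alpha\beta \mathbf{F}\mathbf{M}$. All equilibrium operations therefore take
an `area` argument (default 1 m², in which totals and densities coincide);
city-scale computations pass the 25 m² cell area. The package's calibration
reproduces the reported per-cell capacities and the domain aquatic
equilibrium only under this normalization, which is why it is the default
behaviour rather than an option.

With $b = (\mu_a+\eta_a)\mu_f\mu_m S / (r(1-r)\beta\eta_a^2)$ and the basic
offspring number $Q_0 = K/(4b)$, the wild ($L=0$) aquatic equilibria solve
$\mathbf{A}^2 - K\mathbf{A} + bK = 0$: extinction always exists, and for
$Q_0 \ge 1$ the persistent state $\mathbf{A}^* = K(1+\sqrt{1-1/Q_0})/2$
appears together with a saddle (threshold) root. Under a constant release
$L$ the equilibria solve the cubic

$$\mathbf{A}^3 - K \mathbf{A}^2 + bK\mathbf{A} + bcK = 0,\qquad
c = \frac{\mu_m L}{(1-r)\eta_a \mu_g},$$

solved in closed form (`gm_cubic_roots()`): Cardano's formula when the
discriminant $\phi = P^3/27 + Q^2/4 > 0$ (depressed-cubic coefficients
$P = bK - K^2/3$, $Q = -2K^3/27 + bK^2/3 + bcK$) and the trigonometric form
in the three-real-root case $\phi < 0$, where the two positive roots
$\mathbf{A}^\#_1 > \mathbf{A}^\#_2$ are admissible. The release rate at
which they merge and vanish is analytic (`critical_release_rate()`):

$$L_c(K) = \frac{(1-r)\eta_a\mu_g}{bK\mu_m}\left(
\sqrt{-\tfrac{4}{27}\bigl(bK - \tfrac{K^2}{3}\bigr)^3}
+ \tfrac{2K^3}{27} - \tfrac{K^2 b}{3}\right),$$

defined for $K > 3b$ (below that the wild population is already frail —
$Q_0 < 3/4$ — and the bifurcation structure degenerates). The domain-level
critical rate applies $L_c$ to the block-count-weighted mean capacity
(`domain_critical_release()`). Stability is classified numerically
(`classify_equilibria()`): central-difference Jacobian (step
$10^{-6}\times$ scale, one-sided at the non-negativity boundary) and its
eigenvalues, with tolerance $10^{-9}\times$ the largest rate —
$\mathbf{A}^\#_1$ is an attractor, $\mathbf{A}^\#_2$ a saddle, and both the
wild extinction state and the GM-only state $(0,0,0,0,L/\mu_g)$ are
attractors. No symbolic proof is attempted; the labels are cross-checked
against forward integrations in the test suite.

### Carrying-capacity calibration

Direct estimation of $k$ is impractical, so it is fitted from an assumed
adult-female equilibrium: `calibrate_carrying_capacities()` solves
$n_h F^*(K_h) + w\, n_s F^*(K_s) = F_{\mathrm{target}}$ under $K_h = 5K_s$
(80% of breeding sites are in houses) by root bracketing. The street weight
$w$ defaults to 1 (a plain block-count sum); an alternative convention
down-weights streets by 0.2, and the argument exposes it. With the standard
map and $F_{\mathrm{target}} = 10000$ (0.25 mosquitoes/m² over 40000 m²)
this gives $K_h \approx 3.68$, $K_s \approx 0.74$ per 25 m² cell, matching
the reported fitted values to a fraction of a percent.

## The synthetic city map

The reference experiments ran on a 40×40 raster of a real neighbourhood
(5 m cells; 26800 m² of house blocks, 13200 m² of streets) that is published
only as a figure. `default_city_map()` therefore builds a synthetic
Manhattan-style stand-in: street bands one cell wide every six cells, then
17 house cells in the bottom-right corner reassigned to streets so the
composition is exactly 1072 house / 528 street cells. It is committed at
`inst/extdata/city_map_synthetic.txt` (the generator reproduces it
bit-for-bit) and its capacities are calibrated to the 10000-female target.
The localized release footprint — reported only as a 943.71 m² central
rectangle — is a committed 38-cell (950 m²) compact central block; release
totals are exact, only the local density differs by the 0.7% area mismatch.
Everything that depends on the raster is therefore reproducible only up to
map choice, which is why the spatial-experiment checks carry the loosest
tolerances (see Limitations).

## The spatial solver

`simulate_pde()` advances the five fields with a cell-centred finite-volume
scheme: five-point diffusion stencils with arithmetic-mean face
coefficients, zero-flux (homogeneous Neumann) boundaries — the same
isolation assumption the ODE reduction uses — and Crank–Nicolson
time-centred reactions, by default one step per day. Each step solves the
coupled nonlinear system for $E, A, F, M$ by a damped Newton iteration:
analytic reaction Jacobian, sparse LU factorizations that are cached while
convergence stays fast and rebuilt when it slows, line search with up to
eight halvings, tolerance $10^{-10}$ on the residual scaled per field, at
most 50 iterations, and a hard failure (never a silent one) if the iteration
diverges.

The GM-male equation is linear with constant coefficients and feeds back on
the others only through $\alpha$, so $G$ is advanced by its exact one-step
transition operator $e^{\Delta t (L_G - \mu_g I)}$, computed once per solver
context, with the day-long constant-rate release response
$(L_G-\mu_g I)^{-1}(e^{\Delta t(L_G-\mu_g I)} - I)\,l$. This choice is not
cosmetic: a Crank–Nicolson step is A-stable but not monotone, and the sharp
spikes injected by infrequent pulse releases (a 30-day ration landing on 38
cells in one day) make it oscillate into negative densities, whereas the
matrix exponential is positivity-preserving and exact. Releases are
materialized as a constant rate over the whole release day, independent of
any sub-day step size, so refining $\Delta t$ refines the discretization
without changing the forcing.

After each step tiny negative round-off values (relative magnitude below
$10^{-8}$) are clamped to zero and $A$ is capped at $k$; larger violations
abort the run. That operationalizes the invariant-domain property: the
shipped scenarios run start to finish without ever tripping the guard.
Streets keep a small positive $k$, so the logistic factor is always
defined. Where $M + G$ underflows to zero mid-run, $\alpha$ takes its
defining branch value 1; this only occurs at extinction, where the egg
source vanishes anyway.

Numerical behaviour documented by the test suite: pure transport conserves
mass to $10^{-13}$; a 1×1 map reproduces the stiff single-cell ODE to
$2.6\times10^{-7}$ relative over 100 days at $\Delta t = 0.01$; symmetric
problems stay symmetric to round-off; halving the daily step changes
30-day pulsed-release totals by under 0.5%; and the analytic equilibria are
fixed points of the scheme to $10^{-8}$ over 50 steps.

## Release experiments

`make_release_schedule()` expresses release sizes as multiples of the
domain female equilibrium; the standard policy is 11× (110000 GM males per
day on the calibrated map, ≈116 mosquitoes/m²/day inside the central
footprint). Three experiment drivers implement the standard release
experiments:

* `localization_comparison()` — localized versus spatially homogeneous
  release of the same daily total;
* `heterogeneity_comparison()` — the same scenario on the heterogeneous map
  versus a homogenized map holding every cell at the block-count-weighted
  mean capacity;
* `frequency_scan()` — a fixed 30-day GM ration released every $p$ days,
  $p = 1,\dots,30$, with the collapse threshold operationalized as the
  largest period whose aquatic total at day 100 is below 50% of its initial
  value (the change is reported only qualitatively, as "abrupt"; the
  fraction is an exposed argument);
* `release_sweep()` — 300-day homogeneous daily releases over a rate grid,
  paired with the analytic expectation `expected_equilibrium_curve()`.

On the committed map the solver reproduces the reported qualitative
structure: daily 11× releases collapse the population (the domain-critical
rate is ≈18.4 per cell per day, ≈29500 per day domain-wide, well below the
110000 released); the localized-versus-homogeneous difference peaks at
≈43% of the initial aquatic population near day 51 (mobile phases: ≈40%
at day 60); and the frequency threshold lands at 6 days (period 7 retains
69% of the population under the 50% rule). Control runs stay within 0.7%
of the analytic aquatic/adult equilibria for 100 days.

## Numerical choices and known limitations

* **Time step.** One day by default. The aquatic relaxation rate
  $eE/k$ reaches ~20/day at equilibrium, so daily Crank–Nicolson steps are
  stable but track the fast transient only in a time-averaged sense;
  equilibria themselves are exact fixed points of the scheme, which is what
  the long-horizon experiments measure. Sub-day steps are available via
  `discretization_spec(dt = )`.
* **Egg totals under diffusion.** Starting at the per-cell analytic
  equilibrium, adult diffusion across house/street borders lowers the local
  $F\,M$ product, and the egg total drifts ~23% below its analytic value
  over 100 days while aquatic and adult totals stay within 0.7%. This is a
  genuine property of the spatial model, not solver error (it persists under
  step refinement).
* **Raster approximation.** The localization and heterogeneity percentages
  are sensitive to the raster and footprint position. On the synthetic map
  the heterogeneous-versus-homogenized difference reaches ~17% (reported:
  up to 8% on the real raster) and the localized-versus-homogeneous
  difference at day 100 is ~16% on the aquatic phase (~21% on the mobile
  phases; reported: ~29%). Probing a coarser street grid moves
  these by under 2 points, so the gap reflects the unavailable raster, not
  the street-pattern granularity.
* **Threshold region of the release sweep.** Near the domain-critical rate
  the coupled system departs from the weighted-average-capacity
  idealization: streets are individually supercritical at these rates and
  act as absorbing sinks for diffusing adults, so full collapse occurs at
  ≈0.8 of the predicted $L_{crit}$ and 300-day finals deviate up to ~10%
  from the analytic curve between 0.7 and 1.0 $L_{crit}$ (longer horizons
  do not close the gap). Away from the threshold the curve is matched to a
  few percent below it and the population is extinct above it — the
  qualitative bifurcation the formula predicts.
* **Out of scope.** No temperature/food/humidity dependence, no wind or
  advection, no disease transmission, no adaptive meshing; stability of
  equilibria is established numerically, not proved.

## Reproducing the reference-scale numbers

`scripts/acceptance.R` (repository root) regenerates the synthetic map,
calibrates it, runs the 100-day comparisons and the 30-period frequency
scan, and writes the headline numbers as JSON. Problem sizes mirror the
study: a 40×40 grid, daily steps, 100-day release experiments, a 30-period
scan. The whole script runs in about two minutes on one CPU; the test suite
takes about one.
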