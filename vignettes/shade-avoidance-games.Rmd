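---
title: "Selection on shade-avoidance plasticity in virtual rosette canopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on shade-avoidance plasticity in virtual rosette canopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shadegame)
```

## The question

Plants detect future competition through the red : far-red ratio (R:FR) of
the light they receive: leaves absorb red and reflect or transmit far-red,
so a falling R:FR signals that neighbours are near. The shade avoidance
syndrome — petiole elongation, hyponastic leaf raising, reduced blade
growth — is a plastic answer to that cue. `shadegame` asks how natural
selection acts on the *shape of the response curve itself*: is a given
R:FR sensitivity an evolutionarily stable strategy in a stand of
competitors at a given planting density?

The package couples two layers:

1. a simplified functional-structural stand simulator of Arabidopsis-like
   rosettes competing for light on a regular grid, and
2. an adaptive-dynamics layer that turns mutant-in-resident performance
   matrices into pairwise invasibility plots (PIPs) and classifies their
   singular strategies (convergence-stable ESS, branching point,
   non-convergent ESS, repeller).

## The trait under selection

Each plant carries a plastic response curve

\[ F = \min\!\left(2,\; \left(\frac{R\!:\!FR}{R\!:\!FR_{control}}\right)^{-\alpha}\right) \]

mapping locally perceived R:FR (control value 2.3, the unshaded source
ratio) to a relative organ growth factor, capped at 2 so an organ cannot
more than double in a day. The curvature $\alpha$ is the heritable
strategy (grid 0–0.7 in steps of 0.1); $\alpha = 0$ gives $F \equiv 1$, no
plasticity. Each day,

* **petioles** multiply their length by the $F$ computed from the R:FR at
  the petiole's own midpoint, *after* the day's sink-strength growth; the
  carbon cost of the added length, $(F-1)\,L\,\rho$ with $\rho$ the linear
  density, is queued as extra petiole demand for the next day and the
  length is not rolled back if that payment is later rationed;
* **laminas** down-regulate their sink demand, $D = D_p / F^{\,n}$, where
  $D_p$ is the potential (beta-growth) demand and the exponent $n$ sets the
  strength of the lamina response relative to the petiole response:
  $n = 2$ (Average), $n = 1$ (Weak), $n = 4$ (Strong). The source texts
  for this model family are internally inconsistent about the Weak
  scenario (1 in one place, 0 in another); this package defaults to the
  values above and accepts any $n \ge 0$, so both readings are runnable.

Plastic responses act only on organs still in their growth phase.

## The stand simulator

**Architecture.** Leaves (petiole + elliptical lamina blade, aspect ratio
2:1) appear in a 137.5° spiral every 1.5 days after a 3-day germination
lag (about 28 leaves over a 46-day run); the first-leaf azimuth is
randomised per plant, which, with Monte Carlo ray noise, provides the
replicate stochasticity. Leaves senesce strictly after 40 days: a
senesced leaf stops intercepting light and exerting sink demand, but its
biomass stays in the plant total, because performance is total
accumulated biomass. Hyponasty raises a leaf 16°/day (to a maximum of
80°) when the nearest other leaf tip is closer than 2 mm or the blade
perceives R:FR < 0.5. Only leaves whose petiole is still growing can
move — hyponasty is differential petiole growth, so a finished petiole
cannot reorient. Without that restriction, old leaves in dense stands keep
turning vertical and the late canopy artificially re-opens.

**Light.** A multiband (red, far-red, PAR) Monte Carlo ray tracer runs on
one stand tile with exact toroidal wrap-around in x and y — the limit of
replicating the canopy infinitely, which removes border effects the same
way the 20 × 20 plot replication of the original platform does (that
400-canopy count is kept as a reportable configuration). The diffuse
(cosine-weighted) source emits R:FR 2.3 and 220 µmol m⁻² s⁻¹ PAR for 9 h
per day. Blades absorb 0.85 of red/PAR and 0.15 of far-red and split the
remainder equally between specular reflection and transmission, so
canopies lower both the light level and its R:FR; petioles are sensors of
negligible area. Three estimates come out of each daily light pass:

* *forward pass* (default 20,000 rays, ≤ 2 scattering bounces): per-organ
  absorbed energy and an exact energy audit (emitted = absorbed +
  escaped, with residual energy after the bounce limit booked as
  escaped);
* *gather pass* (default 12 rays per organ sensor, cosine-weighted about
  the organ's own normal): a low-variance estimate of direct +
  transmitted incident flux per band. Orienting the gather hemisphere by
  the blade normal matters: a hyponastic, near-vertical blade receives
  sky light only at its projection and "faces" its neighbours sideways;
* the *scattered component*: per-organ incident energy arriving in the
  forward pass via at least one reflection. This is the lateral far-red
  reflection signal from neighbours. It is disjoint from the gather
  estimate (which counts only unreflected paths), so the two add without
  double counting.

Perceived organ R:FR and incident PAR are gather + scattered; whole-plant
mean R:FR is total perceived red over total perceived far-red, amounts
weighted by organ area.

**Carbon.** Per lamina, assimilation follows a negative-exponential light
response $A = p_{max}(1 - e^{-\phi I / p_{max}})$ on incident PAR, scaled
by blade area, the 9-h photoperiod and a CO₂-to-biomass conversion. All
assimilate enters one plant pool and is partitioned over growing organs by
relative sink strength: each organ demands the daily increment of its
beta growth curve (final mass $W_{max}$, duration $t_e$, inflection
$t_m$); the root is a pure sink demanding 10% of total leaf potential
demand. Under shortage every sink gets its proportional share; under
surplus all demands are met and the leftover is split half to the root and
half over laminas pro rata (the no-competition fate of extra carbon).
There is no respiration and no mortality: plants that run out of light
simply stop growing. Mass balance is exact by construction and tested:
daily biomass gain equals daily pool input.

**Performance** is the focal (centre) plant's total biomass — petioles +
laminas + root — at day 46. The focal plant carries the mutant strategy;
all other plants are residents. With toroidal wrap the mutant recurs in
every tile image, exactly as the original plot-replication convention.

### Parameter defaults and calibration

The organ-level constants of the parent model are not published with it,
so this package ships its own documented defaults (`default_params()`),
chosen once against two regime requirements and then frozen: at 100
plants m⁻² late-rank laminas should approach their potential size
(surplus regime), and at 1600–6400 plants m⁻² growth should be
carbon-limited well before day 46 (competition regime). The shipped set —
$W_{max}$ 30 mg / $t_e$ 20 d / $t_m$ 8 d for laminas, 8 mg / 15 d / 6 d
for petioles, SLA 3×10⁻⁵ m² mg⁻¹, petiole linear density 500 mg m⁻¹,
$p_{max}$ 14 µmol CO₂ m⁻² s⁻¹, $\phi$ 0.05, 0.03 mg µmol⁻¹, and a 2-mg
seed reserve released over the first six days after leaf initiation
begins — yields ~530 mg plants at density 100 versus ~40 mg at 6400, with
day-46 canopy R:FR falling from ~2.2 (100 m⁻²) to ~1.0 (6400 m⁻²).
Early-rank leaves stay small at every density because their growth window
falls in the establishment phase; late-rank leaves at low density reach
70–90% of $W_{max}$.

## The game-theoretic layer

For one (density, scenario), the experiment simulates every
mutant × resident cell of the strategy grid with `replicates` seeds
(full design: 8 × 8 cells × 20 replicates × 5 densities × 3 scenarios =
19,200 runs). The discrete invasion exponent of cell $(m, r)$ is
$\log(\bar w_{m,r} / \bar w_{r,r})$ (natural log; the sign structure is
base-invariant), zero on the diagonal by construction. Replicate
confidence intervals use
$\bar x \pm \mathrm{sd}(x)/\sqrt{n-1}$ with $x_i = \log(w_i/\bar w_{res})$;
cells whose interval includes zero are flagged inconclusive.

To read off singular strategies, mean performance is smoothed first and
exponents are formed afterwards: a tensor-product P-spline GAM (mgcv,
basis 8 × 8, REML with a mild overfit guard, γ = 1.4) is fitted to log
performance over the (mutant, resident) square — all replicates enter the
fit so the penalty is selected against the true replicate scatter; the
log scale matches positive, multiplicatively noisy biomass. The smoothed
invasion surface is the difference of linear predictors,
$s(m, r) = \eta(m, r) - \eta(r, r)$, which zeroes the diagonal to
machine precision.

The local selection gradient $g(r) = \partial s/\partial m|_{m=r}$ is
evaluated by central differences (step 1/200 of the strategy range) on a
201-point mesh; sign changes are refined by bisection. No extrapolation is
attempted: a gradient of constant sign yields a "beyond the tested range"
verdict in the direction of its sign — the expected outcome at the highest
density, where selection keeps favouring more sensitive strategies than
any tested. At each root the standard second-order conditions are
estimated by finite differences: $\partial^2 s/\partial m^2 < 0$ for
evolutionary stability and $dg/dr < 0$ for convergence stability; both
give a cESS. Estimates below an indeterminacy tolerance (absolute, or
2 × a bootstrap standard error over replicates when requested via
`analyse_pip(boot = )`) are reported indeterminate — the honest verdict
for complex PIP regions.

## The synthetic landscape generator

Because the simulator's true fitness surface is unknown, the
game-analysis layer is validated against `landscape_spec()`: the quadratic
family $s(m, r) = k(\alpha^* - r)(m - r) - h(m - r)^2$, the minimal family
whose singular strategy ($\alpha^*$), ESS curvature ($-2h$) and
convergence slope ($-k$) are independent knobs, so all four
singular-strategy classes are reachable. Mutant replicates draw
$w = \text{baseline}\, e^{s(m,r)}$ times log-normal noise with coefficient
of variation `replicate_cv`; diagonal cells reuse the resident draws, so
the estimated diagonal exponent is exactly zero. The default
`replicate_cv = 0.1` is of the order of the replicate scatter of
desk-preset stand runs (biomass CV ≈ 0.05–0.15 across densities). With
zero noise the pipeline recovers $\alpha^*$ to about 10⁻³ and classifies
60/60 random specs correctly; at cv = 0.1 with 20 replicates, $\alpha^*$
is recovered within one grid step (0.1) in ≥ 95% of specs, with the
residual misses concentrated near the edges of the sampled $\alpha^*$
range where the gradient is shallow. The quadratic family is test
scaffolding, not a claim about the simulator's true surface.

## Problem sizes and presets

`preset_config("paper")` encodes the full published design (7 × 7 stands,
20,000 rays, 19,200 runs) — it enumerates and validates, and any slice of
it can be run, but the complete sweep is a cluster-scale computation.
`preset_config("desk")` is the package's routine-validation scale, used by
the test suite and the acceptance script: 5 × 5 stands, densities
{100, 1600, 6400}, strategy grid {0, 0.2, 0.4, 0.6}, 5 replicates, 3,000
forward rays and 8 gather rays per organ. One desk stand-run takes a few
seconds; the directional suites (biomass, R:FR and allocation orderings;
cue-reliability; local selection gradients at $r = 0$ estimated from
$s(0.2, 0)/0.2$) complete in minutes. Because a non-plastic resident has
$F \equiv 1$ regardless of $n$, monomorphic $\alpha = 0$ baselines are
shared across scenarios.

## What the tests do and do not show

The synthetic-landscape suite exercises the full game-theoretic pathway
end to end with known truth; it shows the analysis layer is correct, not
that the simulator's fitness surface matches any real canopy. The
simulator suites are directional: they verify the qualitative structure
the analysis depends on (denser stands are darker, poorer and more
elongated; selection for sensitivity strengthens with density and weakens
with lamina cost) at desk scale, not quantitative agreement with
glasshouse data — the parent platform's validated radiometry and measured
organ parameters are deliberately out of scope. Known limitations: flat
elliptical blades (no curvature or zenith tracking), no blue-light
signalling, no mechanical petiole costs, density-independent organ
initiation, a diffuse light field rather than a lamp array, and
single-generation dynamics with the resident assumed at carrying
capacity.

## Numerical choices and degenerate inputs

Ray counts are fidelity knobs, not results: energy closure is exact by
bookkeeping at any budget, and perception noise averages out over days.
Gather rays that leave through the ground contribute darkness; scattered
residual energy beyond the bounce limit is booked as escaped. An empty
scene absorbs nothing and is not an error; a zero-area lamina produces no
patch; organs with zero perceived far-red report missing R:FR and default
to $F = 1$ that day. Singular strategies are only sought inside the
strategy range, classification is refused on the boundary, and a flat
gradient (≡ 0) is reported degenerate. Allocation handles a zero-demand
pool by sending surplus to the root. All stochastic stages draw from R's
RNG, so a single integer seed makes any stand, experiment or acceptance
run bit-reproducible; per-cell seeds derive from a stable 31-bit hash of
the design coordinates, letting any single run of a large design be
reproduced in isolation.
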