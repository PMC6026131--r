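---
title: "Models and methods for pial arterial network analysis"
author: "pialnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for pial arterial network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pialnet)
```

## The scientific setting

The pial (leptomeningeal) arterial network sits on the cortical surface
and feeds the parenchyma through penetrating arterioles (PAs), each a
flow bottleneck supplying a column-sized territory.  Collateral vessels
— leptomeningeal anastomoses (LMAs) — join pial arteries into loops that
can reroute flow around occlusions.  Traced as a planar graph, the
network splits into a loop-bearing *backbone* and short *offshoots* that
leave the backbone and end in one or more PAs.  The analysis questions
the package addresses are whether the density of PAs and LMAs, and the
offshoot branching structure, differ between cortical regions and
between sensory-deprived (whisker-plucked) and sham-treated animals.

`pialnet` implements the full chain: a seeded synthetic-cohort generator
with ground-truth labels, structural quantification of the graphs,
Voronoi-based territory assignment, and the Poisson mixed-effects count
model with which region and deprivation effects are tested.

## The count model

Counts $C$ (PAs, LMAs, or offshoot vertices) in the region
$\times$ animal cell are modelled as Poisson with a log link and a known
log-area offset, so coefficients act on densities:

$$
\log E[C] \;=\; \gamma_1 S + \alpha_0 Y + \alpha_1 (Y\!\times\!S) +
\gamma_3 G + \gamma_4 R + \gamma_5 (S\!\times\!R) + u_M + \log A ,
$$

where $S$ is deprivation group (reference *sham*), $Y$ age in days
(centred at the cohort mean), $G$ sex (reference *M*), $R$ cortical
region (reference *barrels*), $A$ the region area in mm², and
$u_M \sim N(0, \sigma_u^2)$ a per-animal random intercept shared across
regions, capturing between-animal variability in overall counts.

`fitPoissonGlmm()` maximises the *marginal* likelihood — the Poisson
likelihood integrated over $u_M$ — using adaptive Gauss–Hermite
quadrature (15 nodes by default; 1 node is the Laplace approximation).
For each animal the integrand's mode is found by Newton's method, the
quadrature grid is centred and scaled there, and a quasi-Newton
optimiser (`nlminb`) maximises over the fixed effects and
$\log \sigma_u$, started at the $\sigma_u = 0$ Poisson regression.
Convergence is declared at a relative log-likelihood change below
`1e-8`.  The likelihood kernel is implemented in C++ so that the
calibration experiments below are cheap.  Design matrices use explicit
treatment-coded columns rather than R's formula expansion so that
"drop one factor" removes exactly that factor's columns: dropping
$S\!\times\!R$ from a five-region table frees 4 degrees of freedom, and
dropping $S$, $Y$ or $G$ frees 1, matching the $\chi^2(4)$ and
$\chi^2(1)$ reference distributions used in the factor tests.

Numerical notes: $\sigma_u$ is optimised on the log scale with a lower
bound of $10^{-6}$ (estimates at the bound are reported as 0); standard
errors come from the numerically differentiated observed information,
with a fixed-$\sigma$ fallback when the full Hessian is ill-conditioned
near the $\sigma_u = 0$ boundary; fitted values condition on the
empirical Bayes modes of the animal intercepts.

### Factor tests and post-hoc contrasts

`likelihoodRatioTest()` compares nested fits by twice the difference in
maximised marginal log-likelihood against $\chi^2$ with the difference
in fixed-parameter counts.  `tukeyPosthoc()` computes all pairwise
region contrasts on the link scale with a single-step max-|z|
multivariate-normal adjustment, evaluated by seeded Monte Carlo
($10^5$ draws by default) from the contrasts' joint normal — the
z-based analogue of Tukey's honestly-significant-difference procedure
appropriate for mixed-model contrasts.  Back-transformed density
differences can be read off the count tables descriptively; tests are
performed on the link scale.

`dispersionCheck()` refers the sum of squared Pearson residuals to
$\chi^2$ with $n_{\mathrm{obs}} - n_{\mathrm{fixed}}$ degrees of freedom
(the random intercept is not counted) and always reports both one-sided
tails, for the alternatives of over- and under-dispersion.

`lmaPaRegression()` is ordinary least squares of per-animal LMA totals
on PA totals with a $t$-test on the slope and Bonferroni correction,
applied to the pooled, deprived-only and sham-only point sets (family
size 3).

`detectableEffectSize()` inverts the noncentral-$t$ power function of a
two-sample $t$-test by bisection (to $10^{-6}$): for group sizes 10 and
9 at $\alpha = 0.05$ (one-tailed) and power 0.8 the minimal detectable
Cohen's $d$ is 1.19, i.e. 1.2 to one decimal; the normal-approximation
value $(z_{1-\alpha} + z_{1-\beta})\sqrt{1/n_1 + 1/n_2} \approx 1.14$ is
necessarily smaller because the $t$ reference has heavier tails.

## The synthetic-data generator

`generateCohort()` emulates the features of traced cohorts that the
analysis relies on; its defaults are the package's study conditions:

| parameter | default | meaning |
|---|---|---|
| `slabAreaMm2` | 35 | cortical slab area (mm²) |
| `regionAreasMm2` | barrels 4, forelimb 1.5, hindlimb 1, visual 3, auditory 1.5 | region areas (mm²) |
| `lambdaPaPerMm2` | 17.4 | global PA intensity (mm⁻²) |
| `lmaRatePerMm2` | hindlimb 2, others 1 | per-region LMA intensity (mm⁻²) |
| `sigmaU` | 0.25 | sd of the animal log-intensity intercept |
| `deprivationMultiplier` | 1 | multiplier on deprived barrels intensities |
| `offshootBifurcationProb` | 0.25 | chance an offshoot carries a second PA |
| `nSham`, `nPlucked` | 10, 9 | cohort sizes |
| `ageRangeDays` | 45–65 | uniform age bounds (days) |

The global PA density and the cohort composition (19 animals, 9
deprived / 10 sham, 9 M / 10 F, ages P45–P65) are fixed study
conditions.  True per-region LMA intensities and region areas are not
tabulated anywhere we could adopt them from, so the region-area targets
and the hindlimb-enriched (2×) LMA rates are declared assumptions of
the generator, chosen to be of realistic magnitude for a flattened
mouse cortex preparation; they are configuration, not estimates.

Per animal the generator: (1) draws $u \sim N(0, \sigma_u^2)$; (2)
draws per-region PA counts from
$\mathrm{Poisson}(\lambda_{PA} A_r e^u m_r)$ — with
$m_r$ = `deprivationMultiplier` on the barrels region of deprived
animals — plus a uniform background process at $\lambda_{PA}$ in the
slab outside the regions, placing points uniformly; (3) draws
per-region LMA counts at the per-region rates; (4) builds a connected
backbone tree spanning the attachment sites and adds each LMA as a
chordal edge, so each LMA creates exactly one independent cycle and
loop counting is exactly testable against truth labels; (5) attaches
each PA by an offshoot stub which with probability 0.25 carries one
bifurcation and a second PA leaf (consuming a neighbouring PA from the
pool, so total PA counts remain Poisson-calibrated).

Two construction choices deserve mention.  First, the backbone is a
chain of quadrilateral loops sharing junction nodes, so the bridgeless
core is a single connected subgraph and every offshoot touches the
backbone at exactly one node — the decomposition invariant holds by
construction.  Second, edge polylines at the LMA endpoints realise the
morphological criterion for anastomoses: at each endpoint bifurcation
the acute branching angle points toward the other endpoint.  The
geometric classifier in `identifyLmaEdges(mode = "geometric")` tests
exactly this (bisector of the most acute pair of other incident edge
tangents within 90° of the edge direction, on non-bridge edges only),
and recovers essentially all constructed LMAs with under 1% false
positives.  Sinuosity, which real LMAs often show, is drawn but not
used by the classifier.

What the generator does *not* emulate: vessel diameters (never
quantified), realistic vessel tortuosity statistics, curvature of real
region boundaries (regions are convex polygons), fixation shrinkage,
or spatial interactions between PAs (a hard-core process would be more
realistic than Poisson at very short range).  Passing tests therefore
demonstrate correctness of the measurement and inference machinery
under the stated model, not fidelity of any particular biological
claim about real cortex.

## Territories and count tables

`voronoiTiling()` clips the slab by perpendicular-bisector half-planes
(visiting other seeds nearest-first and stopping once no further
bisector can cut), which partitions the slab exactly: cell areas sum to
the slab area to within $10^{-6}$ relative error.  A PA is counted
"inside" a region only if more than half of its Voronoi cell's area
lies in the region (`assignPaRegions()`).  Exact 0.5 ties have measure
zero in continuous data but are resolved deterministically to the
lexicographically smallest tied region, with a warning.  PAs whose
majority falls outside all regions count toward no region.

LMAs are localised by their midpoint (arc-length midpoint along the
polyline when present); a midpoint in no region is attached to the
nearest region boundary within `nearCutoffMm = 0.3` mm, a default
motivated by the ±50 µm accuracy with which stained region boundaries
can be traced plus the scale of the vessels themselves; it is
configurable.  Offshoots are assigned to the region containing their
attachment node — the assignment rule for branch statistics is not
uniquely dictated by morphology, and the attachment node is the one
point every offshoot has on the backbone.

Missing (damaged) animal–region combinations are *omitted rows*, not
zeros: `buildCountTable(..., omit = )` drops them, and the model's
offset structure makes the remaining rows directly comparable.

## Calibration and what the tests check

The acceptance suite ties the machinery to quantitative expectations:

- the minimal detectable effect size computation (above);
- a 200-animal cohort at default calibration, pushed through the full
  geometry/network/Voronoi/count-table path, reproduces the global PA
  density within three standard errors of 17.4 mm⁻²;
- likelihood-ratio drop-one tests carry df 4 (deprivation × region) and
  df 1 (deprivation);
- the maximised marginal likelihood matches a dense-grid,
  trapezoid-integration oracle on a small toy table to $10^{-3}$;
- type-I error of the deprivation LRT and of the dispersion check sit
  in [0.03, 0.07] at nominal 0.05 over 500 null simulations, and an
  injected deprivation effect of $\log 0.7$ is recovered with |bias| <
  0.05 and ~95% CI coverage over 100 replicates of 40-animal cohorts;
- the backbone/offshoot decomposition agrees with brute-force bridge
  enumeration, and Voronoi cell areas agree with stratified Monte-Carlo
  estimates to 0.5%.

The calibration and recovery experiments simulate count tables directly
from the count model (`simulateCountTable()`) rather than generating
full network geometry for every replicate: the properties under test
concern the inference machinery only, and the count-level simulator is
distributionally identical to the counts the full generator produces.
Full-geometry paths are exercised separately (the density-consistency
check and the per-module tests).  Problem sizes — 500 null replicates,
100 recovery replicates of 40 animals, a 200-animal density cohort —
were chosen so that binomial/Monte-Carlo error is small relative to
the acceptance bands.

## Known limitations

- The Poisson family is the only count family implemented; a
  negative-binomial alternative is out of scope.
- Region polygons are assumed convex by the generator (clipping
  intersects arbitrary simple subjects with convex clippers, so
  user-supplied concave *regions* are handled for areas, but the
  generator never produces them).
- The geometric LMA classifier is a convenience built on constructed
  angle geometry; all pipeline statistics use curated labels.
- With no LMAs in a network there is no backbone; decomposition raises
  an error rather than returning an empty core, and offshoot-flavoured
  count tables propagate it.
- Within-animal hemisphere contrasts and any Bayesian fitting are
  deliberately not provided.
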