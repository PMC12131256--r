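---
title: "From bending traces to group inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bending traces to group inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrig)
```

## The measurement problem

Flexible plant probes — the kind wild chimpanzees strip from stems and bark
to fish *Macrotermes* termites out of their mounds — are beams. Their
functional behaviour is governed by flexural rigidity $EI$, the product of
the material's elastic modulus $E$ (Pa) and the cross-section's second
moment of area $I$ (m$^4$). A four-point bending test measures $EI$
directly: the beam rests on two lower supports a span $L$ apart, two inner
probes at offset $a$ from the supports press down, and the force--displacement
curve's initial slope $dF/dx$ gives

$$EI = \frac{dF}{dx}\,\frac{a\,(3L^2 - 4a^2)}{48}.$$

At $a = L/2$ this collapses to the familiar central-loading form
$\frac{dF}{dx}\,L^3/48$. Because the inner span is in pure bending,
four-point tests need no particular span-to-depth ratio, which is what makes
them practical on thin field samples. Dividing $EI$ by $I$ — computed from
idealized regular cross-sections, $\pi R^4/4$ for circular stems and
$W D^3/12$ for rectangular bark strips — recovers $E$, a geometry-free
material property.

`flexrig` implements this measurement chain end to end: trace ingest with
unit normalization, initial-slope extraction, the beam formulas, a
quality-control filter, grouping of samples by tool-selection category, and
linear mixed-model comparisons between the groups.

## Initial-slope extraction

"Initial slope" is underdetermined: real traces begin with a *toe region*
of seating compliance where force rises sub-linearly, and end (outside the
initial regime) in softening. The extractor:

1. discards leading points with force below `toe_force_frac` (default 2%)
   of the peak force;
2. restricts attention to the first `search_fraction` (default 50%) of the
   remaining displacement range;
3. evaluates least-squares fits for every window that **ends at the search
   boundary** and starts at successive early points (at least `min_points`
   = 5 points);
4. requires the best window to reach `r2_threshold` (default 0.99), and
   returns the **earliest start whose $r^2$ lies within the near-optimal
   band** $r^2 \ge 1 - 2\,(1 - r^2_{\max})$.

The pinned window end is deliberate. A rule of the form "earliest window of
any extent achieving $r^2 \ge 0.99$" fails in both directions: long windows
that straddle a smooth toe still fit well enough to pass (we measured a 3%
slope bias on a noiseless quadratic-toe curve, against a 0.5% requirement),
and short windows *inside* a smooth toe fit almost perfectly while
estimating the local — wrong — slope. Sweeping only the start monotonically
sheds toe curvature; the near-optimal band then makes the noiseless case
exact (pure linear windows have $r^2 = 1$, contaminated ones strictly less)
while under noise it prefers the longest window statistically
indistinguishable from the best, so no lucky micro-window can hijack the
fit. Degenerate traces (constant or all-zero force) and negative fitted
slopes are errors, never silently clamped: a negative slope means a
corrupted test, not a very flexible sample.

## Quality control

Derived moduli above 35 GPa exceed what dense lignified tissue can
plausibly reach and indicate a measurement artifact (slipping supports,
mis-measured cross-section); such samples are flagged and excluded. The
boundary is strict — exactly 35 GPa is retained — and the partition
retained/dropped is exhaustive, so every input sample is accounted for in
the run log. $I$ entering any analysis is always recomputed from the
canonical SI cross-section rather than read from input files, eliminating
unit drift between ingest dialects.

## The mixed models

Multiple samples are cut from each individual plant, so samples are not
independent; a per-plant random intercept absorbs that correlation. On the
natural-log scale (which makes the multiplicative physics additive and the
residuals approximately normal):

* rigidity: $\log EI \sim \text{group} + \log I + (1\,|\,\text{plant})$ —
  the $\log I$ covariate controls for cross-sectional geometry, so the
  group term isolates material-driven differences in rigidity;
* stiffness: $\log E \sim \text{group} + (1\,|\,\text{plant})$ — $E$ is
  already geometry-normalized, so the covariate is dropped.

Models are fit by REML via `lme4`. Inference is implemented in-package
because the usual helper packages are deliberately not dependencies:

* **Type-II F tests.** With no interactions present, the type-II test for
  a term is the joint Wald test of its coefficients. Denominator degrees
  of freedom use the Satterthwaite moment match
  $\nu = 2 v^2 / (\nabla v^\top A\, \nabla v)$, where $v$ is the contrast
  variance, $\nabla v$ its gradient in the variance parameters
  (plant SD, residual SD), and $A$ the asymptotic covariance of those
  parameters from a central-finite-difference Hessian of the REML
  criterion. Multi-df terms are handled by eigendecomposing the contrast
  covariance into independent one-df pieces and moment-matching the sum of
  squared $t$'s — the same construction `lmerTest` uses, against which the
  implementation was verified during development (F to $<10^{-6}$
  relative, df to $\sim 10^{-3}$, Tukey p to $\sim 10^{-5}$; the reference
  values are frozen in the test suite).
* **EMM contrasts.** Estimated marginal means evaluate the model at each
  group level with the covariate at its grand mean; all pairwise
  differences get Satterthwaite df and a Tukey (studentized-range)
  family-wise adjustment. For two-level schemes the family has size one
  and the adjustment is a no-op.
* **Singular fits.** When the plant variance is estimated at zero the
  REML Hessian is not positive definite and Satterthwaite is undefined;
  the code flags the fit, warns, and falls back to residual df rather than
  failing.
* **Effect sizes.** Percent rigidity differences are reported on two
  bases: raw group medians (default, the most literal reading of
  "x% more rigid") and back-transformed EMM differences
  $(\exp(\Delta \mathrm{EMM}) - 1)\cdot 100$, which condition on geometry.
  Both appear in the pipeline output since the field convention is
  ambiguous.

Natural logs are used throughout; every reported statistic (F, t, p) is
invariant to the log base and to the physical units of $EI$ and $E$, which
the test suite checks to $10^{-8}$.

## Grouping schemes

Four categorizations mirror how tool-material selectivity is studied:
tool-source species (yes/no, all samples), species preference
(most preferred / less preferred / never used, all samples), individual
plant use (removal scars present / absent, tool-source species only), and
raw material type (twig / vine / bark / grass, tool-source species only —
material labels are only meaningful for species that actually furnish
tools, and the reference group counts are defined on that subset).
Preference ranks derive from assemblage shares: $\ge 11.7\%$ of recovered
tools $\Rightarrow$ most preferred, $\le 10\%$ $\Rightarrow$ less
preferred. The open interval $(0.10, 0.117)$ is unaddressed by that rule;
shares falling there are classified less-preferred with a warning, keeping
the most-preferred set conservative.

## The synthetic world

The generator emulates the study design so that every stage is testable
with no field data: species nested in preference categories, ~3--7 plants
per species, three samples per plant; per-plant material assignment
(twig-dominated mix with bark common); log-normal $E$ composed as material
mean + preference offset + species effect + plant effect + residual (log-scale
SDs 0.5 / 0.4 / 0.3 by default); tool-like cross-sections (radii 0.5--4 mm,
bark strips up to 8 mm wide); and traces synthesized by inverting the
four-point formula, with optional quadratic toe (continuous in value and
slope at the junction) and Gaussian force noise. Default material means
put twig/vine/grass at 8/4/10 GPa and bark at 0.6 GPa, reproducing the
qualitative signature that bark is far more compliant than woody tissue and
keeping ≥95% of draws inside the 0.1--35 GPa envelope observed for woody
plant parts. The rig default ($L = 0.1$ m, $a = 0.025$ m) is an arbitrary
but plausible portable-rig scale — no apparatus constants are published for
the field device, so they are required configuration on real data.

Determinism: one master seed drives cohort generation, and each trace uses
a derived per-sample substream, so cohorts are bit-reproducible regardless
of the order in which traces are materialized.

**What a green test does not establish.** The generator draws independent
log-normal effects and uniform dimensions; real plant data have skewed
species abundances, correlated dimension-material combinations, irregular
cross-sections (the regular-shape $I$ is itself an approximation), and
possible heteroscedasticity. Passing the synthetic acceptance suite
validates the *machinery* — formulas, slope extraction, QC bookkeeping,
mixed-model inference — not the field conclusions.

**Calibration worlds.** The null-calibration and CI-coverage checks use a
generator configuration consistent with the fitted model: species-level SD
set to 0 (the model has no species random term) and a single material (the
per-plant material offset would otherwise make the plant effect a bimodal
mixture). Under the *realistic* default world, a species-level grouping
factor tested with only a plant random intercept is anticonservative —
a limitation shared by any analysis of this design, worth remembering when
interpreting borderline p-values. At a reduced 40-plant scale even the
model-consistent world shows mild small-sample anticonservatism
(rejection ~0.07--0.09 at $\alpha = 0.05$, identical in an independent
reference implementation), which is why the calibration criterion runs at
its stated 200-plant scale.

## Numerical choices

* Window fits use prefix-sum least squares (O(1) per window), with $r^2$
  defined as 1 for exact fits and undefined (excluded) for zero-variance
  force segments.
* Finite-difference steps scale with the parameter
  ($10^{-4}\,|\theta|$, floored at $10^{-6}$); the Hessian is accepted only
  if positive definite, otherwise the residual-df fallback engages.
* Duplicated displacements are averaged (encoder jitter), non-monotone rows
  are sorted; both happen before any fitting.
* Tie-break in slope selection: earliest qualifying start; at equal $r^2$
  this is also the longest window.
* Strict SI internally (m, N, Pa); non-SI units exist only at I/O
  boundaries with declared-unit conversion, and the written canonical
  metadata round-trips bit-identically through `%.17g`.

## Known limitations

* Only single-grouping-factor random-intercept models are supported — the
  design analyzed here — not crossed or nested random effects.
* No shear correction, viscoelasticity, or plasticity; the beam model is
  linear-elastic Euler--Bernoulli.
* The slope extractor assumes the nonlinearity to guard against is a
  *leading* toe; softening that intrudes into the configured search
  fraction would bias slopes low (mitigated by the 50% default).
* Satterthwaite df (like Kenward--Roger) is an approximation; at very
  small cluster counts its F-tests run slightly hot even in the
  model-consistent world.
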