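# flexrig

Measurement-to-inference pipeline for the biomechanics of flexible plant
probes — the termite-fishing tools chimpanzees strip from twigs, vines,
bark and grass. `flexrig` takes raw four-point-bending force–displacement
traces plus sample metadata and produces, per sample, flexural rigidity
*EI* and elastic modulus *E*, then compares tool-selection categories with
linear mixed models. A hierarchical synthetic-study generator with known
ground truth makes every stage testable without field data.

## The mechanics

For a beam on supports a span *L* apart, loaded by two inner probes at
offset *a*, the initial slope *dF/dx* of the force–displacement curve gives

```
EI = (dF/dx) · a · (3L² − 4a²) / 48        [N·m²]
I  = πR⁴/4  (circular)   or   W·D³/12  (rectangular)
E  = EI / I                                 [Pa]
```

Samples whose derived *E* exceeds 35 GPa (beyond dense woody tissue) are
flagged and dropped by QC. Group comparisons are REML mixed models on the
natural-log scale with a per-plant random intercept (samples are cut in
triplets from individual plants):

```
log EI ~ group + log I + (1 | plant)     # geometry-controlled rigidity
log E  ~ group +         (1 | plant)     # material stiffness
```

followed by type-II F tests with Satterthwaite denominator df and
Tukey-adjusted pairwise contrasts of estimated marginal means — all
implemented in-package on top of `lme4` (verified against independent
reference implementations; see the methods vignette).

## Worked example

Simulate a study (11 species × 4 plants × 3 samples, bark much more
compliant than woody materials, a 0.7 log-rigidity penalty on never-used
species) and analyze two grouping schemes:

```r
library(flexrig)
cfg <- synthetic_config(seed = 7,
  n_species = c(most_preferred = 3, less_preferred = 4, never_used = 4),
  plants_per_species = 4,
  effect_logE = c(most_preferred = 0, less_preferred = 0.12, never_used = 0.7))
res <- run_synthetic(cfg, schemes = c("tool_source", "material_type"))
```

The run log prints the QC and per-model summaries:

```
[ingest] 132 metadata records
[qc] 125 retained, 7 dropped (E > 35 GPa)
[groups] tool_source: yes=81, no=44
[stats] tool_source.log_EI: F(1, 39.78) = 0.5, p = 0.483
[groups] material_type: twig=51, vine=3, bark=24, grass=3
[stats] material_type.log_EI: F(3, 23.56) = 33.72, p = 1.08e-08
```

`res$anova`, `res$contrasts` and `res$percent_diff` hold the tables:

```
        scheme response  term         F df1   df2         p
 material_type   log_EI group   33.7173   3 23.56 1.081e-08
 material_type   log_EI log_I 1914.9090   1 57.81 5.171e-46

        scheme response    contrast estimate       t     p_adj
 material_type   log_EI twig - bark   2.1426  9.8099 3.109e-09

        scheme response reference level pct_median pct_emm
 material_type   log_EI      twig  bark      -97.9   -88.3
```

Reading: raw material type strongly predicts rigidity even after
controlling for cross-sectional geometry (`log_I`); bark implements are
~88% less rigid than twigs at matched geometry (EMM basis; the raw-median
basis, −97.9%, additionally reflects bark's different cross-sections). The
`tool_source` comparison at this small scale is not resolvable
(F(1, 39.8) = 0.5): with only 11 species and a species-level SD of 0.5 the
species-level contrast is underpowered — by design the generator makes
power questions honest.

Fractional denominator df (e.g. `F(3, 23.56)`) are the Satterthwaite
approximation, matching standard mixed-model ANOVA output.

## Real-data layout

```r
res <- run_pipeline(run_config(
  traces   = "path/to/traces/",          # one <sample_id>.csv per sample
  metadata = "path/to/metadata.csv",     # dimensions in cm/mm, see ?read_metadata
  geometry = bend_geometry(L = 0.1, a = 0.025),
  out      = "results/"))
```

or from the shell:

```sh
Rscript inst/cli/flexrig.R analyze --traces traces/ --metadata metadata.csv \
    --geometry 0.1,0.025 --scheme all --out results
```

`simulate` and `all` subcommands write/consume the same on-disk layout.

## Package layout

- `R/trace.R`, `R/metadata.R` — ingest and SI normalization
- `R/mechanics.R` — slope extraction, beam formulas, QC
- `R/groups.R` — the four grouping schemes and preference classification
- `R/lmm.R` — mixed models, Satterthwaite ANOVA, EMM Tukey contrasts
- `R/synth.R` — synthetic cohorts, traces, ground truth
- `R/pipeline.R` — orchestration and CLI
- `vignettes/flexrig-methods.Rmd` — models, design choices, limitations
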