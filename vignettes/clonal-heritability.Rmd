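---
title: "Estimating broad-sense heritability from clonal cell lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating broad-sense heritability from clonal cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(clonherit)
library(dplyr)
```

## The problem

Somatic evolution — of tumours in particular — requires that cell-level
traits be heritable: daughter cells must resemble their mothers beyond what
shared environment explains. `clonherit` implements the quantitative-genetic
machinery for measuring this from time-lapse lineage tracking of clonally
dividing cells. Two whole-lifetime traits are supported:

* **generation time** — the span of one full cell cycle, cytokinesis to
  cytokinesis, in hours;
* **curvilinear speed** — the total Euclidean polyline length of the cell's
  path over its lifetime, in microns, divided by its generation time
  (µm h⁻¹).

Broad-sense heritability H² is estimated as the slope of an ordinary
least-squares regression of trait values between related cells,
H² = Cov(x, y)/Var(x) — the classical parent–offspring regression adapted to
clonal families. Because cytoplasmic factors partitioned at division make
*sisters* transiently similar, the same slope is computed for three
relationships with different meanings:

* **sister–sister** — inflated by transient shared-cytoplasm effects;
* **mother–daughter** — one round of transmission;
* **cousin–cousin** — second-generation descendants of the same progenitor
  via different daughters. Cousins never shared cytoplasm, so their
  similarity isolates stably inherited lineage factors.

A trait whose similarity is stably inherited shows comparable slopes in all
three relationships; a trait whose similarity is only a division-time
artefact shows a sister slope but no cousin slope.

## Inclusion rules

All estimation uses only cells observed for a *complete* cell cycle: both
the birth division and the cell's own division lie inside the recording.
Four exclusion categories are tracked per cell: `founder` (originally
plated, birth unobserved), `off_screen`, `died`, and `censored_at_end`
(still undivided at the last frame). Excluded cells keep their rows in the
trait table; off-screen cells carry a partial-lifetime speed used only by
`offscreen_speed_test()`, which asks whether cells lost from view moved
differently from fully tracked ones (a selection-bias check), never by the
heritability regressions.

`family_census()` reports the exclusion waterfall and how many families
permit at least one cousin comparison — the binding constraint on the
dataset, since a usable family needs complete cells in both granddaughter
branches.

## Averaging and pairing rules

Where a cell has several tracked complete daughters or cousins, their mean
enters the pair, so each family contributes limited pseudo-replication:

* mother–daughter: x = mother, y = mean of her complete daughters;
* sister–sister: one pair per dyad. The regression needs an orientation, so
  the default puts the first-tracked sister on x; a `double_entry` mode
  enters each dyad in both orientations (orientation-invariant slope) and
  counts degrees of freedom on unique dyads to avoid pseudo-replication;
* cousin–cousin: the default `branch` mode emits one point per grandmother
  (branch means on both axes, so no cell is reused); a `focal` mode emits
  one point per complete grandchild against the mean of its cousins.

Slope significance is a two-sided t-test with df = n − 2 (dyads − 2 under
double entry), with no multiple-testing correction: each relationship ×
trait cell is reported on its own, with the conventional star thresholds
(\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001). Estimates are always per
cell line; pooling across lines would conflate between-line differences
with within-line heritability.

## The generative model

No public dataset accompanies this class of experiment, so the package
ships a simulator whose statistical structure matches what the estimator
assumes, giving closed-form truth for validation. Each trait is additive
Gaussian on the pedigree:

$$z = \mu + g + s + u$$

* `g` — stably heritable component, transmitted as an AR(1) process down
  the lineage: \(g_{\text{daughter}} = a\,g_{\text{mother}} + \delta\),
  \(\delta \sim N(0, \sigma_\delta^2)\). Founders draw `g` from the
  stationary distribution \(N(0, \sigma_g^2)\) with
  \(\sigma_g^2 = \sigma_\delta^2 / (1 - a^2)\), so component variances are
  constant across generations.
* `s` — sister-shared transient, drawn once per division and given to both
  daughters (the cytoplasmic-partition effect).
* `u` — independent environmental noise.

With \(\sigma_z^2 = \sigma_g^2 + \sigma_s^2 + \sigma_u^2\), the expected
regression slopes are closed-form:

| relationship | expected slope |
|---|---|
| mother–daughter | \(a\,\sigma_g^2 / \sigma_z^2\) |
| sister–sister | \((a^2 \sigma_g^2 + \sigma_s^2) / \sigma_z^2\) |
| cousin–cousin | \(a^4 \sigma_g^2 / \sigma_z^2\) |

These forms assume a single cell's value on the x axis, which holds for the
sister modes, mother–daughter, and `focal` cousins. The `branch` cousin
mode regresses branch means on branch means; when a branch holds two cells
Var(x) shrinks below \(\sigma_z^2\) and the expected slope exceeds
\(a^4\sigma_g^2/\sigma_z^2\). Parameter-recovery tests therefore use the
focal mode; the branch mode remains the analysis default because it never
reuses a cell across points.

```{r}
cfg <- sim_config(n_founders = 400, seed = 7)
gt <- simulate_pedigree_traits(cfg)
tt <- truth_trait_table(gt)
glance(estimate_h2(enumerate_pairs(tt, "mother_daughter", "speed")))
expected_slopes(cfg) |> filter(relationship == "mother_daughter")
```

## Default parameters and where they come from

The recording design defaults are a 20-minute frame interval over 72 hours
(217 frames), three tracked generations per family, six wells with five
imaging fields assigned round-robin — the standard design for this kind of
experiment. The pixel scale is never embedded in tracking output, so
readers require `microns_per_pixel` explicitly; the simulator default of
0.65 µm px⁻¹ is typical widefield 10× camera sampling.

Trait defaults emulate a fibrosarcoma-like line: speed 37.55 ± 10.03
µm h⁻¹ and generation time 14.22 ± 4.15 h. The reported total SDs fix
\(\sigma_z\); the split between components is this package's own choice,
made once to reproduce the qualitative pattern reported for such lines:

* **speed** (motility-like regime): a = 0.97, \(\sigma_g^2 = 52\),
  \(\sigma_s^2 = 10\), \(\sigma_u^2 = 38.6\) — expected slopes ≈ 0.59
  (sister), 0.50 (mother–daughter), 0.46 (cousin): high and similar across
  relationships, the signature of stable inheritance.
* **generation time** (sister-only regime): a = 0.5,
  \(\sigma_g^2 = 0.5\), \(\sigma_s^2 = 7.75\), \(\sigma_u^2 = 8.97\) —
  expected slopes ≈ 0.46 (sister) but ≈ 0.01 (mother–daughter) and
  ≈ 0.002 (cousin): familial resemblance that is almost entirely the
  transient division-time effect.

Censoring defaults are 5% off-screen and 1% death per cell; with the
end-of-recording filter this leaves roughly 75–80% of tracked cells usable
at the defaults. Speed and generation time are simulated independently by
default (`u_correlation` couples their environmental components when a
weak trait correlation is wanted).

Trait draws are clipped from below at physical floors (speed > 0,
generation time ≥ 2 frame intervals). Clipping, rather than rejection
sampling, keeps each family's random-draw count fixed — which is what makes
per-family substreams possible — and affects < 0.1% of draws in every
default or test regime, a bias absorbed by the Monte-Carlo tolerances.

## Trajectories

Tracks are realised as persistent random walks sampled at the frame
interval. Every step has length exactly `speed × frame_interval`, so the
computed curvilinear speed of a simulated track equals the generating trait
value to floating-point rounding — measurement error is deliberately
excluded so that estimator validation is not confounded by it. Headings
evolve by wrapped-normal increments with SD \(1/\sqrt{\kappa}\)
(`turning_kappa`): \(\kappa = \infty\) is ballistic, \(\kappa = 0\)
isotropic (mean-squared displacement then grows as n·L², the diffusive
check used in the tests). Generation times are realised on the frame grid
(`round(T/Δt)` steps), so recovered generation times are exact to one frame
interval. Daughters start at their mother's final position and frame; the
shared division frame is counted once, in the daughter's lifespan.
Founders are caught mid-cycle at plating, so their observed residual
lifetime is a uniform fraction of a full cycle — founders are excluded from
estimation regardless, but this desynchronises family timing realistically.

## Reproducibility and numerical choices

* One master seed; each family re-seeds the generator from an avalanche
  hash (MurmurHash3 finalizer, exact 32-bit arithmetic) of (seed, family
  index). Growing `n_founders` therefore appends families without
  perturbing earlier ones, and arithmetically related master seeds do not
  produce related streams.
* Identical configuration and seed give byte-identical output files; the
  pipeline writes no timestamps.
* Regression fits require n ≥ 3 pairs and Var(x) > 0; degenerate inputs
  raise typed errors rather than returning NaN.
* Track gaps contribute a single straight segment, so path length (and
  hence speed) is a lower bound in gappy data.
* Sister dyads within one family share latent components, so pairs are not
  independent across a family; validation therefore measures Monte-Carlo
  SEs by family-block resampling rather than trusting the OLS slope SE.

## Problem sizes used in validation

The test suite validates the estimator–oracle equivalence on 1000 random
pair sets; closed-form recovery on five parameter grids of 2000 families
(transmission a ∈ {0, 0.5, 0.9, 0.99}); type-I calibration of the slope
test on 1000 null replicates of 300 families; the qualitative
motility-versus-generation-time pattern on 100 replicates of 110 families
(matching reported per-line family counts of 52–141); and brute-force
covariance oracles on 30 000 families. These sizes give Monte-Carlo SEs
small enough for 3-SE tolerance bands while keeping the suite quick.

## Limitations

* The generative model is the simplest one with closed-form relationship
  covariances: additive Gaussian, AR(1) transmission, division-synchronous
  sister effects. Real cell traits may transmit nonlinearly, drift over
  passages, or interact spatially; passing recovery tests shows the
  estimator is correct *under the model*, not that the model is complete.
* Simulated tracks carry no positional measurement noise and no track
  gaps; real tracking data will bias speed slightly downward (gaps) and
  upward (jitter).
* The Kruskal–Wallis well test treats cells as independent; when whole
  families sit inside one well (as here, and in the real experiment) the
  family-level clustering makes it anticonservative, so a small p-value
  alone should not be read as a spatial effect.
* Variance-component (mixed-model) estimation of H² is deliberately out of
  scope: with few families per well the regression approach is more robust,
  and it keeps the three relationships directly comparable.
* Narrow-sense heritability, and the split between genetic and stable
  epigenetic inheritance, are not identifiable from this design.

## A worked pipeline run

```{r}
td <- tempfile(); dir.create(td)
sim <- simulate_trackset(sim_config(n_founders = 60, seed = 11))
write_track_csv(sim$track_set, file.path(td, "tracks.csv"),
                file.path(td, "lineage.csv"))
summary <- run_pipeline(file.path(td, "tracks.csv"),
                        file.path(td, "lineage.csv"),
                        file.path(td, "out"),
                        microns_per_pixel = 0.65, cell_line = "SIM",
                        quiet = TRUE)
summary$estimates |> select(relationship, trait, h2, p.value, r.squared)
```

The written `out/` directory holds the trait table, every pair set, the
estimate table, the auxiliary tests, a plain-text report and
`summary.json` — each downstream number re-derivable from the emitted
intermediates.
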