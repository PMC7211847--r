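# clonherit

Broad-sense heritability of single-cell traits from clonal lineage
tracking.

Somatic (e.g. tumour) evolution presumes that cell traits are heritable at
the level of the cell population — that daughters resemble mothers beyond
shared environment. `clonherit` measures this from time-lapse
lineage-tracking data. It reconstructs binary-division cell pedigrees from
tracking output, computes two whole-lifetime traits per cell —
**curvilinear speed** (total path length in microns over the cell's
lifetime, divided by its generation time, µm h⁻¹) and **generation time**
(cytokinesis to cytokinesis, hours) — and estimates broad-sense
heritability as the slope of a least-squares regression between trait
values of related cells:

    H² = Cov(x, y) / Var(x)

the classical parent–offspring regression adapted to clonal families. The
slope is computed for three relationships — sister–sister, mother–daughter
and cousin–cousin — because they mean different things: sister similarity
is inflated by cytoplasmic factors shared at division, while cousins never
shared cytoplasm, so a cousin slope isolates stably inherited lineage
factors. Where a cell has several tracked daughters or cousins, their mean
value is used.

The package also ships a generative simulator (heritable AR(1) +
sister-shared + independent trait components on branching pedigrees,
realised as persistent-random-walk trajectories) with closed-form expected
slopes, used to validate the estimator by parameter recovery.

## Worked example

Simulate a study-scale dataset (110 founder families, 20-min frames over
72 h), compute traits and estimate cousin–cousin heritability of speed:

```r
library(clonherit)

sim <- simulate_trackset(sim_config(n_founders = 110, seed = 1))
tt  <- compute_traits(build_forest(sim$track_set), sim$track_set)
fit <- estimate_h2(enumerate_pairs(tt, "cousin_cousin", "speed"))
fit
#> Broad-sense heritability (cousin_cousin, speed, mode branch)
#>   H2 = 0.637*** (R2 = 0.428)
#>   slope SE 0.0786, t = 8.11 on 88 df, p = 2.72e-12, n = 90 pairs
```

90 families allowed a cousin comparison; the slope 0.64 means ~64% of the
variance in whole-lifetime speed is attributable to factors transmitted
stably across two cell divisions. The full report for all relationship ×
trait combinations:

```r
fits <- list()
for (trait in c("speed", "generation_time"))
  for (rel in c("sister_sister", "mother_daughter", "cousin_cousin"))
    fits[[paste(rel, trait)]] <- estimate_h2(enumerate_pairs(tt, rel, trait))
h2_report(fits, tt, cell_line = "HT1080-like")
#> cell line: HT1080-like
#>   families: 110 (90 with >=1 cousin pair)
#>   mean speed: 37.14 +/- 11.04 um/h
#>   mean generation time: 14.37 +/- 4.07 h
#>   H2 speed_sister                 0.63*** (0.4)
#>   H2 speed_mother                 0.56*** (0.42)
#>   H2 speed_cousin                 0.64*** (0.43)
#>   H2 generation_time_sister       0.56*** (0.29)
#>   H2 generation_time_mother       -0.0069 (6.7e-05)
#>   H2 generation_time_cousin       0.055 (0.0019)
#>   stars: * p<0.05, ** p<0.01, *** p<0.001
```

This is the signature pattern the package is built to detect: speed is
heritable across all three relationships (stable inheritance), while
generation time shows only sister–sister similarity (a transient
division-time effect, not inheritance). `autoplot(fit)` draws the pair
scatter with the fitted line; `tidy()`/`glance()` return the fit as
tibbles.

Real data come in through `read_track_csv()` (tracks + lineage sidecar
CSV) or `read_mdf()` (MTrackJ `.mdf` with a lineage sidecar), and
`run_pipeline()` executes the whole read → pedigree → traits → census →
pairs → estimates → report chain, writing every intermediate table plus a
`summary.json`. A thin command-line wrapper lives in
`inst/scripts/clonherit-cli.R` (`simulate` and `run` subcommands).

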