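# fledgetrack

Movement analysis for central-place foraging seabirds: trip metrics,
behavioural state labelling, area-restricted search (ARS) detection, kernel
utilisation areas, and dyadic at-sea association analysis for multi-animal
GPS fix tables.

The package is written for movement ecologists working with colony-based GPS
deployments (1-2 minute sampling) who want a reproducible, tested
implementation of a common analysis chain:

1. **Cleaning** — implied-speed filter (default 90 km/h), linear
   interpolation to a regular grid (default 2 min), trip splitting at a
   colony radius (default 500 m), outlier flagging.
2. **Behaviour labelling** — each fix gets one of four states from its speed
   `v` and absolute turning angle `θ ∈ [0, π]`:
   resting (`v < 6` km/h, `θ < 0.30` rad), intensive foraging
   (`v < 14`, `θ ≥ 0.30`), travelling (`v ≥ 6`, `θ < 0.43`), relocating
   (`v ≥ 14`, `θ ≥ 0.43`), half-open boxes with a configurable tie-break in
   the doubly-claimed rectangle. An optional EM mixture fitter estimates the
   delimiters from data.
3. **ARS** — zones are runs of ≥ 3 consecutive intensive-foraging fixes,
   merged across gaps of < 4 other-behaviour fixes; per-zone centroid
   (median), duration, range and hull surface; 50%/95% kernel utilisation
   areas with the normal reference bandwidth `h = σ·n^(-1/6)`.
4. **Associations** — fix pairs of two birds with both coordinate
   differences strictly `< 0.002°` within `≤ 30 s`, detected on the raw
   tracks with a time-window join; events within 50 m of the nest are
   dropped and single-event pairs pruned; group sizes via per-minute graph
   components.
5. **Statistics** — with ARS fraction `f`, an associated pair holds 0/1/2
   ARS members with probability `(1−f)²`, `1−(1−f)²−f²`, `f²` under
   independence; observed counts are tested by Pearson chi-square (df = 2).
   Homogeneity chi-square and the Marascuilo pairwise-proportion procedure
   cover group-formation tables.

A seeded colony simulator (`simulate_colony()`) generates correlated-random-
walk tracks with known per-fix behavioural states and planted co-movement
episodes, so the whole chain is validated against ground truth.

## Worked example

```r
library(fledgetrack)

bundle <- run_pipeline(default_run_config(seed = 42))

dplyr::filter(bundle$groups, metric == "duration_h")
#>   age_class period metric      mean    sd     n
#> 1 adult     P1     duration_h  9.24  3.51    20
#> 2 juvenile  P1     duration_h  4.64  3.13    31

round(bundle$f_ars, 3)
#> [1] 0.174
bundle$stats[c("observed", "statistic", "df")]
#> $observed
#> [1] 584 206 189
#> $statistic
#> [1] 885.5617
#> $df
#> [1] 2
round(bundle$ud)
#>    50    95
#>  2745 12575
```

The simulated colony (10 birds, 5 days) reproduces the configured structure:
adult trips average ~9.2 h against juvenile ~4.6 h; 17.4% of labelled fixes
fall inside merged ARS zones; the 979 planted association pairs are heavily
skewed away from the independence expectation at that ARS fraction
(χ² = 885.6, df = 2), because planted co-movement spans whole trips; and
the 50%/95% ARS utilisation areas are nested. The analytic expectation
construction itself:

```r
round(ars_association_expected(0.39), 4)
#>     p0     p1     p2
#> 0.3721 0.4758 0.1521
```

i.e. 37%, 48% and 15% of associated pairs with 0, 1 and 2 members in ARS
when ARS behaviour covers 39% of locations.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/run_pipeline.R --seed 42 --out report --figures
```

## Documentation

The methods vignette (`vignettes/fledgetrack-methods.Rmd`) describes the
model and every design decision: unit conventions, the trip-delimitation
rule, the tie-break in the overlapping class boxes, the gap rule for ARS
merging, the kernel bandwidth and grid, the association thresholds, the
independence statistic, and what the synthetic colony does and does not
emulate.
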