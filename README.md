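# snaudit

Computational toolkit for assessing the **school-neighbourhood built
environment** — the physical environment within a street-network catchment
of a school — at both the micro scale (streetscape audits) and the macro
scale (GIS-style walkability metrics). It is written for researchers in
active-transport and physical-activity epidemiology who run, score and
validate streetscape audit campaigns around schools.

## What it computes

**The audit frame.** A school's neighbourhood is the 0.5 km street-network
service area around its geocoded address: every network location within 500
m shortest-path distance along the roads. From that buffer the package
extracts street segments (maximal inter-junction road pieces, each with an
odd and an even side by house-number parity), applies the boundary protocol
rules (exclude residence-free boundary partials; extend segments covered
from both ends when residences sit at both ends and the covered majority
exceeds half), identifies crossing-audit intersections (≥ 3 connecting
roads, one audit per connecting road) and subdivides long segments
(halves for 0.2–0.4 km, thirds for 0.41–0.6 km).

**Hierarchical audit scoring.** Item values recode and sum into capped
sub-scales; sub-scales carry a valence sign (+/−) into section scores
(destinations & land use, positive streetscape, aesthetics & social,
segment, crossing); the overall grand score is the signed sum

```
Grand = Σ_s  sign(s) · min(Σ_{i ∈ s} recode(x_i), cap_s)
```

with a best-case maximum of **210 points** under the packaged default
scheme. Cross-domain sub-scales sum school-level item averages across
sections: pedestrian infrastructure (max **27**), pedestrian design (max
**22**), bicycle facilities (max **11**). Schemes are YAML and fully
user-configurable; every declared maximum is re-derived and enforced at
load time.

**Macro metrics.** Intersection density and residential density
(counts/km² of the 95 m centreline-corridor area), land-use mix as
normalised entropy `−Σ p_i ln p_i / ln 5` over five land-use categories,
and the composite walkability index — the per-school sum of within-sample
z-scores of the three components (mean 0 by construction).

**Reliability and concordance.** Two-rater intraclass correlations
(one-way, two-way consistency, two-way agreement; exact F-based 95% CIs)
with the Cicchetti bands (≥ 0.75 excellent, 0.60–0.74 good, 0.40–0.59
fair, < 0.40 poor); Pearson/Spearman odd-versus-even street-side
concordance tables for validating the condensed one-side-per-segment
protocol; crossing-audit shares by intersection type.

**Synthetic data.** A seeded generator emulates a small city (jittered
street grid, residences, five-category land use, two-sided correlated audit
values, two-rater noise), so the entire pipeline is testable end to end
without external spatial data.

## Worked example

```r
library(snaudit)

scheme <- default_scheme()
scheme
#> Scoring scheme: 104 items, 35 sub-scales ( 34 scored )
#>   grand maximum: 210 points
#>   cross-domain maxima: pedestrian_infrastructure=27, pedestrian_design=22, bicycle_facilities=11

# full synthetic campaign: 12 schools, 500 m buffers, two-sided audits,
# two raters at the first two schools
sim <- simulate_study(city_config(seed = 7))

sim$summaries[["SCH01.combined"]]
#> School SCH01 ( combined sides )
#>   destinations_land_use      15.310
#>   positive_streetscape        8.101
#>   aesthetics_social           1.982
#>   segment                    15.345
#>   crossing                    6.866
#>   pedestrian_infrastructure    6.315
#>   pedestrian_design           6.016
#>   bicycle_facilities          2.982
#>   grand score                47.604
```

Section rows are school means of per-unit audit scores (points); the grand
score is their signed sum, and the three cross-domain rows are sums of
school-level item averages. Odd-versus-even concordance across the 12
schools — the check behind the condensed protocol:

```r
sim$concordance[, c("measure", "odd_mean", "even_mean", "r", "p", "method")]
#>                     measure odd_mean even_mean     r        p   method
#> 1                     grand    48.23     48.33 0.839 6.50e-04  pearson
#> 2 pedestrian_infrastructure     6.49      6.50 0.872 2.20e-04  pearson
#> 3         pedestrian_design     5.81      5.91 0.458 1.34e-01  pearson
#> 4        bicycle_facilities     3.17      3.13 0.876 1.89e-04 spearman
#> 5     destinations_land_use    15.24     15.20 0.769 3.45e-03 spearman
#> 6      positive_streetscape     8.17      8.19 0.930 1.15e-05  pearson
#> 7         aesthetics_social     2.19      2.20 0.876 1.84e-04  pearson
#> 8                   segment    16.12     16.22 0.828 8.92e-04  pearson
#> 9                  crossing       NA        NA    NA       NA     <NA>
```

A large positive `r` means one street side represents both; the crossing
row is combined-only because crossing audits have no street side. Inter-
rater reliability from the co-audited schools:

```r
rel <- sim$reliability[[1]]
reliability_report(rel$rater1, rel$rater2, scheme)[1:3,
    c("measure", "icc", "ci_lower", "ci_upper", "classification")]
#>                     measure   icc ci_lower ci_upper classification
#> 1                     grand 0.968    0.958    0.975      excellent
#> 2 pedestrian_infrastructure 0.891    0.864    0.913      excellent
#> 3         pedestrian_design 0.842    0.806    0.872      excellent
```

Macro-scale profiles and the zero-mean walkability index:

```r
head(sim$macro[, c("school_id", "intersection_density",
                   "residential_density", "land_use_mix", "walkability")], 4)
#>   school_id intersection_density residential_density land_use_mix walkability
#> 1     SCH01                 45.7                1054        0.429       0.533
#> 2     SCH02                 49.7                1099        0.341       1.383
#> 3     SCH03                 48.6                1083        0.418       1.475
#> 4     SCH04                 47.7                1037        0.530       1.511
```

And a small worked tally — crossing audits by intersection type:

```r
crossing_type_shares(c(516, 224, 15, 12))$share_reported
#> [1] 67.3 29.2  2.0  1.6
```

## Command line

A thin wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("cli", "snaudit", package = "snaudit"))') \
  simulate --schools 12 --seed 7 --out-dir out/
```

Subcommands: `simulate`, `buffer`, `score`, `macro`, `reliability`,
`concordance`, `shares`. Every run writes a JSON manifest (command, flags,
seed, input digests, outputs, version).

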