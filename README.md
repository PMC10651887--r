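# seagrassN15

Analysis of ¹⁵N amino-acid tracer incubations of seagrass and seawater:
who turns dissolved organic nitrogen into ammonium, who takes it up, and
how much the plant's presence amplifies water-column productivity.

The package is written for biogeochemists and microbial ecologists who
run (or want to plan and validate) bottle-incubation tracer experiments
in seagrass meadows, including paired ambient-pH / CO₂-vent designs used
as natural ocean-acidification experiments. It also covers the
metagenome side of such studies: quality tiering and functional
screening of metagenome-assembled genomes (MAGs) for ammonification
enzymes.

## What it computes

**Ammonification** (amino-acid mineralisation) from the source–sink
tracer model. With the spiked dissolved free amino-acid (DFAA) pool as
the source and seawater ammonium as the sink,

```
rate = (R(t)_sink − R(0)_sink) / ((R_source − R(0)_sink) · t) · [NH₄]̄
```

in nmol N h⁻¹ per bottle, where `[NH₄]̄` is the mean ammonium amount over
the incubation. Night rates are separated by re-anchoring `R(0)_sink` at
the mean end-of-day enrichment of the day-harvested bottles; host
(plant-associated) activity is attributed by subtracting the
seawater-only mean of the same site × interval cell.

**Nitrogen uptake** by plant tissue and particulate organic matter (POM)
from atom-percent excess:

```
uptake = excess / (R · t) · N_T
```

with `R` the mean enrichment of the ammonium pool and `N_T` the sample's
total nitrogen (µmol), per g dry mass (tissue) or per litre filtered
(POM).

**Carbon conversion and amplification**: O₂ changes convert to carbon
rates via a photosynthetic quotient (default 1.0) after water-column
subtraction, and the benthic–pelagic amplification factor is the fold
increase in POM nitrogen uptake with the plant times the particulate
C:N molar ratio.

**Forward simulator**: a mass-conserving model of the whole incubation
(2 sites × {seagrass, seawater-only} × day/night, 0.66 L bottles, a
98 atom% amino-acid spike into a ~1 µM background pool, label transfer
AA → NH₄ → tissue/POM, realistic δ-space measurement noise), so every
estimator can be tested against known truth without any field data.

**MAG screening**: Bowers-style quality tiers (high: completeness > 90%
and redundancy < 10%), field-wise EC-wildcard matching (`1.4.*` matches
`1.4.1.2` but never `1.14.13.1`), the three ammonification enzyme
classes (EC 1.4.\*, EC 3.5.\*, EC 4.3.1\*), and metabolic-module
completion with the inclusive 75% rule.

## Worked example

Simulate the default experiment and estimate everything:

```r
library(seagrassN15)
library(dplyr)

ex <- simulate_experiment(seed = 1)   # 24 bottles, 2 sites

rates <- attribute_host_rate(estimate_ammonification(ex))
rates |>
  group_by(site, attribution, interval) |>
  summarise(rate_nmol_h = mean(value), .groups = "drop")
#>    site    attribution     interval rate_nmol_h
#>  1 control bottle_total    day           10.2
#>  3 control bottle_total    night          7.69
#>  4 control host_attributed day            6.22
#>  7 control seawater_only   day            3.98
#> 10 vent    bottle_total    day            2.56
#> 16 vent    seawater_only   day            1.00
#> ...
```

Ammonification is several-fold higher at the ambient-pH control site
than at the CO₂ vent, and higher with the plant than in seawater alone;
the `host_attributed` rows are the per-bottle rates after subtracting
the seawater-only mean of the same cell — the bottle-level signature of
seagrass-associated microbes.

```r
up  <- estimate_uptake(ex)
estimate_amplification(filter(up, units == "umol_L_h"))
#>   site    fold_n cn_ratio amplification
#> 1 control  0.323     5.09          1.64
#> 2 vent     0.418     5.97          2.49

estimate_carbon(ex) |>
  filter(treatment == "seagrass") |>
  group_by(site, interval) |>
  summarise(mgC_gDM_h = mean(value), .groups = "drop")
#>   site    interval mgC_gDM_h
#> 1 control day          0.624
#> 2 control full         0.120
#> 3 vent    day          0.637
#> 4 vent    full         0.118
```

Daytime plant carbon fixation lands near 0.6 mg C g⁻¹ h⁻¹ under the
default parameters and does not differ between sites, while the
amplification column is `fold_n × C:N` — the factor by which POM carbon
uptake is inflated by plant-associated nitrogen supply under the
constant-stoichiometry assumption. (The fold here is an estimator
output on synthetic data, not a field value; see the vignette on why
POM uptake scaled by ammonium-pool enrichment is a comparative index.)

The MAG screen on a synthetic 67-genome cohort:

```r
synth <- synth_annotations(67, class_prevalences = c(
  has_ec_1_4 = 1, has_ec_3_5 = 1, has_ec_4_3_1 = 61/67), seed = 19)
screen_counts(ammonification_screen(synth$annotations))
#>   class        n_mags
#> 1 has_ec_1_4       67
#> 2 has_ec_3_5       67
#> 3 has_ec_4_3_1     61
```

An end-to-end run (`run_report("out", default_config(seed = 1))`)
writes the bottle table, all rate tables, amplification factors, the
MAG screen and a run manifest as tab-delimited text.

## Documentation

The methods vignette (`vignettes/nitrogen-tracer-model.Rmd`) describes
the model and its assumptions, every tunable parameter with units and
defaults, the simulator's numerical scheme, what the synthetic data do
and do not emulate, and known limitations.
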