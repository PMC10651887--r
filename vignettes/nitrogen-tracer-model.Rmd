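---
title: "Modelling 15N amino-acid tracer incubations of the seagrass holobiont"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 15N amino-acid tracer incubations of the seagrass holobiont}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seagrassN15)
```

## The scientific problem

Seagrass meadows persist in coastal waters whose dissolved inorganic
nitrogen is chronically low. One route by which the plant and the
surrounding water column can still be well supplied is microbial
**ammonification**: free-living and epiphytic bacteria cleave the C–N
bonds of dissolved free amino acids (DFAA) and release ammonium, which
the plant and the particulate organic matter (POM) then take up. The
classic way to measure this in the field is a bottle incubation with a
^15^N-labelled amino-acid tracer: bottles hold either a seagrass shoot
plus unfiltered seawater or seawater only, at an ambient-pH site and at
a naturally acidified CO~2~-vent site, and the label is followed from
the amino-acid pool into ammonium, plant tissue and POM over a day and
the following night.

`seagrassN15` implements the full analysis chain for such experiments:
isotope-notation arithmetic, a forward simulator of the incubation (so
every estimator can be validated against known truth), the tracer rate
estimators, oxygen-to-carbon conversion, benthic–pelagic amplification
factors, and the functional screening rules applied to
metagenome-assembled genomes (MAGs) from the same system.

## Isotope bookkeeping

All enrichments are stored internally as decimal ^15^N atom fractions
$F$. Mass spectrometers report $\delta^{15}N$ (per mil against
atmospheric N~2~); the two are linked through the isotope ratio
$R = {}^{15}N/{}^{14}N$:

$$R = R_{ref}\,(1 + \delta/1000), \qquad F = \frac{R}{1+R},$$

with $R_{ref} = 0.0036765$ for air N~2~ (the conventional reference
value; `r_ref_air()`). Natural abundance is then
$F_{nat} \approx 0.0036630$. Input tables may carry atom percent
(0–100) instead of fractions; an explicit unit column or argument
switches the dialect — never a heuristic, because a "0.76 at%"-style
value is only unambiguous once its unit convention is declared.

Pool mixing is exact two-term mass balance (`mix_pools()`,
`spike_pool()`): amounts add, ^15^N adds, the mixture fraction is the
amount-weighted mean. The tracer addition of the incubation protocol —
50 µL of a 0.05 M amino-acid solution at 98 atom% into 0.66 L holding
1 µM DFAA at natural abundance — enriches the DFAA pool to

```{r}
dfaa <- isotope_pool(1.0 * 0.66, natural_abundance_15n(), volume = 0.66)
spike_pool(dfaa, spike_definition(50e-6, 0.05, 0.98))
```

about 0.776 as an atom fraction. The spike volume is ignored in the
diluted volume (tens of µL against 660 mL; `include_spike_volume`
re-enables it), and the amino-acid mixture is booked at one N atom per
molecule (`n_atoms_per_molecule`), since its exact composition is a
configurable unknown.

## The rate estimators

### Source–sink ammonification (`ammonification_rate()`)

The mineralisation rate is inferred from the transfer of label from the
source (the spiked DFAA pool, enrichment $R_{source}$, effectively
constant) into the sink (seawater NH~4~^+^):

$$\text{rate} \;=\; \frac{R(t)_{sink} - R(0)_{sink}}
   {\left(R_{source} - R(0)_{sink}\right)\, t}\;\overline{[NH_4]},$$

reported in nmol N h^-1^ per bottle, with $\overline{[NH_4]}$ the
average ammonium amount over the window (mean of the endpoint amounts
by default). The numerator is the **sink's gain in enrichment**. A
variant with $R(t)_{sink} - R_{source}$ in the numerator circulates in
print; it is negative whenever the sink sits below the source and is
inconsistent with the source–sink dilution model, so it is available
only behind `printed_form = TRUE` for audit, never as a default.

Assumptions worth keeping in view: the source enrichment is constant
(safe — the DFAA pool only loses nitrogen, which leaves its atom
fraction unchanged); the ammonium pool size is approximately constant;
and the sink's enrichment rises linearly. When uptake strongly draws
the pool down (as in bottles holding an actively absorbing plant), the
estimator inherits a bias of order the relative pool change — the
simulator makes that bias visible rather than hiding it.

The overnight rate is obtained by re-anchoring: $R(0)_{sink}$ for the
night window is the **mean end-of-day sink enrichment across the
day-harvested bottles of the same site × treatment cell**
(`night_rate_partition()`), because each individual bottle is only
opened once.

Host attribution (`attribute_host_rate()`) subtracts, from each
seagrass bottle, the mean seawater-only rate of its site × interval
cell; negative attributions are flagged and kept — forcing them to
zero would bias every cell mean upward.

### Atom-percent-excess uptake (`nitrogen_uptake_rate()`)

Nitrogen incorporation into plant tissue or POM follows

$$\text{uptake} \;=\; \frac{\text{excess}}{R\,t}\; N_T,$$

where *excess* is the sample's atom-fraction gain over its
pre-incubation baseline, $N_T$ the sample's total nitrogen
($\text{dry mass} \times \%N / 14.0067$, in µmol, or a directly
measured filter amount), and $R$ the mean enrichment of the ammonium
pool over the window. $R$ is taken as the **excess above natural
abundance** by default (`r_mode = "excess"`): with an absolute-$R$
convention a completely unlabelled system would still report nonzero
uptake from its natural-abundance baseline. The absolute convention
remains available because published applications are ambiguous on this
point. Tissue rates are normalised per g dry mass, POM rates per litre
filtered.

For POM the label can arrive as ammonium or as intact amino acids; the
estimator still scales by the ammonium-pool $R$, as the method
prescribes. When the amino-acid route dominates and the two pools'
enrichments differ strongly between treatments, POM "uptake" values are
index numbers rather than absolute fluxes — a real limitation of the
method that the simulator reproduces faithfully.

### Oxygen to carbon (`oxygen_to_carbon_rate()`) and amplification

Net O~2~ changes convert to carbon through a photosynthetic quotient
(PQ, mol O~2~ per mol CO~2~; default 1.0) after subtracting the
water-column O~2~ rate, times 12.011 µg µmol^-1^; positive is fixation,
negative respiration.

The benthic–pelagic amplification factor multiplies the fold increase
in integrated POM nitrogen uptake with the plant present by the
particulate molar C:N ratio:
`amplification = fold_n × C:N`. The formula, not any particular
printed product, is the contract; `estimate_amplification()` computes
the fold from the full-window (day + night) POM uptake of
night-harvested bottles.

### Factorial comparisons

`factorial_anova()` is deliberately thin plumbing over `stats::aov()`:
fixed-effects decomposition over up to three crossed factors with an
optional log transform (variance stabilisation for strictly positive,
highly variable rates). It refuses interaction models with empty
cells instead of silently dropping terms.

## The forward simulator

`simulate_bottle()` integrates the labelled-nitrogen transfer system
illustrated by the incubation design:

* DFAA pool → (ammonification, at the DFAA atom fraction) → NH~4~ pool;
* an unlabelled organic pool → (background regeneration, at natural
  abundance) → NH~4~;
* NH~4~ → (plant uptake × dry mass; POM uptake × volume, at the NH~4~
  atom fraction) → tissue / POM accumulators;
* DFAA → (direct uptake) → POM;
* O~2~ changes linearly, +NPP before the day census, −respiration
  after.

Day rates apply before `t_day_census` (default 6 h, the deployment-to-
evening window of the protocol), night rates until `t_night_census`
(default 20 h). All windows are schedule parameters, never constants —
the daytime window is variously described as 6 or "approximately 7"
hours in field protocols, so nothing may hard-code it.

**Numerics.** Integration is fixed-step explicit with default
`dt = 0.05` h — transparent and adequate for piecewise-constant rates.
Transfers move computed amounts of N and ^15^N from pool to pool, so
both are conserved to machine precision *by construction*, and the
conservation test (1e-9 relative) guards the bookkeeping rather than
the step size. Source pools that only lose nitrogen keep their atom
fraction exactly; the ammonium pool both gains and loses, so its
outflow fraction is evaluated at an explicit midpoint state
(second-order accurate), which keeps the dt-halving change of every
census value well below 0.1%. A step that would drive a pool negative
stops with an error naming the pool — the simulator refuses to
fabricate nitrogen.

**Study conditions.** `default_design()` fixes the experiment shape to
the field design: 2 sites × (8 seagrass + 4 seawater-only bottles),
0.66 L bottles, alternate bottles harvested at the day and night
censuses (day-harvest bottles contribute t0/day rows, night-harvest
bottles all three). Defaults were chosen once, for realism:

* DFAA 1 µM at natural abundance; tracer spike as above; NH~4~ carrier
  77.6 µL of 0.05 M NH~4~Cl (≈ +5.9 µM) booked at natural abundance,
  since only "known δ" is stated in the protocol literature;
* ammonification of a few nmol h^-1^, roughly 4× greater at the
  control site and 2.5× greater with the plant;
* plant dry mass 0.25 g (wet shoots of 2–3.5 g at a typical ~0.1
  dry:wet ratio) and NH~4~ uptake 1.2 (day) / 0.4 (night)
  µmol g^-1^ h^-1^ — at the lower end of the observed 1.2–15 range,
  deliberately: a closed 0.66 L bottle holds only ~4.2 µmol NH~4~, and
  the literature's upper rates would exhaust it within two hours,
  which no mass-conserving forward model can represent;
* O~2~ metabolism giving ≈0.7 mg C g^-1^ h^-1^ daytime fixation at
  PQ = 1;
* measurement noise in δ-space: 2‰ on δ^15^N–NH~4~ (wet-chemical
  conversion methods), 0.5‰ on tissue/POM δ^15^N (elemental-analyser
  IRMS), 0.05 µM on nutrient concentrations, 2 µmol L^-1^ on O~2~.
  Concentrations truncate at 0 and fractions to [0, 1], with the
  truncation count reported, never silent.

**What the simulator does not emulate** — and hence what passing tests
do not certify about field data: hydrodynamic exchange (bottles are
closed), light curves and diel rate ramps (rates are piecewise
constant), epiphyte and sediment processes, microbial growth dynamics,
isotope fractionation (transfers carry the source fraction exactly),
and any coupling between the nitrogen system and the O~2~ budget.

## Validation design

Each estimator is checked along two independent routes:

1. **Analytic fixtures.** Records constructed directly from the
   source–sink forward relation (constant source, constant pool, sink
   rising linearly from natural abundance) must be inverted *exactly*
   (1e-9 relative) at planted rates of 1, 5 and 20 nmol h^-1^. The
   constant-pool assumption cannot hold inside the mass-conserving
   simulator (ammonification feeds the pool), which is precisely why
   this route is analytic.
2. **Simulator recovery.** With ammonification the only active process
   (seawater-only bottles), the estimator recovers the planted rate
   within 5% noise-free; with 2‰ δ-noise and 8 replicate bottles, the
   mean absolute error over 200 noise realisations stays under 15%.
   The uptake estimator is exercised on a seagrass bottle drawing on a
   pre-enriched (5 at%) ammonium carrier, where the pool enrichment is
   constant by construction (uptake alone cannot change a pool's atom
   fraction): exact noise-free up to the final-$N_T$ convention,
   within 15% MAE under noise.

The screening rules are validated against brute-force enumeration
written independently of the implementation (field-wise EC comparison
over 10^4^ random pairs; per-gene × per-pattern loops on hand-built
cohorts), and the synthetic MAG generator plants its class prevalences
and module fractions constructively, so realised counts equal targets
exactly whenever the target × cohort size is an integer (otherwise the
nearest achievable count is used, with a warning).

Problem sizes in the shipped tests — 24-bottle experiments, 200 noise
seeds, 10^4^ EC pairs, 67-genome cohorts — were chosen as the smallest
sizes at which the statistical checks are stable.

## MAG functional screening

The metagenome side reproduces the decision rules applied to MAG
tables, not the assembly pipeline that produces them (binning,
taxonomy and read recruitment are external tooling and out of scope).

* **Quality tiers** (`quality_tier()`): *high* requires completeness
  strictly > 90% and redundancy strictly < 10% (the printed
  thresholds); *medium* spans `medium_floor`–90% completeness at
  redundancy < 10. The floor defaults to 50 — the refinement rule
  actually applied to the bins — with 42 available to reproduce a
  cohort whose observed medium completeness range starts lower; the
  two published numbers conflict, so both semantics are explicit.
* **EC wildcards** (`ec_matches()`): field-wise, never string-prefix —
  `1.4.*` must not match `1.14.x.y`. A trailing `1*` constrains its
  own field (`4.3.1*` matches ammonia lyases only). Unannotated fields
  (`-`) are compatible with any constraint, so partial annotations
  match on their known fields.
* **Ammonification screen** (`ammonification_screen()`): a MAG carries
  a class iff ≥ 1 gene matches — EC 1.4.\* (CH–NH~2~ oxidoreductases),
  EC 3.5.\* (non-peptide C–N hydrolases, e.g. ureases), EC 4.3.1\*
  (ammonia lyases).
* **Module completion** (`module_completion()`): fraction of a
  module's orthologs present; *complete* at ≥ 0.75 — the boundary is
  inclusive, so 6 of 8 genes completes a module and 5 of 8 does not.
* **Function matrix** (`function_matrix()`): completion fractions for
  every MAG of medium tier or better, rows and columns in lexicographic
  order so output files are deterministic.

Module definitions are user-supplied ortholog sets; a toy map ships for
tests and examples (`toy_modules()`), and real curated definitions drop
in through the same `module_definition()` shape — never a download
dependency.

## Known limitations

* The source–sink estimator is biased when the ammonium pool changes
  appreciably within a window; the package reports the method's value
  and leaves the bias visible in simulator comparisons rather than
  correcting it (isotope-dilution corrections beyond the model are out
  of scope).
* POM uptake scaled by the ammonium-pool enrichment understates the
  amino-acid-routed label; treat POM rates as comparative indices.
* The `nmol h^-1^` ammonification unit is per bottle (0.66 L); per-litre
  reporting is a flag away but the per-bottle convention is the
  default.
* Negative rates and excesses are flagged, never clamped — organic
  fluxes legitimately change sign between day and night.
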