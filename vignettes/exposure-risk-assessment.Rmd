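---
title: "Screening-level risk assessment of trace elements in protein powders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening-level risk assessment of trace elements in protein powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemrisk)
```

## The problem

Protein powder supplements are consumed daily in multi-gram servings, so
even trace-level contamination with toxic elements (Pb, Cd, Hg, Tl, Be,
...) translates into a chronic oral exposure worth screening. `elemrisk`
implements the standard screening chain used in food-safety exposure
assessment, from the raw ICP-MS measurement to a per-product verdict:

1. **Digestion back-calculation.** The instrument reports a solution
   concentration $C_{inst}$ (µg·L⁻¹) for the diluted acid digest. The
   concentration in the original powder (µg·kg⁻¹) is
   $C = C_{inst} \cdot DF \cdot V / W$, with dilution factor $DF$
   (default 5), returned digest volume $V$ (mL, converted to L) and
   weighed powder mass $W$ (g, converted to kg). The mL and g inputs are
   converted at this single point so all downstream concentrations are in
   µg·kg⁻¹.
2. **Censoring semantics.** A measurement is exactly one of *quantified*
   (a number), *below limit* (left-censored at a reporting limit, printed
   `<X`) or *above range* (beyond the top calibration standard, printed
   `NR*`, not quantifiable without re-dilution).
3. **Exposure.** Estimated daily intake per element,
   $EDI = C \cdot IR / BW$ (µg per kg body weight per day), with intake
   rate $IR$ = serving mass × servings/day and body weight $BW = 70$ kg
   by default.
4. **Non-carcinogenic risk.** Hazard quotient $HQ = EDI / RfD$ against
   the oral reference dose, and the hazard index
   $HI = \sum HQ$ over a fixed 15-element list (Li, Be, Mo, Cd, Sn, Ba,
   Hg, Tl, Pb, Al, V, Mn, Fe, Co, Cu). $HI > 1$ flags a product.
5. **Carcinogenic risk.** Slope-factor cancer risk for Be, Cd and Pb,
   with $CR \le 10^{-4}$ conventionally read as low.

## Data-handling policies

Three decisions dominate the numbers and are explicit, named parameters
of `assessment_config()` rather than silent behaviour.

**Censoring policy.** The screening literature substitutes 0, LOQ/2 or
LOQ for left-censored values. The packaged reference tables were
evidently computed with **zero substitution** — recomputing the
highest-HI sample with censored values set to zero reproduces its
published HI to better than 0.1%, while LOQ/2 does not — so `"zero"` is
the default; `"half_limit"` and `"at_limit"` are retained for
sensitivity analysis, and HI is provably monotone across the three.

**Above-range results.** A result above the calibration range has no
number to impute; it is excluded from every sum. This makes HI a lower
bound for affected samples (mostly Al, Fe, Cu, Mn), so the exposure
table keeps the excluded rows visible and each HI carries the count of
excluded elements.

**Slope-factor convention.** The slope-factor equation is usually
written $CR = EDI \times CSF$. The published screening tables this
package reproduces, however, are only obtainable as $EDI / CSF$ with the
tabulated constants (4300 for Be, 380 for Cd, 8.5 for Pb): every
spot-checked cell matches the division and none matches the product.
Both conventions are implemented; `"table_match"` (division) is the
default because reproducing the tables is this package's purpose, and
`"literal_eq5"` (multiplication) is available. They differ exactly by
$CSF^2$, which the test suite asserts. Reports name the convention used.

Two smaller conventions: the HI element list is the fixed 15-element set
above, *not* "everything with an RfD" — total Cr has reference values
only as Cr(VI) and is excluded from both risk sums; and classification
cuts are strict (`HI > 1`, `CR > threshold`) with the boundary counted
as low, mirroring the conventional table legends.

## The packaged reference panel

`reference_panel()` returns a 36-sample market survey of commercial
protein powders (27 whey, 2 pea, 2 soy, 2 mixed plant, 2 blend, 1
casein): 20 elements per sample (Mg exceeded calibration everywhere and
is absent), serving masses of 10–60 g and digested masses of
0.41–0.52 g. `tox_reference()` carries the RfD/CSF/RDA/UL constants and
the two membership flags. `qc_recoveries()` holds the matrix-spike and
readback recoveries (87.8–123.2%) that validate the measurements; all
pass the inclusive 100 ± 25% matrix-spike band, and the package applies
100 ± 20% to certified reference materials.

```{r}
res <- assess_panel(reference_panel())
res
subset(res$hi, sample_id == "P1")
```

## Known discrepancies in the reference tables

Recomputing the full published HI table from its own printed inputs
reproduces 35 of 36 samples within ~6% (most within 1%). Two cells
differ beyond rounding: one sample (P31) recomputes ~6% below its
printed value and another (P12) ~13% below, under every censoring
policy; both printed values are internally consistent between their 1-
and 3-serving columns but not derivable from the printed concentrations,
serving masses and reference doses. The tests therefore pin the
highest-HI sample tightly (1%) and treat those cells as source errata
rather than adjusting any policy to chase them.

## The synthetic generator

`generate_panel()` emulates the full sample flow so every stage is
testable without real data: true concentrations are drawn log-uniformly
per element (the observed panels span 2–4 orders of magnitude per
element, so uniform sampling would make censoring events vanishingly
rare or dominant), pushed through the forward dilution model with each
sample's simulated digestion geometry (digested mass uniform over the
observed 0.41–0.52 g span, serving masses drawn from the observed
serving sizes, a nominal 10 mL returned volume flagged as nominal in the
metadata), and perturbed with multiplicative gaussian noise truncated at
zero — the simplest model consistent with percent-RSD quality-control
reporting; per-element noise defaults to the median replicate RSD of the
packaged QC fixture (0.1–13%). Readings whose back-calculated value
falls below the element's reporting limit become censored records;
solution readings above the top calibration standard (50 µg·L⁻¹)
become above-range records.

A single seed drives one seeded stream per element (keyed by the
element's fixed position in the 21-element panel) plus one for
sample-level attributes, so adding or removing elements does not perturb
the other elements' draws and identical seeds give bit-identical files.

What the generator does *not* emulate: spectral interferences, drift,
internal-standard correction, digestion recovery losses, or correlation
between elements within a sample. Passing the synthetic recovery tests
therefore shows the arithmetic chain is exact, not that the method is
robust to real instrument pathology.

## Numerical choices and scale

All computation is double precision and unrounded; rounding happens only
in report tables (HI to 3 decimals, CR to 2 significant figures).
Degenerate inputs error early: non-positive masses, volumes, dilution
factors, reference doses or slope factors are rejected, as is
back-calculation without an explicit returned volume. The test suite
runs the 36-sample panel end to end (well under a second), 1000-tuple
round-trip checks of the dilution algebra at 1e-12 relative tolerance,
noiseless pipeline recovery at 1e-9, and a 1000-sample noise-calibration
check of the generator (empirical RSD within ±0.5 points of the nominal
5%); these sizes keep the whole suite at a few seconds while leaving
Monte-Carlo error far below every asserted tolerance.

## Limitations

This is a deterministic screening calculation: no dose-response
modelling beyond the HQ/HI/CR ratios, no age- or population-stratified
intake, no probabilistic exposure, and no treatment of censored values
beyond simple substitution (no maximum-likelihood or Kaplan–Meier
censored estimators). Above-range exclusion biases risk downward for the
affected elements, which is the conservative direction for a
*pass* verdict but not for a *fail* one; the exclusion counts in the
output exist so readers can see where that bias lives.
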