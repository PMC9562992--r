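---
title: "Calibrated functional evidence and ACMG/AMP classification of GAA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated functional evidence and ACMG/AMP classification of GAA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaavcep)
```

## Overview

`gaavcep` implements, end to end, the procedure by which an in vitro
residual-activity assay for the lysosomal enzyme acid alpha-glucosidase
(GAA) is turned into clinical-grade evidence for classifying *GAA*
variants:

1. **assay arithmetic** — normalization of raw activities to % wild type
   and replicate averaging;
2. **calibration** — activity zones estimated from a control panel of
   variants with known classifications, with the PS3/BS3 evidence strength
   set by ClinGen SVI control-count guidance;
3. **evidence assignment** — ACMG/AMP codes at ClinGen *GAA* VCEP
   thresholds and strengths;
4. **combination** — the ACMG/AMP combining rules over applied strengths,
   with explicit conflict semantics and counterfactual ablation.

Every stage is a pure function of its inputs, so a classification report is
regenerable bit-identically (modulo timestamp) and every intermediate
decision is recorded.

## Assay arithmetic

Raw activities (nM 4MU/hour/mg protein) are normalized as

$$a = 100 \cdot \frac{\max(v - b,\ 0)}{w - b}$$

where $v$, $w$, $b$ are the variant, wild-type and mock-transfection
activities. Whether published percentages were computed with or without
background subtraction is generally unstated in assay reports; we subtract
by default (standard enzymology practice; with $b = 0$ the formula reduces
to the plain ratio), and inputs already given in % wild type bypass this
step entirely. A run with $w \le b$ is invalid.

Replicates are averaged arithmetically. Two conventions matter:

* **Display rounding** is one decimal, *half away from zero* (base R's
  `round()` is round-half-even). Published activity tables are not
  self-consistent at half-way cases, so a single convention is fixed and
  used everywhere.
* **Threshold comparisons always use the unrounded mean.** A display
  convention must never change a classification.

"Not detectable" is carried as a `below_detection` flag and compared as 0%
against every threshold; this matches the downstream behavior (PS3 applies
to not-detectable variants, since 0 is below any positive pathogenic
bound). Any replicate count $n \ge 1$ is accepted; $n = 1$ warns, because a
single replicate carries no within-assay reproducibility information.

## Calibration

`activity_calibration()` is the package's model-fitting function. From a
panel with at least one pathogenic and one benign control it estimates

* `pathogenic_max` — the maximum activity among pathogenic /
  likely-pathogenic controls, and
* `benign_min` — the minimum activity among benign / likely-benign
  controls,

and fails if the two classes overlap (a non-validatable assay). The packaged
panel of 12 controls (7 pathogenic, 4 benign, 1 pseudodeficiency) gives
`pathogenic_max = 11`, `benign_min = 54`.

```{r}
cal <- activity_calibration(gaa_control_panel())
cal
```

**Boundary semantics.** The pathogenic zone is *strictly below*
`pathogenic_max`; the benign zone is *at or above* `benign_min`. The
control that defines the pathogenic bound therefore sits at the edge of the
indeterminate zone, not inside the pathogenic zone: an activity of exactly
11% receives no PS3, while 10.7% does. This asymmetry is deliberate — the
bound was set *by* a pathogenic control, so activity equal to it carries no
more evidence than the indeterminate zone, and it reproduces the observed
assignment pattern (10.7% → PS3; 11.7% → none). Below-detection
measurements always classify into the pathogenic range, even in the
degenerate case `pathogenic_max = 0`.

**The pseudodeficiency sentinel.** Pseudodeficiency alleles (e.g.
c.1726G>A, p.Gly576Ser) suppress in vitro activity without causing disease.
The sentinel never participates in threshold estimation; it is only
required to fall strictly inside the indeterminate gap, and a violation
attaches a validation warning to the fit rather than failing it — the
thresholds themselves are still well-defined, but the panel deserves
review.

**Evidence strength.** SVI guidance ties PS3/BS3 strength to the number of
validated controls: `determine_strength()` operationalizes "a balanced mix
of at least 11" as *total ≥ 11 with both classes represented* (the source
is not quantitative about balance; stricter ratios are exposed via the
`min_each` argument but off by default). The default policy is
`"conservative"` — always supporting — because a panel can meet the count
while still having a wide indeterminate gap with no pathogenic control
near the boundary, exactly the situation of the packaged panel; the
`"svi"` policy grants moderate when the count is met. The policy is a
choice the laboratory makes once, not a tuning knob.

The fit has the usual modelling surface: `print()`, `summary()` (echoes
the panel), `coef()` (the two bounds), `predict()` (zones or evidence
codes for new activities), `plot()` (controls with zone boundaries), and
`simulate()` (synthetic panels at the fitted boundaries).

## Evidence assignment

`build_evidence_profile()` runs six assigners per variant. All numeric
comparisons are strict inequalities, so a value exactly at a threshold
yields no code; defaults are the ClinGen *GAA* VCEP values:

| Code | Condition (defaults) | Applied strength |
|------|----------------------|------------------|
| PS3 / BS3 | activity zone from the calibration | calibrated (supporting or moderate) |
| PM2 | AF < 0.001 in **all** provided populations, or absent | supporting |
| BS1 | AF > 0.005 in **any** population | strong |
| PM3 | confirmed in trans with a pathogenic variant | moderate |
| PM5 | different **missense** variant at the same codon, pathogenic | moderate |
| PP3 / BP4 | REVEL > 0.7 / < 0.5 | supporting |
| PP4 | Pompe-specific phenotype **and** pseudodeficiency excluded | moderate |

Notes on the less obvious choices:

* PM2's quantifier is universal over the populations provided: one
  population at 0.002 blocks PM2 even if others are rare. An empty
  frequency map ("absent") qualifies.
* PM5 verifies its own precondition: the cited same-codon variant must be
  a missense change (citing a nonsense, frameshift or synonymous variant
  is an error, not a silent no-code).
* PP4 is decomposed into two auditable booleans
  (`phenotype_consistent`, `pseudodeficiency_excluded`) because low blood
  GAA activity is uninterpretable while a pseudodeficiency allele may be in
  play; the pipeline does not adjudicate clinical records, it only demands
  both flags.
* The western-blot annotation (`protein_bands`) is carried into reports
  for the reviewer but, by construction, never influences any evidence
  item — a property the test suite checks by exhaustive toggling.
* PM3 is fixed at moderate; points-based PM3 scaling across multiple
  probands is out of scope.

Profiles are mutually exclusive by construction: PM2/BS1, PP3/BP4 and
PS3/BS3 can never co-occur, and each code appears at most once.

## The combination engine

`combine_evidence()` applies the ACMG/AMP 2015 combining rules to the
strength-slot counts, where **each item counts at its applied strength**:
PS3 applied as supporting increments the supporting slot, PP4 applied as
moderate increments the moderate slot. Benign evidence uses the
stand-alone / strong / supporting slots of the standard; because strength
substitution is unrestricted (anticipating VCEP revisions), a benign item
carrying very_strong counts as strong and one carrying moderate counts as
supporting — the standard defines no benign slots between those.

Outcomes:

* a pathogenic-side rule satisfied, no benign item present → Pathogenic or
  Likely pathogenic, rationale `no_conflict` (dually for benign);
* items of **both** categories present and either side alone satisfies a
  non-VUS rule → VUS, `evidence_in_conflict`;
* otherwise → VUS, `insufficient_evidence`.

`matched_rule` records which rule fired (e.g. `LP:2M+2P` for two moderate
plus two supporting), or both sides' rules in a conflict.

One labelling subtlety: a profile with only pathogenic-category items that
fails every rule is reported as `insufficient_evidence` even where a
curator, looking at an indeterminate assay result and a near-threshold
in-silico score, might narratively call it "conflicting". The rationale
label follows the implemented definition; the report surfaces such rows
(VUS with indeterminate activity) with an explanatory note instead of
bending the label.

`ablate()` recombines a profile with a code removed. The report's
`tier_without_functional` column is the ablation of PS3/BS3, quantifying
per variant what the assay evidence contributed; on the packaged tables it
shows exactly two variants (c.316C>T, c.1103G>A) owing their
likely-pathogenic tier to the assay.

The engine is validated against an independent transcription of the rule
list as vectorized boolean predicates, exhaustively over all strength-count
vectors up to 4 per slot ($5^7 = 78\,125$ profiles), plus monotonicity
fuzzing (adding same-category evidence never moves the tier the wrong way
along B < LB < VUS < LP < P).

## Synthetic data

`generate_panel()` draws control panels from a `panel_spec()`: true
activities uniform within each zone (pathogenic on
$[0, \mathrm{pathogenic\_max}]$, benign on $[\mathrm{benign\_min}, 100]$,
pseudodeficiency strictly between), expanded to replicates with additive
zero-mean Gaussian noise clipped at 0. Defaults mirror the real panel's
structure: 7 + 4 + 1 controls, boundaries 11/54, two replicates, noise
scale 1 percentage point — the order of magnitude of the observed replicate
spread (replicate pairs differing by up to ~1.7 points). Uniform zone
distributions are a modelling convenience in the absence of any stated
distribution, and are config-exposed.

`generate_observations()` stratifies activities, allele frequencies and
REVEL scores across the evidence strata (pathogenic/indeterminate/benign;
PM2/none/BS1; BP4/none/PP3) with random phase/codon/phenotype booleans,
attaching the intended stratum labels for self-consistency checks. Both
generators are seeded and restore the global RNG state.

What the generator does **not** emulate: batch and transfection-efficiency
effects, heteroscedastic noise at low activities, correlated replicate
error, realistic allele-frequency spectra, or any relationship between a
variant's activity and its REVEL score. Passing the synthetic-recovery
tests therefore demonstrates that the estimator and rule engine are
correct under the stated model, not that the assay itself is robust to
real-world artefacts — that is what the control panel and the SVI
validation requirements are for.

A boundary-recovery property is part of the acceptance suite: over 200
seeded panels with noise scale $\sigma = 2$, the fitted bounds stay within
$3\sigma$ of the true boundaries (upper side for `pathogenic_max`, lower
side for `benign_min`) in at least 95% of panels.

## Packaged study tables

`gaa_control_panel()`, `gaa_assay_replicates()` and
`gaa_variant_observations()` return the curated tables the analysis runs
on (12 controls; 8 tested variants from 7 screen-positive infants), and
`write_study_fixtures()` writes them as byte-stable TSV/JSON. Two allele
frequencies were published only as inequalities; the observation table
encodes them as representative values satisfying the inequality (0.0005
for "< 0.001 in all continental populations", 0.006 for "> 0.005 in South
Asians") and exact published values verbatim — the evidence assignment
depends only on which side of the threshold a value falls.

## Numerical and testing choices

* Problem sizes in the test suite: exhaustive $5^7$ engine enumeration;
  200 panels for boundary recovery; 100–200 fuzzed observations for
  mutual-exclusion and totality checks; 20 panels for self-consistency.
* TSV numerics are written with 17 significant digits, so write/read
  round-trips are bit-identical.
* Ties/degenerate inputs: `pathogenic_max = 0` panels are legal (only
  below-detection measurements then reach the pathogenic zone); empty
  observation tables produce an empty, well-formed report; an empty
  evidence profile is VUS with `insufficient_evidence`.

## Limitations

* The calibration is assay-specific: thresholds from one expression system
  do not transfer, and adding controls can move `pathogenic_max` — the
  strict-boundary semantics make that safe (new evidence can only be
  gained, not silently lost).
* OddsPath likelihood-ratio calibration of functional evidence and the
  Bayesian points-based reformulation of ACMG/AMP are not implemented.
* Codes outside the set used here (PVS1, PS1–PS4, PM1, PM4, PM6, PP1,
  PP2, BA1, BS2–BS4, BP1–BP3, BP5–BP7) are accepted by the engine as
  pass-through items but are not assigned from observations.
* VCF ingestion is out of scope; variants arrive as curated HGVS rows.
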