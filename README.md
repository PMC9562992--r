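# gaavcep

Functional-assay calibration and ACMG/AMP classification of *GAA* variants.

## The problem

Newborn screening for Pompe disease (glycogen storage disease type II,
biallelic *GAA* deficiency) flags infants by low acid alpha-glucosidase
activity in blood, then confirms by *GAA* sequencing. Most screen-positive
infants carry at least one variant of uncertain significance (VUS), and in
late-onset disease there is no neonatal phenotype to settle the question.
An in vitro expression assay — site-directed mutagenesis of a *GAA*
(NM_000152.5) construct, transient expression in HEK293 cells, enzyme
activity against 4MUG normalized to the wild-type construct — can supply
the missing functional evidence, but only if it is calibrated the way the
ClinGen Sequence Variant Interpretation (SVI) working group requires before
PS3/BS3 may be applied.

This package is for clinical laboratory geneticists and variant curators
who run such an assay and need the downstream bookkeeping to be exact,
auditable, and reproducible.

## The model

Let `a(v)` be the residual activity of variant construct `v` as % of wild
type (below-detection compared as 0). From a control panel of variants with
known classifications the calibration fit estimates

* `pathogenic_max = max{ a(v) : v pathogenic control }`
* `benign_min     = min{ a(v) : v benign control }`

and requires strict separation `pathogenic_max < benign_min`. Functional
evidence is then assigned by zone: `a < pathogenic_max` gives PS3,
`a >= benign_min` gives BS3, and the interval between — the indeterminate
zone, where a pseudodeficiency sentinel control must fall — gives no
functional evidence at any strength. The strength of PS3/BS3 follows SVI
control counts: a balanced panel of ≥ 11 pathogenic-plus-benign controls
permits the moderate level (`policy = "svi"`); the default
`policy = "conservative"` stays at supporting.

Remaining evidence codes are assigned at ClinGen *GAA* VCEP thresholds
(PM2_supporting below 0.001 in all populations; BS1 above 0.005 in any;
PP3/BP4 at REVEL > 0.7 / < 0.5; PM3 and PM5 at moderate; PP4 at moderate
when GAA deficiency is documented with pseudodeficiency alleles excluded),
and combined by the ACMG/AMP 2015 rules with each code counted at its
*applied* strength. Mixed-category profiles where either side alone would
reach a non-VUS tier resolve to VUS with rationale "evidence in conflict".

## Worked example

```r
library(gaavcep)

cal <- activity_calibration(gaa_control_panel())
cal
#> Functional assay calibration (GAA residual activity, % wild type)
#>   pathogenic zone:    < 11%   (7 pathogenic controls)
#>   indeterminate zone: [11%, 54%)
#>   benign zone:        >= 54%  (4 benign controls)
#>   policy: conservative -> PS3_supporting / BS3_supporting

report <- classify_variants(gaa_variant_observations(), cal)
report[, c("variant_cdna", "activity_zone", "final_tier", "rationale")]
#>   variant_cdna    activity_zone             final_tier             rationale
#> 1     c.316C>T pathogenic_range      likely_pathogenic           no_conflict
#> 2    c.1103G>A pathogenic_range      likely_pathogenic           no_conflict
#> 3    c.1721T>C pathogenic_range      likely_pathogenic           no_conflict
#> 4     c.664G>A    indeterminate uncertain_significance  evidence_in_conflict
#> 5    c.2450A>G pathogenic_range uncertain_significance insufficient_evidence
#> 6    c.1048G>A pathogenic_range      likely_pathogenic           no_conflict
#> 7    c.1378G>A    indeterminate uncertain_significance insufficient_evidence
#> 8    c.1123C>T    indeterminate      likely_pathogenic           no_conflict

summary(report)
#> Final classifications:
#>   Likely pathogenic      5
#>   VUS                    3
#> Variants whose tier depends on the functional assay: 2
```

The calibration puts five of the eight tested variants in the pathogenic
activity zone and three in the indeterminate zone. Combining the evidence
yields five likely-pathogenic calls and three VUS; the
`tier_without_functional` column shows that two of the likely-pathogenic
calls (c.316C>T and c.1103G>A) exist only because of the assay evidence —
without PS3 they revert to VUS.

A file-based pipeline (`run_pipeline()`) and a thin command line
(`inst/cli/gaavcep.R`, subcommands `calibrate` / `classify` / `synth` /
`profile-init`) wrap the same functions; `write_study_fixtures()` emits the
packaged tables as TSV/JSON for them.

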