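# fuzzyct

Automated detection of the **multihematoma fuzzy sign** — a noncontrast-CT
marker of acute traumatic intraparenchymal hematoma (tICH) expansion — and
a complete in-silico replica of the propensity-score-matched study design
used to validate such markers.

## Who this is for

Researchers working on NCCT markers of hematoma expansion after cerebral
contusion, and methodologists who want a fully synthetic, ground-truthed
testbed for the surrounding observational machinery (greedy caliper
matching, matched conditional odds ratios, balance diagnostics, subgroup
and ROC analyses).  No clinical data are required anywhere: the package
ships a CT phantom generator and a patient-level cohort simulator.

## The marker and the statistics

A contusion region is sign-positive when all three criteria hold on the
baseline scan:

1. **Multiplicity/adjacency (c1)** — at least three hyperdense hematomas
   (HU ≥ 50, 26-connected components of at least 0.1 mL), each pair within
   `d_max` of each other, where `d_max` is the largest (3-D Feret) diameter
   of the largest hematoma and distances are nearest-surface separations;
2. **Fuzzy corridor (c2)** — the corridor between each adjacent pair has a
   mean density above the gray/white parenchyma band (40 HU) but below the
   clot threshold: blood-density "fuzz", not brain tissue;
3. **Contrast (c3)** — clot exceeds the corridor by ≥ 20 HU
   (mean vs. mean).

Expansion on follow-up is growth ≥ 30% relative or ≥ 5 mL absolute of the
total hematoma volume.  The validation replica estimates the sign→expansion
effect as crude, sex/age-adjusted, all-confounder-adjusted and
propensity-score-adjusted odds ratios, and as the pair-stratified
conditional odds ratio after 1:1 greedy matching with a 0.05 caliper on
the propensity score (the discordant-pair ratio n10/n01, with McNemar's
(n10−n01)²/(n10+n01) test).  Discrimination is compared by rank-based AUC
with DeLong intervals; for a binary marker AUC = (sensitivity +
specificity)/2.

## Worked example

```r
library(fuzzyct)

# a ground-truthed phantom designed to carry the sign
ph  <- generatePhantom(scenarioSpec("positive", seed = 3), seed = 3)
seg <- segmentHematomas(ph$volume)
seg
#> HematomaSegmentation: 3 component(s) at threshold 50 HU
#>   id nVoxels volumeML meanHU centroidX centroidY centroidZ feretMM
#> 1  1    4253    5.316  68.82     28.85     21.46     38.09   23.90
#> 2  2    1375    1.719  68.88     38.03     38.24     38.38   21.00
#> 3  3    1199    1.499  69.17     22.14     39.98     38.61   20.52

detectFuzzySign(ph$volume, seg)
#> SignEvidence: 3 component(s); c1=TRUE c2=TRUE c3=TRUE -> sign TRUE
#>   cluster {1,2,3}, d_max 23.9 mm
#>   idA idB separationMM bridgeMeanHU clotMeanHU clotMinusBridgeHU
#> 1   1   2        4.031        44.27      68.85             24.58
#> 2   1   3        4.743        44.32      69.00             24.67
#> 3   2   3        5.000        44.16      69.03             24.86
```

Three clots (5.3, 1.7 and 1.5 mL) sit within 5 mm of each other — far
inside the 23.9 mm adjacency bound — and every inter-clot corridor reads
~44 HU: denser than parenchyma, ~25 HU below clot.  All three criteria
hold, so the sign is called.

```r
# the full matched-cohort study replica on a simulated 482-patient cohort
rep <- runStudy(studyConfig(params = cohortParams(nPatients = 482),
                            seed = 11))
rep
#> StudyReport: 482 eligible patients, sign prevalence 40.9%, expansion 58.7%
#>   175 matched pairs (caliper 0.05); McNemar chi2 64.00
#>                 method oddsRatio ciLow ciHigh   pValue nUsed
#> 1                crude      13.9  8.35   23.3 6.45e-24   482
#> 2     adjusted_sex_age      14.5  8.64   24.3 4.16e-24   482
#> 3 adjusted_confounders      14.3  8.17   24.9 1.02e-20   482
#> 4          ps_adjusted      11.6  6.89   19.6 3.24e-20   482
#> 5  matched_conditional       9.0  4.68   17.3 4.35e-11   175
#> ROC (pre-matched cohort):
#>                      predictor   auc ciLow ciHigh  n1  n0
#> 1     multihematoma_fuzzy_sign 0.758 0.723  0.794 283 199
#> 2           multiple_hematomas 0.677 0.634  0.719 283 199
#> 3 time_to_baseline_ct_inverted 0.585 0.533  0.637 283 199
#> 4              baseline_volume 0.609 0.559  0.660 283 199
```

The confounded simulator inflates the crude odds ratio (13.9) relative to
the matched conditional estimate (9.0); the sign discriminates expansion
best among the four candidate predictors.  The report also carries the
eligibility flowchart, the standardized-difference balance table
(Love-plot data), the sensitivity analysis restricted to patients with
three or more hematomas, and subgroup/interaction results; `writeStudyReport()`
serialises everything to JSON/CSV and `readStudyReport()` loads it back.

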