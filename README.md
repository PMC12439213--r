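# contourqa

Quality assessment of organ-at-risk (OAR) delineations in radiotherapy
planning. When AI auto-segmentation enters a contouring workflow, three
questions decide whether it is clinically usable: how closely do the
contours agree with a trusted reference, what does any disagreement do to
the reported dose, and how much clinician time does the workflow actually
save? `contourqa` computes all three for multi-observer cohorts, and ships
a synthetic digital-phantom cohort generator so the whole pipeline runs and
is tested without any clinical data.

## What it computes

**Geometric agreement** of each test mask A against a reference B on a
spacing-aware voxel grid:

- Dice similarity coefficient `DSC = 2|A∩B| / (|A| + |B|)`
- Hausdorff distance `HD = max( max d(S_A→S_B), max d(S_B→S_A) )` (mm)
- Mean surface distance `MSD = ( mean d(S_A→S_B) + mean d(S_B→S_A) ) / 2` (mm)
- Signed volume difference `VD = V_A − V_B` (cc, and relative to V_B in %)
- Centre-of-mass difference (mm, physical coordinates)

Surfaces `S` are the voxels removed by a face-connected erosion; directed
distances `d` come from an exact anisotropic Euclidean distance transform
(compiled, Felzenszwalb–Huttenlocher). Spinal-cord-like structures are
harmonized first by a caudal cut-off at the most cranial inferior end
across all compared contours.

**Dosimetric impact**: DVH summaries (Dmin/Dmax/Dmean/Dmedian, Gy) from a
dose grid and mask, or parsed from a TPS-style text export, differenced
against the reference under the organ's clinical-goal metric (Dmax for
serial organs and the mandible, Dmean for parallel organs).

**Workflow statistics**: group percentile summaries (5-25-50-75-95 + mean),
inter-observer variability (pooled SD per organ, averaged over organs),
percent reductions, median contouring time saved with and without AI
processing overhead, and contour-count bookkeeping.

## Worked example

Simulate a small multi-observer study (4 patients, 3 manual observers,
2 adjusted-AI observers, 1 AI output, 12 organ analogues) and evaluate it:

```r
library(contourqa)

st  <- make_cohort(n_patients = 4, n_manual = 3, n_adjusted = 2, seed = 42)
rep <- run_study(st)
print(rep)
#> contour-QA run report
#>   records: 288 (missing metrics: 0)
#>   median contouring time: manual 62 min, adjusted 18.25 min
#>   time saved: 43.75 min (71%); with processing: 36.5 min (59%)
#>   mean observer SD [msd_mm]: manual 0.278, adjusted 0.074 (-73%), ai_only 0.129 (-54%)
#>   mean observer SD [dsc]: manual 0.036, adjusted 0.009 (-76%), ai_only 0.015 (-59%)
#>   mean observer SD [hd_mm]: manual 1.107, adjusted 0.648 (-41%), ai_only 0.241 (-78%)
#>   mean observer SD [vd_cc]: manual 1.433, adjusted 0.238 (-83%), ai_only 0.342 (-76%)
#>   mean observer SD [cmd_mm]: manual 0.822, adjusted 0.247 (-70%), ai_only 0.291 (-65%)
```

288 records is one row per (patient, organ, observer, group) contour pair
against the ground truth. The mean observer SDs show the generator's design
recovered by the measurement pipeline: manual observers (2.0 mm boundary
noise) are more variable than adjusted-AI (0.8 mm) and AI-only (0.6 mm)
contours, for every geometric metric. Per-organ percentile tables live in
`rep$summaries`:

```r
head(subset(rep$summaries, metric == "dsc" & group == "manual"), 4)
#>       oar_name  group metric  n  mean     sd    p5   p25   p50   p75   p95
#> 31   brainstem manual    dsc 12 0.905 0.0312 0.866 0.887 0.899 0.920 0.954
#> 32 spinal_cord manual    dsc 12 0.870 0.0540 0.787 0.866 0.878 0.886 0.936
#> 33      larynx manual    dsc 12 0.908 0.0364 0.861 0.879 0.908 0.929 0.964
#> 34    mandible manual    dsc 12 0.824 0.0278 0.776 0.810 0.832 0.844 0.854
```

The timing arithmetic works directly on group medians too — with a manual
median of 55 min, an adjusted median of 17 min and 10 min of AI processing
and import:

```r
time_saving(55, 17, processing_min = 10)
#> $median_saved_min                  38
#> $pct_saved                         69
#> $median_saved_with_processing_min  28
#> $pct_saved_with_processing         51
```

`run_study(st, out_dir = "out")` writes `records.csv`, `summaries.csv`,
`headline.json` and `run.log`; `write_study(st, dir)` materializes a study
as NIfTI masks + dose volumes + timing CSV + manifest, and `run_study(dir)`
evaluates such a directory. A thin command-line front end with
`simulate` / `evaluate` / `report` subcommands is installed at
`inst/cli/contourqa.R`.

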