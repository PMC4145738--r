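# dwifinger

DWI-based neural fingerprinting for ischemic-stroke subtype clustering.

Acute ischemic infarcts restrict water diffusion and appear hyperintense on
diffusion-weighted MRI (DWI); chronic infarcts (stroke sequela) show elevated
diffusivity and appear hypointense. `dwifinger` turns that physiology into a
compact per-subject feature — the **neural fingerprint** — and clusters it to
separate normal controls, acute stroke and stroke sequela without
supervision. It is aimed at neuroimaging methods researchers who want a
fully reproducible, end-to-end testable implementation of the approach,
including a synthetic DWI phantom so that no clinical data is needed to run
any of it.

## The method in one paragraph

Each subject is imaged with one b = 0 volume and 20 diffusion gradients at
b = 1000 s/mm² in a constant order. Given a lesion (target) ROI and its
contralateral mirror ROI (the target reflected across the midsagittal
plane), the fingerprint is

```
x_i = mean(S_i over target ROI) / mean(S_i over mirror ROI),   i = 1..20
```

one ratio per gradient. The mirror reference cancels scanner gain, so normal
tissue gives x ≈ 1, acute lesions x > 1, sequela x < 1, and the shape across
gradients carries directional tissue information. Fingerprints are clustered
by K-means (k = 3) under Euclidean or cosine distance, and the result is
scored against the clinical reference with a class-weighted F-score

```
F = Σ_j (|P_j|/n) · max_i 2·P·R / (P + R)
```

(precision P = |Pj∩Ci|/|Ci|, recall R = |Pj∩Ci|/|Pj|) and direct-match
accuracy with Wald 95% confidence intervals. Target ROIs come from three
strategies: manual masks (with Bland–Altman interrater statistics),
semiautomatic mirror-difference histogram thresholding, and an automatic
voxelwise FA group comparison (Welch t-test, uncorrected p < 0.005). See
`vignettes/neural-fingerprinting.Rmd` for the full methods account.

## Worked example

Simulate the default synthetic cohort — 8 normals, 8 acute, 3 sequela on a
48×48×20 grid with Rician noise — and run the full pipeline with
ground-truth ("manual") ROIs and Euclidean K-means:

```r
library(dwifinger)
cohort <- make_cohort(8, 8, 3, master_seed = 42)
res <- run_pipeline(cohort, roi_method = "manual", metric = "euclidean", seed = 42)
res
#> <pipeline_result: manual ROI, euclidean metric | accuracy 100% (19/19), F = 1.00>

fpm <- fingerprint_matrix(res$fingerprints)
round(tapply(rowMeans(fpm), res$fingerprints$class, mean), 3)
#>     1     2     3
#> 1.000 1.309 0.631
```

All 19 subjects cluster into their true classes (accuracy 100%, F = 1). The
per-class fingerprint means show why: normals sit at 1.000 (left/right
symmetry), acute lesions push the ratio to 1.309 (restricted diffusion,
hyperintense), sequela pull it to 0.631 (elevated diffusivity,
hypointense).

The package also ships a transcription of the clinical study table it
reproduces — 19 subjects, clinical reference plus six clustering columns
(manual/semiauto/auto × Euclidean/cosine) — and recomputes its metrics:

```r
reproduce_table1()
#>  column roi_method    metric f_score accuracy_percent ci_low ci_high n_match
#>      ME     manual euclidean    1.00              100    100     100      19
#>      MC     manual    cosine    0.69               68     48      89      13
#>      SE   semiauto euclidean    0.75               68     48      89      13
#>      SC   semiauto    cosine    0.89               89     76     100      17
#>      AE       auto euclidean    0.60               58     36      80      11
#>      AC       auto    cosine    0.66               63     41      85      12
```

Manual ROIs with Euclidean distance classify perfectly; automated
segmentation degrades the clustering, which is the study's central
observation.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dwifinger.R simulate --out cohort/ --seed 42
Rscript inst/cli/dwifinger.R pipeline --out run/ --roi manual --metric euclidean
Rscript inst/cli/dwifinger.R reproduce-table1   # exits nonzero on any metric mismatch
```

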