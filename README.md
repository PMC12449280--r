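# invertseg

Reusing CT-trained segmentation models on MRI by intensity inversion.

Voxel-wise annotation of new structures in MRI is slow, and most mature
multi-organ and lesion segmentation models are trained on CT. One key
obstacle to simply running a CT model on an MR image is contrast: dense
tissue such as bone is bright (hyperdense) in CT but dark (hypointense) in
T1-weighted MRI. `invertseg` implements the preprocessing that bridges this
gap — taking the image negative and forcing the background air to black —
together with everything needed to evaluate the transfer quantitatively:
isotropic resampling, pluggable segmentation backends, class-wise Dice
evaluation with bootstrap confidence intervals, tumor localization and
volume-stratified analyses, and paired nonparametric statistics. A seeded
synthetic abdominal phantom generator provides co-registered CT-like,
T1w-like and T2w fat-saturated-like volumes with ground-truth labels, so
every claim is testable end to end without patient data.

## The preprocessing

For a volume with intensity multiset `X`, intensities are first clipped to
`[0, 3000]`, then inverted within their original range, and finally all
values at or below the first percentile are set to zero:

```
INV(x) = 0                          if x <= percentile_1(X)
         max(X) - x + min(X)        otherwise
```

The percentile step keeps the area around the patient black after
inversion (background air in exported MRI is a tie mass at the image
minimum); without it, the bright inverted background misleads models that
rely on the body/air contrast. Three variants are exposed: `unprocessed`,
`inverted` (clip + plain negative) and `inverted_black` (clip + negative +
background zeroing).

## Evaluation

Predictions are scored against reference labels with the Dice similarity
coefficient, DSC = 2|A∩B| / (|A|+|B|), aggregated with case-level
percentile-bootstrap 95% confidence intervals. Variants are compared with
two-sided Wilcoxon signed-rank tests (exact null for up to 25 non-zero
pairs), p-values adjusted with the Benjamini–Hochberg procedure;
Shapiro–Wilk normality and Spearman volume–DSC correlations are reported
alongside. Per-case tumor predictions are classified as correctly
localized, incorrectly localized, or not detected.

## Worked example

```r
library(invertseg)

# one synthetic subject: 96^3 voxels at 2 mm, a 29 cm^3 left renal lesion
case  <- generatePhantom(PhantomSpec(seed = 11L))
truth <- resampleIsotropic(truthLabels(case), 1)   # 1 mm working grid
t1    <- resampleIsotropic(t1Volume(case), 1)

w <- defaultWindows()   # rule-based CT-intensity-prior backend
raw <- evaluateCase(windowSegment(t1, w), truth,
                    sequence = "T1w", variant = "unprocessed")
inv <- evaluateCase(windowSegment(preprocessVolume(t1, "inverted_black"), w),
                    truth, sequence = "T1w", variant = "inverted_black")
round(c(unprocessed = mean(raw$dsc, na.rm = TRUE),
        inverted_black = mean(inv$dsc, na.rm = TRUE)), 3)
#>    unprocessed inverted_black
#>          0.001          0.586
```

Without preprocessing, the CT-style backend finds essentially nothing in
the T1w image (mean DSC 0.001 across the 12 phantom classes); after
inversion with a black background it recovers most organs (mean DSC
0.586, with kidneys, liver, muscle and aorta all above 0.9 — air-filled
lungs and fat remain failures, as their intensities have no CT-like
counterpart after inversion). The full experiment grid — cohorts, both MRI
sequences, all variants, statistics and report files — runs through
`runExperiment()`; see the vignette in `vignettes/` for the model,
parameter and design details.

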