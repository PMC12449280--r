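---
title: "Cross-modality segmentation transfer by intensity inversion: models, phantom and design choices"
author: "invertseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality segmentation transfer by intensity inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invertseg)
```

## The problem and the procedure

Mature multi-organ and lesion segmentation models exist for CT; MRI lags
behind, especially for abdominal pathology such as renal tumors. A CT
model applied directly to MRI mostly fails because the contrast polarity
differs: dense tissue (bone, contrast-filled vessels) is bright in CT and
dark in T1-weighted MRI, while fat is dark in CT and bright in T1w. The
procedure implemented here makes a T1w image "look CT-like" with three
deterministic steps:

1. **Clip** intensities to `[0, 3000]` (scanner-unit outliers removed);
2. **Invert**: `x -> max(X) - x + min(X)`, the image negative within its
   original range;
3. **Zero the background**: all values at or below the 1st percentile of
   the clipped image are set to exactly 0.

Step 3 matters because inversion turns the dark air around the patient
into the brightest structure in the image, and segmentation models rely
heavily on the body/air contrast. In exported MR images the background is
a large tie mass at the image minimum (scanners mask it to zero), so the
1st-percentile *value* threshold blacks out all of it. We read "within
the first percentile" as the inclusive value threshold
`x <= quantile(X, 0.01)` (linear-interpolation percentile): background
air occupies far more than 1% of the voxels, so a 1%-of-voxels quota
could never darken it all, whereas the value threshold lands inside the
background tie mass and removes it completely. The threshold is computed
on the clipped, pre-inversion intensities, and ties at exactly the
threshold are zeroed. T2w fat-saturated images are treated identically;
whether inversion helps or hurts there is an empirical question the
pipeline answers (it hurts: water-rich organs are already bright, i.e.
CT-like in ordering, before inversion).

For T2wfs sequences the recommendation that emerges is the opposite:
apply no preprocessing at all, because the bright water-rich organs
already match a CT-like brightness ordering for the structures a renal
pipeline cares about.

## Pipeline geometry

Volumes are read from NIfTI, reoriented to the canonical closest-to-RAS
axis order on load (so "left kidney" is well defined from voxel indices),
and resampled to 1 mm isotropic spacing before preprocessing —
geometry-first, then intensity. Intensity volumes are interpolated
trilinearly; label maps use nearest-neighbor so no fractional ids can
appear and no new ids are invented. Voxel `(0,0,0)` centres stay aligned
and the physical extent is preserved to within one voxel per axis; label
volume is conserved within 5% for structures of at least 100 voxels
(asserted in the tests).

## Segmentation backends

The backend contract is minimal: a function from a `Volume` to a
`LabelMap` on the same grid. Real CT models (TotalSegmentator-style
tools, nnU-Net derivatives) attach through `externalSegment()`, which
writes the volume to disk, substitutes `{input}`/`{output}` in a command
template, and reads back one label file or a directory of per-class masks
merged through an explicit JSON name-to-id mapping. Nothing is resampled
or renamed silently, and a failing command surfaces as an error with its
exit status. Training or re-implementing such models is out of scope.

For desk-scale, fully reproducible experiments the package ships a
rule-based **window segmenter**: per class, an intensity window, an
optional left/right-of-midline constraint (midline = the grid's middle
sagittal plane), a minimum 26-connected-component volume in mm³, and an
integer priority resolving overlaps (ties broken by table order). It is
deterministic by construction. The default window table is expressed on
the volume's min–max-rescaled intensities (`scale = "relative"`) —
mirroring the fixed input normalization CT-trained networks apply — and
encodes *CT intensity priors*: it resolves the phantom's classes on
CT-like input, fails almost completely on raw T1w-like input, and
recovers most classes after inversion. That is precisely the mechanism
the transfer procedure exploits, reproduced in a testable form. Windows
can also be given in raw intensity units (`scale = "raw"`).

## The synthetic phantom

`generatePhantom()` renders one subject from a jittered procedural
geometry (paired kidneys, a renal lesion, liver, spleen, gallbladder,
aorta, spine, lungs, fat, a muscle shell, background air) into three
co-registered volumes over one ground-truth label map. What it emulates
is *intensity structure*, not anatomy:

* **CT-like**: air ≪ lung < fat < muscle < soft organs < contrast-bright
  aorta < bone, in HU-like units (air −1000, bone 1600). The soft-organ
  spacing is wider than real HU so that intensity windows alone can
  separate classes; the values are package defaults, editable in
  `inst/extdata/tissues_default.csv`.
* **T1w-like**: fat brightest; the soft-tissue ordering is an exactly
  monotone *decreasing* map of the CT ordering; bone dark; air-filled
  lungs near the noise floor. This makes the mechanism claim testable:
  the rank correlation of per-tissue means between inverted T1w and CT
  is positive (> 0.8, in practice ≈ 1), while raw T1w vs CT is negative.
* **T2wfs-like**: water-rich organs (kidney, spleen, gallbladder, lesion)
  brightest; fat and bone suppressed; air darkest.

Gaussian noise (default SD 0.009 of each modality's intensity scale) and
a smooth multiplicative polynomial bias field (default amplitude 0.01)
are added. MRI background air is *exactly* zero — emulating the scanner
background masking of exported images — which is what makes the
percentile threshold of the inversion land on the background tie mass;
CT air carries noise around −1000. Lung intensities straddle the
threshold, so lungs are partially zeroed and invert into a bright
artifact, reproducing the known lung artifact of this preprocessing.
The lesion is a sphere of requested volume centred in the chosen kidney
(large lesions balloon beyond it, clipped to the body; a lesion whose
realized volume would miss the request by more than 10% is rejected).
Its contrast is clearly distinct from kidney parenchyma in CT-like and
T2wfs-like images but subtle in T1w-like ones (≈ half the organ/background
contrast), so small lesions degrade gracefully and the volume–DSC
correlation analysis has something to measure.

Cohorts derive per-case seeds deterministically from one master seed;
lesion volumes are drawn log-uniformly (default 1–200 cm³, a mid-sized
renal-tumor range scaled to the phantom's 192 mm field of view) and sides
with 45/55 left/right probabilities. The same spec is always bit-identical.

What the phantom does **not** model: MR physics (no TR/TE), partial
volume beyond interpolation, motion, fold-over, coil geometry, or
anatomical realism beyond relative position. Passing tests therefore
demonstrate that the *procedure* behaves as designed under controlled
intensity structure — not that any particular clinical DSC level would be
reached on patient data.

## Statistics

* **Dice**: `2|A∩B|/(|A|+|B|)`; when both masks are empty the value is
  undefined and excluded from means (scoring it 1 would inflate synthetic
  summaries; the count of exclusions is reported). Group means pool all
  (case, class) records; confidence intervals are case-level percentile
  bootstrap (B = 2000 by default, seeded).
* **Wilcoxon signed-rank**, two-sided, on per-case comparison units
  (mean DSC across classes, or the tumor-class DSC). Zero differences are
  dropped; tied absolute differences get midranks; the exact null
  distribution is used for up to 25 non-zero pairs (dynamic programming
  over rank sums, exact also under ties) and a normal approximation with
  tie and continuity corrections above. The exact path is verified
  against exhaustive 2^n sign-flip enumeration in the tests.
* **Benjamini–Hochberg** adjustment over all comparisons emitted together
  (one family per report); raw and adjusted p-values are both printed.
* **Shapiro–Wilk** is reported descriptively only: the comparisons are
  always nonparametric rather than branching to t-tests on a normality
  gate, which keeps the analysis path single and documented.
* **Spearman** correlation uses midranks and a t-approximation p-value.
* **Localization**: a tumor prediction is *not detected* if empty,
  *correct* if it overlaps any reference-tumor voxel (an optional minimum
  overlap fraction is available and defaults to 0 — the weakest
  defensible reading, made explicit and configurable), *incorrect*
  otherwise. The volume split assigns records at exactly the median
  volume to the upper stratum.

## Numerical and design notes

* Percentiles use linear interpolation (R type 7) throughout.
* `invertPlain` is an exact involution on integer-valued volumes; on
  float data it is an involution up to one ulp.
* Degenerate inputs are first-class: constant volumes invert to
  themselves (plain) or to all-zero (black background); all-zero paired
  differences yield p = 1 with a degenerate flag; empty summary groups
  are flagged rows, never silently dropped.
* Window overlaps are resolved by explicit integer priority (higher
  wins); 26-connectivity is the 3-D morphology default.
* The experiment driver resamples before preprocessing, runs every
  case × sequence × variant cell independently, continues past per-case
  backend failures (erroring only if more than half fail), and writes a
  manifest (config, config hash, package version) from which a rerun
  reproduces every CSV byte for byte.
* Default problem sizes — 96³ voxels at 2 mm, cohorts of 20 (direction
  analyses) and 30 (volume analyses) — are the package's chosen working
  scale for a fully synthetic study; they keep a complete experiment in
  the minutes range on a single CPU while leaving every class with
  thousands of voxels.

## Known limitations

The window backend is an intensity model, so classes whose inverted
position has no CT counterpart (fat, which as the brightest T1w tissue
always inverts to the bottom of the range; air-filled lungs) fail in
inverted T1w even though a shape-aware CNN might recover them; this
mirrors, but exaggerates, the worst-performing classes of CNN-based
transfer. Boundary voxels acquire intermediate intensities under
trilinear resampling and can form thin mislabelled shells at organ
interfaces; the per-class minimum-component filter removes most but not
all of them. The phantom's left/right convention follows the canonical
RAS axis order; images without any stored orientation are taken as
already canonical.
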