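# mmseeg

Multivariate multiscale sample entropy (mMSE) analysis of resting-state EEG
over electrode sets corresponding to the seven canonical resting-state
functional networks, with the complete statistical layer used to compare
networks and groups.

## What it does, and for whom

Resting-state EEG complexity is commonly summarized by multiscale sample
entropy: the sample entropy of a signal evaluated on coarse-grained copies
(non-overlapping window means of length *s*) across scale factors
*s* = 1…12. This package implements the multivariate form — composite delay
vectors spanning all *p* channels of a network's electrode set, with
entropy −ln(B<sub>m+1</sub>/B<sub>m</sub>) from Chebyshev-distance template
matching — for researchers who want to:

* compute per-subject mMSE profiles (scales 1–12; *m* = 2, *r* = 0.15,
  τ = 1, 1024-sample segments) for the DMN, DAN, FPN, LN, SMN, VAN and VN
  electrode sets of the 10–20 system, or any user-defined montage;
* reduce each profile to four curve features — **AUC** (trapezoidal area,
  total complexity), **MaxSlope** (steepest pairwise rise among scales 1–4),
  **AvgEnt** (mean of scales 9–12), **DiffEnt** (v₉ − v₄);
* quantify segment-wise reliability (Cronbach's alpha over three 40-s
  segments) and test network and group effects with a mixed
  within/between-subject ANOVA (Greenhouse–Geisser correction, partial eta
  squared, Bonferroni post-hocs over the 21 network pairs);
* preprocess raw recordings with the staged cascade: resample to 256 Hz,
  1–40 Hz zero-phase band filtering, SD-based bad-channel removal,
  444/222/111 µV epoch rejection on disjoint 10,240-sample (40 s) epochs,
  average referencing;
* read/write BrainVision and EDF recordings;
* generate fully synthetic two-group EEG cohorts with controllable
  white/1-f/AR(1) mixture structure, cross-channel correlation, injectable
  artifacts and known group contrasts, so every stage is testable without
  access to real data.

An exhaustive brute-force implementation of the entropy estimator
(`msampen_brute`) ships alongside the optimized kernel and anchors the test
suite at 10⁻¹² agreement.

## Worked example

```r
library(mmseeg)

# one synthetic subject: 19 montage channels, 3 x 40 s epochs at 256 Hz
spec <- cohort_spec(n_group_a = 1, n_group_b = 0, seed = 42)
rec  <- generate_subject_recording(spec, "a", "s01", 42)
rec
#> <eeg_recording> 19 channels x 30720 samples @ 256 Hz (120.0 s)

# preprocess (band filter + staged rejection; reference-free synthetic data)
ep <- preprocess_pipeline(rec, rereference = FALSE)

# mMSE profiles for all seven networks
su <- subject_network_mmse(ep, default_montage())
round(su$networks$SMN$values, 2)
#>  [1] 1.15 2.09 2.35 2.41 2.43 2.12 2.12 2.16 2.07 2.07 1.84 1.93

head(feature_table(list(su), level = "aggregate")[, c("network", "AUC", "MaxSlope", "AvgEnt", "DiffEnt")], 3)
#>   network   AUC MaxSlope AvgEnt DiffEnt
#> 1     DMN 23.15   0.9711  1.985 -0.2940
#> 2     DAN 23.03   0.9758  1.945 -0.3442
#> 3     FPN 23.13   0.9714  1.972 -0.3109
```

The profile shows the expected skewed inverted-U: suppressed at scale 1 by
the 40 Hz band limit, peaking at fine scales 3–4, declining toward the
coarse-scale plateau summarized by AvgEnt; DiffEnt < 0 measures that
decline.

A full two-group study in one call:

```r
res <- run_pipeline(list(seed = 1))   # 20 + 20 subjects, 3 epochs each
res$anova$AvgEnt
#> <mixed_anova> 39 subjects (a vs b), 1 dropped
#>           effect   df1_gg   df2_gg       F        p partial_eta_sq
#>            group 1.000000  37.0000 360.631 1.14e-20          0.907
#>        condition 5.011065 185.4094   0.527 7.56e-01          0.014
#>  condition:group 5.011065 185.4094   1.022 4.06e-01          0.027
```

Group a (white-noise-heavy mixture) shows higher MaxSlope, lower AvgEnt and
more negative DiffEnt than group b (1/f-heavy) — the designed
fine-scale/coarse-scale trade-off, detected here at p ≪ 0.001.

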