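---
title: "Multiscale entropy of resting-state EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy of resting-state EEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmseeg)
```

## The measure

Sample entropy (SampEn) of a series is the negative log of the conditional
probability that two embedding vectors of length $m$ lying within Chebyshev
distance $r$ of each other still lie within $r$ when each is extended by one
further sample. Multiscale entropy (MSE) evaluates SampEn on coarse-grained
copies of the signal — means of consecutive non-overlapping windows of length
$s$ for scale factors $s = 1, 2, \dots, \varepsilon$ — so that the resulting
profile separates signals whose irregularity lives only at the sampling scale
(white noise: entropy decays with $s$) from signals with long-range temporal
structure (1/f noise: an approximately flat profile).

The multivariate extension replaces the univariate embedding by composite
delay vectors spanning all $p$ channels of a channel set,

$$X(i) = \big[x_1(i), x_1(i+\tau_1), \dots, x_1(i + (m_1-1)\tau_1),\;
x_2(i), \dots, x_p(i + (m_p-1)\tau_p)\big],$$

with $i = 1 \dots N - n^*$, $n^* = \max_k m_k \tau_k$. $B_m$ is the fraction
of ordered vector pairs with distinct time origins within Chebyshev distance
$r$. For dimension $m + 1$ each vector is extended by one further delayed
sample in each of the $p$ variates separately, giving $p(N - n^*)$ vectors
over which $B_{m+1}$ is computed, and the entropy is
$-\ln\,(B_{m+1}/B_m)$ in nats.

**Pair-counting convention.** At dimension $m+1$ the extended family contains,
for every time origin $i$, $p$ vectors that share the identical base $X(i)$
and differ only in the final coordinate. This package counts only pairs with
*distinct time origins* at both dimensions. Same-origin pairs have base
distance zero by construction; for the short coarse-grained series this
analysis works with (85 samples at scale 12 for $n = 1024$) and for strongly
inter-correlated channels, including them inflates $B_{m+1}$ by a term of
order $p(p-1)(N-n^*)$ trivial near-matches, biasing entropy downward most
severely exactly where entropy is highest. With distinct-origin counting the
estimator reduces exactly to univariate SampEn when all channels are
identical, which is the natural consistency requirement. The brute-force
reference implementation (`msampen_brute`) uses the same convention, and the
optimized kernel is tested against it to $10^{-12}$.

**Undefined values.** When $B_m = 0$ or $B_{m+1} = 0$ the entropy of that
segment/scale is undefined; it is returned as `NA` with a reason attribute,
never as $\pm\infty$. Profile values average only the defined segments and
the per-scale validity counts are retained.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | embedding dimension per variate |
| `r` | 0.15 | similarity radius, in units of the scale-1 segment SD |
| `tau` | 1 | embedding delay per variate |
| `max_scale` | 12 | coarsest scale factor; the profile covers scales 1–12 |
| `segment_length` | 1024 | samples per analysis segment at 256 Hz (4 s) |

Each 40-s epoch (10,240 samples) is split into ten disjoint 1024-sample
segments. Each segment is standardized once, at scale 1, and $r$ is held
fixed across scales (the Costa convention): coarse-graining then *reduces*
the variance of temporally irregular signals, which is precisely what makes
their entropy fall across scales. Per-segment entropies are averaged within
an epoch and epoch profiles averaged within a subject; segment- and
epoch-level values are kept for the reliability analysis.

Each channel set's $p$ equals the number of electrodes it lists — five for
every default network set. The seven default sets (DMN, DAN, FPN, LN, SMN,
VAN, VN) are fixed 10–20 electrode lists; sets may overlap, and LN and VAN
differ in a single position, which is a documented property of this montage,
not an error.

## Curve features

With $v_1 \dots v_{12}$ the profile values:

* **AUC** — trapezoidal area $\sum_{i=1}^{11} (v_i + v_{i+1})/2$: total
  complexity.
* **MaxSlope** — $\max_{1 \le i < j \le 4} (v_j - v_i)/(j - i)$, signed:
  the steepest rise among the fine scales. An absolute-value variant is
  available via `absolute = TRUE`.
* **AvgEnt** — mean of $v_9 \dots v_{12}$: the coarse-scale entropy plateau.
* **DiffEnt** — $v_9 - v_4$: change from the fine-scale peak region to the
  plateau; negative for the inverted-U profiles typical of band-limited
  neural signals.

Aggregate features are computed on the epoch-averaged profile; AUC, AvgEnt
and DiffEnt are linear in the profile so this equals the mean of per-epoch
features, while MaxSlope (a maximum) is deliberately computed on the averaged
curve as well, with per-epoch values retained for reliability.

## Statistics

* **Cronbach's alpha** over the first three 40-s epochs as "items", per
  network for every scale and every feature: $\alpha = \frac{k}{k-1}(1 -
  \sum_i \mathrm{var}(y_i) / \mathrm{var}(\sum_i y_i))$, $n-1$ variances.
* **Mixed ANOVA**: network (7 levels) within subjects, group between
  subjects, via the orthonormal-contrast (multivariate) formulation with
  effect-coded group — i.e. Type III sums of squares, so the unbalanced
  designs this kind of cohort produces are handled. Greenhouse–Geisser
  epsilon is estimated from the pooled within-group covariance as
  $(\mathrm{tr}\,S^*)^2 / ((k-1)\,\mathrm{tr}\,S^{*2})$ on the
  double-centered $S^*$, bounded to $[1/(k-1), 1]$, and multiplies both
  within-effect degrees of freedom. Partial eta squared is
  $SS_e/(SS_e+SS_{err})$ per stratum.
* **Post-hocs**: paired $t$ tests over all 21 network pairs, $p$ multiplied
  by 21 and capped at 1; the family is the set of pairs within one feature.
* Subjects with any missing network cell are dropped listwise (and counted);
  degenerate inputs (zero error variance) yield $F = 0$ or a flagged
  undefined value rather than silent infinities.

The ANOVA implementation is verified against R's `aov()` split-plot
decomposition on balanced data (where Type I and Type III coincide) to
$10^{-8}$, and the epsilon against an eigenvalue-based oracle.

## The synthetic cohort: what it emulates, and what it does not

Each subject's recording mixes, per channel, three standardized noise
classes — white (scale-local information), 1/f (scale-invariant structure)
and AR(1) (short memory) — with non-negative amplitude weights, then couples
the channels through a common-mode mixing matrix
$M = (1-\alpha) I + \tfrac{\alpha}{p-1}(J - I)$ and rescales each channel to
15 µV SD, a typical resting EEG amplitude. Two groups differ only in their
mixture weights (defaults: group a 0.8 white / 0.2 pink, group b 0.2 white /
0.8 pink); there are no additive mean offsets, so every downstream group
difference arises from temporal structure alone. Per-subject seeds are
derived deterministically from the cohort seed, and a small multiplicative
log-normal jitter on the weights (`subject_sd = 0.15`) gives subjects stable
trait-like individual differences — without it, all subjects in a group are
exchangeable and internal-consistency coefficients are structurally near
zero, since there is no between-subject true-score variance for the items to
agree on.

**Why the mixing default is extreme.** When `mixing_strength` is not set it
resolves to $0.99\,(p-1)/p$, inducing inter-channel correlations of ~0.998.
This is deliberately stronger than scalp EEG's typical referenced channel
correlations. At the analysis parameters fixed throughout ($p = 5$, $m = 2$,
$r = 0.15$, $n = 1024$), the composite vectors live in 10–11 dimensions, and
for weakly correlated channels the probability that two vectors match within
$r$ in *every* coordinate is so small that $B_m$ is empty at many scales —
the estimator is simply undefined on such data at this segment length. Real
scalp recordings are usable because volume conduction and the dominance of
low-frequency power make neighboring channels strongly covariant and
successive samples nearly redundant; the generator reproduces that regime by
concentrating signal in the common mode. The cost is a known non-realism:
the generator's spatial structure is one shared source plus independent
residuals, not a topographically organized source mixture.

A second consequence of that spatial model: the common mode is an
eigenvector of the average-referencing operator, so re-referencing to the
common average *exactly removes* the generator's cross-channel covariance
($H(aI + bJ) = aH$), leaving near-independent channels on which the
estimator is undefined. Synthetic-cohort pipeline runs therefore disable the
re-reference stage by default (`preprocess$rereference = FALSE` in the run
configuration); the stage itself is implemented, tested (zero column means,
idempotence) and applied when preprocessing real referenced recordings.

**Noise-class contracts.** On raw (unfiltered) mixed 4-channel segments the
profile reproduces the textbook signatures: white noise decays
monotonically across scales 1–12 and 1/f noise stays comparatively flat
(the tests assert a flatness ratio below 0.3). The skewed inverted-U shape
arises once the signal is band-limited: after the 1–40 Hz pass band at
256 Hz, successive samples are correlated, scale-1 entropy is suppressed,
and the profile rises to a fine-scale peak (scales 2–5) before declining.
This is also the regime in which the white-heavy group shows a steeper
fine-scale rise (higher MaxSlope), a lower coarse-scale plateau (lower
AvgEnt) and a more negative DiffEnt than the pink-heavy group — the
fine-vs-coarse trade-off the cohort is designed to exhibit. The
direction-of-effect test asserts exactly these contrasts at
Bonferroni-corrected $p < 0.05$ on the default 20 + 20 cohort.

## Preprocessing cascade

Stage order for raw recordings: resample to 256 Hz (rational polyphase) →
1 Hz high-pass → SD-based bad-channel removal → 444 µV epoch rejection →
40 Hz low-pass → average reference → 222 µV rejection → pluggable artifact
hook (identity by default; the slot where component-based artifact removal
would run) → 111 µV rejection. Filters are 4th-order Butterworth applied
forwards and backwards (zero phase). All three rejection passes share the
final 10,240-sample epoch grid, fixed immediately after the high-pass; an
epoch is rejected iff its maximum absolute amplitude across channels exceeds
the stage threshold, and every rejection is logged with the epoch index and
the triggering value. Bad channels are flagged per band by standardizing
each channel's band-limited SD against the channel population — $z > 5$ in
0–5 Hz, $z > 2.5$ in 5–40 Hz — and are excluded from all downstream
analysis; any network containing an excluded electrode becomes a missing
(not zero) cell for that subject. Interpolation of removed channels is
cosmetic in the original procedure and is not performed.

## Numerical and design notes

* The optimized counting kernel (C++) enumerates ordered base-vector pairs
  with early-abort Chebyshev comparison; counts, not ratios, cross the
  language boundary so zero-match conditions are signalled explicitly.
* Coarse series drop the trailing remainder ($\lfloor N/s \rfloor$ windows).
* `segment_length / max_scale` must leave at least $m\tau + 2$ coarse
  samples; configurations violating this are rejected at validation time.
* The per-subject seed map is `(cohort_seed mod 100003) * 20011 + 104729 *
  index + 17 (mod 2147480017)`, keeping all seeds in 32-bit range.
* Problem sizes used by the test-suite and the acceptance script — 20 + 20
  subjects, 3 epochs each for the cohort contrast; 8 subjects per noise
  class for the profile signatures; 50 random instances for the oracle
  equivalence — were chosen as the smallest sizes at which the asserted
  group-level properties are stable across seeds.

## Known limitations

* The generator's spatial model (single common mode) cannot emulate
  topographic source structure, realistic artifact morphology, or data that
  survive average referencing; validation against the re-reference stage
  must therefore use real recordings.
* MaxSlope is the noisiest feature (its segment-level reliability is
  markedly lower than AvgEnt's, as the cohort run's alpha grids show) —
  consistent with it being a maximum of noisy differences.
* Entropy at coarse scales rests on as few as 85 samples; undefined values
  are possible and are propagated as missing rather than imputed.
* The electrode-set montage is an approximation to source-space networks by
  construction; the package treats the printed electrode lists as ground
  truth and makes no claim about source localization.
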