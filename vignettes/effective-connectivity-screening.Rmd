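---
title: "Directed EEG connectivity features and random-forest screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed EEG connectivity features and random-forest screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegforest)
```

## The problem and the model

`eegforest` implements an interpretable screening pipeline for two-class
multichannel EEG cohorts (e.g., patients vs. controls). Rather than
classifying raw signals, it classifies *directed effective connectivity*:
model-based, directional couplings between channels, which admit a
clinical reading ("channel A drives channel B in the theta band") that a
black-box classifier does not.

Each recording is band-limited (zero-phase Butterworth, 0.5 and 50 Hz,
order 4 per filter by default), cut into 60 s windows, and each window is
modelled as an order-$p$ multivariate autoregressive (MVAR) process

$$x_t = \sum_{k=1}^{p} A_k\, x_{t-k} + u_t, \qquad u_t \sim N(0, C),$$

with $m$ channels, coefficient matrices $A_k \in \mathbb{R}^{m\times m}$
and innovation covariance $C$. The coefficients operationalize Granger
causality: entry $(i,j)$ of $A_k$ is the lag-$k$ influence of channel $j$
on channel $i$. Estimation is multichannel ordinary least squares on the
stacked one-step regression after subtracting channel means; $C$ is the
empirical residual covariance with denominator $n-p$ (the correction for
estimated parameters is negligible at thousands of samples per window).
A multivariate Ljung–Box portmanteau diagnostic
(`portmanteau_whiteness()`, $m^2(h-p)$ degrees of freedom for maximum
lag $h$) supports the choice of window length and model order: residual
whiteness indicates the model has absorbed the temporal structure.

In the frequency domain, with $\bar A_0 = I$ and $\bar A_k = -A_k$,

$$A(f) = \sum_{k=0}^{p} \bar A_k e^{-i 2\pi f k / f_s}, \qquad
  H(f) = A(f)^{-1}, \qquad S(f) = H(f)\, C\, H(f)^{H}.$$

$S(f)$ is the *model-based* spectral matrix. Two directed measures are
computed for every ordered channel pair (column $j$ = source, row $i$ =
sink):

* **GPDC** (generalized partial directed coherence, Baccalá et al. 2007):
  $\mathrm{GPDC}_{ij}(f) = \dfrac{|A_{ij}(f)|/\sqrt{C_{ii}}}
  {\sqrt{\sum_k |A_{kj}(f)|^2 / C_{kk}}}$ — noise-weighted outflow from
  $j$, with unit column norm $\sum_i \mathrm{GPDC}_{ij}^2(f) = 1$.
* **dDTF** (direct directed transfer function, Korzeniewska et al. 2003):
  the product of the full-frequency DTF
  $\eta_{ij}(f)^2 = |H_{ij}(f)|^2 \big/ \sum_{f'}\sum_k |H_{ik}(f')|^2$
  and the partial coherence
  $\chi_{ij}(f)^2 = |S^{-1}_{ij}(f)|^2 / (S^{-1}_{ii}(f) S^{-1}_{jj}(f))$,
  which suppresses indirect (mediated) flows into sink $i$.

Both are averaged entrywise over the canonical bands — delta 1–4, theta
4–8, alpha 8–12, beta 12–30, gamma 30–50 Hz — on a 1 Hz grid with
*inclusive* endpoints, so shared edges (4, 8, 12 Hz) contribute to both
adjacent bands. Feature names are `metric/band/src->dst`; self-pairs are
excluded, giving $2 \times 5 \times m(m-1)$ features per window — 3420
for the 19-channel 10–20 montage.

Conventions worth stating because the literature is inconsistent: we use
the standard column-source orientation for both measures internally and
expose only the unambiguous `src->dst` names; the diagonal is zeroed
(self-influence carries no pairwise information); the metric value
itself (not its square) is band-averaged; and the frequency argument
carries the sampling rate ($e^{-i2\pi f k/f_s}$) so band edges are in
physical Hz.

## The classifier and its interpretability

Windows are classified by a bagged ensemble of Gini decision trees
(`fit_forest()`). Each of $T = 200$ trees is grown on a bootstrap
resample of the training rows and — deliberately — on a random subset of
$\lfloor P \cdot N \rfloor$ features drawn once **per tree** ($P = 2.5\%$,
i.e. 85 of 3420), not per split as in the more common random-forest
variant. Splits minimize the child-size-weighted Gini impurity
$G = p_A(1-p_A) + p_B(1-p_B)$, scanning thresholds at midpoints of
consecutive sorted values, with a deterministic tie-break (lowest
feature index, then lowest threshold) for reproducibility; growth stops
when a child would hold fewer than $M = 10$ samples. The ensemble score
is the mean leaf class-1 fraction, which supports ROC analysis.

Interpretability comes from the normalized Gini importance: every
split's impurity decrease, weighted by the fraction of the tree's
samples reaching that node, is credited to the split feature; the
per-feature totals are normalized to sum to 1. Across cross-validation
folds the package reports both the **minimum** importance (was the
feature *consistently* used?) and the **mean** (how much overall?), with
descending top-$k$ rankings of each.

## Cross-validation designs

Two 7-fold designs (K configurable) answer different questions:

* `subject_unaware_folds()` splits *within* each subject (contiguous
  temporal blocks by default, shuffling optional) and pools the k-th
  chunks. Every test subject has been seen during training — the
  optimistic regime.
* `leave_p_subjects_out_folds()` partitions *subjects* into
  class-balanced groups; test subjects are never seen during training —
  the clinically realistic regime for screening a new patient.

The gap between the two quantifies subject-level nuisance variation.
Fold AUCs use the midrank Mann–Whitney convention (equal to the
trapezoidal area under the tie-grouped ROC polygon) and are aggregated
by an unweighted mean over folds.

## The synthetic cohort generator

Because a real cohort cannot ship with the package, `cohort_spec()` and
`generate_cohort()` build two-class cohorts from ground-truth MVAR
models: a base coupling list shared by both classes, class-effect
couplings present only in patients, per-subject multiplicative
coefficient jitter (heterogeneity), and per-subject stationary
simulation (stability checked, jitter redrawn up to 100 times). Band
localization uses damped AR(2) resonator blocks: a pole pair at radius
$\rho$ whose angle is set so the *spectral peak* (not the pole angle)
lands on the requested frequency — the peak of an AR(2) spectrum sits at
$\cos\omega_p = \cos\theta\,(1+\rho^2)/(2\rho)$, and this
parameterization keeps the closed form testable.

The default validation scenario (`toy_cohort_spec()`) plants a theta
effect: all six channels (F3, F4, C3, C4, O1, O2) carry mild AR(1)
dynamics, O1 carries a shared 6 Hz resonator ($\rho = 0.95$), and
patients alone receive a lag-1 coupling O1→O2 with coefficient 0.15.
GPDC of the pair then peaks at theta because the source column's own
term $|A_{\mathrm{O1},\mathrm{O1}}(f)|$ dips at the resonance.

Three design choices here were genuinely open and deserve their
rationale:

* **Sampling rate 110 Hz** (not the 250 Hz of typical clinical EEG). At
  250 Hz a 6 Hz pole pair sits at angle $2\pi\cdot 6/250 \approx 0.15$
  rad, so close to $z=1$ that the delta band is amplified along with
  theta and the planted effect loses band specificity. At 110 Hz the
  angle (0.34 rad) separates theta from the DC region while the 50 Hz
  gamma edge stays below Nyquist (55 Hz). This mirrors a real
  limitation: a lag-5 MVAR at 250 Hz spans only 20 ms and localizes
  rhythms through its poles, not its numerator taps.
* **Coupling 0.15.** GPDC is a self-normalized ratio: scaling cancels,
  and a strong coupling saturates $\mathrm{GPDC} \to 1$ across *all*
  bands, destroying band-specific discriminability. 0.15 keeps the
  effect in the informative, non-saturated regime while still yielding
  unseen-subject AUC near 1 and planted-feature effect sizes well above
  Cohen's $d = 1$.
* **Nine minutes per subject** (nine 60 s windows). With only three
  windows per subject, cross-fold minimum importances are dominated by
  bootstrap noise — each of 300 features appears in only ~5 of 200 trees
  per fold. Nine windows stabilize the rankings at negligible cost
  (about 5 s per cohort end-to-end at this scale, and the full 20-seed
  recovery study in under two minutes).

A companion scenario, `heterogeneous_cohort_spec()`, reproduces the
seen- vs unseen-subject phenomenon: both classes share a flat O1→O2
coupling (0.25), patients add +0.2, and a large multiplicative jitter
(SD 0.4) makes subjects overlap across classes. Subject-unaware CV then
outscores leave-p-subjects-out by design, because within-subject
variation (estimation noise only) is much smaller than between-subject
variation (jitter). `null_cohort_spec()` removes the class effect
entirely for end-to-end null calibration; note that leave-subjects-out
AUC under the null is noisy at this cohort size and often dips *below*
0.5 — the familiar anti-learning artifact of subject-level CV with
clustered data — so null calibration is read from the across-seed mean.

What the generator does **not** emulate: volume conduction and common
reference (which induce instantaneous correlations EEG practitioners
must worry about), artifacts (blinks, muscle), nonstationarity within a
window, and 1/f background spectra. Passing tests on this generator
therefore validate the estimation and ranking machinery, not robustness
to real-world EEG contamination.

## Numerical choices and degenerate inputs

* MVAR fitting refuses segments shorter than $mp+1$ usable points and
  reports rank-deficient regressors (constant or duplicated channels)
  rather than silently regularizing.
* `spectral_stack()` requires $0 < f < f_s/2$ and names the offending
  frequency if $A(f)$ or $S(f)$ is singular.
* Band averages demand that every 1 Hz grid point of the band was
  actually evaluated; no silent interpolation.
* `best_split()` returns a no-split (and tree growth stops) for pure
  nodes, nodes below $2M$ samples, and nodes where no admissible split
  decreases impurity; a forest that never splits yields all-zero
  importances with a warning rather than an error.
* Forest, fold assignment, jitter and simulation all derive per-use
  sub-seeds from one master seed, and seeded helpers restore the
  caller's RNG state.
* Zero-phase filtering uses order-4 Butterworth designs per filter;
  measured stop-band attenuation of the forward–backward cascade at
  60 Hz is about 19 dB, and very high orders are avoided because the
  transfer-function form becomes numerically fragile.

## Problem sizes used in the shipped validation

The package's own test suite and acceptance script run entirely on the
synthetic generator at the scales above: 6 channels, 6+6 subjects, nine
60 s windows per subject, 300 features per window, 200-tree forests,
3-fold CV (with only six subjects per class, leave-2-per-class-out gives
three folds; subject-unaware CV uses the same K for comparability), and
20-seed replication for the stochastic claims. The 19-channel/3420
feature accounting is exercised structurally (name generation and
per-tree subset sizes) without simulating a 19-channel cohort.

## Known limitations

* Per-equation OLS is the only MVAR estimator; Yule–Walker/Vieira–Morf
  variants and regularized fits are out of scope.
* Inclusive band endpoints double-count the shared edges 4, 8, 12 Hz,
  and the gamma band's upper edge coincides with the default low-pass
  cutoff; both follow the feature definition rather than signal-
  processing optimality, and the model-based metrics remain defined
  there.
* The forest is binary-class only, and per-tree (not per-split) feature
  subsetting is intentional — it matches the ensemble this package
  implements, at some cost in tree decorrelation.
* EDF support covers the plain EDF layout (equal rates across retained
  signals, annotation channels dropped); EDF+ annotations and
  discontinuous records are not parsed.
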