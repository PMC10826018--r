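---
title: "Methods: fall-risk classification from trunk-sway posturography"
author: "swayrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fall-risk classification from trunk-sway posturography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Computerized posturography quantifies standing body sway and is a candidate
screening signal for fall risk in community-dwelling older adults. A lumbar
tracker records trunk displacement in the medial–lateral (M-L) and
anterior–posterior (A-P) directions under four stance conditions of
increasing difficulty — feet apart/together ("wide"/"narrow") crossed with
eyes open/closed (W-EO, W-EC, N-EO, N-EC) — with two 30-s trials per
condition, i.e. eight bi-axis trajectories per participant. From each
trial, 31 stabilogram parameters are computed; averaging the two trials per
condition and concatenating the four conditions yields 124 posturographic
features, complemented by five personal metrics (age, sex, height, weight,
BMI).

Two binary risk labels are studied: *criteria I*, any self-reported fall in
the previous year, and *criteria II*, a Timed-Up-and-Go (TUG) time of 10 s
or more. Both are imbalanced (roughly 23% and 31% positive). The package
implements the full analysis: signal conditioning, feature extraction,
wrapper feature selection by binary metaheuristics, imbalance-aware
classification, and Shapley-value explanation — plus a seeded synthetic
cohort generator, because no public dataset with this exact structure is
deposited.

## Signal conditioning

Trajectories are low-pass filtered with a fourth-order zero-phase
Butterworth filter at 5 Hz, realized as forward–backward filtering, so the
effective magnitude response is the squared single-pass response and the
net phase shift is zero. Note the attenuation arithmetic this implies: at
15 Hz the single-pass analog prototype gives $|H|^2 = 1/(1+3^8) \approx
1.5\times10^{-4}$, and the digital design (bilinear transform, frequency
warping) attenuates slightly more; the test suite checks the measured
attenuation against the digital transfer function evaluated at 15 Hz.

Edges are handled by odd-reflection padding (default 3 × filter order
samples) combined with steady-state initial filter conditions — past inputs
and outputs seeded with the first padded value — which removes start-up
transients even with a short pad. A transient at the $10^{-3}$ relative
level within ~1 s of each edge is inherent to any forward–backward
implementation; it is irrelevant for 30-s records.

Axes are demeaned *after* filtering, so all positional measures are taken
about the mean point of the filtered trajectory. Whether the original
recordings were demeaned or referenced to the first sample is a convention
choice; demeaning follows standard center-of-pressure practice, where the
distance measures are defined about the mean.

## The 31 stabilogram parameters

With demeaned axes $x$ (M-L), $y$ (A-P) and radial series
$r_i=\sqrt{x_i^2+y_i^2}$:

* **Distance** (× M-L, A-P, radius): mean distance (mean $|x|$; mean $r$),
  maximal distance, RMS distance, range (max − min per axis; maximal radius
  for the radial series — documented convention), and mean velocity (path
  length / duration; planar path length for the radial series).
* **Area**: 95% confidence ellipse area
  $2\pi F \sqrt{s_x^2 s_y^2 - s_{xy}^2}$ with $F = 3.00$, the large-sample
  $F(0.05; 2, n-2)$ (configurable). Degenerate covariance yields 0.
* **Hybrid**: sway area per second
  $\frac{1}{2T}\sum_i |y_{i+1}x_i - y_i x_{i+1}|$; mean frequency
  $\mathrm{MFREQ} = \mathrm{MVELO}/(2\pi\,\mathrm{MDIST})$ per axis and for
  the radial series (for a sinusoid this recovers its frequency, for a
  circular path the rotation rate); fractal dimension
  $\ln N / \ln(N d / L)$ with $L$ the planar path length and $d$ the
  maximal distance from the mean point (radius convention, default) or the
  maximal pairwise distance (diameter convention, configurable — under
  which a straight constant-speed traversal has FD exactly 1).
* **Frequency** (× M-L, A-P): from a Welch PSD — Hann window, linear
  detrend, 50% overlap, 8-s segments — integrated over 0.15–5 Hz: total
  power $\mu_0$, 50% and 95% power frequencies, centroid frequency
  $\sqrt{\mu_2/\mu_0}$ and frequency dispersion
  $\sqrt{1-\mu_1^2/(\mu_0\mu_2)}$ (0 for a line spectrum, approaching 1
  for broadband sway).

Segment length is 8 s rather than the more common 5 s: at 0.2 Hz
resolution the Hann leakage of a 1-Hz line already produces a dispersion
of ~0.13, blurring the line-spectrum limit; 0.125 Hz resolution keeps it
near 0.07 while still averaging ~6 segments on a 30-s record.

**Undefined-value policy.** Degenerate inputs (zero motion) give 0 for
magnitude measures and `NaN` for frequency ratios; rows containing flagged
values fail validation rather than silently propagating.

## Dataset assembly

The two trials of a condition are arithmetically averaged per parameter;
participants missing any condition (as happens with the hardest task,
N-EC) are excluded and logged. Columns are named
`<condition>__<parameter>` (`weo`, `wec`, `neo`, `nec`). Data are split
50/20/30 into train/validation/test, stratified on the active label by
largest-remainder allocation per class (215 rows give 107/43/65).
Features are min-max normalized to [0, 1] with the transform fitted on the
training split only; validation/test values are clipped into [0, 1].

## Wrapper feature selection

A feature mask $X^*$ over the 124 posturographic columns is scored by

$$\mathrm{fitness} = w_1\,\mathrm{GM} + w_2\,\mathrm{AUC} + w_3\,\lambda,
\qquad \lambda = 1 - |X^*|/|X|,$$

where GM $= \sqrt{\text{sensitivity}\times\text{specificity}}$ and AUC are
the mean 3-fold stratified cross-validated scores of an inner Complement
Naive Bayes classifier on the training split, restricted to the masked
columns plus the personal metrics (which bypass selection and are always
appended). The weights default to (0.4, 0.4, 0.2): the classification
terms dominate and sparsity is a mild regularizer. The fold assignment is
fixed by the fitness seed, making fitness a deterministic function of the
mask — which is what allows brute-force verification of the optimizers.

Three population metaheuristics search the mask space, all operating on
continuous positions in $[0,1]^d$ mapped to bits through an S-shaped
transfer function ($\sigma(10(v-0.5))$, sampled), with empty masks
repaired to one random bit before scoring and a global best-so-far
(mask, fitness) tracked so histories are monotone:

* **Slime Mould Algorithm** — rank-dependent weights, the oscillatory
  approach/wrap behavior, and a shrinking oscillation branch. One
  deliberate adaptation: the original oscillation $vc \cdot X$ contracts
  toward the origin, which in the bit-probability cube is the empty mask;
  the oscillation here is centered on the best-so-far position. Without
  this, planted-feature recovery collapses (median 2/5 instead of 5/5 in
  the package's benchmark).
* **Harris Hawks Optimization** — energy-controlled switch between
  exploration and the four besiege modes, including Levy-flight rapid
  dives with greedy acceptance.
* **Artificial Bee Colony** — employed/onlooker/scout phases with greedy
  per-source selection. Neighbor moves perturb a random ~30% of dimensions
  (the modification rate of binary ABC variants); the classic
  one-dimension move is too slow on mask problems, measurably failing to
  reach the brute-force optimum within the package's budget.

Univariate filter baselines (mutual information on quantile-discretized
features; one-way ANOVA F) rank features against the label and keep the
top *k*; ties break by column name. The full-scale search setting is
population 100 × 100 epochs; tests and the acceptance script use reduced
settings (30 × 30 to 30 × 50, stated per run) chosen to keep the whole
suite at desk scale.

Fitness is computed by cross-validation on the training split only; the
validation split is reserved for model comparison and the test split for
reporting. Whether a held-out-split fitness would behave better is an open
design question; CV-on-train is the conservative, leakage-free default.

## Imbalance-aware classification

All classifiers consume the selected posturographic features plus the
personal metrics and expose a continuous positive-class score (hard labels
at 0.5):

* **Complement Naive Bayes** (Rennie et al.): parameters estimated from
  each class's complement with additive smoothing $\alpha = 1$; suited to
  imbalanced data. Note a structural property relevant to simulation
  design: CNB models the *relative profile* of feature mass across
  columns, so class shifts that move all features in the same direction
  are nearly invisible to it.
* **Easy Ensemble**: 9 AdaBoost learners (SAMME, weighted-CNB base), each
  trained on a balanced subset keeping all minority rows and undersampling
  the majority without replacement.
* **Balanced Bagging**: 9 CNB base estimators on balanced bootstraps
  (minority count drawn with replacement from each class), with features
  drawn with replacement.
* Traditional comparators: RBF-SVM (C = 1, scores = decision values),
  CART decision tree, and a one-hidden-layer (100 units) MLP. Fixed common
  defaults, logged; they serve only as comparators.

Evaluation reports the confusion counts, accuracy, sensitivity (recall),
specificity, GM, the rank-based AUC (equivalent to the trapezoidal area
under the ROC, ties handled) and the ROC points. Split-size rounding uses
largest remainder; the score threshold is 0.5.

## Shapley explanation

The value of a coalition is the interventional (background-substitution)
expectation of the model score: features in the coalition take the
explained instance's values, the rest keep the background row's values,
averaged over the background sample (training split, capped at 100 seeded
rows). `exact_shapley()` enumerates all $2^m$ coalitions (refused above
m = 12); `shap_values()` is a permutation estimator whose per-instance
attributions sum exactly to score − base value (local accuracy holds by
construction, per permutation telescoping). Features are ranked by mean
absolute attribution, ties by name. The explained model defaults to the
best (selection, classifier) pair by test AUC per criterion.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not tracker physics:

* **Personal metrics**: age ~ N(72, 7²) (weakly tied to the deficit), ~1/3
  male, sex-specific heights, BMI ~ N(24.8, 4.1²) with weight derived.
* **Latent balance deficit**: standard normal, hidden but exported for
  ground-truth tests.
* **TUG**: log-normal in a risk score correlated 0.8 with the deficit,
  thresholded so that P(TUG ≥ 10 s) equals the configured prevalence
  (default 30.7%) in distribution; median ~8.7 s.
* **Fall history**: driven by a risk score correlated only 0.55 with the
  deficit and further degraded by an independent-noise mixture (default
  probability 0.4; at 1.0 the label is pure noise). The fall label is
  deliberately noisier than the TUG label, so classification is expected
  to work better under criteria II — the package's central qualitative
  property.
* **Trajectories**: Gaussian white noise per axis (correlation 0.25),
  shaped by a 2nd-order 1.2-Hz low-pass so power sits below ~2 Hz, scaled
  to RMS = 4 mm × condition gain (1, 1.35, 1.8, 2.4 along
  W-EO < W-EC < N-EO < N-EC) × max(0.1, 1 + 0.8 × deficit) × log-normal
  trial jitter (σ = 0.1); A-P is 25% larger than M-L. The clamp at 0.1
  keeps amplitudes positive for very negative deficits. Sampling rate
  defaults to 90 Hz (typical tracker hardware); displacements are in mm.
  Amplitudes are calibrated to ordering and effect-size ratios only — no
  absolute agreement with any particular hardware is claimed, and no
  tracker noise/dropout is simulated.

A separate planted-feature generator builds feature tables with known
ground truth: 5 informative columns of 124, class-shifted by 1.25 SD with
alternating signs, at 30.7% prevalence. Alternating signs matter for two
reasons: they are the realistic pattern (a deficit raises distance and
area measures while moving frequency measures in both directions), and
same-direction shifts are structurally invisible to Complement NB (see
above). The 1.25 SD effect is calibrated so the informative set's
Bayes-level AUC is ≈ 0.94, i.e. realized performance after imperfect
selection lands in the 0.85–0.90 AUC regime reported for posturographic
classification of slow-TUG status.

## What passing tests do and do not show

The suite verifies the formulas against closed forms and independent
re-implementations (to 1e-9), the optimizers against brute-force optima on
an exhaustively enumerable 10-feature problem (≥ 8/10 seeds each), planted
recovery (median 5/5 informative features; selection + CNB test AUC
median ≥ 0.85 at n = 300), the imbalance property (Easy Ensemble recall
beats tree/SVM recall on 9:1 overlapping classes), the Shapley axioms and
the sampler-vs-oracle agreement, and a no-leakage instrumentation test
(perturbing non-training rows never changes the fitted normalizer or the
selected mask). Problem sizes in tests (e.g. n = 300 cohorts, 30 × 30
wrapper runs, 10-s trials where only bookkeeping is at stake) are the
package's chosen desk-scale settings.

What this does *not* show: that real trunk-sway data are shaped noise with
condition-independent spectra, that real effect sizes match the planted
1.25 SD, or that the selected features on real recordings would be stable
across cohorts. The synthetic generator has no postural control dynamics
(no intermittent corrections, no drift, no condition-dependent spectral
changes), so absolute classification numbers on it are a property of the
simulation, not a clinical claim.

## Known limitations

* Complement NB's profile-relative nature makes it insensitive to
  proportional class shifts; with strongly correlated features its
  probability outputs are poorly calibrated (scores remain usable for
  ranking/AUC).
* The metaheuristics implement the faithful core update rules, not every
  published operator variant; they are validated behaviorally (brute-force
  optimum, planted recovery) rather than line-by-line against reference
  implementations.
* Walking-aid use is generated but excluded from the default feature set
  (configurable), matching the default personal-metric list.
* `fall_risk_model()` fits one pipeline per call; no hyperparameter search
  beyond the documented defaults is performed, and probabilities are not
  calibrated.
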