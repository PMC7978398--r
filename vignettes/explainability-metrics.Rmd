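---
title: "Quantifying the explainability of PPG quality classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the explainability of PPG quality classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Convolutional classifiers for photoplethysmography (PPG) signal quality —
deciding whether a 30-second pulse waveform segment is artifact-free or
corrupted — routinely reach high accuracy, but accuracy alone says nothing
about *where* the model looks when it decides. When experts have marked the
onset and offset of every artifactual stretch, a model that truly recognizes
artifacts should concentrate its attention there. `ppgexplain` turns that
intuition into two global, quantitative metrics computed over a whole test
set, so that different models can be compared objectively rather than by
eyeballing individual saliency maps.

Throughout, a segment is a vector $x_i$ of $n$ samples (by default $n =
7201$: 30 s at 240 Hz with an inclusive endpoint), the expert annotation is
a binary mask $z_i$ with $z_{i,j} = 1$ inside annotated artifact, and the
model's attention $\hat z_i$ is a nonnegative per-sample vector derived
from a saliency map.

## From saliency to attention

Attention maps are the absolute values of a gradient-based attribution:

* **Integrated gradients**: $(x_j - b_j)\cdot$ the path-averaged gradient
  between a baseline $b$ and the input, which satisfies *completeness*
  ($\sum_j a_j \approx F(x) - F(b)$).
* **Guided backpropagation**: a backward pass through the network in which
  each ReLU zeroes both the entries whose forward pre-activation was
  negative and the entries whose incoming backward signal is negative; the
  resulting map is clamped at zero and is therefore already nonnegative.
* **Difference-from-reference** (DeepSHAP-style): expected gradients —
  integrated gradients averaged over a background of reference inputs —
  which satisfies summation-to-delta against the background mean output.
  We chose expected gradients over exact DeepLIFT multipliers because it
  honours the same summation contract through the generic
  gradient interface, whereas layer-wise multipliers would tie the
  attribution code to one architecture; no downstream metric depends on
  the difference.

For image-input (2D) models the attribution matrix is reduced to a
per-sample profile by taking the column maximum of the absolute values and
resampling to $n$ by nearest neighbour — absolute value first, then the
max, then the resize.

Two attribution choices are conventions, recorded here because no standard
exists for them: the integrated-gradients baseline defaults to the all-zero
signal, and the default reference background is 16 all-zero signals with
small Gaussian jitter (sd 0.01) under a fixed seed. Both are overridable,
and comparisons between models are only meaningful under a shared choice.

## The two metrics

**Congruence** is the proportion of attention mass inside the annotation,

$$\mathrm{Cong}(z_i, \hat z_i) = \frac{\sum_j z_{i,j}\,\hat z_{i,j}}
  {\sum_j \hat z_{i,j}},$$

averaged (unweighted) over the records of a dataset. It is scale-free and
ignores *coverage*: a model attending to one pixel inside the annotation
scores 1.

**Annotation Classification** measures coverage: attention scores are
thresholded to predict whether each unit of signal is annotated, the
threshold sweeping the sorted scores (tied scores cross together), and the
AUROC of that sweep is the metric. The three variants differ in the unit:

* *Pixel* — every sample is a unit, scored by its own attention;
* *Sectional* — each maximal run of constant annotation value is a unit,
  scored by its maximum attention;
* *Interval* — fixed 5-second tiles are units, scored by their maximum
  attention and labelled artifactual if they overlap any annotation.

The AUROC is computed as the Mann–Whitney statistic (ties counted half),
which is identical to the trapezoidal area under the threshold-sweep curve;
the package computes it both ways and the tests pin their equality.

Units are pooled across the whole dataset into a single ROC rather than
averaged per record; pooling follows from the metrics being defined over a
whole test set, and a per-record average is available by applying the unit
builders record by record. Attention maps are not normalized before
pooling: congruence is scale-free by construction, and a per-record
rescaling would change pooled AUROCs in ways no part of the method
specifies.

Sectional AUROC carries a known bias: annotated sections are typically much
shorter than unannotated ones, and longer sections have larger maxima under
diffuse attention. The comparison report therefore prints the mean section
length per class next to the grid, and sectional values should be read with
that caveat.

Explainability metrics are computed on annotated (artifactual) records
only — they are undefined without an annotation. Records whose attention
mass is exactly zero have undefined congruence and are skipped with a
warning, but still contribute their zero-score units to the classification
variants.

## Edge cases and numerical choices

* Sample coordinates are 0-based with half-open `[start, end)` intervals
  everywhere; annotation times in seconds map to samples by
  `floor(t * fs)`. Abutting intervals never double-count a sample, and
  overlapping annotation intervals are rejected rather than merged so that
  annotation-file errors surface immediately.
* Interval tiling: a segment of duration $(n-1)/f_s$ is cut into
  $\lceil (n-1)/L \rceil$ tiles of $L$ samples; a shorter final remainder
  is kept as its own tile, and the inclusive endpoint sample joins the last
  tile — so the default 30 s geometry yields exactly six 5-second
  intervals.
* Integrated gradients uses midpoint sampling of the path. For
  ReLU-family networks the path gradient is piecewise constant, so the
  remaining quadrature error sits in the few panels where the activation
  pattern changes; those panels are detected (the boundary gradient agrees
  with one side) and the jump located by bisection, after which
  completeness holds to ~1e-6 relative at 512 steps. Smooth integrands
  (e.g. through a sigmoid head) are left to the midpoint rule.
* AUROC requires both classes among the pooled units; a single-class
  collection raises a degenerate-AUROC error, and
  `compare_models()` flags the affected cell and marks the grid
  incomplete instead of silently dropping it.
* A guided map can be identically zero — for instance when an untrained
  head has all-negative weights, every backward signal is clipped. The
  congruence of such a record is undefined by the formula above, and the
  skip-with-warning rule applies.

## The classifier fixture

The metrics only need a differentiable model exposing a scalar output and
input gradients (`model_output()` / `model_input_gradient()`). The
package ships a compact 1D residual CNN — stem convolution, average
pooling, residual blocks of two convolutions with a skip connection,
global average pooling, sigmoid head — with hand-written forward and
backward passes (Rcpp convolutions), because guided backpropagation needs
control of the ReLU backward rule. The training protocol follows the
conventional recipe: Glorot-uniform initialization, 80-tap kernels, binary
cross-entropy, Adam at 1e-4, 50 epochs, and selection of the epoch with
the best validation accuracy. Two details the protocol leaves open are
fixed here: the validation set is a seeded stratified 80/20 split, and
"best performance" means highest validation accuracy with ties broken by
the earliest epoch. The positive class is *artifact-free*; artifactual
records are the negative class, so NPV and specificity are the rates that
describe artifact detection. That full-scale recipe is sized for
tens of thousands of records; the desk-scale runs in the tests and
examples keep the architecture (fewer, narrower blocks) and loss but use
a larger step (1e-3 to 1e-2) for a few epochs, which reaches clean
separation on the easy synthetic task in minutes on one CPU.

## What the synthetic data does and does not show

`simulate_clean_ppg()` produces a quasi-periodic two-Gaussian beat
(systolic bump plus delayed dicrotic bump), beat-period jitter, and low
respiratory-band baseline wander. `inject_artifacts()` overwrites
randomly placed, non-overlapping episodes (Gaussian noise, flatline,
spike bursts, or saturation; default two episodes of 2–8 s at three
times the clean signal's standard deviation — strong enough that a small
CNN separates the classes within minutes, which is what an end-to-end
fixture needs) and returns the exact ground-truth intervals.
`synthetic_attention()` constructs attention maps whose congruence is
known by construction — exactly the target for the uniform profile,
fluctuating around it for the randomized one — which is what makes the
metric pipeline testable without any recorded data.

These generators validate the *metrics*, not any clinical claim: the
morphology is a plausibility device, artifact boundaries are exact whereas
human annotations are approximate, and a model that excels on this
synthetic task has been shown only to detect gross injected corruption.
Results on recorded PPG with expert annotations are a separate question
that the package's I/O (`read_ppg_dataset()`) lets you ask, not one the
tests answer.

## The comparison and correlation drivers

`compare_models()` fills the model × saliency-method grid of all four
metrics — the shape in which such comparisons are reported.
`summarize_differences()` reduces a two-model grid to its headline
numbers: the mean congruence difference, the mean annotation-classification
difference over the nine method × variant cells, per-variant means over
both models, and each model's mean congruence.

`explainability_performance_study()` probes whether explainability just
restates accuracy: it trains models on stratified fractions of the
training data (defaults 5–50%, five models each, i.e. 25 models) to induce
a spread of test accuracies, then correlates each explainability metric
with accuracy, NPV, and specificity across models (Pearson r, two-sided
p). Because six pairs are tested, the report carries a Bonferroni
column at $\alpha/6 \approx 0.008$. The saliency method for the study is
configurable; integrated gradients is the default in the examples because
its maps are never identically zero, while guided maps can vanish on
badly-trained models (which the study would then exclude with a warning).

Problem sizes in the shipped tests and acceptance script are chosen for a
single CPU: the end-to-end run trains on 80 records of the default
30 s / 240 Hz geometry for 8 epochs, and the correlation study
demonstration uses fractions {0.2, 0.5} with two repetitions on
30 s / 80 Hz records — large enough to exercise every code path, small
enough to finish in minutes. The study's correlations at that size are
illustrative of the report's shape, not estimates of any population value.

## Known limitations

* The attribution baselines/backgrounds are conventions; absolute
  congruence values depend on them, so only comparisons under a shared
  configuration are meaningful.
* Sectional AUROC inherits the section-length bias described above.
* The pooled-units choice makes records with many annotated samples weigh
  more in pixel AUROC than in congruence, which averages per record.
* The CNN fixture is deliberately small; it demonstrates the metric
  pipeline, not state-of-the-art quality classification.
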