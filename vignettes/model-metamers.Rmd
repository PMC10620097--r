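---
title: "Model metamers: synthesis, certification, and model-brain comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model metamers: synthesis, certification, and model-brain comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metamerlab)
```

## The idea

Any staged sensory model — a deep network, a filterbank cascade, a toy
convolutional stack — maps a stimulus through a sequence of intermediate
representations. Each stage discards some stimulus information; the set of
inputs mapped to (approximately) the same activations is the stage's
*invariance class*. A **model metamer** is a synthetic stimulus constructed to
sit in the same invariance class as a natural reference: its activations at a
chosen stage match the reference's, while nothing else about it is
constrained. If the model's invariances mirror those of an observer
(biological or artificial), the metamer should remain recognizable to that
observer; if they diverge, the metamer will look or sound like noise to
everyone but the generating model. metamerlab implements the full workflow:
synthesis, certification, behavioral and cross-model comparison, and
voxel-level encoding analyses, with a self-contained toy-model zoo so every
step is runnable and testable without external checkpoints.

## The staged-model contract

A `staged_model` is an ordered list of named stages. Every stage name is a
*cut point*: the model output depends on the input only through that stage's
activations, and evaluating the same input twice yields identical
activations. Residual-style blocks would expose only their merge points;
stages sit after nonlinearities (`conv1_relu`, `fc_relu`, ...), since those
are the representations downstream computation actually consumes. Model
preprocessing (channel normalization for images, the filterbank front end for
audio) is a stage inside the differentiable graph, so its gradients
participate in synthesis.

No automatic-differentiation framework is assumed: layers (dense,
convolution, average pooling, normalization, FIR filterbank) carry
hand-derived adjoints, and the test suite checks every path against central
finite differences. The toy zoo provides:

* a 16x16 grayscale image model — normalization, two conv+ReLU stages with
  average pooling, a dense ReLU stage, and a linear classifier;
* an audio model — a fixed cochleagram front end (32 windowed-sinc bandpass
  channels, envelope extraction, temporal downsampling, compressive power
  0.3) followed by the same convolutional stack.

The `briefly_trained` variant is fit by SGD on parametric stimulus sets
(disks, squares, crosses, stripes for images; tones, chirps, AM noise for
audio) until held-out accuracy exceeds 80–90%; `random_weights` leaves the
initialization untouched. Audio defaults to 20 kHz sampling with 0.2-s
tokens; the front end's channel count (32) and compression exponent (0.3) are
free design choices recorded in the layer parameters — the cochleagram here
is deliberately simplified, not a model of the periphery.

## Synthesis

Given a reference signal and a stage, synthesis minimizes the normalized
activation distance

$$\mathcal{L} = \frac{\lVert A - A' \rVert}{\lVert A \rVert},$$

where $A$ are the reference activations and $A'$ the candidate's, by gradient
descent **on the input signal** with the model weights frozen. The defaults
follow the standard recipe:

| parameter | default | meaning |
|---|---|---|
| `total_steps` | 24,000 | gradient steps |
| `eta_init` | 1.0 | L2 bound on each step |
| `decay_factor` / `decay_interval` | 0.5 / 3,000 | eta halves every 3,000 steps |
| image init | N(0.5, 0.05) | i.i.d. start near mid-gray |
| audio init | N(0, 1e-7) | near-silent start |
| `step_rule` | `rescale_always` | every step has norm exactly eta |
| `relu_override` | `TRUE` | see below |

Each update is $\Delta = -g \cdot \eta / \lVert g \rVert$. The method
prescribes a *maximum* step norm; because no separate inner learning rate is
given, the natural reading is to take the raw gradient direction and rescale
it to the bound, which `rescale_always` implements (a `clamp_only` rule, which
only shrinks oversized steps, is available). The unsquared norm ratio is the
default loss; a squared variant is a flag.

**ReLU handling.** Starting from a near-constant initialization, a matched
ReLU stage emits mostly zeros, and the zero derivative on the negative side
stalls the optimization. When the matched stage ends in a rectifier,
`relu_override = TRUE` propagates gradients through *that one rectifier* as
identity during synthesis; all other rectifiers keep their usual gradient.
This changes only the optimizer's search direction, never the forward
computation being matched.

**Regularized preset.** `synthesis_config(regularized = TRUE)` reproduces the
natural-image-prior variant: objective
$\lVert A - A'\rVert / \lVert A'\rVert + \lambda_\alpha R_\alpha(x) +
\lambda_{TV} R_{TV}(x)$ with $R_\alpha$ the 6-norm and $R_{TV}$ the total
variation of the mean-subtracted, model-normalized signal,
$\lambda_\alpha = 0.005$, $\lambda_{TV}$ in 1x/10x/100x tiers of 5e-6, a
16x larger initial step size, and clipping of images to [0, 1] after each
step. TV boundary terms whose neighbor falls outside the image are omitted
(the sum is otherwise undefined at edges); the mean subtraction inside
$R_{TV}$ is algebraically inert but retained for fidelity to the printed
form, and the regularizers are evaluated on the model-normalized signal with
the affine normalization chained into their gradients.

## Certification

Gradient descent approaches but never exactly reaches the reference
activations, so a candidate must earn the label "metamer". Three match
metrics are computed at the matched stage: Spearman rho (average ranks for
ties), squared Pearson correlation, and

$$\mathrm{SNR_{dB}} = 10 \log_{10} \frac{\sum x^2}{\sum (x-y)^2}.$$

Each must land *outside* a null distribution of the same metrics computed
between random pairs of natural stimuli (distinct indices, uniformly
resampled pairs; 1,000,000 pairs at full scale, 10^3–10^4 in tests). "Outside"
defaults to strictly above the null maximum — the most conservative reading —
with a quantile rule available. An exact match (infinite SNR) always passes.
Additionally the model must assign the candidate the same classifier label as
its reference. The verdict is the conjunction; failures are flagged for
exclusion.

Low-dimensional stages need care: with a 4-class logits stage, random
same-class natural pairs saturate Spearman rho at exactly 1.0, so no
candidate can strictly exceed the null maximum. This is a degeneracy of rank
metrics at small dimension, not of the candidate; for such stages the
`metric_subset = "snr_db"` mode carries the decision, mirroring the
established practice of SNR-only criteria for low-dimensional models.

On toy models the certified candidates behave exactly as the theory says:
early-stage metamers are nearly pixel-identical to their references (little
invariance has accumulated), while final-stage metamers keep the model's
label at signal-space correlations below 0.2.

## Cross-model transfer

`cross_model_recognition()` presents one model's metamers to any other
recognition model; `aggregate_transfer()` averages accuracy per stage over a
group of generation models within each recognition model (self cells —
recognition model equals generation model — are *missing*, never zero) and
then across recognition models, with s.e.m. across recognition models.
`transfer_permutation_test()` compares two generation-model groups: the
statistic is the difference of group means after averaging across stages and
recognition models; the null permutes generation-model labels independently
within each recognition model, moving whole accuracy curves (missing cells
travel with their curve and stay missing in the averages). The default
p-value convention is $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 +
n_{perm})$, which can never reach zero; the alternative convention
$1 - \mathrm{rank}/n_{perm}$ is provided (clamped at $1/n_{perm}$) because
prose descriptions of rank-based permutation p-values are ambiguous about
rank direction.

## Behavioral statistics

The unit of analysis is proportion correct per participant x condition; model
observers enter as pseudo-participants, one per matched human stimulus set.
`mixed_anova_permutation()` computes F from the standard split-plot
sums-of-squares decomposition (between factor: observer type; within factor:
stage) or a one-way repeated-measures layout, and assesses significance by
permutation: observer labels across participants for main effects; observer
labels and per-participant condition labels independently for interactions.
The F computation is verified against both `stats::aov()` with an error
stratum and a from-scratch hand computation.

`confusion_split_half()` measures error-pattern reliability: 1,000 random
participant halvings, row-normalized confusion matrices per half, Spearman
correlation over cells (diagonal included by default; an off-diagonal mode
exists since the choice is not standardized), compared per split against a
globally response-shuffled version, with
$p = (1 + n_{overlap})/n_{splits}$. With an odd participant count the extra
participant joins a random half. Note this procedure is *structurally
conservative*: under a true null the per-split true-minus-shuffled difference
is symmetric around zero and the splits share one dataset, so p concentrates
near 0.5 rather than distributing uniformly — it can under-reject but not
over-reject (the package's calibration suite measures exactly this).

`per_stimulus_reliability()` correlates per-stimulus proportions correct
across participant halves, using exactly `min_trials` (default 4) subsampled
trials per stimulus per half and excluding stimuli below the minimum from
that split, so that no stimulus exerts more influence than another.
`extreme_item_consistency()` selects the k most and least recognizable
stimuli on one half and evaluates the difference on the other, reporting the
proportion of splits with a positive held-out difference and its complement
as p.

## Encoding and representational similarity

`corrected_variance_pipeline()` implements noise-ceiling-corrected voxel-wise
encoding. Per train/test split of the stimuli (83/82 proportions, scaling as
about 50.3%/49.7% for other stimulus counts; 10 splits): features are
mean-centered on the training set; a per-voxel ridge regression is fit to
scan-averaged responses with the penalty chosen by leave-one-out
cross-validation over 81 log-spaced values ($10^{-40}$ to $10^{40}$); the
closed-form LOO errors (via SVD) provably equal explicit refits on the
centered data, and centering happens once per split rather than per fold
(the same convention as scikit-learn's efficient RidgeCV). Test performance
$r^2$ is corrected as

$$r^{2*} = \frac{r^2}{r'_v \, r'_{\hat v}},$$

where the voxel reliability $r'_v$ is the median Spearman-Brown-corrected
(n = 3) Pearson correlation between scan pairs on the training stimuli, and
the prediction reliability $r'_{\hat v}$ is the median corrected correlation
between per-scan-fit predictions of the test stimuli. Both are floored at the
one-tailed P < 0.05 critical Pearson correlation for their sample sizes —
0.182 at n = 83 and 0.183 at n = 82 — recomputed from the actual split sizes
rather than hard-coded, so the floors adapt when stimulus counts differ.
Degenerate reliability correlations (undefined or -1, possible when a huge
penalty flattens predictions) carry no information and fall through to the
floor. The per-voxel median over splits is reported.

`best_stage_cross_validated()` picks each participant's evaluation stage from
the *other* participants' per-stage summaries, so selection and evaluation
never share data; the modal chosen stage is reported for downstream
comparisons. `compute_rdm()` z-scores each unit across stimuli (the axis is a
config flag; the alternative is per stimulus across units) and computes
1 - Pearson r between stimulus patterns; `rdm_similarity_cv()` selects the
best stage on train-sound RDMs and scores Spearman rho on held-out test-sound
RDM upper triangles, with a leave-one-participant-out ceiling.

## Synthetic ground truth

`simulate_observers()` generates trial tables where a trial is correct with
probability $\mathrm{logistic}(\mathrm{logit}(p_c) + \epsilon_s)$ — item
effects $\epsilon_s$ are Gaussian on the logit scale (a simple, controllable
knob for reliability analyses) — and errors follow a row-stochastic confusion
kernel over wrong classes. `simulate_voxel_responses()` builds voxels as
sparse nonnegative linear readouts of a known stage's time-averaged features
(nonnegativity keeps the generating stage identifiable, mimicking pooling-like
readouts), scaled to unit variance, with i.i.d. per-scan noise, so the
expected inter-scan correlation is $1/(1 + \sigma^2_{noise})$. Everything is
exactly reproducible from (spec, seed).

What the simulations do *not* emulate: fMRI noise spectra and spatial
correlations, human lapses and attention drift, realistic class confusions.
Passing parameter-recovery tests therefore demonstrates the correctness of
the estimators under their own assumptions, not their robustness to real
measurement pathologies.

## Numerical choices and degenerate inputs

* Norm-ratio gradients at an exact match ($\lVert A - A'\rVert = 0$) are
  defined as zero; synthesis diverging to non-finite values raises an error
  carrying the partial trace.
* The filterbank's compressive power-law derivative is clamped near zero
  envelope ($\max(e, 10^{-8})^{-0.7}$) so silent channels do not produce
  infinite gradients; the forward pass still maps silence to exact zeros.
* Filter bandwidths are proportional (18% of center frequency) with a 40-Hz
  floor so the lowest channels stay resolvable by a 101-tap FIR.
* Zero gradients leave the signal unchanged under either step rule; ties in
  extreme-item selection are broken randomly under the split's RNG.
* Null-distribution pairs with degenerate metrics (zero-variance activations)
  are resampled and counted in `n_degenerate`.

## Problem sizes used by the tests and the acceptance script

Full-scale defaults (24,000 steps, 10^6 null pairs, 1,000 splits, 10,000
permutations) are impractical for a test suite, so the package's own checks
run the same code at reduced sizes chosen to keep every conclusion
statistically meaningful: synthesis runs of 300–3,000 steps with the decay
interval scaled proportionally; null distributions of 10^2–3x10^3 pairs;
calibration suites of 500 replicates at 500 permutations; encoding recovery
with 80 stimuli, 12 voxels, 3 simulated participants, and 6 splits. The
acceptance script reports which size each number was computed at.

## Known limitations

* Toy models are small and grayscale/mono; nothing here loads external
  checkpoints, and conclusions about specific published architectures are out
  of scope.
* The cochleagram front end is a simplified stand-in (no adaptive gain, no
  realistic filter shapes or phase characteristics).
* The split-half reliability p-value is conservative by construction (see
  above); treat it as an upper bound on evidence against consistency, not a
  calibrated test.
* Momentum or Adam-style optimizers, adversarial training, and adversarial
  example generation are deliberately absent.
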