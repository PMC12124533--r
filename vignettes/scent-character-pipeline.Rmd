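---
title: "Debiased scent-character analysis of GC-MS chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Debiased scent-character analysis of GC-MS chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentpipe)
```

## The problem

Urinary volatile-organic-compound (VOC) profiling by GC-MS is a candidate
non-invasive screen for prostate cancer, but attempts to reduce
chromatograms to lists of named compounds have not generalized across
cohorts: the discriminative peaks found in one collection center rarely
discriminate in another. `scentpipe` takes the alternative route of
classifying the raw signal itself. Each sample is a time × m/z ion-count
matrix $I(t, m)$ (canonically ~7300 timesteps × 480 channels over a
41-minute run); the pipeline corrects it per sample, removes source-site
batch structure across samples, encodes the result as a fixed-size image,
and trains a convolutional classifier whose latent space is made
adversarially uninformative about the source site.

The central confound is that samples cluster by the clinic that collected
them, not by disease state. Any classifier trained naively can reach
inflated accuracy by reading the site, not the disease. The package
therefore treats debiasing as a first-class, *quantified* step: empirical
Bayes correction at the feature level, gradient-reversal training at the
representation level, and audits (k-means matched accuracy, PCA centroid
separation, a frozen-feature probe) that measure how much site signal
remains at each stage.

## Per-sample correction stack

`runPreprocess()` applies, in order:

1. **m/z binning** (`roundMz`). Raw channels are rounded half-up to
   integers and co-binned channels summed. Total ion count is conserved
   exactly; half-up is pinned so x.5 never depends on parity.
2. **Time segmentation** (`segmentTime`). `N = ceiling(T/Δt)` equal
   frames; the canonical 41 min at Δt = 1.5 gives 28 frames of ≈1.46 min.
   Local frames let the noise threshold adapt along the run.
3. **Quantile noise subtraction** (`quantileNoiseCorrect`). Within each
   (frame, m/z bin) cell the 15th percentile (sorted linear interpolation
   at rank $(n-1)q$; the convention is pinned by an oracle test) is
   subtracted and the result clamped at zero. The operation is idempotent
   and preserves the relative order of intensities within a cell.
4. **Baseline drift correction** (`baselineDriftCorrect`). Per channel, a
   degree-2 polynomial (configurable) is fitted by iterative peak
   stripping — refit, replace values above the fit by the fit, repeat to
   convergence — then subtracted and clamped. Degree 2 matches slow
   thermal/column drifts; a TIC-only mode exists because drift is often
   shared across channels. A channel whose fit fails is left unchanged
   with a warning rather than corrupted.
5. **Internal-standard normalization** (`mirexNormalize`). Mirex is spiked
   at constant concentration into every sample; its peak is located as the
   maximum-area contiguous TIC excursion inside 29.4–29.8 min and measured
   by trapezoidal integration. All intensities are scaled by
   `reference / area`, so detected samples end at identical Mirex area.
   Detection requires the area to exceed 5× the window's median-level
   area; below that the sample is declared Mirex-undetected (a documented
   failure mode of real runs) and `preprocessDataset()` applies the median
   scale factor of detected samples from the same source batch.

The numbered correction sequence (quantile before baseline) is the
default stage order; the workflow-figure enumeration (baseline before
quantile) is available by reordering `cfg$stages`, since the two sources
of the protocol disagree and the difference is empirically small on
synthetic data. Mirex area is measured after noise and baseline
correction, where the integration is not inflated by the floor.

## Empirical-Bayes source-batch correction

`fitEB()`/`applyEB()` operate on a samples × features matrix
(`segmentFeatures()`: per-(frame, m/z) aggregate intensities by default —
28 × M′ features that respect the assumption that batch effects are
stable across time within a frame; raw TIC timesteps optional). The model
follows the classical location/scale empirical-Bayes template with the
priors swapped: for batch $b$ and feature $g$,

$$x_{ibg} = \alpha_g + \gamma_{bg} + \delta_{bg}\,\varepsilon_{ibg},$$

with additive shifts $\gamma_{bg} \sim N(\mu_b, \sigma_b^2)$ and
multiplicative factors $\delta_{bg} \sim \Gamma(\text{shape}_b,
\text{rate}_b)$. Naive per-(batch, feature) estimates (batch mean minus
grand location; within-batch SD over pooled SD) are computed first; the
batch-level hyperparameters are then fitted across features by maximum
likelihood with method-of-moments starts, and the per-feature estimates
are shrunk toward them: the normal-normal posterior mean for
$\gamma^*_{bg}$ in closed form, and the posterior mean of $\delta_{bg}$ by
deterministic quadrature on a log grid, since a gamma prior on a normal
scale parameter is not conjugate. Correction is
$x^{adj} = (x - \alpha_g - \gamma^*_{bg})/\delta^*_{bg} + \alpha_g$, with
optional clamping at zero for count-like data.

One identifiability caveat is made explicit rather than hidden: an
additive shift common to *all* batches cannot be estimated from the data,
because the per-feature grand location absorbs it. `fitEB()` therefore
accepts known `grandLoc`/`grandScale` vectors (simulation truth, or an
external anchor such as a spike-in series); parameter-recovery tests use
this path. No batch is privileged as a reference.

Audits: `sourceClusteringAudit()` runs k-means (20 restarts, fixed seed)
and reports matched accuracy under the exact maximum-accuracy
cluster-to-label assignment (permutation search; the audit is defined for
the handful of sites a study has, not hundreds). `pcaAudit()` reports the
two-component scores and the between/within centroid distance ratio. On
the package's standard biased fixture the audit drops from ≈0.95 before
correction to ≈0.30 after — near the 1/4 chance level for four sites.

## Image encoding

`toHeatmapImage()` resamples a (windowed) chromatogram to exactly
256 × 256 pixels by area-weighted binning (time → columns, m/z → rows),
maps intensity by `log1p` followed by min-max scaling to 8 bits, and
colors through a fixed monotone lookup table, so pixel order never
inverts intensity order and identical input yields identical bytes.
Normalization is per-image by default; a dataset-level scale
(`global.norm`) is exposed because the choice decides whether absolute
intensity differences (including batch brightness) are visible to the
classifier. `toPeakProjectionImage()` renders the per-channel traces as
an oblique painter's-order silhouette — the "3D peaks" view — by pure
array arithmetic (no graphics device, hence byte-deterministic).
`tileZoomWindows()` emits one image per time frame (28 tiles on the
canonical grid) for zoomed-in analysis. `compressionRatio()` quantifies
the encoding loss: ~3.5M 32-bit values into a 256×256×3×8-bit image is a
≈71.2-fold compression.

## Domain-adversarial classifier

`trainAdversarial()` implements the tug-of-war objective
$\mathcal{L}_{total}(\theta, \lambda) = \mathcal{L}_0(\theta) -
\lambda\,\mathcal{L}_q(\theta)$, $\lambda \in [0, 1]$: a disease head
minimizes its cross-entropy $\mathcal{L}_0$, a source head minimizes
$\mathcal{L}_q$, and the shared backbone receives the source branch's
gradient negated and scaled by $\lambda$ (a gradient-reversal layer:
identity forward, $-\lambda$ backward). The identity
`ltotal = l0 - lambda * lq` holds exactly on every logged epoch, and the
reversal sign is validated against a finite-difference oracle in the test
suite.

Because no deep-learning runtime is a dependency, the network is
implemented directly in R with im2col convolutions: an average-pooling
stem (256 → 32 pixels), four 3×3 conv blocks (8, 12, 16, 16 channels,
ReLU, 2×2 average pooling), and a flattened final feature map as the
latent embedding. Design choices that matter and why:

* **Latent normalization** (`normalize = "center"`): per-feature mean
  subtraction plus a *single global* RMS scalar. Centering is what makes
  the linear heads trainable on these low-variance embeddings; using one
  scalar instead of per-feature variance division is deliberate — a
  per-feature normalizer re-amplifies exactly the directions the reversed
  gradient shrinks, so the adversary would only ever fool its current
  head instead of removing source information from the space that heads,
  probes and inference share. Batch-normalization and unit-sphere
  variants remain available for comparison.
* **Optimization**: Adam (lr 0.003) with per-branch gradient-norm
  clipping and light weight decay; the source head is clipped separately
  so that at $\lambda = 0$ it cannot perturb the backbone's update scale
  (a tested invariant). Extra head-only steps per minibatch keep both
  linear heads near-optimal for the current backbone — for the source
  head this is what makes reversal pressure meaningful. During training
  the adversarial feature gradient is norm-matched to the task gradient
  before the $-\lambda$ scaling (so $\lambda$ stays a relative strength
  and the tug-of-war cannot run away; the pure-reversal contract without
  this cap is what the finite-difference oracle validates), and the
  learning rate drops to 0.3× once the reversal activates — the
  representation forms during warmup, the adversarial phase fine-tunes.
* **Schedule** (`lambda_schedule = "warmup"`): task-only for the first
  third of training, linear ramp over the middle third, full strength
  after. Reversal from step one reliably prevents the disease task from
  ever forming at this scale.
* `backbone = "resnet18"` is accepted as a flag but raises an informative
  error: it would require an external pretrained runtime, and the bundled
  small CNN is the supported desk-scale backbone.

`residualBiasProbe()` is the quantitative residual-bias measure: freeze
the backbone, train a *fresh* source head (same linear form, zero init,
full-batch Adam, fixed epoch budget) on a stratified split of the latent
embeddings, and report held-out source accuracy. This mirrors the
diagnostic of re-training a network for additional epochs to hunt for the
source site after debiasing has been switched off.

### What the synthetic benchmark shows — and what it cannot

The motivating clinical chromatograms are not publicly deposited, so the
package ships a generator (`simConfig()`/`generateDataset()`) that
emulates the *statistical* structure the pipeline assumes: Gaussian peaks
with m/z fragment fingerprints, per-risk amplitude multipliers on six
signature peaks, per-site gamma multiplicative factors and normal
additive shifts, quadratic drift, a truncated-normal noise floor with
persistent per-channel stripe artifacts, and a Mirex peak with dropout.
Defaults are desk-scale (1000 × 64 grid; the full 7300 × 480 is one
argument away). Real effect sizes are unknown, so the generator's defaults
were chosen once to resemble the regime reported for multi-center urinary
volatilomics — a class signal learnable by an undebiased classifier (to
the ~80% accuracy range) and site structure strong enough to dominate
unsupervised clustering (~96% k-means source accuracy) — and are
documented here rather than revisited. The standard biased benchmark also
allocates risk classes unevenly across sites, as real multi-center
cohorts do (a collection site may contribute almost exclusively
cancer-positive samples), which is precisely the condition under which an
undebiased classifier learns the site shortcut.

Two phenomena observed on this benchmark deserve honesty. First, with
class-correlated bias, source and disease information overlap: a probe
can recover the site partly *from legitimate class information*, which
places a floor (~0.5 for the default allocation) under the achievable
probe accuracy no matter how well the adversary works. Second, even with
strong reversal the probe rarely falls to chance — residual nonlinear
site traces persist, matching the recurring empirical finding that
networks re-trained on debiased multi-center data can still identify the
collection site with high accuracy. Passing tests on this generator demonstrate the mechanics and
the direction of the trade-offs (accuracy falls as $\lambda$ rises on
biased data; the site audit collapses after empirical-Bayes correction);
they do not demonstrate clinical performance, instrument realism
(fragmentation chemistry and retention-time physics are not modelled), or
transfer to real multi-site cohorts.

## Evaluation

`makeFolds()` deals samples round-robin within each risk class after a
seeded shuffle: test sets partition the data with per-class counts within
one of proportionality (365 samples give ≈73-sample folds).
`confusionAndReport()` computes the confusion matrix (rows = truth),
per-class precision/recall/F1/support, macro averages, and accuracy, with
zero-denominator metrics reported as 0 under a flag.
`mergeTwoClass()` collapses LowRisk and HighRisk into PCa+ *on the same
predictions* (no second model is trained), so cross-risk confusions
vanish and merged accuracy can only improve. `crossValidate()` pools
confusion counts across folds before computing pooled metrics and also
reports per-fold accuracies, since pooled and mean-of-fold accuracy are
both defensible readings of a cross-validated figure.

## Numerical choices and degenerate inputs

* Quantile definition: type-7 (sorted linear interpolation at
  $(n-1)q$), pinned by a brute-force oracle test.
* Variance floor `1e-8` on per-feature pooled scale in `fitEB()`;
  `deltaStar` floored at `1e-6`.
* A segment that overlaps the run but contains no timesteps is a
  configuration error; trailing empty segments (run shorter than the
  grid) are ignored.
* All-zero channels skip baseline fitting; all-zero chromatograms encode
  to all-zero images; identical rows give PCA separation 0, not NaN.
* NaNs are treated as corruption and rejected by `validateDataset()`,
  never imputed.
* Every stochastic step (generator, folds, k-means, training, probe
  splits) takes an explicit seed and restores the caller's RNG state.

## Problem sizes used by the test suite

Module tests run on toy fixtures (hundreds of timesteps, ≤ 16 channels).
The benchmark tests use the desk-scale generator default (1000 × 64) with
~200 samples, 90–150 training epochs, and 3–5 seeds for median-based
comparisons; these sizes are the package's chosen desk-scale study
conditions and are stated here so that readers know what regime the
reported behaviour refers to.
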