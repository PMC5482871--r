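---
title: "Class-structure-constrained classification of histopathology images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-structure-constrained classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hiercls)
```

## The problem

Multi-class recognition of breast-tumour histopathology images is harder
than the benign/malignant decision: the eight tumour types (adenosis,
fibroadenoma, phyllodes tumor, tubular adenoma; ductal, lobular, mucinous
and papillary carcinoma) differ subtly, while images of one type vary
broadly in stain, contrast and appearance. A plain softmax classifier
ignores everything we know about how those eight labels relate: each
subclass belongs to exactly one superclass, and two sibling subclasses are
more alike than two tumours from different superclasses.

`hiercls` builds that prior knowledge into training. A convolutional
backbone maps each image to an l2-normalised embedding and to class
logits; the training objective combines

* the softmax cross-entropy
  $J = -\frac{1}{N}\sum_i \sum_j 1\{y_i = j\}\,\log p(y_i = j \mid x_i)$, and
* a hierarchical distance-constraint loss on quadruplets
  $(x, p^+, p^-, n)$ — an anchor, a same-subclass positive, a
  sibling-subclass positive and a cross-superclass negative. The ideal
  feature space satisfies, for margins $m_1 < m_2$,
  $$D(x, p^+) + m_1 < D(x, p^-) + m_2 < D(x, n),$$
  and the trainable relaxation is the two-term hinge
  $$E_t = \tfrac{1}{2N}\sum_i \max\{0,\ D(x_i,p_i^+) - D(x_i,p_i^-) + m_1 - m_2\}
        + \tfrac{1}{2N}\sum_i \max\{0,\ D(x_i,p_i^-) - D(x_i,n_i) + m_2\}.$$

The combined objective is $E = \lambda J + (1-\lambda) E_t$, optimised by
stochastic gradient descent with momentum.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 0.5 | weight of the softmax term; 0.5 is the value at which the joint objective performs best, and 0/1 are diagnostic boundary modes |
| $m_1$, $m_2$ | 0.2, 0.4 | margins of the tiered constraint; must satisfy $m_1 < m_2$. No canonical values exist for them, so the defaults were chosen once to be commensurate with distances between unit vectors (range $[0,2]$) |
| embedding dim $d$ | 64 | size of the normalised feature vector; unstated in the method's source, config-exposed |
| base_lr | 0.01 | SGD learning rate |
| momentum | 0.9 | standard default; the method's source states momentum SGD without a value |
| iterations | 5000 | nominal training budget; desk-scale tests use a few hundred steps |
| batch size | 32 | per-step mini-batch; unstated upstream, config-exposed |

Distances are plain (non-squared) Euclidean, measured **after** l2
normalisation of the embedding head output; a squared variant exists
behind a flag for ablation. The strict inequalities define
`constraint_satisfied()` (a diagnostic), while training always uses the
non-strict hinge — the operative objective.

## Quadruplet mining and batching

How the four-image inputs are selected is not prescribed by the method's
source, so the package makes the simplest reproducible choice: for every
anchor in the batch that has all three partner types present, one random
eligible partner combination is drawn per anchor (`per_anchor`
configurable), under a fixed seed. `hierarchy_balanced_batch()` composes
mini-batches so that mining cannot silently starve: it allocates the batch
evenly over subclasses and, if no subclass received two slots, moves one
slot so some subclass is represented twice alongside a sibling and an
opposite-superclass image. Batches that still admit no quadruplet (e.g. a
single-class stream) fall back to the $\lambda$-weighted softmax term for
that step rather than failing the run.

## Evaluation

Two recognition rates are reported, matching the conventions of
patient-grouped histopathology benchmarks: the patient-level rate (mean
over patients of each patient's correct fraction — every patient counts
equally) and the image-level rate (correct fraction over all images).
These differ exactly when patients contribute unequal image counts; the
image-level rate equals the image-count-weighted mean of patient scores,
an identity the tests verify. Cross-validated results are summarised as
mean ± sample (n−1) standard deviation across folds; the sd convention is
switchable but the sample form matches the usual ± table entries.

## Splitting, augmentation, leakage

Splits are **patient-wise**: a patient's images never straddle
train/validation/test. Global patient counts follow the fractions with
round-to-nearest (test takes the remainder) — e.g. 82 patients at
(0.50, 0.25, 0.25) give 41/20/21 — and are apportioned across subclasses
by largest remainder. The published 61/21 subject split membership of the
reference dataset is not public, so seeded stratified splitting is the
reproducible substitute; numeric parity with any particular historical
fold assignment is not attainable and not attempted. The default
fractions put half the patients in training; the 25/25 split of the rest
is this package's choice, consistent with a 61 train+validation / 21 test
partition of 82 subjects.

Augmentation applies four operators on $[0,1]$ intensities — additive
intensity shift in ±0.1, rotation in ±90°, horizontal/vertical flips,
integer translation in ±20 px — and a "random combination" mode that
includes each operator independently with probability ½, composing in the
fixed order intensity → rotation → flip → translation (fixed order keeps
runs reproducible). Rotation resamples bilinearly; rotation and
translation fill exposed pixels by mirror reflection (the fill policy is
unstated upstream; reflection avoids introducing out-of-gamut constants).
The intensity shift is additive by default, with a multiplicative variant
behind a flag.

Oversampling balances classes **within each magnification** (count tables
of the reference dataset are stratified that way): the target is the
largest class count at that magnification, each minority source image
receives $\lceil \text{target}/\text{count} \rceil - 1$ augmented copies,
and a trim list drops one copy from just enough sources to hit the target
exactly. Augmentation is legal on the training split only;
`materialize_augmented_set()` refuses plans that do not match the training
split's counts, and `audit_no_leakage()` fails loudly if any augmented
image stems from a validation or test patient.

## The synthetic world

Because the reference dataset cannot be shipped, the package generates a
BreaKHis-shaped synthetic substitute: 2 superclasses × 4 subclasses,
patients grouped under one subclass each, images per patient at chosen
magnification factors, written as PPM files in the same folder hierarchy.
Each image is

* a base colour field whose red/blue channel means encode the superclass
  (peak-to-peak shift `superclass_effect` = 0.25),
* plus an oriented sinusoid whose spatial frequency and orientation encode
  the subclass (amplitude `subclass_effect` = 0.15; frequencies step by
  ×1.7 within a superclass, the second superclass is offset by ×1.3 and
  22.5°, so all eight signatures are distinct),
* plus a per-patient colour offset (sd `patient_effect` = 0.04) shared by
  all of a patient's images,
* plus i.i.d. Gaussian pixel noise (sd 0.05), clipped to $[0,1]$.

Magnification is simulated by scaling the texture frequency by
$\sqrt{40/\text{mag}}$ (higher magnification → coarser structure).
Defaults (4 patients/subclass, 6 images/patient, 64×64, 40X only) were
fixed a priori as a desk-scale regime in which the class structure is
present but must be learned: subclass information lives only in texture,
superclass information only in colour, and the constraint
`subclass_effect < superclass_effect` encodes that subclass differences
are the subtle ones. By construction the pairwise-distance ordering
same-subclass < same-superclass < cross-superclass holds in expectation —
precisely the structure the quadruplet constraint is designed to enforce —
so the generator is a ground-truth testbed for the loss.
`expected_separability()` verifies the ordering by Monte Carlo on simple
image statistics (channel means, up-weighted ×2 so their ~0.3 dynamic
range is commensurate with unit-sum spectral energies; radial spectrum
peak; orientation-bin energies), and warns when the patient effect is
large enough that image-wise splits would leak identity.

What a green test does **not** establish: the synthetic images are
stationary sinusoids with Gaussian noise — no nuclei, no stain variation,
no spatial heterogeneity, no label noise — so passing the structure
recovery criterion demonstrates that the optimisation and the loss do what
they claim on data with a known hierarchy, not that any particular
accuracy transfers to real slides.

## Backbone and numerical choices

The backbone is deliberately small (the 22-layer inception-style basis
network and ImageNet transfer learning used at full scale are out of
scope): by default three conv blocks — 5×5/8/stride 2, 3×3/16, 3×3/32 —
each ReLU-activated, 3×3 stride-2 max pooling between blocks, a global
mean pool, a linear embedding head (l2-normalised for the distance loss)
and a linear classifier head. Everything is implemented with im2col
convolutions on BLAS matrix products; backward passes scatter through
precomputed inverse index maps, and the first layer skips its input
gradient entirely.

Numerical/design decisions made where the design was genuinely open:

* **Initialisation.** The fixed-sd Gaussian scheme (0.01 everywhere,
  1e-4 in the last conv block) that large transfer-learned nets use
  stalls a from-scratch desk-scale net: a 1e-4 final layer emits
  near-zero embeddings whose normalisation then amplifies gradient noise.
  The package defaults to He-scaled Gaussian init
  ($\sigma = \sqrt{2/\text{fan-in}}$) and keeps the fixed-sd scheme
  available via `backbone_config(init = "fixed")`.
* **Input centring.** Images are centred per image and channel, so a
  constant image maps to the zero tensor and no dataset statistics need to
  be stored with the checkpoint; this replaces a stored training-split
  mean while providing the same train/test consistency.
* **Classifier input.** Logits are computed from the *unnormalised*
  embedding; only the distance loss sees the normalised copy. Normalising
  before the classifier would cap logit magnitudes and floor the
  attainable cross-entropy.
* **Normalisation epsilon** 1e-12 under the l2 norm; distance gradients
  use the zero subgradient at $D = 0$.
* **Hinge boundary.** `constraint_satisfied()` evaluates the strict
  chain; the loss uses $\max\{0,\cdot\}$, zero on the closed region.
* **Model selection.** One epoch = one nominal pass over the training
  manifest; after each epoch the validation image-level rate is computed
  and the best checkpoint kept (ties go to the later epoch).
* **Degenerate batches** warn and train on the $\lambda J$ term alone.
* **λ validation.** λ is accepted on the closed interval $[0,1]$; the
  open interval is the documented training regime and the endpoints exist
  for the softmax-only / hinge-only diagnostics.

## File formats

No image codec ships with this R stack, so images are read and written as
binary PPM (P6) — lossless for 8-bit RGB and implementable with
`readBin`/`writeBin` alone. Manifests are CSV
(`path,patient_id,subclass,magnification,split[,augmented_from]`),
configurations and metric reports are JSON, and checkpoints are RDS files
holding parameters, configs and the training log.

## Known limitations

* Pure-R convolutions are desk-scale: hundreds of 64×64 images, not
  thousands of high-resolution slides.
* The hinge term shapes the embedding space slowly relative to the
  cross-entropy; at short budgets the margin-satisfaction fraction keeps
  rising after classification accuracy has saturated.
* No stain normalisation, patch extraction, ROC analysis or significance
  testing — all out of scope.
* The synthetic generator's realism limits are listed above; its defaults
  are part of the stated experimental world and are not tuned to test
  outcomes.
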