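---
title: "Sparsity-guided multiple functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-guided multiple functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfcnet)
```

## The problem

Resting-state fMRI yields, for each subject, one mean BOLD time series per
brain parcel (ROI). A functional connectivity network (FCN) summarizes the
statistical dependence between parcels; group differences in such networks
carry diagnostic information for neuropsychiatric conditions. Two standard
constructions sit at opposite extremes. Pearson correlation measures each
pair in isolation, producing a dense network that confounds direct
interaction with shared influence from third regions. Sparse representation
(an L1-penalized regression of each region on all others) captures
conditional relationships and yields sparse networks, but its uniform
penalty shrinks genuinely strong couplings and can make the result look
arbitrary.

`smfcnet` implements a construction that combines the two, and a
classifier designed for stacks of such networks:

1. **Weighted sparse representation (WSR)** decides *which* edges exist.
2. **Pearson correlation** decides the *weight* of every surviving edge.
3. Sweeping the sparsity prior over a grid gives a stack of networks at
   multiple sparsity levels, which feed parallel branches of a
   convolutional classifier.

## Network construction

For subject-level time series $X \in \mathbb{R}^{L \times N}$ (columns
centered and scaled to unit Euclidean norm), the Pearson matrix is simply
$P = X^\top X$. The unit-norm convention is chosen deliberately: it is the
unique scaling under which this cross-product *is* the sample correlation,
so no separate normalization by $L$ or $L-1$ ever enters downstream
formulas.

WSR solves, per sparsity level $\lambda$,

$$\min_W \tfrac12 \lVert X - XW \rVert_F^2
  + \lambda \lVert C \odot W \rVert_1, \qquad W_{ii} = 0,$$

where the penalty weight $C_{ji} = \exp(-P_{ji}^2/\sigma)$ relaxes the
penalty on pairs that are strongly correlated marginally; $\sigma = 0.2$
by default. Each column is an independent weighted lasso whose dictionary
is $X$ with the target's own column zeroed (ruling out the trivial
self-representation). The binarized, OR-symmetrized support
$G^{\lambda}$ of $W^{\lambda}$ then masks the Pearson matrix:
$M^{\lambda} = G^{\lambda} \odot P$. Retained entries equal $P$
bit-exactly; only the topology comes from the sparse model. The default
grid is dyadic, $2^{-4}, 2^{-3}, \dots, 2^{5}$, giving $d = 10$ networks
whose density is non-increasing in $\lambda$.

### Solver

Each column problem is solved by ADMM with $\rho = 1$, zero
initialization, and the weighted soft-threshold $z$-update at thresholds
$\lambda C_{ji}/\rho$. We run to primal/dual tolerances
`abstol = 1e-8`, `reltol = 1e-6` (cap 1000 iterations) — tighter than the
customary `1e-6`/`1e-4` because the masking step consumes exact supports:
at looser tolerances the distance to the fully converged lasso solution is
of the same order as the `eps = 1e-5` support cutoff, which risks
misclassifying borderline coefficients. At these settings the solver
agrees with a coordinate-descent lasso run to `1e-10` within about
`5e-7`, at a cost of roughly five extra iterations per column. Columns
that hit the iteration cap return the best iterate and flag the fit.

Two conventions are worth recording because the underlying choices were
genuinely open:

* **Symmetrization.** $|W| + |W^\top|$ and the OR rule on supports give
  identical masks; only the support is consumed, so the OR rule is used.
* **Signed correlations** are kept in $M$ (masking multiplies by $P$, not
  $|P|$): anticorrelations are information, not noise.

### Hard-threshold alternative

For comparison, `hard_threshold_stack()` builds the classical
proportional-threshold ladder: for each percentage $q$ in
$\{10, 20, \dots, 90, 99\}$ it discards the $q\%$ weakest off-diagonal
entries by absolute value. Exactly
$\lfloor (1 - q/100) \cdot N(N{-}1)/2 \rfloor$ edge pairs survive, with
ties broken by (row, column) order so results are reproducible.

## The classifier

Each network in the stack enters its own two-layer **functional
connectivity convolution (FC-Conv)** branch:

* a $1 \times N$ *regional connectivity* kernel with $H$ channels
  (default 64) maps the $N \times N$ matrix to an $N \times 1 \times H$
  tensor — one weighted summary of each row, i.e. of each region's
  connection profile;
* an $N \times 1$ *spatial integration* kernel with $V$ channels
  (default 32) collapses that to a $1 \times 1 \times V$ feature vector.

The $d$ branch outputs are concatenated ($d \cdot V$ features) and passed
through dense layers of $D_1 = 128$ and $D_2 = 64$ units into a 2-way
softmax. Dropout (0.2) follows the concatenation and the first dense
layer; both convolution kernels carry an L2 penalty of $10^{-5}$; weights
are he_normal-initialized; training minimizes cross-entropy with Adam
(learning rate 0.001, batch size 20, 200 epochs, no early stopping). The
cross-shaped kernels are the point: connectivity information lives in
rows and columns, not in square pixel neighborhoods, so conventional
image convolutions are a poor fit.

Choices the architecture description leaves open, fixed here: ReLU
activations after every conv and dense layer (the convention paired with
he_normal initialization), biases everywhere, no batch normalization and
no pooling. With $d = 1$ the same code is the single-network variant; no
architectural change is involved.

The forward and backward passes are implemented directly as dense matrix
algebra (a batch's $d$ branches are evaluated as three BLAS calls each),
with Adam and inverted dropout. All randomness — initialization, batch
shuffling, dropout — flows from one integer seed through R's RNG, so a
fixed seed and fixed data reproduce training histories bitwise. Gradients
are verified against finite differences in the test suite.

## Evaluation design

`nested_cv()` implements the nested cross-validation with ensembling:

* stratified 5-fold outer CV (stratification is required for every fold
  to contain both classes; plain random folds cannot guarantee usable
  confusion tables at these sample sizes);
* per outer fold, 20% of the training set is held out as a validation
  split and a stratified 5-fold CV runs on the rest; repeated 5 times
  with fresh validation splits, this yields $5 \times 5 = 25$ base
  classifiers, which predict the untouched outer test fold;
* the fold prediction is the **majority vote** of the 25 (odd, so no
  ties); the ensemble *score* — used for ROC/AUC, which a vote cannot
  provide — is the mean positive-class probability across the 25;
* the whole procedure repeats 10 times; metrics are reported as
  mean ± sd across repetitions.

When a hyperparameter grid is supplied, candidates are compared by mean
validation accuracy within each inner repetition; with no grid (the
default) the inner structure still provides the ensemble's diversity.
Fold bookkeeping (which subjects trained which voter) is retained and
asserted leak-free in the tests.

Metrics follow the standard confusion-table formulas (ACC, SEN, SPE,
BAC $=$ (SEN+SPE)/2, PPV, F1) with AUC as the rank (Mann–Whitney)
statistic. Undefined ratios (zero denominators) are reported `NA`, never
coerced to 0.

## Occlusion analysis

Importance is measured by deletion. For a connection $(i, j)$: zero the
entries $(i,j)$ and $(j,i)$ in **all** $d$ networks of every subject's
stack, re-evaluate the stored ensembles on their own held-out folds, and
record the drop in accuracy. For a region $n$: zero row and column $n$
throughout, and transform the per-repetition degradation as
$D_n = \exp(\mathrm{ACC} - \mathrm{ACC}_{\text{masked},n})$ (accuracies
as fractions), then min–max normalize $C_n = (D_n - \min D)/(\max D -
\min D)$, so the least and most contributing regions sit at 0 and 1 by
construction. Per-repetition contributions are averaged for the overall
profile. Occluded accuracy is always computed on held-out test subjects —
training-set evaluation would flatter uninformative edges — and a
parameter checksum asserts that no weights change during the analysis.

A resolution caveat: majority-vote accuracy moves in steps of one
subject, so when the classifier is far from its decision boundary many
single-edge occlusions produce exactly zero drop and are ranked only by
the deterministic tie-break. Occlusion is informative precisely when the
task is neither saturated nor hopeless; the synthetic defaults below are
chosen with that in mind.

## Synthetic cohorts

`sample_cohort()` generates labeled cohorts with known ground truth: a
shared Erdős–Rényi covariance support (density 0.15, entries
$\pm[0.15, 0.3]$), plus `n_discriminative_edges` planted edges, disjoint
from the baseline support, whose covariance differs between groups by
`effect_size` (split $\mp e/2$ so neither group carries the full
magnitude — this keeps both matrices comfortably positive definite; if a
configuration still fails the eigenvalue check the effect is shrunk with
a warning). Subjects are multivariate normal draws, optionally AR(1)
filtered in time with the innovation scaled so the stationary covariance
is preserved, plus white observation noise, then normalized per the
package convention.

Defaults define the desk-scale study condition used throughout the tests:
40 + 40 subjects, $N = 20$ ROIs, $L = 200$ time points, 8 planted edges
of effect 0.5, AR(1) coefficient 0.3, and `noise_sd = 1.5`. The noise
level deserves comment: with unit-variance signals this puts roughly 70%
of observed variance in noise, which is deliberate twice over. It is the
realistic side for ROI-averaged band-passed BOLD, where the neurally
driven component is a minority of total variance; and it keeps cohort
classification accuracy high but *below* saturation, so that occlusion
analysis retains resolution (see the caveat above). At a nearly noiseless
setting the planted edges are individually redundant and every
single-edge occlusion drop is exactly zero.

Two planting modes exist. The default plants in the **covariance** (the
difference is directly visible to Pearson correlation). The
**precision** mode plants sparse structure in the inverse covariance —
the natural ground truth for support recovery, since WSR's
regress-each-node-on-the-rest construction targets conditional
dependence. The support-recovery comparison (guided mask vs.
density-matched hard threshold, `mode = "precision"`) is run at
`noise_sd = 0.2`: it probes the construction method, not the classifier,
and at heavy noise both methods' supports collapse to the same
uninformative estimate, making the comparison vacuous. The compared grid
level is the one whose guided-mask density best matches the true support
density, and the hard threshold is matched to the guided mask's edge
count, so the two methods are compared at identical density.

What the generator does *not* emulate: hemodynamic convolution, motion
and physiological artifacts, site effects, and the heavy-tailed,
non-stationary aspects of real BOLD. Passing recovery tests therefore
demonstrates correctness of the machinery — that the pipeline finds
planted differences when they exist and finds nothing when labels are
permuted — not clinical-grade performance on real cohorts.

## Reduced problem sizes

Full-scale settings (120 ROIs, ten-level grid, $25 \times 5 \times 10$
trained networks, 200 epochs) are the package defaults, but the test
suite and the acceptance script run the deliberately reduced desk-scale
configuration: the synthetic defaults above, the five-level grid
$2^{-4}, \dots, 2^{0}$ (the informative density range at the synthetic
correlation scale — higher levels are empty there), a slimmed classifier
($H = 16$, $V = 8$, $D_1 = 32$, $D_2 = 16$, 40 epochs), two outer
repetitions for the recovery estimate and one for the permutation
control. These sizes are the package's own choice of a configuration
that a laptop reproduces in minutes while still exercising every stage
at full fidelity.

## Known limitations

* The WSR solver factorizes one $N \times N$ system per column; fine for
  atlas-scale $N$ (hundreds), not intended for voxel-level networks.
* Majority-vote occlusion has one-subject resolution (above).
* `exp()` in the region contribution uses accuracy fractions; percent
  units would change $D_n$'s scale but not any ranking.
* The ensemble score (mean softmax probability) is one reasonable choice
  among several; ROC curves from vote margins would differ slightly.
* Dynamic (sliding-window) connectivity, atlas extraction and fMRI
  preprocessing are out of scope: the package consumes ROI time series.
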