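---
title: "Margin-specific dictionaries for sparse representation classification of mammographic masses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-specific dictionaries for sparse representation classification of mammographic masses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammosrc)
```

## The problem

Computer-aided detection on mammograms produces candidate regions of
interest (ROIs), most of which are normal tissue. The classification stage
must separate true masses from these false positives. Masses are
radiologically categorised by the character of their *margin* --
circumscribed, obscured, micro-lobulated, ill-defined or spiculated -- and
the appearance of a mass depends heavily on that category. Pooling all
margin types into one "mass" class makes the positive class very
heterogeneous, which is exactly the situation in which sparse
representation classifiers lose their discriminative power.

## Sparse representation classification

Each ROI is summarised by a feature vector $y \in \mathbb{R}^{812}$
(next section). Training vectors become columns ("atoms") of a dictionary
$A = [A_{\mathrm{mass}}, A_{\mathrm{normal}}]$, each column scaled to unit
$\ell_2$ norm. A test vector is coded as a sparse linear combination of
the atoms by solving the $\ell_1$-regularised (Lagrangian basis-pursuit)
problem

$$\hat{x} = \arg\min_x \tfrac12 \lVert A x - y \rVert_2^2
            + \lambda \lVert x \rVert_1 ,$$

and classified by the class-restricted reconstruction residuals
$r_i(y) = \lVert y - A\,\delta_i(\hat x) \rVert_2$, where $\delta_i$
zeroes all coefficients outside class $i$: the predicted class is the one
with the smaller residual, ties going to "normal" (the conservative call
in a screening context).

### The margin-specific configuration

Instead of one pooled dictionary, the package builds $T$ dictionaries,
one per margin type present in the training data. Dictionary $D_t$
contains the masses of margin $t$ plus an equal number of normal samples
drawn once, without replacement, under the model seed (candidate sets are
dominated by normals, and an unbalanced dictionary biases the sparse code
toward the over-represented class). Each test vector is coded against
every $D_t$ and the class residuals are fused at score level:

$$\mathrm{Res}_i = \sum_{t=1}^{T} \lVert y - D_t\,\delta_i(\hat x_t)
\rVert_2, \qquad i \in \{\mathrm{mass}, \mathrm{normal}\}.$$

The decision is $\arg\min_i \mathrm{Res}_i$ and the ROC score is the
confidence $\mathrm{Res}_{\mathrm{normal}} - \mathrm{Res}_{\mathrm{mass}}$
(larger = more mass-like). The sign convention follows directly from the
arg-min decision rule, so that thresholding the confidence at 0
reproduces the predicted label exactly.

With $T = 1$ the fused residuals reduce, exactly, to plain
single-dictionary SRC; the package's "single configuration" baseline is
built this way (all masses pooled, balanced negatives, raw atoms).

### Fisher discrimination dictionary learning

Raw per-margin dictionaries can be small, so each one is refined by
Fisher discrimination dictionary learning. With per-class data $A_i$,
a class-structured dictionary $D = [D_1, D_2]$ and codes $X_i$ (block
$X_i^j$ = rows of $X_i$ belonging to $D_j$), the objective is

$$\sum_i \Big\{ \lVert A_i - D X_i \rVert_F^2
 + \lVert A_i - D_i X_i^i \rVert_F^2
 + \sum_{j \neq i} \lVert D_j X_i^j \rVert_F^2 \Big\}
 + \lambda_1 \lVert X \rVert_1
 + \lambda_2\big( \mathrm{tr}\, S_W(X) - \mathrm{tr}\, S_B(X)
 + \eta \lVert X \rVert_F^2 \big),$$

i.e. every class must be representable by the whole dictionary and by its
own sub-dictionary while other sub-dictionaries contribute nothing, plus
sparsity and a Fisher term that compacts within-class code scatter and
spreads between-class scatter ($\eta > 0$ keeps the Fisher term convex).
Learning alternates (a) class-wise proximal-gradient coding with a fixed
step of $1/L$, $L$ a Lipschitz bound of the smooth part, and (b)
atom-by-atom dictionary updates whose unit-norm-constrained minimiser is
closed-form ($d_k = E_k c_k / \lVert E_k c_k \rVert$). Both steps are
monotone, so the recorded objective trace never increases -- a property
the test suite audits to $10^{-8}$ relative tolerance. Learning is run
jointly over both classes of each margin dictionary, since each
dictionary carries both mass and normal atoms.

### Sparsity concentration in the true class

Sparsity quality is quantified by
$\mathrm{SCTC}(\hat x) = \lVert \delta_{\mathrm{true}}(\hat x) \rVert_1 /
\lVert \hat x \rVert_1 \in [0, 1]$ (0 by convention for an all-zero
code). In evaluation, a mass of margin $t$ is scored against its own
margin dictionary under the margin-specific configuration and against the
pooled dictionary under the single configuration; SCTC is reported for
mass test samples only, per margin. Normal samples have no margin, so a
per-margin normal SCTC is not defined.

## The feature battery

`extract_features()` returns 812 values in seven fixed blocks:

| block | length | content |
|---|---|---|
| `lbp` | 354 | uniform LBP histograms (59 bins), $(P,R) \in \{(8,1),(8,2),(8,3)\}$, over mask interior and margin band |
| `sgld` | 312 | 13 co-occurrence statistics $\times$ 6 distances (1,2,4,6,8,10) $\times$ 4 directions |
| `rls` | 20 | Galloway's 5 run-length statistics $\times$ 4 directions |
| `glds` | 96 | 4 gray-level difference statistics $\times$ 24 displacements |
| `nrl` | 5 | normalized radial length: mean, sd, area ratio, zero crossings, entropy |
| `intensity` | 5 | contrast measure, mean, sd, skewness, excess kurtosis |
| `stellate` | 20 | region-based gradient-alignment spiculation measures |

Conventions that the numbers depend on:

* Gray levels are quantized uniformly over the in-mask intensity range:
  64 levels for co-occurrence and difference statistics, 16 for run
  lengths (keeps small-ROI matrices populated).
* Co-occurrence matrices count only pixel pairs with *both* endpoints in
  the mask, accumulate symmetrically and are normalized to sum 1.
  Logarithms are base 2 with $0 \log 0 = 0$; correlation is defined as 0
  when a marginal variance vanishes, so no statistic is ever non-finite.
* The LBP block computes each 59-bin histogram twice per radius: over the
  mask interior (mask eroded by $R+2$) and over a margin band (mask
  dilated by $R+2$ minus the interior). The margin band is where margin
  type expresses itself, which is the package's rationale for this
  doubling; $59 \times 3 \times 2 = 354$. A region that erodes away falls
  back to the full mask so histograms always sum to 1.
* Run lengths are maximal runs of equal quantized level along a scan
  direction, broken wherever the line leaves the mask.
* Radial lengths run from the mask centroid to each 4-boundary pixel,
  normalized by their maximum; the zero-crossing count is taken over the
  boundary ordered by polar angle; entropy uses a 10-bin histogram.
* The intensity contrast measure is
  $(\mu_{\mathrm{in}} - \mu_{\mathrm{band}}) /
   (\mu_{\mathrm{in}} + \mu_{\mathrm{band}})$ with a 5-pixel outer band;
  zero-variance patches report 0 skewness and excess kurtosis.
* Stellate features summarise two gradient maps -- absolute cosine
  alignment of the gradient with the direction to the centroid, and the
  radial gradient magnitude -- over core (inner third of the radial
  extent), inner and outer regions: per-region means and sds, pairwise
  mean differences, and the global mean and sd of the alignment map.

## Feature normalization: a deliberate departure

Two choices here differ from the most obvious defaults and were made
after the obvious defaults demonstrably failed:

* **No mean-centering.** If features are mean-centered before atoms are
  normalized, the normal-class atoms acquire a systematic component
  *opposite* to the mass direction, and because sparse codes are signed,
  normal atoms then reconstruct mass queries through negative
  coefficients. Residual contrast between the classes collapses.
  Classical SRC normalizes scale only, and so does this package.
* **Scale = normal-class standard deviation.** Dividing by the overall
  training sd shrinks precisely the discriminative features, because the
  overall sd contains the between-class variance. Scaling by the sd of
  the normal (reference tissue) samples equalises the blocks' wildly
  different numeric ranges without touching the case-control contrast,
  and is insensitive to the mass/normal mix (in screening data normals
  dominate, so the two statistics nearly coincide anyway). Features whose
  normal-class sd is degenerate fall back to the overall sd, then to 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_factor` | 0.1 | $\ell_1$ weight as a fraction of $\max\lvert A^\top y\rvert$ (the smallest weight that zeroes the code); self-scaling per query |
| solver `tol`, `max_iter` | $10^{-6}$, 1000 | relative objective-change stop for FISTA |
| `n_atoms` | $\min(n_i, 40)$ | atoms per class in each learned dictionary |
| `lambda1`, `lambda2`, `eta` | 0.01, 0.01, 1 | FDDL sparsity, Fisher weight, elastic term |
| FDDL `max_iter`, `tol` | 30, $10^{-4}$ | outer alternation budget |
| `k`, `runs` | 10, 30 | cross-validation protocol (folds stratified by class and margin) |

`lambda_factor = 0.1` deserves a note: at much smaller values (e.g. 0.01)
the codes are effectively dense, the coder drifts toward an
ill-conditioned least-squares fit on large dictionaries and FISTA needs
thousands of iterations; at 0.1 the codes are genuinely sparse -- which
is the premise of the whole method -- and the solver converges quickly.
Sparsity is monotone in the penalty, which the test suite checks.

## What the synthetic generators emulate

No clinical images ship with the package; two generators stand in.

**Phantom ROIs** (`gen_roi`) place a radial blob on band-limited
correlated noise ("parenchyma-like" texture, correlation length
`background_texture_scale`). One mechanism per margin type: sharp smooth
edge (circumscribed); the same blob alpha-blended at reduced contrast
(obscured); high-frequency low-amplitude angular modulation of the
boundary (micro-lobulated); a wide blurred edge (ill-defined); 6--14
thin radial spikes (spiculated). Normal patches are pure texture with a
pseudo-mask over the central region so all features stay computable.
The phantom parameters are chosen for visual and morphological
plausibility (e.g. spiculated masks are measurably rougher by
$P^2/4\pi A$); no quantitative morphology of real masses is claimed.

**Feature-space clusters** (`gen_feature_clusters`) draw one isotropic
Gaussian per margin plus one for normal tissue. Every margin mean lies at
distance `separation` $\times$ `margin_scale` (default $6\sigma$) from
the normal mean, decomposed as 80% along one *shared* mass axis and 60%
along a margin-specific axis: masses of all margins share intensity and
shape character and differ in margin texture, and either component alone
would be unrealistic -- fully orthogonal margins would make every
wrong-margin dictionary vote "normal", which contradicts the mechanism
the configuration exploits. The default dimension is 200 so that a
per-margin dictionary (some 160 atoms) is *undercomplete*, the regime the
real 812-dimensional battery operates in; in a low dimension every
dictionary spans the whole space, residuals lose meaning, and neither
configuration can be meaningfully compared.

What the generators do **not** emulate: benign-vs-malignant structure,
whole-mammogram context, segmentation errors, correlated and heavy-tailed
feature noise, margin ambiguity between radiologists. Passing the
synthetic benchmark therefore shows that the implementation realises the
intended mechanism under the stated conditions -- not that the same
margins of improvement would be observed on clinical data.

## Evaluation harness and problem sizes

`cross_validate()` runs stratified $k$-fold cross-validation `runs`
times; every sample is scored exactly once per run, per-run AUC is the
rank (Mann-Whitney) statistic over the pooled out-of-fold confidences,
and per-margin SCTC is averaged over all mass records. The package's own
benchmark -- and what `scripts/acceptance.R` recomputes -- uses 100
masses per margin plus 500 normals per generator seed, 3 runs of 5-fold
CV on each of 10 seeds, which keeps a full desk run in the ten-minute
range while leaving the protocol's structure (multi-run, stratified,
out-of-fold scoring) identical to the full 30x10 configuration.

## Numerical choices and degenerate inputs

* FISTA uses the exact largest eigenvalue of $A^\top A$ (cached per
  dictionary) as step bound, adaptive restart, and per-query freezing;
  non-convergence returns the best iterate flagged, never an error.
* A zero query codes to zero, yields equal residuals, and is classified
  "normal" with confidence 0 (the documented tie-break).
* Degenerate atoms (a sample with zero scaled norm) are replaced by the
  uniform unit vector to keep the unit-norm invariant.
* Model persistence is plain text (17 significant digits), which reloads
  bit-identically; a reloaded model classifies identically to the
  original, audited in the tests.
* All randomness (phantoms, sampling, folds, initialisation) derives
  from explicit integer seeds; every pipeline artifact records its seed.

## Known limitations

* The LBP interior/band doubling is one consistent reading of the
  354-bin layout, not an established standard; likewise the 20-feature
  stellate composition.
* SCTC is defined here for mass test samples only.
* Margin types absent from training are skipped (with a warning), so a
  test mass of an unseen margin is still classified but never gets a
  margin-matched dictionary.
* The FDDL coding step solves each class's subproblem to a fixed inner
  budget rather than to optimality; monotonicity, not optimality, is the
  guaranteed property.
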