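---
title: "Kernel-weighted clustering for gene selection: model and design"
author: "kernelGS"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Kernel-weighted clustering for gene selection: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelGS)
```

# The problem

Expression studies in oncology typically measure thousands of genes on a
few dozen samples. Most genes are irrelevant to the phenotype, and
classifiers trained on the full matrix overfit. A *filter* method scores
genes from the structure of the data alone, independently of any
classifier, so that a small, informative subset can be selected cheaply
before modelling. kernelGS implements such a filter: genes are weighted
by how tightly, in a kernel-induced feature space, the samples of each
class concentrate around their class centroid along that gene.

# The model

Let $X$ be the $n \times l$ matrix of expression values (samples in
rows), with class labels partitioning the samples into $C \ge 2$ classes
$C_1, \dots, C_C$. The pipeline is:

1. **Z-score normalisation.** Each gene column is replaced by
   $(x - \mu)/\sigma$, with $\mu$ and $\sigma$ the gene's mean and
   sample standard deviation ($n-1$ denominator) over all samples.
   Genes with zero variance are set to all zeros and recorded; they
   carry no class structure and end up with the largest dissimilarity a
   constant column can have, i.e. none relative to its own centroid,
   so their weight is driven purely by the regulariser.
2. **Class centroids.** $v_{ik}$ is the mean of gene $k$ over the
   samples of class $i$.
3. **Per-gene dissimilarity.** With a kernel $K$ normalised so that
   $K(x, x) = 1$, the feature-space squared distance is
   $\lVert\Phi(a) - \Phi(b)\rVert^2 = 2(1 - K(a, b))$. The kernel is
   applied coordinate-wise (one gene value at a time), and
   $$D_k = \sum_{i=1}^{C} \sum_{j \in C_i} 2\bigl(1 - K(x_{jk}, v_{ik})\bigr)
   \in [0, 2n).$$
   A gene whose within-class values sit close to their centroid has a
   small $D_k$ and is informative.
4. **Weighted objective.** The gene weights $w$ minimise
   $$J(w) = \sum_k w_k D_k + \delta \sum_k w_k^2,
   \qquad w_k \in [0, 1],\ \sum_k w_k = 1 .$$
   The first term alone would put all mass on the single smallest
   $D_k$; the quadratic term alone would spread the mass uniformly;
   $\delta$ balances the two.

The kernel is a convex mixture of two Gaussians,
$$K(a, b) = c\,e^{-\gamma_1 (a-b)^2} + (1 - c)\,e^{-\gamma_2 (a-b)^2},$$
which keeps $K(x,x) = 1$ and the $(0, 1]$ range while, for
$\gamma_2 < \gamma_1$, adding a heavier tail than a single RBF: distant
values retain some similarity, so single outlying measurements do not
saturate the dissimilarity as quickly. With $c \in \{0, 1\}$ or
$\gamma_1 = \gamma_2$ the mixture degenerates to a single RBF, which is
how the original single-kernel variant is recovered.

# The optimiser

Eliminating the sum constraint with a Lagrange multiplier gives the
closed-form stationary point
$$w_k = \frac{1}{l} + \frac{1}{2\delta}\bigl(\bar D - D_k\bigr),$$
where $\bar D$ is the mean dissimilarity; this raw vector sums to one
algebraically. For small $\delta$ it can have negative entries, which
the box constraint forbids. `updateWeights()` then clips the negative
entries to zero and renormalises by shifting the threshold over the
remaining support — the Euclidean projection onto the simplex. We chose
the projection (rather than rescaling the clipped vector) because it is
the exact KKT solution of minimising $J$ at fixed $\delta$ under the
full constraint set: the update remains the constrained minimiser in
every regime, which the test suite verifies against a dense simplex-grid
search. Either way the update is monotone: $D_k \le D_{k'}$ implies
$w_k \ge w_{k'}$, so the final ranking always equals the ranking by
ascending dissimilarity (a fast oracle the tests exploit).

$\delta$ is rescaled each iteration so the two terms of $J$ stay on the
same order of magnitude:
$$\delta^{(t)} = \left|\frac{\sum_k w_k^{(t-1)} D_k}
{\sum_k \bigl(w_k^{(t-1)}\bigr)^2}\right| ,$$
optionally scaled by a constant $\alpha$ (default 0.05) in the original
single-kernel schedule; with $\alpha = 1$ the two variants coincide and
the package tests that identity. With uniform weights the ratio equals
$\sum_k D_k$, which is therefore the first $\delta$ every run uses
(the schedule is evaluated *before* the first weight update, from the
uniform initialisation $w^{(0)} = 1/l$).

The loop computes $D$ once (it does not depend on $w$), then alternates
the $\delta$ rescaling and the weight update until the absolute change
in $J$ drops below $\theta = 10^{-6}$ or 100 iterations are reached. We
use the absolute change rather than the signed one so that an objective
increase cannot be mistaken for convergence. In practice the iteration
is a fixed-point scheme in $\delta$ and converges in a handful of steps
(4–6 on all synthetic regimes exercised here). Two degenerate cases are
handled explicitly: a single gene gets weight 1 immediately, and data
that are perfectly class-separated per gene (every $w_k D_k = 0$) make
the $\delta$ ratio undefined — the run stops with the current weights,
a warning, and `converged = FALSE`.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `gamma1` | 1 | bandwidth of the local kernel; on z-scored data per-gene squared differences are $O(1)$, so 1 is sensitive at the natural scale |
| `gamma2` | 0.1 | bandwidth of the flatter kernel; an order of magnitude smaller supplies the heavy tail |
| `c` | 0.5 | mixture weight; 0.5 treats both components symmetrically, and the grid search exposes it |
| `theta` | 1e-6 | convergence tolerance on the objective change |
| `maxIter` | 100 | iteration cap |
| `alpha` | 0.05 | scaling of the single-kernel $\delta$ schedule |

All of these are exposed through `selectGenes()`, the evaluation
functions and the CLI; `gridSearchKernel()` searches the kernel triple
by cross-validated accuracy.

# Evaluation harness

`crossValidate()` uses stratified folds (per class, shuffle then deal
round-robin), so per-fold class proportions deviate from the global
ones by at most one sample per class and every class with at least two
samples is present in every training fold — this is checked up front,
and the fold count is reduced with a warning when the smallest class is
smaller than the requested number of folds. Normalisation statistics
are always fitted on the training fold only.

Where the gene ranking is fitted was a genuinely open design point: the
statistically sound protocol refits the selection inside each training
fold, and that is the default (`selection = "fold"`). A `"global"` mode
reuses one ranking fitted on all samples — optimistic, but useful for
reproducing protocols that select once up front — and a `"fixed"` mode
evaluates an externally supplied subset, which is how rankings from
other methods are compared on an equal footing.

Two classifier families are provided: $k$-nearest neighbours (default
$k = 5$, Euclidean distance on the selected genes, with an optional
kernel-induced distance mode using $\sum_k 2(1 - K)$ per gene) and a
soft-margin SVM using the double-RBF kernel on the selected-gene
vectors with unit cost. For two-class data the report contains
sensitivity (TPR) and specificity (TNR) of the designated positive
class — the lexicographically second label unless overridden — plus a
pooled ROC curve built by sweeping the decision threshold over the
unique classifier scores, with the area computed by the trapezoid rule.
For multiclass data TPR/TNR are macro-averages of the per-class recalls
and specificities, stated in the report header. All randomness
(fold assignment, any classifier tie-breaking) is derived
deterministically from one seed, so identical configurations reproduce
reports byte for byte.

# The synthetic-data generator

`simulateExpression()` emulates the small-$n$, large-$l$ microarray
regime: gene baselines $b_g \sim N(0, \text{baselineSd}^2)$, class-mean
shifts $\mu_{g,i} = \text{effectSize}\cdot\text{noiseSd}\cdot s_i$ for
the informative genes with class scores $s_i$ equally spaced in
$[-1, 1]$ (two classes sit at $\pm 1$, so their means differ by twice
the effect size; multiclass problems get ordered, symmetric structure),
and i.i.d. Gaussian noise. `syntheticPresets()` carries the shapes of
four classic benchmarks (77×7129/2, 40×1519/2, 62×4026/3, 152×65522/5
as samples×genes/classes), with 20 informative genes, effect size 2 and
unit noise as the default regime; the baseline SD defaults to 1,
i.e. gene baselines on the same scale as the noise, which z-scoring
removes again — it exists so that raw matrices look realistic, not to
influence the method.

The generator deliberately does **not** model gene–gene correlation,
batch effects, heavy-tailed intensities or missingness. Passing the
recovery tests therefore shows that the optimiser retrieves mean-shift
signal planted on an independent Gaussian background at the stated
effect size — it does not certify performance on correlated or
artefact-laden real data, where effective sample sizes are smaller and
redundant genes share weight.

# Numerical choices and degenerate inputs

* Exponential underflow for large $\gamma (a-b)^2$ is harmless: the
  kernel distance simply saturates at exactly 2; no clamping is done.
* Zero-variance genes are mapped to all-zero columns rather than
  rejected, because real matrices contain constant probes.
* Ties in the ranking are broken by gene index ascending, everywhere,
  so rankings and weight tables are deterministic.
* The weight-table writer prints 12 significant digits; re-reading
  reproduces the vector at that precision (tested).
* Problem sizes in the test suite were chosen so the whole suite and
  the replication script each run in about a minute on one core: the
  recovery study uses the 40×1519 two-class regime with 10 planted
  genes over 10 seeds, and the loop-contract checks run every preset
  once, including the 152×65522 one.

# Known limitations

* The dissimilarity treats genes independently; two perfectly redundant
  informative genes each receive full weight, so the top-$k$ subset can
  be redundant (no within-subset de-correlation is attempted).
* Data that are perfectly separated per gene terminate the optimiser at
  the uniform weights (see above) — a rare but real boundary case.
* The double-kernel SVM uses one shared kernel triple for selection and
  classification; fitting them separately would be possible but is not
  provided.
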