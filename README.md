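# kernelGS

Filter gene selection for expression-based cancer classification, built
on a double RBF-kernel weighted clustering criterion, with a full
cross-validated evaluation harness and a seeded synthetic-data
generator.

## Who this is for

Analysts working with small-sample, high-dimensional expression
matrices (tens of samples, thousands of genes, 2–5 phenotype classes)
who need a fast, classifier-independent ranking of genes by class
informativeness — e.g. to pick a top-k panel before fitting a
classifier, or to compare a new ranking method against a kernel-based
baseline on equal footing.

## The method

Given a z-scored matrix $X$ ($n$ samples × $l$ genes) with class labels,
each gene $k$ gets a dissimilarity score

$$D_k = \sum_{i=1}^{C} \sum_{j \in C_i} 2\bigl(1 - K(x_{jk}, v_{ik})\bigr),$$

the kernel-induced squared distance between each sample's value and its
class centroid $v_{ik}$, summed over all samples, where

$$K(a,b) = c\,e^{-\gamma_1 (a-b)^2} + (1-c)\,e^{-\gamma_2 (a-b)^2}$$

is a heavy-tailed convex mixture of two Gaussian kernels. Gene weights
$w$ on the probability simplex minimise the regularised objective

$$J(w) = \sum_k w_k D_k + \delta \sum_k w_k^2,$$

via the closed-form update $w_k = 1/l + (\bar D - D_k)/(2\delta)$
(projected onto the simplex when the box constraint binds), with
$\delta$ rescaled each iteration as
$\lvert \sum_k w_k D_k / \sum_k w_k^2 \rvert$ (the DKBCGS schedule;
the original KBCGS schedule scales this by $\alpha = 0.05$) until the
objective change falls below $10^{-6}$. Genes are ranked by descending
weight. See `vignette("kernelGS-methods")` for assumptions, parameter
guidance and design rationale.

## Worked example

Simulate a benchmark-shaped dataset (40 samples × 1519 genes, two
classes, 10 planted informative genes at effect size 2), run the
selector, and evaluate the top-10 panel with stratified 10-fold
cross-validation and a 5-NN classifier:

```r
library(kernelGS)

spec <- SyntheticSpec(nSamples = 40, nGenes = 1519, nClasses = 2,
                      nInformative = 10, effectSize = 2, seed = 7)
sim <- simulateExpression(spec)

sel <- selectGenes(sim$dataset,
                   params = KernelParams(gamma1 = 1, gamma2 = 0.1, c = 0.5))
sel
#> GeneSelection (DKBCGS variant)
#> OptimizerState: 5 iteration(s), converged (theta = 1e-06), delta = 30171.3
#> GeneWeights over 1519 genes
#>   top: g9=0.0009005, g8=0.0008936, g6=0.0008855, g1=0.000878, g4=0.0008758

sum(topGenes(sel, 20) %in% sim$informative)
#> [1] 10                      # all 10 planted genes in the top 20

crossValidate(sim$dataset, k = 10, classifier = "knn", folds = 10, seed = 7)
#> EvalReport [knn/fold-selection (k=5, euclidean), k = 10 genes, seed = 7]
#>   ACC = 1.0000, TPR = 1.0000, TNR = 1.0000, AUC = 1.0000
#>   pooled confusion (predicted x truth):
#>          truth
#> predicted class1 class2
#>    class1     20      0
#>    class2      0     20
```

The convergence happened in 5 iterations; the weights concentrate on
the planted genes (`g1`–`g10`), and the cross-validated panel separates
the classes perfectly at this effect size. The selection is refit
inside every training fold by default, so no test-fold information
leaks into the ranking.

Other entry points: `sweepK()` (error-rate curve over the panel size,
1–50 by default), `gridSearchKernel()` (factorial search over
$\gamma_1, \gamma_2, c$), `rocCurve()`, and the file-based workflow
`readExpressionMatrix()` / `writeWeightTable()`. A command-line wrapper
lives at `inst/scripts/kernelgs` with `simulate`, `select`, `evaluate`,
`sweep` and `grid` subcommands.

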