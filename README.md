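# splitrank

Restructuring supervised classification problems by categorical attributes.

## The problem

Many tabular prediction problems — QSAR-style activity modelling on
molecular descriptors, prognosis prediction from expression profiles with
clinical covariates — carry discrete or categorical attributes alongside
their continuous features. Such an attribute partitions the sample space
into non-overlapping sub-problems, and the right attribute can turn a
problem that defeats a simple hypothesis class into a handful of easy ones:
a decision boundary that is globally neither linear nor quadratic may be
exactly linear (or quadratic) within every cell of the partition. splitrank
answers two questions for users of this strategy:

1. **Which categorical attribute should partition the problem?**
2. **How much does the partition actually help a given model family?**

## The metric

For a candidate attribute *z* with levels 1..*q* and a model family *M*
(linear discriminants, or kernelized discriminants via the dual form), the
score of *z* is the expected conditional entropy of the class label *y*
given the partition and a random model *m* = (**w**, *c*) from *M*:

    Ĥ(y | z) = (1/N) Σᵢ Σⱼ p̂(z = j) · H(y | z = j, w_ij, c_ij)

Each of *N* trials draws one random discriminant direction per sub-problem
(a unit normal **w** in feature space, or random dual weights α with unit
RKHS norm so that f(x) = Σ αᵢ K(xᵢ, x) + c for a kernel *K*), then sets
each offset *c* to the exact minimizer of the weighted two-cell entropy of
the split {f ≥ 0} vs {f < 0} by scanning every achievable threshold.
Multi-class sub-problems use k(k−1)/2 one-vs-one discriminants and measure
the class entropy of the voted decision regions. Sub-problem entropies are
weighted by the empirical level proportions p̂(z = j), and the trial
average is reported in bits: 0 means every sub-problem is (in expectation)
trivially separable, log₂ k means the partition plus a random model leaves
the labels maximally uncertain. Attributes are ranked ascending; unlike the
decision-tree criterion H(y|z), the metric conditions on a *model*, so it
measures how much the partition helps the chosen hypothesis class rather
than how predictive the attribute is on its own.

The top-ranked attribute then *restructures* the problem: one soft-margin
SVM of the same family is trained per attribute level, and prediction
routes each sample to its level's classifier (unseen levels fall back to
the largest training level).

## Worked example

The bundled generator reproduces a family of piecewise-separable benchmark
patterns: `X1, X2` uniform on a rectangle, a quadrant attribute `X3`, a
random binary attribute `X4`, and labels that are linearly separable within
every quadrant but not globally.

```r
library(splitrank)

data <- generate_pattern(1, n_train = 400, n_test = 1600, seed = 42)
ranking <- rank_attributes(data$train, n_projections = 1000, seed = 42)
ranking
#> <ranking_report> N=1000 seed=42 kernel=linear
#>   rank attribute q entropy_bits
#> 1    1        X3 4    0.7906290
#> 2    2        X4 2    0.8934961

fam <- model_family(kernel_spec("linear"))
for (a in list(NULL, "X3", "X4")) {
  ev <- evaluate(data$train, data$test, a, fam, seed = 1)
  cat(sprintf("%-8s cv = %5.2f  test = %5.2f\n",
              if (is.null(a)) "baseline" else a, ev$cv, ev$test))
}
#> baseline cv = 64.00  test = 63.62
#> X3       cv = 98.00  test = 98.81
#> X4       cv = 60.25  test = 63.44
```

The quadrant attribute gets the smaller estimated entropy (0.79 vs 0.89
bits), and restructuring by it lifts held-out accuracy from 63.6% to 98.8%
while the uninformative `X4` changes nothing — the ranking predicted
exactly which partition helps. `benchmark_replicates()` wraps this whole
protocol (10 replicate sets sharing the base draw with `X4` redrawn,
mean ± sd per row) and `attribute_conditional_entropy()` exposes the
per-trial detail. Kernelized scoring uses `kernel_spec("poly2")` (the
homogeneous degree-2 polynomial kernel `(u'v)^2`) or
`kernel_spec("gaussian", gamma)`.

A command-line interface covers the same pipeline for shell use:

```sh
Rscript inst/bin/splitrank simulate --pattern 1 --seed 7 --out d/
Rscript inst/bin/splitrank rank --data d/train.csv --schema d/schema.json \
    --projections 1000 --seed 7 --out d/ranking.tsv
```

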