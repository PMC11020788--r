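# tdeshape

Shape-constrained detection of temporal expression patterns in time-course
single-cell RNA-seq.

## What it does, and for whom

Given a genes × cells count matrix collected at T ≥ 3 ordered stages (with
one or more biological samples per stage), `tdeshape` tests, gene by gene,
whether mean expression follows one of four temporal shapes — **growth**
(monotone up), **recession** (monotone down), **peak** (transient up),
**trough** (transient down) — while accounting for the correlation of cells
within a sample. It is aimed at analysts of developmental, treatment-response
or disease-progression time courses who want pattern-specific temporal genes
rather than an unstructured "any difference between stages" test.

Per gene *g* it fits a linear additive mixed model on log-normalized
expression

y_gji(t) = w′_gji α_g + Σ_k s_k(t) β_gk + u_gji + e_gji,  β_gk ≥ 0,

where u_g ~ N(0, σ²_gu Σ) is a per-sample random intercept (Σ block-diagonal
all-ones) and e_g ~ N(0, σ²_g I). The shape lives in the basis: monotone
I-splines for growth/recession (unconstrained part W0 = [1]) and convex
C-splines plus a free linear term for peak/trough (W0 = [1, t]); mirrored
patterns negate the cone columns. Fitting is a least-squares **cone
projection** solved by active-set ascent after a closed-form blockwise
whitening of the random effect. Each pattern is tested with the B-statistic
B = (SSR₀ − SSR₁)/SSR₀ against a **mixture-of-beta** null whose weights are
the null probabilities of each active-face dimension; the four pattern
p-values are merged by the **Cauchy combination rule**, and FDR is estimated
by **sample-level permutation** of the time labels. A "linear" version drops
the random effect for designs with a single sample per stage. A built-in
gamma-Poisson simulator with sample-level batch effects and per-time-point
effect profiles provides ground-truth data for calibration and power checks.

## Worked example

```r
library(tdeshape)

params <- sim_params(n_genes = 500, n_cells_per_sample = 50, seed = 1)
truth  <- simulate_counts(params)          # counts + true pattern labels
bundle <- as_expression_bundle(truth)      # filter, log-normalize, package
bundle
#> Time-course expression bundle
#>   genes: 498  cells: 750
#>   time points: 5  samples: 15
#>   cells per time point: 150, 150, 150, 150, 150

res <- tde_test(bundle, model = "mixed", permutations = 5, seed = 1)
summary(res)
#> Temporal pattern screen summary
#>   genes tested: 498
#>   significant at FDR <= 0.05: 117
#>    growth      peak recession    trough
#>        45        17        38        17
```

Two genes were dropped by the 99%-zero filter. 117 of 498 genes are called
temporal at an estimated FDR of 5% (the generator planted ~30% temporal
genes of six shapes; the weakest and the multi-modal ones are genuinely hard
to detect at this depth). Comparing calls with the generator's truth among
the hits:

```r
hits <- res[res$fdr <= 0.05, ]
table(called = hits$pattern, truth = truth$true_pattern[hits$gene])
#>            truth
#> called      bi-plateau growth multi-modal none peak recession trough
#>   growth            10     27           4    2    1         0      1
#>   peak               2      1           2    6    6         0      0
#>   recession          4      0           6    2    2        22      2
#>   trough             1      0           4    0    0         0     12
```

Monotone truths are labelled almost perfectly; step-like ("bi-plateau")
profiles are monotone too and are absorbed by growth/recession, as the label
set intends. Each row of `res` carries the four per-pattern p-values, the
combined p-value, the permutation FDR, the assigned pattern and (for the
mixed model) the estimated variance ratio; `write_results(res, "out.tsv")`
saves the table. Single genes can be inspected with
`fit_lamm(bundle, "gene00007", "peak", model = "mixed")`, which returns a
fitted-model object with `coef`, `fitted`, `residuals`, `predict`, `plot`
and `simulate` methods.

A thin command-line wrapper lives at `inst/scripts/tde-cli.R`
(`fit`, `simulate`, `benchmark` subcommands).

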