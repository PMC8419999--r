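# umiresid

Analytic Pearson residuals for normalization and highly-variable-gene
selection in single-cell RNA-seq UMI count data.

## The problem

UMI count matrices mix two kinds of variation: technical variation driven
by each cell's sequencing depth, and the biological variation an analysis
is after. The standard remedy — divide by depth, then apply a nonlinear
variance-stabilizing transform — handles neither end of the expression
range well: low-expression genes collapse toward zero variance after a
square-root or log transform, while depth-regression models with a free
per-gene slope are overspecified and yield noisy, strongly coupled
parameter estimates that have to be smoothed after the fact.

`umiresid` implements the parsimonious alternative: a rank-one null model
in which gene *g* takes a fixed fraction *p<sub>g</sub>* of each cell's
total count *n<sub>c</sub>*,

```
X_cg ~ Poisson(mu_cg)  or  NB(mu_cg, theta),    mu_cg = n_c * p_g ,
```

whose Poisson maximum likelihood solution is closed-form
(`mu_hat = row sum * column sum / grand total`). Pearson residuals of this
fit,

```
Z_cg = (X_cg - mu_hat_cg) / sqrt(mu_hat_cg + mu_hat_cg^2 / theta) ,
```

with a single shared overdispersion `theta = 100` and clipping to
`±sqrt(n_cells)`, have variance close to 1 for genes that only vary with
depth — so excess residual variance directly flags biologically variable
genes, including weakly expressed markers of rare cell populations that
every depth-normalize-then-transform pipeline misses.

The package also ships the surrounding evidence as runnable code:

* **Regression diagnostics** — per-gene two-parameter Poisson regressions
  on log depth (`fit_two_param_regression`) that show the free slope is
  redundant (its average is `ln 10 ≈ 2.3` per decade of depth, i.e. 1 on
  the natural-log scale), and a per-gene overdispersion MLE
  (`fit_theta_mle`, `run_bias_experiment`) that reproduces the systematic
  downward bias of theta estimates at low expression and their divergence
  when the optimizer is run longer.
* **Competitor transforms** — sqrt / Anscombe / Freeman–Tukey, `log(1+x)`
  with median or CPM scaling, per-gene standardization, Fano factor.
* **Synthetic data** — null UMI counts, negative-control grids over
  `theta ∈ {10, 100, 1000, ∞}`, and a labeled multi-type benchmark with an
  injected 50-cell rare population carrying ten pseudo marker genes.
* **A cell-type-separation benchmark** — HVG selection × transform → PCA
  (50 dims) → leave-one-out kNN (k = 15) → macro F1.

## Worked example

```r
library(umiresid)

spec  <- simulation_spec(n_genes = 2000, seed = 1)
bench <- make_benchmark(spec, seed = 1)     # 8 types + injected rare type
#> LabeledDataset: 4013 cells x 2010 genes, 9 classes (rare, type_6, ...)

scores <- hvg_table(bench$counts, method = "pearson_var", k = 100, theta = 100)
head(scores[order(-scores$score), ], 5)
#>    gene_id mean_expression score selected
#> 32 gene_32            9.24  5.07     TRUE
#> 31 gene_31            9.35  4.97     TRUE
#> 33 gene_33            8.83  4.83     TRUE
#> 34 gene_34            8.56  4.67     TRUE
#> 35 gene_35            8.24  4.62     TRUE
sum(scores$selected[grepl("^pseudo_", scores$gene_id)])
#> [1] 8        # 8 of the 10 rare-population markers are in the top 100

res <- run_grid(bench, list(
  pipeline_spec("pearson_var", "pearson",       n_hvgs = 500),
  pipeline_spec("sqrt_var",    "sqrt_cpmedian", n_hvgs = 500)))
res[, c("pipeline", "macro_f1", "accuracy", "f1_rare")]
#>                 pipeline macro_f1 accuracy f1_rare
#> 1    pearson_var+pearson    0.999    1.000    0.99
#> 2 sqrt_var+sqrt_cpmedian    0.882    0.987    0.00
```

The residual variance scores place the up-regulated marker blocks and the
pseudo genes at the top; selection by square-root-transform variance never
sees the rare markers. Downstream, the Pearson-residual pipeline classifies
the rare type almost perfectly (per-class F1 0.99) while the sqrt pipeline
misses it entirely (F1 0) — yet both have high *overall accuracy* (1.000
vs 0.987), which is exactly why the benchmark reports macro F1.

## Command line

```sh
exec/umiresid simulate  --mode null --seed 1 --output sim/
exec/umiresid residuals --input sim/matrix.mtx --theta 100 --clip sqrt_n --output res/
exec/umiresid hvg       --input sim/matrix.mtx --method pearson_var --n-top 2000
exec/umiresid theta-bias --output bias/
exec/umiresid benchmark  --output bench/
```

Every output directory contains a `provenance.json` with the parameters,
seed and package version needed to re-run the command.

## Further reading

The methods vignette (`vignettes/analytic-pearson-residuals.Rmd`) documents
the model and its assumptions, all tunable parameters and defaults, what
the synthetic generators do and do not emulate, and the numerical choices.
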