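# dcornet

Gene co-expression network analysis built on the **empirical distance
correlation** instead of (or alongside) Pearson's correlation.

Co-expression pipelines in the WGCNA tradition start from a gene-by-gene
correlation matrix, and the default Pearson coefficient only sees linear
association: a gene pair following a parabolic, threshold or clustered
relationship can have near-zero Pearson correlation while being strongly
dependent, and a single aberrant sample can inflate or destroy the
coefficient. Distance correlation, from energy statistics, detects *any*
form of dependence (it is zero in population only under independence),
needs no distributional assumptions, and is far less sensitive to
outliers — which makes it an attractive backbone for weighted network
construction. `dcornet` provides that backbone together with the full
evaluation machinery needed to compare metrics: permutation tests and
power/ROC curves, scale-free-topology soft-threshold selection,
topological overlap, dendrogram-based module detection, split-half
stability and Fisher-exact module-preservation statistics, and seeded
synthetic-data generators so that every step can be exercised and
validated without any external dataset.

## The statistic

For paired samples $(X_k, Y_k)$, $k = 1, \dots, n$, form the pairwise
distance matrices $a_{kl} = |X_k - X_l|$, $b_{kl} = |Y_k - Y_l|$ and
double-center them:

$$A_{kl} = a_{kl} - \bar a_{k\cdot} - \bar a_{\cdot l} + \bar a_{\cdot\cdot},
\qquad
B_{kl} = b_{kl} - \bar b_{k\cdot} - \bar b_{\cdot l} + \bar b_{\cdot\cdot}.$$

The squared empirical distance covariance is
$V_n^2(X, Y) = n^{-2} \sum_{k,l} A_{kl} B_{kl}$, and the empirical
distance correlation is

$$R_n(X, Y) = \sqrt{\frac{V_n^2(X, Y)}{\sqrt{V_n^2(X)\, V_n^2(Y)}}}
\in [0, 1].$$

Pearson, Spearman and a simplified maximal information coefficient (MIC)
are implemented as comparator metrics behind the same interface. The
network side follows the standard unsigned weighted construction:
similarity $s_{ij} = |\mathrm{cor}(i, j)|$, soft-threshold adjacency
$a_{ij} = s_{ij}^\beta$ with $\beta$ chosen so the connectivity
distribution approximates a scale-free power law
$p(k) \sim k^{-\gamma}$ (fit index = signed $R^2$ of the log–log
regression, target 0.9), topological overlap
$\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$,
average-linkage clustering of $1 - \omega$, and a minimum-size branch
cut with unassigned genes collected in the grey module.

## Worked example

A parabolic gene pair is invisible to Pearson but obvious to distance
correlation:

```r
library(dcornet)

pair <- gen_relationship("parabolic", n = 60, seed = 2)
cor_pearson(pair$x, pair$y)                          # 0.072
cor_spearman(pair$x, pair$y)                         # 0.208
mic(pair$x, pair$y)                                  # 0.542
dcor(pair$x, pair$y)                                 # 0.503

indep_test(pair$x, pair$y, "pearson", n_perm = 199, seed = 1)  # p = 0.625
indep_test(pair$x, pair$y, "dcor",    n_perm = 199, seed = 1)  # p = 0.005
```

The permutation test (199 permutations, add-one estimator) rejects
independence decisively with distance correlation (p = 0.005, the
smallest attainable value) while Pearson sees nothing (p = 0.625).

The full pipeline on a synthetic matrix with four planted 40-gene
modules plus 40 background genes across 100 samples:

```r
sim <- gen_module_expression(rep(40, 4), n_background = 40,
                             n_samples = 100, within_corr = 0.7, seed = 1)
res <- detect_modules(sim$expr, metric = "dcor")
table(res$colors)
#>      blue     brown      grey turquoise    yellow
#>        40        40        40        40        40
```

All four planted modules are recovered exactly (adjusted Rand index 1
against the planted labels; the 40 background genes land in grey).

A thin command-line front end with `synth`, `filter`, `net`, `power` and
`stability` subcommands is installed under `inst/cli/dcornet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dcornet.R", package = "dcornet"))')" \
    net --expr expression.tsv --out-dir run1 --metric dcor
```

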