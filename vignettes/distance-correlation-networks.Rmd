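---
title: "Distance-correlation co-expression networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-correlation co-expression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcornet)
```

# Why distance correlation for co-expression

Weighted gene co-expression network analysis groups genes into modules
by clustering a gene-by-gene similarity matrix. When that similarity is
the absolute Pearson correlation, the network can only encode linear
co-variation: a pair of genes related through a parabola, a threshold
switch, or a small number of expression regimes has a Pearson
coefficient near zero and is effectively removed from the network —
doubly so after soft-thresholding, which raises similarities to a power
and crushes small values further. Empirically, when gene pairs are
screened by distance correlation, roughly a tenth of strongly dependent
pairs in typical expression compendia have absolute Pearson correlation
below common cut-offs, so a linear backbone silently discards them.

The empirical distance correlation $R_n$ repairs this: it is zero (in
population) exactly under independence, lives on $[0, 1]$, requires no
normality, and reacts mildly to outliers. Its cost is $O(n^2)$ per pair
in the number of samples and the loss of the correlation's sign; for
unsigned networks the sign was being discarded anyway.

# The metrics

Four dependence metrics sit behind one interface (`cor_pearson`,
`cor_spearman`, `mic`, `dcor`, and matrix-level `cor_matrix`):

* **Pearson** and **Spearman** delegate to `stats::cor`; Spearman is
  Pearson on average ranks.
* **Distance correlation** is computed from the doubly centered
  distance matrices (`dist_center`) with the univariate absolute
  difference as the distance — the standard choice for scalar
  expression profiles. `cor_matrix(expr, "dcor")` flattens each gene's
  centered matrix and obtains all pairwise $V_n^2$ values in one
  cross-product, so a 200-gene, 100-sample matrix takes well under a
  second.
* **MIC** is a deliberately simplified estimator of the maximal
  information coefficient: over all grid shapes $r \times c$ with
  $r, c \ge 2$ and $r c \le B(n) = \max(4, \lfloor n^{0.6} \rfloor)$,
  one axis is split into equal-frequency bins and the other axis's
  partition is optimized by dynamic programming over equal-frequency
  superclumps (at most $15 r$ of them); both orientations are searched.
  Values can differ from the reference MINE implementation, which
  optimizes both axes; here MIC is a comparator, not the product. The
  floor of 4 on $B(n)$ keeps a $2 \times 2$ grid admissible at very
  small $n$. Ties on either axis are broken by stable sort order, which
  makes the estimator deterministic.

Degenerate input (a constant profile) would make every metric
undefined; all of them return 0 with a warning instead of `NA`, so
downstream matrices stay finite. Vectors containing non-finite values
are rejected outright.

# Permutation testing

Independence is tested by permuting one margin: the statistic (absolute
value for the signed metrics) is recomputed for `n_perm` permutations of
`y` and the p-value is the add-one estimator
$p = (1 + \#\{T_\pi \ge T_{obs}\}) / (1 + n_{perm})$, which can never be
zero and is exactly sized under exchangeability. The default
`n_perm = 199` makes the smallest attainable p-value $1/200$. Each of
the fast paths exploits structure: the centered distance matrices stay
doubly centered under a simultaneous row/column permutation, so the dcor
permutation loop only re-indexes the precomputed matrix of `y`; the MIC
loop runs entirely in C++. One root seed spawns per-repetition streams
(`spawn_seeds`), and every seeded helper restores the caller's RNG
state.

Power is summarized by the rejection-proportion curve: the fraction of
Monte Carlo repetitions with $p \le \alpha$, on the significance grid
$\alpha = 0, 0.01, \dots, 1$, integrated by trapezoid (`curve_auc`). A
powerless test traces the diagonal (area 0.5); the grid step and
trapezoid rule are our choice, fine enough that curve discretization is
negligible against Monte Carlo noise.

# Network construction and module detection

`similarity` takes absolute values (unsigned network); `adjacency`
raises to the soft power $\beta$; `connectivity` sums off-diagonal
adjacency; `tom_similarity` implements the standard unsigned
topological-overlap formula
$\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell = A A$ computed on a zero-diagonal copy, diagonal fixed at 1,
and the denominator floored at machine epsilon. Conventions: the
diagonal is excluded from connectivity, set to 1 in TOM, and 0 in the
TOM dissimilarity.

$\beta$ is selected by the scale-free-topology criterion
(`pick_soft_threshold`): for each candidate power the connectivity
vector is binned into 10 equal-width bins (empty bins dropped), and the
fit index is $-\mathrm{sign}(slope) \cdot R^2$ of the regression of
$\log_{10} p(k)$ on $\log_{10} \bar k$, so a *rising* degree
distribution is penalized. The recommended power is the smallest
candidate whose index reaches the conventional 0.9 target.

When no candidate reaches the target — which is the rule, not the
exception, for data that are not even approximately scale-free, such as
a matrix with a few equally sized planted modules — `detect_modules`
falls back to the widely used unsigned-network default powers by sample
count: $\beta = 6$ for $\ge 40$ samples, 7 for 30–39, 8 for 20–29, 9
below. Taking instead the candidate with the maximal fit index is
tempting but degenerate: on planted-module data the index keeps creeping
upward with $\beta$ while the adjacency underflows toward zero and every
gene ends up unassigned.

Clustering is average linkage (UPGMA, `stats::hclust`) on the TOM
dissimilarity. Module extraction uses a **static branch cut**
(`cut_tree_modules`): cut the tree at `cut_height_fraction` (default
0.99) of the maximum merge height, keep branches with at least
`min_cluster_size` (default 30) leaves as modules, and send everything
else to the grey module (label 0). This is simpler than the hybrid
dynamic tree cut used by the WGCNA package — it has two transparent
parameters instead of a family of shape heuristics — and on planted
benchmarks it recovers the ground truth exactly (see below), which is
what the method is validated against here; users porting results from
`cutreeDynamic` should expect module boundaries, not module content, to
shift. Tied merge heights can carry floating-point noise of order
$10^{-16}$ from the linkage averaging; sub-tolerance inversions are
clamped before cutting. Modules are renumbered by decreasing size (ties
broken by the smallest contained gene index) and mapped onto the
conventional colour sequence (turquoise, blue, brown, ...), with grey
reserved for unassigned genes.

# Evaluation harness

* `split_half_stability` splits samples into random equal halves,
  ranks gene pairs by $|corr|$ in half 1, and reports the mean absolute
  difference of the coefficients across halves for the top-$n$ pairs —
  smaller is more replicable.
* `split_half_preservation` detects modules independently in each half
  and cross-tabulates the partitions; each cell gets a one-sided
  Fisher's exact p-value (the hypergeometric upper tail, via
  `stats::phyper`) for overlap enrichment, reported as $-\log p$
  (natural log, the scale on which values above ~50 indicate very
  strong preservation).
* `complex_pair_fraction` quantifies the motivation: among pairs with
  dcor above 0.5, the fraction with $|r| < 0.5$ — dependence a linear
  cut-off would discard.
* `enrichment_score` aggregates member p-values of an annotation
  cluster as the mean of $-\log_{10} p$ (equivalently $-\log_{10}$ of
  their geometric mean); no annotation database is queried, only the
  aggregation is provided.

# Synthetic study conditions

The generators in this package *are* the study conditions; their
defaults are fixed once and all validation runs on them.

`gen_relationship` draws six bivariate families: independent, linear,
power ($y = \mathrm{sign}(x)|x|^3 + \varepsilon$), threshold (a step in
$x$), quadripartite, and parabolic ($y = x^2 + \varepsilon$ on symmetric
$x$). The quadripartite family needs care: four equally probable
clusters on the corners of a square factorize into independent margins,
so that layout would be *independent*. We instead place the four
clusters on $(\pm 1, 0)$ and $(0, \pm 1)$: the cluster-level variables
are uncorrelated yet strongly dependent, which is precisely the regime
where a dependence metric should beat a linear one.

Per-family noise standard deviations (linear 1.5, power 4, threshold
0.8, quadripartite 0.1, parabolic 1) were chosen so that at $n = 30$ the
*best* metric's power lies in the informative mid-range (roughly 0.5 to
0.95): with too little noise every metric saturates and orderings are
invisible; with too much nothing rejects. These are unitless log-scale
expression values.

Outlier contamination (`inject_outliers`, `relationship_generator`)
emulates subsampling from a cohort containing a few aberrant samples:
each drawn point is, with probability 0.03, replaced by a point
displaced 8 x-standard-deviations from the fitted line's center, either
along the line (inflating $|r|$) or perpendicular to it (deflating it).
Because the *chance of catching an outlier grows with the sample size*,
Pearson's power can genuinely *decrease* from $n = 15$ to $n = 60$ under
perpendicular contamination while distance correlation's increases —
the qualitative signature the harness checks. The displacement must be
large relative to the point cloud for the effect to dominate at
$n = 60$; 8 SD corresponds to the visibly detached off-line points that
motivate robustness concerns in real compendia.

`gen_module_expression` plants modules through a shared latent factor,
$g = \sqrt{\rho} f + \sqrt{1 - \rho}\, \varepsilon$, giving expected
within-module Pearson correlation exactly $\rho$; background genes are
independent noise and gene order is shuffled. What these fixtures do
*not* emulate: count-specific mean–variance structure, batch effects,
library-size artefacts, or correlated background — so passing recovery
tests demonstrates the pipeline's correctness on its stated model, not
robustness to every artefact of real microarray/RNA-seq data.

`gen_powerlaw_degrees` samples degrees from $P(k) \propto k^{-\gamma}$
on $1..k_{max}$; with `exact = TRUE` it returns the deterministic
rounded-expected-count sequence, the cleanest substrate for checking the
fit index.

# Validation and problem sizes

The test suite validates every numerical kernel against an independent
re-derivation: distance correlation against an explicit $O(n^2)$
double-loop oracle (100 random pairs, $n \le 50$, tolerance $10^{-10}$),
MIC's dynamic programme against exhaustive enumeration of all admissible
grids at small $n$, TOM against the triple loop up to $g = 20$, LOF
against an independently coded implementation, and the overlap Fisher
p-values against `choose()`-based hypergeometric enumeration.
Statistical behaviour is checked at simulation sizes chosen to keep the
default suite fast while leaving Monte Carlo error well inside the
asserted margins: size calibration at $\alpha = 0.05$ uses 1000
simulated independent pairs per metric ($n = 30$, 199 permutations;
acceptance band 3 binomial SEs), the cross-family AUC orderings use 300
repetitions per curve, and planted-module recovery uses 200 genes
$\times$ 100 samples over 5 seeds (adjusted Rand index $\ge 0.9$
against the planted labels, grey excluded; observed: 1.0 on all seeds).

# Known limitations

* Distance correlation is $O(n^2)$ per pair in samples and the pairwise
  pass stores one $n \times n$ centered matrix per gene block;
  thousands of genes are fine, tens of thousands call for block-wise
  streaming that this package does not implement.
* Only unsigned networks are supported; dcor cannot distinguish
  activation from repression.
* The MIC estimator is intentionally simplified (one-axis
  optimization); do not compare its absolute values against published
  MINE scores.
* The static branch cut will not reproduce `cutreeDynamic` label
  boundaries on real data; validation is against planted ground truth,
  not against WGCNA's output.
* Module eigengenes, module merging and module–trait analysis are out
  of scope.
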