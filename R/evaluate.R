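#' Power curve of a permutation independence test
#'
#' Repeatedly draws an (x, y) sample from `generator`, computes the
#' permutation p-value for the chosen metric, and tabulates the
#' proportion of rejections as a function of the significance level on a
#' 0, 0.01, ..., 1 grid. For a dependent generator this is the test's
#' power curve; for an independent generator it should hug the diagonal.
#'
#' @param generator either a relationship kind accepted by
#'   [gen_relationship()] (the sample size `n` is then required) or a
#'   `function(seed)` returning `list(x, y)` (see
#'   [relationship_generator()]).
#' @param metric dependence metric.
#' @param n sample size, used when `generator` is a kind name.
#' @param n_reps number of Monte Carlo repetitions (default 1000).
#' @param n_perm permutations per test (default 199).
#' @param seed root seed; per-repetition seeds are spawned from it.
#' @param noise_sd forwarded to [gen_relationship()] when `generator` is
#'   a kind name.
#' @return object of class `power_curve`: list with `sig_levels`,
#'   `rejection_rate`, `pvalues`, `metric`, `n_reps`.
#' @export
power_curve <- function(generator, metric = "dcor", n = NULL,
                        n_reps = 1000, n_perm = 199, seed = NULL,
                        noise_sd = NULL) {
  metric <- match_metric(metric)
  if (is.character(generator)) {
    if (is.null(n)) stop("supply the sample size n for a named generator")
    generator <- relationship_generator(generator, n = n,
                                        noise_sd = noise_sd)
  }
  stopifnot(is.function(generator), n_reps >= 1)
  seeds <- spawn_seeds(seed, 2L * n_reps)
  pvals <- vapply(seq_len(n_reps), function(i) {
    d <- generator(seeds[[2L * i - 1L]])
    indep_test(d$x, d$y, metric = metric, n_perm = n_perm,
               seed = seeds[[2L * i]])
  }, numeric(1))
  sig <- seq(0, 1, by = 0.01)
  rate <- vapply(sig, function(a) mean(pvals <= a), numeric(1))
  structure(list(sig_levels = sig, rejection_rate = rate, pvalues = pvals,
                 metric = metric, n_reps = n_reps),
            class = "power_curve")
}

#' Area under a power curve
#'
#' Trapezoidal integral of the rejection proportion over the significance
#' level. 0.5 corresponds to a test with no power (the diagonal curve);
#' values near 1 indicate the dependence is detected at tiny significance
#' levels.
#'
#' @param curve a `power_curve` object, or a list with ascending
#'   `sig_levels` and `rejection_rate`.
#' @return area in \[0, 1\].
#' @export
curve_auc <- function(curve) {
  x <- curve$sig_levels
  y <- curve$rejection_rate
  if (length(x) < 2) stop("need at least 2 grid points")
  if (is.unsorted(x)) stop("significance grid must be ascending")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Table of power-curve AUCs across relationships, sizes and metrics
#'
#' Convenience wrapper running [power_curve()] + [curve_auc()] over a
#' grid of relationship kinds, sample sizes and metrics.
#'
#' @param kinds character vector of relationship kinds.
#' @param ns integer vector of sample sizes.
#' @param metrics metrics to compare.
#' @param n_reps,n_perm,seed see [power_curve()].
#' @return data.frame with columns kind, n, metric, auc.
#' @export
auc_table <- function(kinds, ns, metrics = METRICS, n_reps = 1000,
                      n_perm = 199, seed = NULL) {
  grid <- expand.grid(kind = kinds, n = ns, metric = metrics,
                      stringsAsFactors = FALSE)
  seeds <- spawn_seeds(seed, nrow(grid))
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    curve_auc(power_curve(grid$kind[i], metric = grid$metric[i],
                          n = grid$n[i], n_reps = n_reps, n_perm = n_perm,
                          seed = seeds[[i]]))
  }, numeric(1))
  grid
}

#' Split-half stability of highly correlated gene pairs
#'
#' Randomly splits the samples into two equal halves (an odd sample is
#' dropped with a message), computes the full pairwise correlation matrix
#' for each half with the chosen metric, ranks gene pairs by the absolute
#' correlation in half 1, and for each requested `top_n` reports the mean
#' absolute difference between the two halves' coefficients over those
#' pairs. Smaller differences mean the metric's strong pairs replicate
#' better.
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param metric dependence metric.
#' @param top_ns numbers of top-ranked pairs to evaluate.
#' @param seed seed controlling the sample split.
#' @return data.frame with columns top_n and mean_abs_diff.
#' @export
split_half_stability <- function(expr, metric = "dcor",
                                 top_ns = c(100, 500, 1000), seed = NULL) {
  n <- ncol(expr)
  g <- nrow(expr)
  if (n < 4) stop("need at least 4 samples to split")
  n_pairs <- g * (g - 1) / 2
  stopifnot(all(top_ns >= 1), all(top_ns <= n_pairs))
  half <- floor(n / 2)
  if (n %% 2 == 1) message("odd sample count: dropping one sample")
  idx <- with_seed(seed, sample.int(n, 2 * half))
  c1 <- cor_matrix(expr[, idx[1:half], drop = FALSE], metric)
  c2 <- cor_matrix(expr[, idx[(half + 1):(2 * half)], drop = FALSE], metric)
  ut <- upper.tri(c1)
  v1 <- c1[ut]
  v2 <- c2[ut]
  ord <- order(-abs(v1))
  data.frame(top_n = top_ns,
             mean_abs_diff = vapply(top_ns, function(tn) {
               sel <- ord[seq_len(tn)]
               mean(abs(v1[sel] - v2[sel]))
             }, numeric(1)))
}

#' Module overlap with Fisher's exact preservation p-values
#'
#' Cross-tabulates two module partitions over the same gene universe and,
#' for each cell, tests over-enrichment of the overlap with a one-sided
#' Fisher's exact test on the collapsed 2x2 table (in/out module A
#' crossed with in/out module B); this is the hypergeometric upper tail.
#' Reports counts, p-values and -log(p) (natural log, so preservation
#' scores are on the conventional scale where values above ~50 indicate
#' very strong preservation).
#'
#' @param labels_a,labels_b named integer (or character) module labels
#'   over the same genes; 0/"grey" denotes unassigned.
#' @return list with matrices `counts`, `fisher_p`, `neg_log_p` (rows =
#'   modules of A, columns = modules of B).
#' @export
module_overlap <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop("partitions cover different gene sets")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("partitions cover different gene sets")
  }
  n <- length(labels_a)
  la <- sort(unique(labels_a))
  lb <- sort(unique(labels_b))
  counts <- table(factor(labels_a, levels = la),
                  factor(labels_b, levels = lb))
  counts <- matrix(as.integer(counts), nrow = length(la),
                   dimnames = list(as.character(la), as.character(lb)))
  ra <- rowSums(counts)
  cb <- colSums(counts)
  p <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      # hypergeometric upper tail = one-sided Fisher exact p
      p[i, j] <- stats::phyper(counts[i, j] - 1L, ra[i], n - ra[i],
                               cb[j], lower.tail = FALSE)
    }
  }
  list(counts = counts, fisher_p = p, neg_log_p = -log(p))
}

#' Fraction of strong-dcor pairs invisible to Pearson
#'
#' Among upper-triangle gene pairs whose distance correlation exceeds
#' `dcor_cut`, the fraction whose absolute Pearson correlation is below
#' `pearson_cut` - i.e. the share of strongly dependent pairs a linear
#' cut-off would discard. Returns 0 with a warning when no pair passes
#' the dcor cut.
#'
#' @param corr_pearson,corr_dcor correlation matrices over the same
#'   genes.
#' @param dcor_cut,pearson_cut thresholds (default 0.5 each).
#' @return fraction in \[0, 1\].
#' @export
complex_pair_fraction <- function(corr_pearson, corr_dcor, dcor_cut = 0.5,
                                  pearson_cut = 0.5) {
  if (!all(dim(corr_pearson) == dim(corr_dcor))) {
    stop("correlation matrices have mismatched dimensions")
  }
  ut <- upper.tri(corr_dcor)
  strong <- corr_dcor[ut] > dcor_cut
  if (!any(strong)) {
    warning("no pair exceeds the dcor cut; returning 0")
    return(0)
  }
  mean(abs(corr_pearson[ut][strong]) < pearson_cut)
}

#' Annotation-cluster enrichment score
#'
#' The enrichment score of a group of annotation terms is -log10 of the
#' geometric mean of the member p-values, equivalently the arithmetic
#' mean of -log10(p). Higher scores mean stronger joint enrichment.
#'
#' @param member_pvalues p-values in (0, 1\].
#' @return non-negative score.
#' @export
#' @examples
#' enrichment_score(c(0.01, 0.0001))  # 3
enrichment_score <- function(member_pvalues) {
  if (!length(member_pvalues)) stop("empty p-value list")
  if (any(member_pvalues <= 0 | member_pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  mean(-log10(member_pvalues))
}
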