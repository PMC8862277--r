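test_that("curve AUC integrates by trapezoid with the diagonal at 0.5", {
  full <- list(sig_levels = seq(0, 1, 0.01),
               rejection_rate = rep(1, 101))
  expect_equal(curve_auc(full), 1)
  diag_curve <- list(sig_levels = seq(0, 1, 0.01),
                     rejection_rate = seq(0, 1, 0.01))
  expect_equal(curve_auc(diag_curve), 0.5)
  # hand trapezoid: (0,0) -> (0.5,1) -> (1,1)
  pw <- list(sig_levels = c(0, 0.5, 1), rejection_rate = c(0, 1, 1))
  expect_equal(curve_auc(pw), 0.75)
  expect_error(curve_auc(list(sig_levels = c(1, 0),
                              rejection_rate = c(0, 1))), "ascending")
  # monotone under pointwise dominance
  lower <- list(sig_levels = seq(0, 1, 0.1),
                rejection_rate = seq(0, 1, 0.1)^2)
  expect_lt(curve_auc(lower), curve_auc(diag_curve))
})

test_that("power curves separate perfectly for a noiseless linear relation", {
  pc <- power_curve("linear", metric = "pearson", n = 60, n_reps = 20,
                    n_perm = 199, seed = 2, noise_sd = 0)
  expect_true(all(pc$pvalues == 1 / 200))
  # rejection is 1 at every level >= the smallest attainable p-value
  expect_true(all(pc$rejection_rate[pc$sig_levels >= 1 / 200] == 1))
  expect_s3_class(pc, "power_curve")
  # rejection_rate is non-decreasing in the significance level
  expect_true(all(diff(pc$rejection_rate) >= 0))
  # reproducibility by root seed
  pc2 <- power_curve("linear", metric = "pearson", n = 60, n_reps = 20,
                     n_perm = 199, seed = 2, noise_sd = 0)
  expect_identical(pc$pvalues, pc2$pvalues)
})

test_that("the independence generator's curve tracks the diagonal", {
  pc <- power_curve("independent", metric = "dcor", n = 30, n_reps = 150,
                    n_perm = 99, seed = 7)
  expect_lt(abs(curve_auc(pc) - 0.5), 0.08)
})

test_that("module overlap p-values equal enumerated hypergeometric tails", {
  # identical two-module partitions over 20 genes
  lab <- rep(c(1L, 2L), each = 10)
  names(lab) <- paste0("g", 1:20)
  ov <- module_overlap(lab, lab)
  expect_identical(unname(ov$counts[1, 1]), 10L)
  expect_identical(unname(ov$counts[1, 2]), 0L)
  expect_equal(unname(ov$fisher_p[1, 1]),
               bf_fisher_tail(10, 10, 10, 20), tolerance = 1e-12)
  expect_true(all(diag(ov$neg_log_p) > ov$neg_log_p[row(ov$neg_log_p) !=
                                                      col(ov$neg_log_p)]))
  # all random tables with margins <= 30 agree with the enumeration and
  # with fisher.test's one-sided p
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    la <- sample(0:2, n, replace = TRUE)
    lb <- sample(0:3, n, replace = TRUE)
    names(la) <- names(lb) <- paste0("g", 1:n)
    ov <- module_overlap(la, lb)
    for (r in rownames(ov$counts)) {
      for (cc in colnames(ov$counts)) {
        k <- ov$counts[r, cc]
        rs <- sum(ov$counts[r, ])
        cs <- sum(ov$counts[, cc])
        expect_equal(ov$fisher_p[r, cc], bf_fisher_tail(k, rs, cs, n),
                     tolerance = 1e-10)
        tab <- matrix(c(k, rs - k, cs - k, n - rs - cs + k), 2, 2)
        expect_equal(ov$fisher_p[r, cc],
                     stats::fisher.test(tab, alternative = "greater")$p.value,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("module overlap handles grey-only partitions and gene mismatch", {
  la <- c(g1 = 0L, g2 = 0L, g3 = 0L, g4 = 0L)
  lb <- c(g1 = 1L, g2 = 1L, g3 = 2L, g4 = 2L)
  ov <- module_overlap(la, lb)
  expect_true(all(ov$fisher_p == 1))
  expect_error(module_overlap(la, lb[1:3]), "different gene sets")
  # name-based alignment: shuffled order gives the same table
  ov2 <- module_overlap(la, lb[c(3, 1, 4, 2)])
  expect_identical(ov$counts, ov2$counts)
})

test_that("complex-pair fraction isolates nonlinear pairs", {
  # planted: half the strong-dcor pairs are parabolic (low pearson)
  set.seed(9)
  n <- 80
  x <- rnorm(n)
  expr <- rbind(l1 = x, l2 = x + rnorm(n, sd = 0.1),
                p1 = rnorm(n), p2 = NA)
  expr["p2", ] <- expr["p1", ]^2 + rnorm(n, sd = 0.3)
  cp <- cor_matrix(expr, "pearson")
  cd <- cor_matrix(expr, "dcor")
  strong <- cd[upper.tri(cd)] > 0.5
  expect_identical(sum(strong), 2L)  # the linear pair and the parabolic pair
  expect_equal(complex_pair_fraction(cp, cd), 0.5)
  # purely linear data: no complex pairs
  lin <- rbind(a = x, b = 2 * x + rnorm(n, sd = 0.1),
               c = -x + rnorm(n, sd = 0.1))
  expect_equal(complex_pair_fraction(cor_matrix(lin, "pearson"),
                                     cor_matrix(lin, "dcor")), 0)
  expect_warning(
    f0 <- complex_pair_fraction(cp, cd, dcor_cut = 0.999999),
    "no pair")
  expect_identical(f0, 0)
  expect_error(complex_pair_fraction(cp[1:3, 1:3], cd), "mismatch")
})

test_that("enrichment score is the mean negative log10 p-value", {
  expect_equal(enrichment_score(c(0.01, 0.0001)), 3)
  expect_equal(enrichment_score(1), 0)
  expect_equal(enrichment_score(c(0.05, 0.05, 0.05)), -log10(0.05))
  expect_error(enrichment_score(numeric(0)), "empty")
  expect_error(enrichment_score(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(enrichment_score(1.2), "\\(0, 1\\]")
})

test_that("split-half stability is zero for perfectly redundant genes", {
  # every gene is an affine copy of one profile: all |corr| = 1 in any
  # half, so the halves agree exactly
  set.seed(16)
  base <- rnorm(20)
  expr <- rbind(g1 = base, g2 = 2 * base + 1, g3 = -base, g4 = 0.5 * base)
  rownames(expr) <- paste0("g", 1:4)
  for (m in c("pearson", "dcor")) {
    st <- split_half_stability(expr, metric = m, top_ns = c(2, 6), seed = 3)
    expect_equal(st$mean_abs_diff, c(0, 0), tolerance = 1e-12)
  }
  # determinism of the split
  set.seed(17)
  expr2 <- matrix(rnorm(6 * 20), nrow = 6,
                  dimnames = list(paste0("g", 1:6), NULL))
  s1 <- split_half_stability(expr2, "pearson", top_ns = c(3, 10), seed = 5)
  s2 <- split_half_stability(expr2, "pearson", top_ns = c(3, 10), seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s2$mean_abs_diff > 0))
  expect_error(split_half_stability(expr2, top_ns = 1000, seed = 1),
               "top_ns")
})

test_that("auc_table lays out one row per kind/size/metric cell", {
  tab <- auc_table("linear", ns = 20, metrics = c("pearson", "dcor"),
                   n_reps = 25, n_perm = 49, seed = 8)
  expect_identical(nrow(tab), 2L)
  expect_identical(sort(tab$metric), c("dcor", "pearson"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})
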