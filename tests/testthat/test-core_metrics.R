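test_that("pearson and spearman match hand-computed closed forms", {
  expect_equal(cor_pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  # symmetric grid with y = x^2: zero linear correlation
  x <- seq(-1, 1, by = 0.1)
  expect_equal(cor_pearson(x, x^2), 0, tolerance = 1e-12)
  # 4-point example by hand-expanded sums: cov/(sd_x sd_y)
  x4 <- c(1, 2, 3, 4); y4 <- c(1, 3, 2, 4)
  cov_h <- sum((x4 - 2.5) * (y4 - 2.5)) / 3
  r_hand <- cov_h / (sqrt(sum((x4 - 2.5)^2) / 3) * sqrt(sum((y4 - 2.5)^2) / 3))
  expect_equal(cor_pearson(x4, y4), r_hand)

  expect_equal(cor_spearman(c(1, 2, 3), c(10, 100, 1000)), 1)
  expect_equal(cor_spearman(c(1, 2, 3), c(3, 2, 1)), -1)
  # ties -> average ranks, then the pearson formula
  x4 <- c(1, 1, 2, 3); y4 <- c(1, 2, 3, 4)
  rx <- c(1.5, 1.5, 3, 4)
  expect_equal(cor_spearman(x4, y4), cor_pearson(rx, c(1, 2, 3, 4)))
})

test_that("degenerate and invalid inputs follow the stated conventions", {
  expect_warning(p0 <- cor_pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_identical(p0, 0)
  expect_warning(d0 <- dcor(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_identical(d0, 0)
  expect_error(cor_pearson(1:3, 1:4), "same length")
  expect_error(cor_pearson(1, 1), "at least 2")
  expect_error(dcor(c(1, NA, 3), 1:3), "non-finite")
})

test_that("centered distance matrices have zero row/col sums and match the hand oracle", {
  expect_equal(dist_center(c(0, 0, 0)), matrix(0, 3, 3))
  A <- dist_center(c(0, 1))
  expect_equal(rowSums(A), c(0, 0))
  A3 <- dist_center(c(0, 1, 3))
  expect_equal(A3, bf_center(c(0, 1, 3)), tolerance = 1e-12)
  expect_equal(A3, t(A3))
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1))
    A <- dist_center(x)
    expect_lt(max(abs(rowSums(A))), 1e-10)
    expect_lt(max(abs(colSums(A))), 1e-10)
  }
})

test_that("distance covariance matches brute-force sums", {
  expect_equal(dcov_sq(rep(2, 5), rnorm(5)), 0)
  expect_equal(dcov_sq(c(0, 1, 3), c(0, 1, 3)), bf_dcov_sq(c(0, 1, 3), c(0, 1, 3)))
  expect_equal(dcov_sq(c(0, 1), c(1, 0)), bf_dcov_sq(c(0, 1), c(1, 0)))
  # V_n^2(X) = V_n^2(X, X)
  x <- rnorm(15)
  expect_equal(dcov_sq(x, x), mean(dist_center(x)^2))
})

test_that("dcor equals the O(n^2) brute-force implementation on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- if (i %% 3 == 0) x^2 + rnorm(n, sd = 0.5) else rnorm(n)
    expect_equal(dcor(x, y), bf_dcor(x, y), tolerance = 1e-10)
  }
})

test_that("dcor is symmetric, bounded and affine invariant", {
  expect_equal(dcor(1:5, 2 * (1:5) + 1), 1)
  set.seed(3)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    d <- dcor(x, y)
    expect_identical(d, dcor(y, x))
    expect_gte(d, 0)
    expect_lte(d, 1 + 1e-12)
  }
  set.seed(4)
  x <- rnorm(25); y <- x^2 + rnorm(25)
  d0 <- dcor(x, y)
  expect_equal(dcor(3.2 * x - 7, y), d0, tolerance = 1e-10)
  expect_equal(dcor(x, -0.5 * y + 2), d0, tolerance = 1e-10)
})

test_that("mic handles exact, degenerate and enumerable cases", {
  x <- as.numeric(1:16)
  expect_equal(mic(x, x), 1)
  expect_equal(mic(x, rep(1, 16)), 0)
  # 2x2 checkerboard on 8 points vs exhaustive-grid enumeration
  xc <- c(-2, -2, -1, -1, 1, 1, 2, 2)
  yc <- c(-1, 1, -1, 1, -1, 1, -1, 1)
  expect_equal(mic(xc, yc), bf_mic(xc, yc), tolerance = 1e-12)
  expect_error(mic(1:3, 1:3), "at least 4")
})

test_that("mic dynamic programme agrees with exhaustive grid search on random data", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- if (i %% 2 == 0) x + rnorm(n) else rnorm(n)
    expect_equal(mic(x, y), bf_mic(x, y), tolerance = 1e-10)
  }
})

test_that("permutation p-values honour the add-one estimator and the seed", {
  x <- rnorm(30)
  # a perfect relation is the strict maximum among permutations
  expect_equal(indep_test(x, x, metric = "dcor", n_perm = 199, seed = 9),
               1 / 200)
  for (m in c("pearson", "spearman", "mic")) {
    p1 <- indep_test(x, 2 * x + 1, metric = m, n_perm = 99, seed = 5)
    p2 <- indep_test(x, 2 * x + 1, metric = m, n_perm = 99, seed = 5)
    expect_identical(p1, p2)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
  expect_error(indep_test(x, x, metric = "kendall"))
})

test_that("null p-values are roughly uniform for a signed metric", {
  set.seed(21)
  p <- replicate(400, {
    indep_test(rnorm(20), rnorm(20), metric = "pearson", n_perm = 39)
  })
  # rejection at 0.1 within 4 binomial SEs
  expect_lt(abs(mean(p <= 0.1) - 0.1), 4 * sqrt(0.1 * 0.9 / 400))
})

test_that("cor_matrix mirrors per-pair calls and flags constant genes", {
  set.seed(8)
  expr <- matrix(rnorm(10 * 20), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  for (m in c("pearson", "spearman", "mic", "dcor")) {
    cm <- cor_matrix(expr, m)
    expect_identical(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, 10))
    expect_identical(attr(cm, "metric"), m)
  }
  cm <- cor_matrix(expr, "dcor")
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    expect_equal(cm[pair[1], pair[2]],
                 dcor(expr[pair[1], ], expr[pair[2], ]), tolerance = 1e-10)
  }
  cmm <- cor_matrix(expr, "mic")
  expect_equal(cmm[2, 7], mic(expr[2, ], expr[7, ]), tolerance = 1e-12)
  # proportional genes are perfectly similar under every metric
  expr2 <- rbind(g1 = 1:10, g2 = 2 * (1:10), g3 = rnorm(10))
  for (m in c("pearson", "spearman", "mic", "dcor")) {
    expect_equal(cor_matrix(expr2, m)[1, 2], 1, tolerance = 1e-12)
  }
  exprc <- rbind(expr2, gc = rep(1, 10))
  expect_warning(cmc <- cor_matrix(exprc, "pearson"), "constant")
  expect_equal(unname(cmc["gc", "g1"]), 0)
  expect_equal(unname(cmc["gc", "gc"]), 1)
})
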