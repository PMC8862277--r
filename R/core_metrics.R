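#' Pearson product-moment correlation of two expression profiles
#'
#' Sample linear correlation. If either profile has zero variance the
#' coefficient is undefined; by convention 0 is returned with a warning so
#' that downstream similarity matrices stay finite.
#'
#' @param x,y numeric vectors of equal length (one gene's expression
#'   across samples), finite values only, length >= 2.
#' @return a correlation in \[-1, 1\].
#' @export
#' @examples
#' cor_pearson(c(1, 2, 3), c(2, 4, 6))
cor_pearson <- function(x, y) {
  check_pair(x, y)
  if (is_constant(x) || is_constant(y)) {
    warning("constant input: Pearson correlation undefined, returning 0")
    return(0)
  }
  as.numeric(stats::cor(x, y, method = "pearson"))
}

#' Spearman rank correlation of two expression profiles
#'
#' Pearson correlation of average-ranked data (ties receive average
#' ranks). Degenerate (constant) input returns 0 with a warning.
#'
#' @inheritParams cor_pearson
#' @return a correlation in \[-1, 1\].
#' @export
cor_spearman <- function(x, y) {
  check_pair(x, y)
  if (is_constant(x) || is_constant(y)) {
    warning("constant input: Spearman correlation undefined, returning 0")
    return(0)
  }
  as.numeric(stats::cor(x, y, method = "spearman"))
}

is_constant <- function(x) {
  max(x) - min(x) == 0
}

#' Doubly centered pairwise distance matrix
#'
#' Builds the n x n matrix of absolute pairwise differences
#' \eqn{a_{kl} = |x_k - x_l|} and double-centers it:
#' \eqn{A_{kl} = a_{kl} - \bar a_{k.} - \bar a_{.l} + \bar a_{..}}.
#' Every row and column of the result sums to zero, which is the property
#' the distance covariance rests on.
#'
#' @param x numeric vector, length >= 2, finite values only.
#' @return a symmetric n x n matrix with zero row/column sums.
#' @export
dist_center <- function(x) {
  check_sample_vector(x, "x")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  a <- abs(outer(x, x, "-"))
  rm <- rowMeans(a)
  a - rm - rep(rm, each = n) + mean(a)
}

#' Squared empirical distance covariance
#'
#' \eqn{V_n^2(X, Y) = n^{-2} \sum_{k,l} A_{kl} B_{kl}} where A and B are
#' the doubly centered distance matrices of x and y. Always non-negative
#' up to floating-point error; tiny negative round-off is clamped to 0.
#'
#' @inheritParams cor_pearson
#' @return a non-negative scalar.
#' @export
dcov_sq <- function(x, y) {
  check_pair(x, y)
  v <- mean(dist_center(x) * dist_center(y))
  max(v, 0)
}

#' Empirical distance correlation
#'
#' The energy-statistics dependence measure
#' \eqn{R_n = \sqrt{V_n^2(X,Y) / \sqrt{V_n^2(X) V_n^2(Y)}}}, bounded in
#' \[0, 1\], equal to 1 for exact univariate affine dependence and (in
#' population) 0 only under independence. When either marginal distance
#' variance is zero (a constant profile) the ratio is undefined and 0 is
#' returned with a warning.
#'
#' @inheritParams cor_pearson
#' @return a value in \[0, 1\].
#' @export
#' @examples
#' x <- rnorm(30)
#' dcor(x, 2 * x + 1)   # exactly 1
#' dcor(x, x^2)         # detects the nonlinear dependence
dcor <- function(x, y) {
  check_pair(x, y)
  A <- dist_center(x)
  B <- dist_center(y)
  vx <- mean(A * A)
  vy <- mean(B * B)
  if (vx * vy <= 0) {
    warning("constant input: distance correlation undefined, returning 0")
    return(0)
  }
  vxy <- max(mean(A * B), 0)
  r2 <- vxy / sqrt(vx * vy)
  sqrt(min(max(r2, 0), 1))
}

#' Simplified maximal information coefficient
#'
#' Maximum over r x c grids (r, c >= 2, r * c <= B(n) = n^alpha) of the
#' normalized mutual information \eqn{MI / \log_2 \min(r, c)}. This is a
#' simplified estimator: one axis is split into equal-frequency bins and
#' the partition of the other axis is optimized by dynamic programming
#' over equal-frequency "superclumps" (at most `max_clumps_factor * r` of
#' them); both orientations are searched and the larger value kept.
#' Values can therefore differ slightly from the original MINE
#' ApproxMaxMI estimator. The grid bound is floored at 4 so that a 2 x 2
#' grid is always admissible.
#'
#' @inheritParams cor_pearson
#' @param alpha exponent of the grid-size bound B(n) = n^alpha, in (0, 1\];
#'   default 0.6.
#' @param max_clumps_factor multiple of the row count used as the number
#'   of candidate superclumps on the optimized axis; default 15.
#' @return a value in \[0, 1\]; 0 for constant input.
#' @export
mic <- function(x, y, alpha = 0.6, max_clumps_factor = 15) {
  check_pair(x, y, min_n = 4L)
  stopifnot(alpha > 0, alpha <= 1, max_clumps_factor >= 1)
  if (is_constant(x) || is_constant(y)) return(0)
  mic_cpp(as.numeric(x), as.numeric(y), alpha, max_clumps_factor)
}

#' Permutation test of independence for any supported metric
#'
#' Tests H0: X and Y independent against H1: dependent by permuting y and
#' recomputing the dependence statistic (|r| for the signed Pearson and
#' Spearman metrics; dcor and MIC are already non-negative). The p-value
#' uses the add-one estimator
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}
#' so p = 0 never occurs. Deterministic for a given seed.
#'
#' @inheritParams cor_pearson
#' @param metric one of `"pearson"`, `"spearman"`, `"mic"`, `"dcor"`.
#' @param n_perm number of permutations (default 199).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' x <- rnorm(30)
#' indep_test(x, x + rnorm(30), metric = "dcor", seed = 1)
indep_test <- function(x, y, metric = "dcor", n_perm = 199L, seed = NULL) {
  metric <- match_metric(metric)
  n <- check_pair(x, y, min_n = if (metric == "mic") 4L else 2L)
  stopifnot(n_perm >= 1)
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(n))
    stats <- perm_stats(metric, x, y, perms)
    (1 + sum(stats$perm >= stats$obs)) / (1 + n_perm)
  })
}

# Observed statistic and its permutation distribution (y permuted only).
# Each metric gets a fast path: the Pearson/Spearman statistic reuses
# centered/ranked data; dcor reuses the centered distance matrices, which
# stay doubly centered under a simultaneous row/column permutation; MIC
# loops in C++.
perm_stats <- function(metric, x, y, perms) {
  n_perm <- ncol(perms)
  switch(metric,
    pearson = ,
    spearman = {
      if (metric == "spearman") {
        x <- rank(x)
        y <- rank(y)
      }
      if (is_constant(x) || is_constant(y)) {
        return(list(obs = 0, perm = numeric(n_perm)))
      }
      xc <- x - mean(x)
      yc <- y - mean(y)
      denom <- sqrt(sum(xc^2) * sum(yc^2))
      obs <- abs(sum(xc * yc)) / denom
      perm <- abs(colSums(xc * matrix(yc[perms], nrow = length(x)))) / denom
      list(obs = obs, perm = perm)
    },
    dcor = {
      A <- dist_center(x)
      B <- dist_center(y)
      vx <- mean(A * A)
      vy <- mean(B * B)
      if (vx * vy <= 0) {
        return(list(obs = 0, perm = numeric(n_perm)))
      }
      denom <- sqrt(vx * vy)
      stat <- function(Bp) {
        v <- mean(A * Bp)
        if (v <= 0) 0 else sqrt(min(v / denom, 1))
      }
      perm <- vapply(seq_len(n_perm), function(i) {
        p <- perms[, i]
        stat(B[p, p, drop = FALSE])
      }, numeric(1))
      list(obs = stat(B), perm = perm)
    },
    mic = {
      if (is_constant(x) || is_constant(y)) {
        return(list(obs = 0, perm = numeric(n_perm)))
      }
      list(obs = mic_cpp(x, y, 0.6, 15),
           perm = mic_perm_cpp(x, y, perms, 0.6, 15))
    }
  )
}

#' Pairwise correlation matrix of an expression matrix
#'
#' Computes the gene-by-gene similarity matrix for the chosen metric.
#' Only the upper triangle is computed and mirrored, so the result is
#' exactly symmetric; the diagonal is 1 for non-constant genes. Constant
#' genes are flagged with a warning and their off-diagonal entries follow
#' the per-metric degenerate convention (0), with 0 on the diagonal for
#' the unsigned metrics' undefined self-correlation kept at 1 for
#' consistency with correlation-matrix semantics.
#'
#' For `metric = "dcor"` all pairs are computed in one pass: each gene's
#' doubly centered distance matrix is flattened and the pairwise
#' \eqn{V_n^2} values are obtained by a single cross-product, which keeps
#' the cost practical for thousands of genes.
#'
#' @param expr numeric genes x samples matrix with gene IDs as rownames.
#' @param metric one of `"pearson"`, `"spearman"`, `"mic"`, `"dcor"`.
#' @param block_size number of genes per block in the dcor cross-product
#'   pass (memory control; default 128).
#' @return a symmetric g x g matrix with class attribute `"metric"` set.
#' @export
cor_matrix <- function(expr, metric = "dcor", block_size = 128L) {
  metric <- match_metric(metric)
  stopifnot(is.matrix(expr), is.numeric(expr))
  g <- nrow(expr)
  n <- ncol(expr)
  if (g < 2 || n < 2) stop("need at least 2 genes and 2 samples")
  if (any(!is.finite(expr))) stop("expression matrix contains non-finite values")
  constant <- apply(expr, 1, is_constant)
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): correlations set to 0 by convention")
  }
  out <- switch(metric,
    pearson = suppressWarnings(stats::cor(t(expr), method = "pearson")),
    spearman = suppressWarnings(stats::cor(t(expr), method = "spearman")),
    dcor = dcor_matrix(expr, block_size),
    mic = mic_matrix_cpp(expr, 0.6, 15)
  )
  if (any(constant)) {
    out[constant, ] <- 0
    out[, constant] <- 0
  }
  out[!is.finite(out)] <- 0
  diag(out) <- 1
  out <- (out + t(out)) / 2   # enforce exact symmetry
  dimnames(out) <- list(rownames(expr), rownames(expr))
  attr(out, "metric") <- metric
  out
}

# All-pairs distance correlation via one cross-product over flattened
# centered distance matrices: V2[i, j] = mean(A_i * A_j).
dcor_matrix <- function(expr, block_size = 128L) {
  g <- nrow(expr)
  n <- ncol(expr)
  out <- matrix(0, g, g)
  vdiag <- numeric(g)
  n_blocks <- ceiling(g / block_size)
  blocks <- split(seq_len(g), ceiling(seq_len(g) / block_size))
  flat <- function(idx) {
    m <- matrix(0, n * n, length(idx))
    for (j in seq_along(idx)) m[, j] <- as.vector(dist_center(expr[idx[j], ]))
    m
  }
  for (bi in seq_len(n_blocks)) {
    Fi <- flat(blocks[[bi]])
    vdiag[blocks[[bi]]] <- colMeans(Fi * Fi)
    for (bj in bi:n_blocks) {
      Fj <- if (bj == bi) Fi else flat(blocks[[bj]])
      out[blocks[[bi]], blocks[[bj]]] <- crossprod(Fi, Fj) / (n * n)
    }
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  denom <- sqrt(outer(vdiag, vdiag))
  r2 <- ifelse(denom > 0, pmax(out, 0) / denom, 0)
  sqrt(pmin(pmax(r2, 0), 1))
}
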