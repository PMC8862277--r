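# Independent brute-force oracles. These deliberately re-derive every
# quantity from its definition with explicit loops, sharing no code with
# the package implementation.

# distance correlation via explicit double loops over the three V_n^2 sums
bf_dcor <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n)
  b <- matrix(0, n, n)
  for (k in 1:n) {
    for (l in 1:n) {
      a[k, l] <- abs(x[k] - x[l])
      b[k, l] <- abs(y[k] - y[l])
    }
  }
  center <- function(m) {
    A <- matrix(0, n, n)
    gm <- sum(m) / n^2
    for (k in 1:n) {
      for (l in 1:n) {
        A[k, l] <- m[k, l] - sum(m[k, ]) / n - sum(m[, l]) / n + gm
      }
    }
    A
  }
  A <- center(a)
  B <- center(b)
  vxy <- 0; vx <- 0; vy <- 0
  for (k in 1:n) {
    for (l in 1:n) {
      vxy <- vxy + A[k, l] * B[k, l]
      vx <- vx + A[k, l]^2
      vy <- vy + B[k, l]^2
    }
  }
  vxy <- vxy / n^2; vx <- vx / n^2; vy <- vy / n^2
  if (vx * vy <= 0) return(0)
  sqrt(max(vxy, 0) / sqrt(vx * vy))
}

bf_dcov_sq <- function(x, y) {
  n <- length(x)
  A <- bf_center(x)
  B <- bf_center(y)
  s <- 0
  for (k in 1:n) for (l in 1:n) s <- s + A[k, l] * B[k, l]
  max(s / n^2, 0)
}

bf_center <- function(x) {
  n <- length(x)
  a <- matrix(0, n, n)
  for (k in 1:n) for (l in 1:n) a[k, l] <- abs(x[k] - x[l])
  A <- matrix(0, n, n)
  for (k in 1:n) {
    for (l in 1:n) {
      A[k, l] <- a[k, l] - mean(a[k, ]) - mean(a[, l]) + mean(a)
    }
  }
  A
}

# Exhaustive-search MIC over the same grid family as the estimator:
# one axis equal-frequency binned into c parts, the other cut at
# superclump boundaries into exactly r contiguous parts, enumerating all
# boundary subsets instead of using dynamic programming.
bf_mic <- function(x, y, alpha = 0.6, cfactor = 15) {
  n <- length(x)
  B <- max(4, floor(n^alpha))
  equi <- function(v, c) {
    bin <- integer(n)
    ord <- order(v)
    for (pos in seq_len(n)) bin[ord[pos]] <- floor((pos - 1) * c / n) + 1L
    bin
  }
  mi_bits <- function(ubin, vbin) {
    tab <- table(ubin, vbin)
    p <- tab / n
    pu <- rowSums(p); pv <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(ncol(p))) {
        if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pu[i] * pv[j]))
      }
    }
    s
  }
  best <- 0
  for (orient in 1:2) {
    u <- if (orient == 1) x else y
    v <- if (orient == 1) y else x
    ordu <- order(u)
    for (c in 2:max(2, B %/% 2)) {
      if (2 * c > B) next
      rmax <- B %/% c
      vbin <- equi(v, c)
      s <- min(n, ceiling(cfactor * rmax))
      bounds <- floor(seq_len(s) * n / s)  # superclump right edges
      for (r in 2:rmax) {
        cuts <- utils::combn(s - 1, r - 1, simplify = FALSE)
        for (cut in cuts) {
          edges <- c(0, bounds[cut], n)
          ubin <- integer(n)
          for (part in seq_len(r)) {
            pos <- (edges[part] + 1):edges[part + 1]
            ubin[ordu[pos]] <- part
          }
          val <- mi_bits(ubin, vbin) / log2(min(r, c))
          if (val > best) best <- val
        }
      }
    }
  }
  min(best, 1)
}

# TOM by triple loop from the definition
bf_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  g <- nrow(a)
  k <- rowSums(a)
  omega <- matrix(0, g, g)
  for (i in 1:g) {
    for (j in 1:g) {
      if (i == j) { omega[i, j] <- 1; next }
      l <- 0
      for (u in 1:g) l <- l + a[i, u] * a[u, j]
      omega[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  omega
}

# LOF re-derived independently (loops, explicit k-distance neighbourhood)
bf_lof <- function(x, y, k) {
  n <- length(x)
  d <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) d[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  }
  kdist <- numeric(n)
  nb <- vector("list", n)
  for (i in 1:n) {
    others <- sort(d[i, -i])
    kdist[i] <- others[k]
    nb[[i]] <- setdiff(which(d[i, ] <= kdist[i]), i)
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in nb[[i]]) s <- s + max(kdist[j], d[i, j])
    lrd[i] <- length(nb[[i]]) / s
  }
  lof <- numeric(n)
  for (i in 1:n) {
    s <- 0
    for (j in nb[[i]]) s <- s + lrd[j]
    lof[i] <- (s / length(nb[[i]])) / lrd[i]
  }
  lof
}

# one-sided (over-enrichment) Fisher p for a 2x2 collapse by explicit
# hypergeometric enumeration with choose()
bf_fisher_tail <- function(k11, rowsum, colsum, total) {
  hi <- min(rowsum, colsum)
  if (k11 > hi) return(0)
  s <- 0
  for (t in k11:hi) {
    s <- s + choose(rowsum, t) * choose(total - rowsum, colsum - t)
  }
  s / choose(total, colsum)
}

# planted two-block dissimilarity fixture for clustering tests
block_diss <- function(sizes = c(5, 5), within = 0.1, between = 0.9) {
  g <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, g, g)
  for (m in seq_along(sizes)) d[lab == m, lab == m] <- within
  diag(d) <- 0
  d
}
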