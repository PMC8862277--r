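#' Unsigned similarity from a correlation matrix
#'
#' Elementwise absolute value, turning signed Pearson/Spearman
#' correlations into the unsigned co-expression similarity; dcor and MIC
#' matrices are already non-negative and pass through unchanged.
#'
#' @param corr symmetric correlation matrix (optionally carrying a
#'   `"metric"` attribute from [cor_matrix()]).
#' @return matrix of similarities in \[0, 1\].
#' @export
similarity <- function(corr) {
  out <- abs(corr)
  attr(out, "metric") <- attr(corr, "metric")
  out
}

#' Soft-threshold adjacency
#'
#' Raises the unsigned similarity elementwise to the power beta,
#' suppressing weak similarities relative to strong ones (weighted
#' network construction).
#'
#' @param sim similarity matrix with entries in \[0, 1\].
#' @param beta soft-thresholding power, a positive integer.
#' @return adjacency matrix in \[0, 1\] with attribute `"beta"`.
#' @export
adjacency <- function(sim, beta) {
  stopifnot(beta >= 1)
  if (any(sim < 0 | sim > 1)) stop("similarity entries must lie in [0, 1]")
  out <- sim^beta
  attr(out, "beta") <- beta
  out
}

#' Weighted connectivity per gene
#'
#' k_i = sum over j != i of a_ij (the diagonal is excluded).
#'
#' @param adj symmetric adjacency matrix.
#' @return numeric connectivity vector.
#' @export
connectivity <- function(adj) {
  rowSums(adj) - diag(adj)
}

#' Scale-free-topology fit index
#'
#' Bins the connectivity vector into `n_bins` equal-width bins, drops
#' empty bins, and regresses log10 of the bin frequency p(k) on log10 of
#' the mean connectivity per bin. Returns the signed fit index
#' -sign(slope) * R^2, so a decreasing power-law degree distribution
#' p(k) ~ k^(-gamma) scores close to +1 while an increasing distribution
#' is penalized.
#'
#' @param k connectivity vector (positive values).
#' @param n_bins number of equal-width bins (default 10).
#' @return signed fit index in \[-1, 1\].
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2) stop("need at least 2 positive connectivity values")
  if (max(k) == min(k)) {
    stop("all connectivities equal: fewer than 2 usable bins")
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- counts > 0
  if (sum(keep) < 2) {
    stop("fewer than 2 non-empty connectivity bins; cannot fit power law")
  }
  pk <- counts[keep] / length(k)
  mean_k <- vapply(which(keep), function(b) mean(k[as.integer(bin) == b]),
                   numeric(1))
  lp <- log10(pk)
  lk <- log10(mean_k)
  r <- stats::cor(lp, lk)
  -sign(r) * r^2
}

#' Soft-threshold selection by scale-free-topology fit
#'
#' For each candidate power, builds the adjacency, computes the
#' connectivity distribution and its scale-free fit index, and recommends
#' the smallest power whose fit index reaches `target` (0.9 by
#' convention). If no candidate reaches the target a warning is issued
#' and `recommended_power` is `NA`.
#'
#' @param expr genes x samples matrix (ignored when `sim` is supplied).
#' @param metric correlation metric used to build the similarity when
#'   `sim` is not supplied.
#' @param powers ascending candidate powers (default 1:20).
#' @param target fit-index target (default 0.9).
#' @param sim optional precomputed similarity matrix.
#' @param n_bins bins for [scale_free_fit()].
#' @return list with `report` (data.frame: power, fit_index,
#'   mean_connectivity) and `recommended_power`.
#' @export
pick_soft_threshold <- function(expr = NULL, metric = "dcor",
                                powers = 1:20, target = 0.9, sim = NULL,
                                n_bins = 10) {
  stopifnot(length(powers) >= 1, !is.unsorted(powers), all(powers >= 1))
  if (is.null(sim)) {
    if (is.null(expr)) stop("supply either expr or sim")
    sim <- similarity(cor_matrix(expr, metric))
  }
  rows <- lapply(powers, function(beta) {
    adj <- adjacency(sim, beta)
    k <- connectivity(adj)
    fit <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                    error = function(e) NA_real_)
    data.frame(power = beta, fit_index = fit, mean_connectivity = mean(k))
  })
  report <- do.call(rbind, rows)
  hit <- which(!is.na(report$fit_index) & report$fit_index >= target)
  recommended <- if (length(hit)) report$power[hit[1]] else NA_integer_
  if (is.na(recommended)) {
    warning("no candidate power reaches fit-index target ", target)
  }
  list(report = report, recommended_power = recommended)
}

#' Topological overlap matrix
#'
#' Unsigned TOM: with l_ij = sum_u a_iu a_uj (diagonal of the adjacency
#' excluded) and k_i the connectivity,
#' omega_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), omega_ii = 1.
#' Two genes overlap strongly when they are directly connected and share
#' neighbours.
#'
#' @param adj symmetric adjacency with entries in \[0, 1\].
#' @return symmetric TOM in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  minK <- outer(k, k, pmin)
  denom <- minK + 1 - a
  denom[denom < .Machine$double.eps] <- .Machine$double.eps
  omega <- (l + a) / denom
  diag(omega) <- 1
  omega <- pmin(pmax(omega, 0), 1)
  omega <- (omega + t(omega)) / 2
  out <- matrix(as.numeric(omega), nrow(adj), ncol(adj))
  dimnames(out) <- dimnames(adj)
  out
}

#' TOM dissimilarity
#'
#' 1 - TOM, with zero diagonal; the clustering input.
#'
#' @param tomM topological overlap matrix in \[0, 1\].
#' @return dissimilarity matrix.
#' @export
tom_dissimilarity <- function(tomM) {
  d <- 1 - tomM
  diag(d) <- 0
  d
}
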