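#' Read an expression matrix from delimited text
#'
#' Expects a rectangular table with a header row of sample IDs and a
#' first column of gene IDs (or the transpose, with `transpose = TRUE`).
#' Genes are always on rows in the returned matrix.
#'
#' @param path file path.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @param transpose set `TRUE` when the file has samples on rows.
#' @return numeric genes x samples matrix with dimnames.
#' @export
read_expression <- function(path, sep = "\t", transpose = FALSE) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate row identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate column identifier(s)", call. = FALSE)
  }
  message("read expression matrix: ", nrow(m), " genes x ", ncol(m),
          " samples")
  m
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression()]: header row of sample IDs, first column
#' (`gene_id`) of gene IDs. Values are written with full double precision
#' so a read/write round trip is lossless to better than 12 significant
#' digits.
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Elementwise log2(x + 1) transform
#'
#' Standard variance-stabilizing transform for non-negative normalized
#' counts.
#'
#' @param expr numeric matrix with values >= 0.
#' @return transformed matrix.
#' @export
log2_plus1 <- function(expr) {
  if (any(expr < 0, na.rm = TRUE)) {
    stop("negative values: log2(x + 1) expects non-negative input")
  }
  log2(expr + 1)
}

#' Filter genes by mean intensity and coefficient of variation
#'
#' Keeps genes whose mean expression strictly exceeds the grand mean of
#' all per-gene means AND whose coefficient of variation (sd / mean)
#' exceeds `cv_threshold`. Genes with zero mean (CV undefined) are
#' excluded and counted in the report. Both statistics are computed on
#' the matrix as given (no back-transformation).
#'
#' The mean threshold defaults to the grand mean of the input matrix and
#' is recorded in the report; re-applying the filter with that recorded
#' threshold leaves a filtered matrix unchanged.
#'
#' @param expr genes x samples matrix.
#' @param cv_threshold CV cut as a fraction (default 0.05, i.e. 5%).
#' @param mean_threshold intensity cut; defaults to the grand mean of the
#'   per-gene means of `expr`.
#' @return list with `expr` (the filtered matrix) and `report` (counts
#'   and thresholds).
#' @export
filter_genes <- function(expr, cv_threshold = 0.05, mean_threshold = NULL) {
  stopifnot(is.matrix(expr), nrow(expr) >= 1)
  mu <- rowMeans(expr)
  s <- apply(expr, 1, sd)
  grand <- if (is.null(mean_threshold)) mean(mu) else mean_threshold
  cv <- ifelse(mu != 0, s / mu, NA_real_)
  zero_mean <- sum(mu == 0)
  if (zero_mean > 0) {
    message(zero_mean, " gene(s) with zero mean excluded (CV undefined)")
  }
  keep <- !is.na(cv) & mu > grand & cv > cv_threshold
  report <- list(n_input_genes = nrow(expr),
                 n_kept_genes = sum(keep),
                 n_zero_mean = zero_mean,
                 mean_threshold = grand,
                 cv_threshold = cv_threshold)
  list(expr = expr[keep, , drop = FALSE], report = report)
}

#' Fraction of genes passing a Shapiro-Wilk normality screen
#'
#' Applies the Shapiro-Wilk test to each gene's expression profile and
#' returns the fraction of genes with p > `alpha`, i.e. the fraction one
#' would call approximately normally distributed at that level.
#'
#' @param expr genes x samples matrix; 3 <= samples <= 5000 (the test's
#'   validity range).
#' @param alpha screening level (default 0.01).
#' @return fraction in \[0, 1\].
#' @export
normality_fraction <- function(expr, alpha = 0.01) {
  n <- ncol(expr)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires between 3 and 5000 samples")
  }
  p <- apply(expr, 1, function(g) stats::shapiro.test(g)$p.value)
  mean(p > alpha)
}

#' Local outlier factor for a 2-D gene pair
#'
#' Density-based outlier scores for the points (x_i, y_i): the LOF of a
#' point is the mean ratio of its k-nearest-neighbours' local reachability
#' density to its own. Scores near 1 indicate inliers; scores well above
#' 1 indicate points in sparser regions than their neighbours.
#'
#' @param x,y coordinates.
#' @param k neighbourhood size (default 5); must satisfy 1 <= k < n.
#' @return numeric LOF score per point.
#' @export
lof_scores <- function(x, y, k = 5) {
  n <- check_pair(x, y)
  stopifnot(k >= 1, k < n)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  # k-distance and k-neighbourhood (all points within the k-distance,
  # so ties are included)
  kdist <- apply(d, 1, function(r) sort(r)[k])
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= kdist[i]))
  lrd <- vapply(seq_len(n), function(i) {
    nb <- neigh[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    mean(lrd[neigh[[i]]]) / lrd[i]
  }, numeric(1))
}

#' Flag 2-D outliers by LOF threshold
#'
#' @inheritParams lof_scores
#' @param threshold LOF score above which a point is flagged (default
#'   1.5).
#' @return logical vector of flags.
#' @export
lof_outliers <- function(x, y, k = 5, threshold = 1.5) {
  lof_scores(x, y, k = k) > threshold
}
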