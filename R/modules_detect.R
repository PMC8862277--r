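#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' UPGMA merge tree over genes; the standard clustering step applied to
#' the TOM dissimilarity.
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal.
#' @return an object of class `hclust`.
#' @export
hclust_average <- function(diss) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Cut a dendrogram into minimum-size modules
#'
#' Static-height branch decomposition: the tree is cut at
#' `cut_height_fraction` times the maximum merge height; every branch
#' below the cut with at least `min_cluster_size` leaves becomes a
#' module, renumbered by decreasing size (ties broken by the smallest
#' contained gene index); all remaining genes are unassigned (label 0,
#' the grey module).
#'
#' @param dendro an `hclust` tree over the genes.
#' @param min_cluster_size smallest admissible module (default 30).
#' @param cut_height_fraction cut height as a fraction of the maximum
#'   merge height, in (0, 1\] (default 0.99).
#' @return integer module labels (0 = unassigned), named by the tree's
#'   labels when present.
#' @export
cut_tree_modules <- function(dendro, min_cluster_size = 30,
                             cut_height_fraction = 0.99) {
  stopifnot(inherits(dendro, "hclust"),
            cut_height_fraction > 0, cut_height_fraction <= 1)
  g <- length(dendro$order)
  if (min_cluster_size > g) stop("min_cluster_size exceeds number of genes")
  # average linkage is monotone up to floating-point noise in tied
  # merges; clamp sub-tolerance inversions so cutree accepts the tree
  if (is.unsorted(dendro$height)) {
    if (max(dendro$height - cummax(dendro$height)) > 1e-8) {
      stop("dendrogram heights are not non-decreasing")
    }
    dendro$height <- cummax(dendro$height)
  }
  h <- cut_height_fraction * max(dendro$height)
  raw <- if (h >= max(dendro$height)) {
    rep(1L, g)
  } else {
    stats::cutree(dendro, h = h)
  }
  sizes <- table(raw)
  big <- as.integer(names(sizes)[sizes >= min_cluster_size])
  labels <- integer(g)
  if (length(big)) {
    ord <- order(-sizes[as.character(big)],
                 vapply(big, function(b) min(which(raw == b)), integer(1)))
    for (new_id in seq_along(ord)) {
      labels[raw == big[ord[new_id]]] <- new_id
    }
  }
  names(labels) <- dendro$labels
  labels
}

# Colour sequence used for module display, by decreasing module size
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Map module labels to colour names
#'
#' Module 1 (the largest) is turquoise, module 2 blue, and so on through
#' the conventional colour sequence; label 0 is grey. Labels beyond the
#' colour list fall back to `"module<k>"`.
#'
#' @param labels integer module labels as returned by
#'   [cut_tree_modules()].
#' @return character vector of colour names, same names as `labels`.
#' @export
assign_colors <- function(labels) {
  stopifnot(is.numeric(labels), all(labels >= 0))
  out <- ifelse(labels == 0, "grey",
                ifelse(labels <= length(MODULE_COLORS),
                       MODULE_COLORS[pmax(labels, 1)],
                       paste0("module", labels)))
  names(out) <- names(labels)
  out
}

#' Full co-expression module detection pipeline
#'
#' similarity -> soft-threshold selection -> adjacency -> TOM ->
#' average-linkage dendrogram -> static branch cut. The correlation
#' matrix is computed once with the chosen metric. If no candidate power
#' reaches the fit target (which happens whenever the data are not even
#' approximately scale-free, e.g. a few equally sized planted modules)
#' the conventional unsigned-network default power for the sample size is
#' used instead: 6 for >= 40 samples, 7 for 30-39, 8 for 20-29, 9 below.
#'
#' @param expr genes x samples matrix.
#' @param metric correlation metric (default `"dcor"`).
#' @param powers candidate soft-threshold powers.
#' @param sft_target scale-free fit target (default 0.9).
#' @param min_cluster_size,cut_height_fraction see [cut_tree_modules()].
#' @return list with `labels`, `colors`, `dendro`, `sft` (the
#'   soft-threshold report), `beta` (the power used) and `similarity`.
#' @export
detect_modules <- function(expr, metric = "dcor", powers = 1:20,
                           sft_target = 0.9, min_cluster_size = 30,
                           cut_height_fraction = 0.99) {
  sim <- similarity(cor_matrix(expr, metric))
  sft <- pick_soft_threshold(sim = sim, powers = powers, target = sft_target)
  beta <- sft$recommended_power
  if (is.na(beta)) {
    n <- ncol(expr)
    beta <- if (n >= 40) 6L else if (n >= 30) 7L else if (n >= 20) 8L else 9L
    message("falling back to default unsigned power beta = ", beta)
  }
  adj <- adjacency(sim, beta)
  diss <- tom_dissimilarity(tom_similarity(adj))
  dendro <- hclust_average(diss)
  labels <- cut_tree_modules(dendro, min_cluster_size = min_cluster_size,
                             cut_height_fraction = cut_height_fraction)
  names(labels) <- rownames(expr)
  list(labels = labels, colors = assign_colors(labels), dendro = dendro,
       sft = sft$report, beta = beta, similarity = sim)
}
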