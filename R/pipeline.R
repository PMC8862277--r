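#' Split-half module preservation
#'
#' Randomly splits the samples into two equal halves, detects modules
#' independently in each half with the same settings, and cross-tabulates
#' the two partitions with one-sided Fisher's exact tests
#' ([module_overlap()]). Strong diagonal-like -log(p) values indicate
#' that modules replicate across halves.
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param metric dependence metric.
#' @param seed seed controlling the split.
#' @param ... passed to [detect_modules()].
#' @return list with `overlap` (see [module_overlap()]) and the two
#'   half-specific detection results `half1`, `half2`.
#' @export
split_half_preservation <- function(expr, metric = "dcor", seed = NULL,
                                    ...) {
  n <- ncol(expr)
  if (n < 4) stop("need at least 4 samples to split")
  half <- floor(n / 2)
  idx <- with_seed(seed, sample.int(n, 2 * half))
  r1 <- detect_modules(expr[, idx[1:half], drop = FALSE], metric, ...)
  r2 <- detect_modules(expr[, idx[(half + 1):(2 * half)], drop = FALSE],
                       metric, ...)
  list(overlap = module_overlap(r1$labels, r2$labels),
       half1 = r1, half2 = r2)
}

#' Write a module partition as a two-column TSV
#'
#' Columns `gene_id` and `module_colour`.
#'
#' @param labels named integer labels (see [cut_tree_modules()]).
#' @param path output path.
#' @export
write_modules_tsv <- function(labels, path) {
  df <- data.frame(gene_id = names(labels),
                   module_colour = assign_colors(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write per-module gene lists in GMT-style lines
#'
#' One line per non-grey module: colour name, a description, then the
#' member gene IDs, tab-separated - the layout external enrichment tools
#' ingest.
#'
#' @inheritParams write_modules_tsv
#' @export
write_modules_gmt <- function(labels, path) {
  colors <- assign_colors(labels)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in sort(unique(labels[labels > 0]))) {
    genes <- names(labels)[labels == m]
    writeLines(paste(c(colors[labels == m][1],
                       paste0("module_", m, "_n", length(genes)), genes),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a flat key-value config snapshot
#'
#' One `key: value` line per entry, so a run can be reproduced from its
#' output directory.
#'
#' @param config named list of scalar settings.
#' @param path output path.
#' @export
write_config_snapshot <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value config snapshot
#'
#' @param path snapshot path written by [write_config_snapshot()].
#' @return named list of character values (comma-split into vectors).
#' @export
read_config_snapshot <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}
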