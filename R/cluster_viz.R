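#' Z-score standardize each gene row
#'
#' Centers every row to mean 0 and scales it to SD 1, the usual heatmap
#' preparation so expression patterns rather than absolute levels drive the
#' colors. Zero-variance rows become all-zero with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @return Row-standardized matrix of the same shape.
#' @export
zscore_rows <- function(expr) {
  validate_expression(expr)
  m <- rowMeans(expr)
  s <- sqrt(rowSums((expr - m)^2) / (ncol(expr) - 1L))
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    txc_warn("%d zero-variance row(s) set to all-zero Z-scores", sum(flat))
    s[flat] <- 1
  }
  z <- (expr - m) / s
  z[flat, ] <- 0
  z
}

#' Hierarchical clustering of the selected gene set (or of samples)
#'
#' Z-scores the selected rows, computes Euclidean distances along the chosen
#' axis, builds an agglomerative tree, and cuts it into exactly `k`
#' clusters. Average linkage is the default — robust and the common choice
#' for expression heatmaps — with complete and Ward (ward.D2) available.
#' Deterministic given the input.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Selected gene ids (default: all rows).
#' @param k Number of clusters (default 6).
#' @param axis Cluster `"genes"` (rows; default) or `"samples"` (columns).
#' @param linkage One of `"average"`, `"complete"`, `"ward"`.
#' @return A cluster object: `cluster` (named index vector 1..k), `tree`
#'   (the hclust merge tree), `k`, `axis`, `order` (dendrogram leaf order).
#' @export
hierarchical_clusters <- function(expr, genes = rownames(expr), k = 6,
                                  axis = c("genes", "samples"),
                                  linkage = c("average", "complete", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  validate_expression(expr)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) txc_stop("gene '%s' not in expression matrix", missing[1L])
  z <- suppressWarnings(zscore_rows(expr[genes, , drop = FALSE]))
  items <- if (axis == "genes") z else t(z)
  if (k < 1 || k > nrow(items))
    txc_stop("k must be in [1, %d] for %d %s", nrow(items), nrow(items), axis)
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[[linkage]]
  tree <- stats::hclust(stats::dist(items), method = method)
  cl <- stats::cutree(tree, k = k)
  structure(list(cluster = cl, tree = tree, k = k, axis = axis,
                 linkage = linkage, order = tree$order),
            class = "txc_clusters")
}

#' @export
print.txc_clusters <- function(x, ...) {
  sizes <- table(x$cluster)
  cat(sprintf("Hierarchical clustering of %d %s into %d clusters (%s linkage)\n",
              length(x$cluster), x$axis, x$k, x$linkage))
  cat("  sizes:", paste(sizes, collapse = " + "), "=", length(x$cluster), "\n")
  invisible(x)
}

#' Heatmap-ready export of Z-scored expression with cluster annotations
#'
#' Returns the Z-scored selected rows in dendrogram order together with
#' their cluster labels — a thin export any plotting front-end can render.
#'
#' @param expr Expression matrix.
#' @param clusters A gene-axis result of [hierarchical_clusters()].
#' @return A data.frame: gene, cluster, then one column per sample of
#'   Z-scored expression, rows in dendrogram leaf order.
#' @export
heatmap_matrix <- function(expr, clusters) {
  if (clusters$axis != "genes")
    txc_stop("heatmap_matrix expects a gene-axis clustering")
  genes <- names(clusters$cluster)
  z <- suppressWarnings(zscore_rows(expr[genes, , drop = FALSE]))
  ord <- clusters$order
  data.frame(gene = genes[ord], cluster = unname(clusters$cluster[ord]),
             z[ord, , drop = FALSE], check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Render the cluster heatmap to a file (reference renderer)
#'
#' Convenience PNG rendering via pheatmap when available; the contractual
#' output is [heatmap_matrix()].
#'
#' @param expr Expression matrix.
#' @param clusters Gene-axis clustering.
#' @param path Output PNG path.
#' @return The path, invisibly; errors if pheatmap is not installed.
#' @export
plot_heatmap <- function(expr, clusters, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    txc_stop("pheatmap is required for rendering; use heatmap_matrix() instead")
  hm <- heatmap_matrix(expr, clusters)
  mat <- as.matrix(hm[, -(1:2), drop = FALSE])
  rownames(mat) <- hm$gene
  ann <- data.frame(cluster = factor(hm$cluster), row.names = hm$gene)
  grDevices::png(path, width = 1200, height = 1400, res = 150)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = TRUE,
                     annotation_row = ann, show_rownames = FALSE)
  invisible(path)
}
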