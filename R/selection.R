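#' Rank genes by their one-way ANOVA F-value across categories
#'
#' For every gene the classical one-way ANOVA F statistic is computed from
#' the expression matrix: the ratio of the between-category mean square to
#' the within-category mean square. Large F means the gene's expression
#' separates the categories well relative to its replicate noise. Genes are
#' returned in descending-F order (rank 1 = largest F). A gene with zero
#' within-category variance but distinct category means is a perfect
#' separator and receives `Inf`, sorting first; a gene constant everywhere
#' carries no information and receives 0. Ties are broken by gene id so the
#' ranking is deterministic.
#'
#' @param expr Expression matrix (genes x samples), typically the output of
#'   [preprocess_counts()].
#' @param meta Metadata data.frame with `category` (and `dataset` for
#'   dataset-level mode).
#' @param level `"dataset"` (default) averages replicate columns per dataset
#'   via [collapse_to_datasets()] before the ANOVA, so each dataset counts
#'   once; `"sample"` uses every column.
#' @return A data.frame with columns `gene`, `f_value`, `rank`, ordered by
#'   rank. The analysis level is stored in attribute `"level"`.
#' @export
f_values <- function(expr, meta, level = c("dataset", "sample")) {
  level <- match.arg(level)
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  if (level == "dataset") {
    coll <- collapse_to_datasets(expr, meta)
    expr <- coll$expr
    meta <- coll$meta
  }
  g <- factor(meta$category)
  k <- nlevels(g)
  n <- ncol(expr)
  if (k < 2L) txc_stop("need at least 2 categories, got %d", k)
  if (any(tabulate(g, k) == 0L)) txc_stop("a category has zero columns")
  if (n - k < 1L)
    txc_stop("no within-category degrees of freedom (%d columns, %d categories)", n, k)

  ind <- stats::model.matrix(~ 0 + g)            # n x k indicator
  n_per <- colSums(ind)
  gmeans <- expr %*% sweep(ind, 2L, n_per, "/")  # genes x k category means
  grand <- rowMeans(expr)
  ssb <- drop((gmeans - grand)^2 %*% n_per)
  centered <- expr - gmeans[, g, drop = FALSE]
  ssw <- rowSums(centered^2)
  sst <- ssb + ssw

  f <- (ssb / (k - 1)) / (ssw / (n - k))
  scale <- pmax(rowSums(expr^2), 1)
  const_everywhere <- sst <= 1e-12 * scale
  zero_within <- !const_everywhere & (ssw <= 1e-10 * sst)
  f[zero_within] <- Inf
  f[const_everywhere] <- 0

  ord <- order(-f, rownames(expr), method = "radix")
  out <- data.frame(gene = rownames(expr)[ord], f_value = f[ord],
                    rank = seq_along(f), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "level") <- level
  out
}

#' Select the optimal gene set at the elbow of the ranked F-value curve
#'
#' Draws the chord between the first and last points of the ranked F-value
#' curve and finds the rank at maximum perpendicular distance from it — the
#' elbow. Genes with F strictly above the elbow gene's F form the optimal
#' set (when that set is empty, genes tied with the elbow F are taken).
#' Because a perpendicular distance mixes the rank axis with the F axis,
#' both axes are min-max scaled to \[0, 1\] first, making the elbow
#' invariant to the absolute F scale. Infinite F sentinels are clamped just
#' above the largest finite F so the geometry stays well defined while the
#' ordering is preserved. On an exactly linear (degenerate) curve all
#' distances are zero; the smallest rank wins the tie and a warning is
#' emitted.
#'
#' @param ranking Output of [f_values()].
#' @return A selection object (list) with `method = "f_elbow"`,
#'   `selected_genes` in rank order, `elbow_index` (1-based rank of the
#'   elbow gene), the full `curve`, and `params`.
#' @export
elbow_select <- function(ranking) {
  if (nrow(ranking) < 3L)
    txc_stop("elbow selection needs at least 3 ranked genes, got %d", nrow(ranking))
  f <- ranking$f_value
  finite_max <- max(f[is.finite(f)], 0)
  f_clamped <- ifelse(is.infinite(f), finite_max * (1 + 1e-6) + 1e-12, f)

  n <- length(f_clamped)
  x <- (seq_len(n) - 1) / (n - 1)
  yr <- range(f_clamped)
  y <- if (diff(yr) > 0) (f_clamped - yr[1L]) / diff(yr) else rep(0, n)
  # perpendicular distance to the chord through the first and last point
  a <- c(x[1L], y[1L]); b <- c(x[n], y[n])
  chord <- b - a
  dist <- abs(chord[2L] * (x - a[1L]) - chord[1L] * (y - a[2L])) /
    sqrt(sum(chord^2))
  # smallest rank wins among distances tied (to float tolerance) at the max
  elbow <- which(dist >= max(dist) - 1e-12)[1L]
  if (max(dist) < 1e-10)
    txc_warn("degenerate (linear) F-value curve: all chord distances ~0, elbow set to rank 1")

  f_elbow <- f[elbow]
  sel <- which(f > f_elbow)
  if (!length(sel)) sel <- which(f == f_elbow)
  new_selection("f_elbow", ranking$gene[sel], ranking,
                elbow_index = elbow,
                params = list(scaling = "minmax"))
}

#' Select the k genes with largest across-sample variance
#'
#' The conventional default of MDS front-ends: no category labels are used,
#' genes are ordered by variance of transformed expression. Serves as the
#' unsupervised baseline against which elbow selection is compared.
#'
#' @param expr Expression matrix (genes x samples).
#' @param k Number of genes (default 500); `k` above the gene count returns
#'   all genes. Variance ties at the cutoff resolve by gene id.
#' @return A selection object with `method = "variance_topk"`.
#' @export
variance_topk_select <- function(expr, k = 500) {
  validate_expression(expr)
  if (k < 1) txc_stop("k must be >= 1")
  v <- rowSums((expr - rowMeans(expr))^2) / (ncol(expr) - 1L)
  ord <- order(-v, rownames(expr), method = "radix")
  k <- min(k, nrow(expr))
  curve <- data.frame(gene = rownames(expr)[ord], f_value = v[ord],
                      rank = seq_along(v), stringsAsFactors = FALSE)
  new_selection("variance_topk", curve$gene[seq_len(k)], curve,
                params = list(k = k))
}

new_selection <- function(method, genes, curve, elbow_index = NA_integer_,
                          params = list()) {
  structure(list(method = method, selected_genes = genes,
                 elbow_index = elbow_index, curve = curve, params = params),
            class = "txc_selection")
}

#' @export
print.txc_selection <- function(x, ...) {
  cat(sprintf("Gene selection (%s): %d of %d genes selected\n",
              x$method, length(x$selected_genes), nrow(x$curve)))
  if (!is.na(x$elbow_index))
    cat(sprintf("  elbow at rank %d (F = %.4g)\n", x$elbow_index,
                x$curve$f_value[x$elbow_index]))
  invisible(x)
}

#' Run a configured gene selector
#'
#' Dispatch helper used by the cross-validation and pipeline code: runs the
#' selector named by `method` with its parameters on an expression matrix.
#'
#' @param expr Expression matrix.
#' @param meta Metadata data.frame.
#' @param method One of `"f_elbow"`, `"variance_topk"`, `"shadow_feature"`.
#' @param level Analysis level passed to [f_values()].
#' @param ... Further parameters for the selector (e.g. `k`, `n_iter`,
#'   `alpha`, `seed`).
#' @return A selection object.
#' @export
select_genes <- function(expr, meta,
                         method = c("f_elbow", "variance_topk", "shadow_feature"),
                         level = "dataset", ...) {
  method <- match.arg(method)
  switch(method,
         f_elbow = elbow_select(f_values(expr, meta, level = level)),
         variance_topk = variance_topk_select(expr, ...),
         shadow_feature = shadow_feature_select(expr, meta, ...))
}
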