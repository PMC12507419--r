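#' Spearman correlation over pairwise-complete observations
#'
#' Positions missing in either vector are dropped; the remaining values are
#' mid-ranked (average ranks on ties) and Pearson-correlated. Needs at least
#' 3 complete pairs. If either vector has zero rank variance over the
#' complete pairs the coefficient is undefined and `NA` is returned with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length, possibly with `NA`s.
#' @return Spearman's rho in \[-1, 1\], or `NA` when undefined.
#' @export
spearman_pairwise_complete <- function(x, y) {
  if (length(x) != length(y)) txc_stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  if (sum(ok) < 3L)
    txc_stop("fewer than 3 complete pairs (%d); cannot compute Spearman rho", sum(ok))
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    txc_warn("zero rank variance in one vector; Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Classify a query transcriptome against labeled reference samples
#'
#' Spearman's rho (pairwise-complete) is computed between the query and
#' every reference column over the selected genes shared with the query.
#' Each category is summarized by the mean rho over its reference columns
#' and the standard error of that mean; the query is assigned to the
#' category with the largest mean rho. When the top two category means
#' differ by less than `ambiguity_margin` the call is flagged ambiguous and
#' all categories within the margin are reported.
#'
#' @param query Named numeric vector (or one-column matrix) of transformed
#'   expression for the query sample.
#' @param reference Expression matrix of the reference samples.
#' @param meta Metadata data.frame for the reference samples.
#' @param genes Selected gene set to correlate over; at least 50% of them
#'   must be present in the query or an error is raised.
#' @param ambiguity_margin Mean-rho gap below which the top categories are
#'   considered tied (default 0.01 — differences at SEM scale are not
#'   decisions).
#' @param min_overlap Minimum fraction of `genes` the query must share
#'   (default 0.5).
#' @return A classification object: `summary` (per-category mean_rho, sem,
#'   n_ref), `assigned` (top category first, plus any within the margin),
#'   `ambiguous`, `sample_rho` (per-reference-column rho), `n_genes_used`.
#' @export
classify_query <- function(query, reference, meta, genes,
                           ambiguity_margin = 0.01, min_overlap = 0.5) {
  validate_expression(reference)
  meta <- match_meta(meta, colnames(reference))
  if (length(unique(meta$category)) < 2L)
    txc_stop("reference must contain at least 2 categories")
  if (is.matrix(query)) {
    if (ncol(query) != 1L) txc_stop("query must be a single column")
    query <- stats::setNames(query[, 1L], rownames(query))
  }
  if (is.null(names(query))) txc_stop("query must carry gene names")
  if (!length(genes)) txc_stop("empty gene set")
  overlap <- mean(genes %in% names(query))
  if (overlap < min_overlap)
    txc_stop("query shares only %.1f%% of the %d selected genes (minimum %.0f%%)",
             100 * overlap, length(genes), 100 * min_overlap)
  use <- intersect(genes, intersect(names(query), rownames(reference)))
  q <- query[use]
  rho <- apply(reference[use, , drop = FALSE], 2L,
               function(col) spearman_pairwise_complete(q, col))
  per_cat <- split(rho, meta$category)
  summ <- data.frame(
    category = names(per_cat),
    mean_rho = vapply(per_cat, function(v) mean(v, na.rm = TRUE), numeric(1L)),
    sem = vapply(per_cat, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1L)),
    n_ref = vapply(per_cat, length, integer(1L)),
    stringsAsFactors = FALSE)
  summ <- summ[order(-summ$mean_rho, summ$category), , drop = FALSE]
  rownames(summ) <- NULL
  tied <- summ$mean_rho >= summ$mean_rho[1L] - ambiguity_margin
  structure(list(summary = summ,
                 assigned = summ$category[tied],
                 ambiguous = sum(tied) > 1L,
                 sample_rho = data.frame(sample = colnames(reference),
                                         category = meta$category,
                                         rho = unname(rho),
                                         stringsAsFactors = FALSE),
                 n_genes_used = length(use)),
            class = "txc_classification")
}

#' @export
print.txc_classification <- function(x, ...) {
  cat(sprintf("Query classification over %d genes\n", x$n_genes_used))
  cat(sprintf("  assigned: %s%s\n", paste(x$assigned, collapse = " / "),
              if (x$ambiguous) "  (ambiguous)" else ""))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Place a query on the reference MDS map
#'
#' The distance matrix is recomputed over reference columns plus the query
#' and re-embedded jointly by [classical_mds()]; the reference geometry can
#' therefore shift slightly (placement is joint, not out-of-sample — this is
#' recorded in the result).
#'
#' @inheritParams classify_query
#' @param dims Embedding dimensions (default 2).
#' @param query_id Column name given to the query in the embedding.
#' @return An embedding object over reference + query with attribute
#'   `"query_id"`; `$placement` records `"joint"`.
#' @export
project_query <- function(query, reference, meta, genes, dims = 2,
                          query_id = "query", min_overlap = 0.5) {
  validate_expression(reference)
  if (is.matrix(query)) query <- stats::setNames(query[, 1L], rownames(query))
  overlap <- mean(genes %in% names(query))
  if (overlap < min_overlap)
    txc_stop("query shares only %.1f%% of the %d selected genes (minimum %.0f%%)",
             100 * overlap, length(genes), 100 * min_overlap)
  use <- intersect(genes, intersect(names(query), rownames(reference)))
  combined <- cbind(reference[use, , drop = FALSE], query[use])
  colnames(combined)[ncol(combined)] <- query_id
  emb <- classical_mds(as.matrix(stats::dist(t(combined))), dims = dims)
  emb$placement <- "joint"
  attr(emb, "query_id") <- query_id
  emb
}
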