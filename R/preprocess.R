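#' Prefilter lowly expressed genes
#'
#' Keeps genes detected at or above `min_count` in at least `min_fraction`
#' of samples (boundary inclusive). Bulk RNA-seq genes failing this filter
#' contribute mostly sampling noise to between-category statistics.
#'
#' @param counts Gene-by-sample count matrix.
#' @param min_count Detection threshold per cell (default 1 read).
#' @param min_fraction Minimum fraction of samples meeting the threshold
#'   (default 0.8).
#' @return The filtered count matrix, gene order preserved.
#' @export
prefilter_genes <- function(counts, min_count = 1, min_fraction = 0.8) {
  validate_counts(counts)
  if (min_fraction <= 0 || min_fraction > 1)
    txc_stop("min_fraction must be in (0, 1]")
  keep <- rowMeans(counts >= min_count) >= min_fraction
  if (!any(keep))
    txc_stop(paste0("no genes pass the prefilter (>= %g in >= %g%% of samples); ",
                    "relax min_count or min_fraction"),
             min_count, 100 * min_fraction)
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' expressed in every sample, of the ratio of each count to the gene's
#' geometric mean across samples (the estimator popularized by DESeq).
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    txc_stop("no gene has nonzero counts in every sample; prefilter first")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2L, function(x) exp(stats::median(x - loggeo)))
  names(sf) <- colnames(counts)
  sf
}

#' Upper-quartile normalization
#'
#' Rescales every sample so that its 75th percentile of nonzero counts
#' matches the across-sample mean upper quartile. Used for datasets whose
#' count distributions are too skewed for median-of-ratios factors.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Matrix of rescaled (non-integer) count values.
#' @export
upper_quartile_normalize <- function(counts) {
  validate_counts(counts)
  uq <- apply(counts, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(NA_real_)
    stats::quantile(nz, 0.75, names = FALSE)
  })
  if (anyNA(uq) || any(uq <= 0))
    txc_stop("sample '%s' has no positive upper quartile (all-zero?)",
             colnames(counts)[which(is.na(uq) | uq <= 0)[1L]])
  sweep(counts, 2L, mean(uq) / uq, "*")
}

#' Shifted-log variance-stabilizing transform
#'
#' Divides each sample by its size factor and takes `log2(x + pseudocount)`.
#' This tames the count-variance/mean dependence enough for the rank- and
#' F-based statistics downstream, which are insensitive to the exact
#' stabilizer (Spearman classification is invariant to any monotone
#' per-sample transform).
#'
#' @param counts Gene-by-sample count matrix.
#' @param factors Named size factors covering every sample; defaults to
#'   [size_factors()] of `counts`.
#' @param pseudocount Positive shift added before the log (default 1, so a
#'   zero count maps to 0).
#' @return Numeric expression matrix on the log2 scale.
#' @export
vst_transform <- function(counts, factors = size_factors(counts), pseudocount = 1) {
  validate_counts(counts)
  if (pseudocount <= 0) txc_stop("pseudocount must be positive")
  miss <- setdiff(colnames(counts), names(factors))
  if (length(miss))
    txc_stop("size factors missing for sample '%s'", miss[1L])
  f <- factors[colnames(counts)]
  if (any(!is.finite(f) | f <= 0)) txc_stop("size factors must be positive and finite")
  log2(sweep(counts, 2L, f, "/") + pseudocount)
}

#' Remove additive batch effects from an expression matrix
#'
#' Fits each gene by least squares on batch indicators plus, by default,
#' category indicators (so real biology is not absorbed into the batch
#' term), then subtracts the fitted batch component. Batches are
#' treatment-coded against the first batch, so every sample is corrected
#' toward the reference batch and an injected additive offset is removed
#' exactly; this differs from sum-to-zero parametrizations only by a
#' per-gene constant. Operates on transformed expression, never raw counts.
#' A single-batch input is returned unchanged.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata data.frame with `batch` and `category` columns.
#' @param retain_category Keep category in the design so between-category
#'   differences are preserved (default TRUE).
#' @return Batch-corrected expression matrix.
#' @export
remove_batch_effect <- function(expr, meta, retain_category = TRUE) {
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  batch <- factor(meta$batch)
  if (nlevels(batch) < 2L) return(expr)
  design <- if (retain_category) {
    stats::model.matrix(~ factor(meta$category))
  } else {
    matrix(1, ncol(expr), 1L)
  }
  B <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
  full <- cbind(design, B)
  if (qr(full)$rank < ncol(full))
    txc_stop("batch is confounded with category (aliased design columns); cannot separate batch from biology")
  beta <- qr.coef(qr(full), t(expr))           # coefs x genes
  batch_rows <- seq.int(ncol(design) + 1L, ncol(full))
  expr - t(B %*% beta[batch_rows, , drop = FALSE])
}

#' Average replicate columns into one column per dataset
#'
#' Dataset-level analysis summarizes each dataset (e.g. a GEO series) by the
#' arithmetic mean of its replicate columns on the transformed scale.
#' Collapse happens after normalization and batch correction.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata data.frame; `dataset` must be uniform in category.
#' @return A list with `expr` (one column per dataset) and `meta` (one row
#'   per dataset, sample id set to the dataset id).
#' @export
collapse_to_datasets <- function(expr, meta) {
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  ds <- factor(meta$dataset, levels = unique(meta$dataset))
  for (d in levels(ds)) {
    cats <- unique(meta$category[ds == d])
    if (length(cats) > 1L)
      txc_stop("dataset '%s' mixes categories: %s", d, paste(cats, collapse = ", "))
  }
  ind <- stats::model.matrix(~ 0 + ds)
  ind <- sweep(ind, 2L, colSums(ind), "/")
  out <- expr %*% ind
  colnames(out) <- levels(ds)
  first <- meta[!duplicated(meta$dataset), , drop = FALSE]
  cmeta <- data.frame(sample = first$dataset, category = first$category,
                      dataset = first$dataset, batch = first$batch,
                      is_control = first$is_control,
                      stringsAsFactors = FALSE)
  cmeta <- cmeta[match(levels(ds), cmeta$dataset), , drop = FALSE]
  rownames(cmeta) <- NULL
  list(expr = out, meta = cmeta)
}

#' Standard preprocessing chain from counts to expression
#'
#' Convenience composition: prefilter, optional upper-quartile rescaling of
#' flagged datasets, median-of-ratios size factors, shifted-log transform,
#' and batch correction.
#'
#' @param counts Gene-by-sample count matrix.
#' @param meta Metadata data.frame aligned to `counts`.
#' @param min_count,min_fraction Prefilter thresholds, see [prefilter_genes()].
#' @param normalize Apply size-factor normalization (default TRUE); when
#'   FALSE counts are assumed pre-normalized and only log-transformed.
#' @param batch_correct Apply [remove_batch_effect()] (default TRUE).
#' @param uq_datasets Character vector of dataset ids whose samples get
#'   upper-quartile rescaling before size-factor estimation.
#' @param pseudocount Shift for the log transform.
#' @return Expression matrix ready for selection and projection.
#' @export
preprocess_counts <- function(counts, meta, min_count = 1, min_fraction = 0.8,
                              normalize = TRUE, batch_correct = TRUE,
                              uq_datasets = character(), pseudocount = 1) {
  meta <- match_meta(meta, colnames(counts))
  counts <- prefilter_genes(counts, min_count, min_fraction)
  if (length(uq_datasets)) {
    sel <- meta$dataset %in% uq_datasets
    if (any(sel))
      counts[, sel] <- upper_quartile_normalize(counts[, sel, drop = FALSE])
  }
  factors <- if (normalize) size_factors(counts) else
    stats::setNames(rep(1, ncol(counts)), colnames(counts))
  expr <- vst_transform(counts, factors, pseudocount)
  if (batch_correct) expr <- remove_batch_effect(expr, meta)
  expr
}
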