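#' Read a gene-by-sample count matrix from a delimited text file
#'
#' The expected dialect is the one bulk RNA-seq tools exchange: a header row
#' of sample ids, a first column of gene ids, and one tab-delimited row per
#' gene. Counts must be non-negative finite numbers.
#'
#' @param path Path to the text file.
#' @param delimiter Field separator, tab by default.
#' @param min_samples Minimum number of sample columns required (default 2;
#'   set to 1 when reading a single-column query file).
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(0:5, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_count_matrix(m, tf)
#' read_count_matrix(tf)
#' @export
read_count_matrix <- function(path, delimiter = "\t", min_samples = 2L) {
  if (!file.exists(path)) txc_stop("count file not found: '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) txc_stop("'%s' has no data rows", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the gene-id column
  body <- fields[-1L]
  width <- lengths(body)
  if (length(unique(width)) != 1L)
    txc_stop("ragged rows in '%s': row %d has %d fields, row 1 has %d",
             path, which(width != width[1L])[1L] + 1L, width[which(width != width[1L])[1L]],
             width[1L])
  n_samp <- width[1L] - 1L
  if (n_samp < 1L) txc_stop("'%s' has no sample columns", path)
  sample_ids <- utils::tail(header, n_samp)
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) txc_stop("duplicate gene id in '%s': '%s'", path, dup[1L])
  if (anyDuplicated(sample_ids))
    txc_stop("duplicate sample id in '%s': '%s'", path,
             sample_ids[duplicated(sample_ids)][1L])
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_samp))
  )
  m <- if (n_samp == 1L) matrix(vals, ncol = 1L) else t(vals)
  dimnames(m) <- list(gene_ids, sample_ids)
  bad <- !is.finite(m) | m < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    txc_stop("non-numeric or negative value in '%s' at gene '%s', sample '%s'",
             path, gene_ids[idx[1L]], sample_ids[idx[2L]])
  }
  validate_counts(m, min_samples = min_samples)
  m
}

#' Write a count matrix as a tab-delimited text file
#'
#' @param counts Gene-by-sample numeric matrix with dimnames.
#' @param path Output path.
#' @param delimiter Field separator.
#' @return The path, invisibly.
#' @export
write_count_matrix <- function(counts, path, delimiter = "\t") {
  validate_counts(counts, min_samples = 1L)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Requires columns `sample` and `category`; optional columns `dataset`
#' (default: the sample id, i.e. every sample its own dataset), `batch`
#' (default `"batch0"`), and `is_control` (default `FALSE`).
#'
#' @param path Path to a tab-delimited metadata table.
#' @return A data.frame with columns sample, category, dataset, batch,
#'   is_control; one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) txc_stop("metadata file not found: '%s'", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  for (col in c("sample", "category"))
    if (!col %in% names(df)) txc_stop("metadata is missing column '%s'", col)
  as_metadata(df)
}

#' Build a validated metadata table from a data.frame
#'
#' @param df A data.frame with at least `sample` and `category` columns.
#' @return Data.frame with columns sample, category, dataset, batch, is_control.
#' @export
as_metadata <- function(df) {
  if (anyDuplicated(df$sample))
    txc_stop("sample listed twice in metadata: '%s'",
             df$sample[duplicated(df$sample)][1L])
  if (any(is.na(df$category) | !nzchar(df$category)))
    txc_stop("empty category for sample '%s'",
             df$sample[which(is.na(df$category) | !nzchar(df$category))[1L]])
  if (is.null(df$dataset)) df$dataset <- df$sample
  if (any(is.na(df$dataset) | !nzchar(df$dataset)))
    txc_stop("empty dataset id for sample '%s'",
             df$sample[which(is.na(df$dataset) | !nzchar(df$dataset))[1L]])
  if (is.null(df$batch)) df$batch <- "batch0"
  if (is.null(df$is_control)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  df[, c("sample", "category", "dataset", "batch", "is_control")]
}

#' Write a metadata table
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a count matrix and its metadata to their common samples
#'
#' Merged public datasets routinely disagree on a few samples, so the policy
#' is intersect-and-warn rather than fail: samples present in only one input
#' are dropped with a warning, in matrix order.
#'
#' @param counts Gene-by-sample matrix.
#' @param meta Metadata data.frame (see [read_metadata()]).
#' @return A list with elements `counts` and `meta` restricted to the shared
#'   samples; errors if fewer than 2 samples or 2 categories remain.
#' @export
align_samples <- function(counts, meta) {
  validate_counts(counts)
  shared <- intersect(colnames(counts), meta$sample)
  if (length(shared) == 0L)
    txc_stop("count matrix and metadata share no samples")
  dropped <- c(setdiff(colnames(counts), shared), setdiff(meta$sample, shared))
  if (length(dropped))
    txc_warn("dropping %d sample(s) absent from one input: %s",
             length(dropped), paste(utils::head(dropped, 5L), collapse = ", "))
  keep <- colnames(counts)[colnames(counts) %in% shared]
  counts <- counts[, keep, drop = FALSE]
  meta <- match_meta(meta, keep)
  if (ncol(counts) < 2L)
    txc_stop("fewer than 2 samples remain after aligning")
  if (length(unique(meta$category)) < 2L)
    txc_stop("fewer than 2 categories remain after aligning")
  list(counts = counts, meta = meta)
}
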