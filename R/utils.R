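# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Stop with a formatted message, no call in the condition.
txc_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

txc_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Validate a count matrix: numeric, non-negative, finite, unique dimnames,
# >= 2 samples. Returns the matrix invisibly so callers can pipe through.
validate_counts <- function(counts, min_samples = 2L) {
  if (!is.matrix(counts) || !is.numeric(counts))
    txc_stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    txc_stop("counts must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    txc_stop("duplicate gene id: '%s'",
             rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    txc_stop("duplicate sample id: '%s'",
             colnames(counts)[duplicated(colnames(counts))][1L])
  if (ncol(counts) < min_samples)
    txc_stop("need at least %d sample(s), got %d", min_samples, ncol(counts))
  bad <- !is.finite(counts) | counts < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    txc_stop("invalid count at gene '%s', sample '%s': must be finite and >= 0",
             rownames(counts)[idx[1L]], colnames(counts)[idx[2L]])
  }
  invisible(counts)
}

# Validate an expression matrix (real-valued, finite).
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    txc_stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    txc_stop("expression must carry gene and sample ids as dimnames")
  invisible(expr)
}

# Check a metadata data.frame against a matrix's samples; reorder to match.
match_meta <- function(meta, sample_ids) {
  missing <- setdiff(sample_ids, meta$sample)
  if (length(missing))
    txc_stop("metadata is missing %d sample(s), e.g. '%s'",
             length(missing), missing[1L])
  meta[match(sample_ids, meta$sample), , drop = FALSE]
}

# round-half-up, used for stratified subsample sizes
round_half_up <- function(x) floor(x + 0.5)
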