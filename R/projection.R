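#' Euclidean distance matrix over a gene subset
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene ids to restrict to (default: all genes).
#' @return Symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(expr, genes = rownames(expr)) {
  validate_expression(expr)
  if (!length(genes)) txc_stop("empty gene subset")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    txc_stop("gene '%s' not in expression matrix", missing[1L])
  as.matrix(stats::dist(t(expr[genes, , drop = FALSE])))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, `B = -1/2 J D^2 J`, and takes
#' the top eigenpairs; coordinates are eigenvectors scaled by the square
#' root of their eigenvalues. A negative eigenvalue among the retained axes
#' means the distances are not exactly Euclidean in that many dimensions; it
#' is truncated to zero with a warning and the remaining negative spectral
#' mass is reported through the full eigenvalue vector. Axes get a
#' deterministic sign: each is oriented so its largest-magnitude coordinate
#' is positive. `stress` is the relative residual
#' `sqrt(sum((D - D_hat)^2) / sum(D^2))` between the input distances and the
#' embedding distances.
#'
#' @param d Symmetric distance matrix with sample ids as dimnames.
#' @param dims Number of output dimensions (default 2; must be < n samples).
#' @return An embedding object: `points` (samples x dims), `eigenvalues`
#'   (full spectrum, non-increasing), `stress`.
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    txc_stop("distance matrix is not symmetric")
  if (dims < 1 || dims >= n)
    txc_stop("dims must be in [1, %d] for %d samples", n - 1L, n)
  B <- -0.5 * scale(t(scale(t(d^2), scale = FALSE)), scale = FALSE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(dims)]
  if (any(lam < -1e-8 * max(abs(e$values))))
    txc_warn("negative eigenvalue among the %d retained axes; truncated to 0", dims)
  lam <- pmax(lam, 0)
  pts <- e$vectors[, seq_len(dims), drop = FALSE] %*% diag(sqrt(lam), dims)
  for (j in seq_len(dims)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  dimnames(pts) <- list(rownames(d), paste0("dim", seq_len(dims)))
  dd <- sum(d^2)
  stress <- if (dd > 0) sqrt(sum((d - as.matrix(stats::dist(pts)))^2) / dd) else 0
  structure(list(points = pts, eigenvalues = e$values, stress = stress),
            class = "txc_mds")
}

#' @export
print.txc_mds <- function(x, ...) {
  cat(sprintf("Classical MDS embedding: %d samples in %d dimensions (stress %.3g)\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Clustering score: mean silhouette of samples under their category labels
#'
#' Grades how well the categories separate in the embedding the user looks
#' at: the silhouette coefficient `s(i) = (b_i - a_i) / max(a_i, b_i)` is
#' averaged over all samples, with Euclidean distance on the 2D coordinates
#' and the category labels as the clustering. Samples in singleton
#' categories contribute 0. Ranges from -1 (samples closer to another
#' category) to 1 (tight, well-separated categories).
#'
#' @param emb An embedding from [classical_mds()], a coordinate matrix
#'   (samples x dims), or a full distance matrix — the latter gives the
#'   full-space silhouette instead of the plotted-space one.
#' @param meta Metadata data.frame with `category`.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
clustering_score <- function(emb, meta) {
  if (inherits(emb, "txc_mds")) {
    d <- stats::dist(emb$points)
    ids <- rownames(emb$points)
  } else {
    emb <- as.matrix(emb)
    if (isSymmetric(unname(emb), tol = 1e-8) && all(abs(diag(emb)) < 1e-12) &&
        nrow(emb) == ncol(emb)) {
      d <- stats::as.dist(emb)
      ids <- rownames(emb)
    } else {
      d <- stats::dist(emb)
      ids <- rownames(emb)
    }
  }
  meta <- match_meta(meta, ids)
  lab <- factor(meta$category)
  if (nlevels(lab) < 2L) txc_stop("clustering score needs at least 2 categories")
  sil <- cluster::silhouette(as.integer(lab), d)
  mean(sil[, "sil_width"])
}

#' Euclidean distance of each sample from the mean control profile
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata data.frame; rows with `is_control = TRUE` define the
#'   control group.
#' @param genes Gene subset over which distances are computed.
#' @return Named vector of distances for every non-control sample.
#' @export
distance_from_control <- function(expr, meta, genes = rownames(expr)) {
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  if (!length(genes)) txc_stop("empty gene subset")
  ctrl <- meta$is_control
  if (!any(ctrl)) txc_stop("no control samples flagged (is_control)")
  sub <- expr[genes, , drop = FALSE]
  ctrl_mean <- rowMeans(sub[, ctrl, drop = FALSE])
  res <- sqrt(colSums((sub[, !ctrl, drop = FALSE] - ctrl_mean)^2))
  stats::setNames(res, colnames(expr)[!ctrl])
}
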