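#' Boruta-style shadow-feature gene selection
#'
#' Each iteration appends a "shadow" copy of every gene — its values permuted
#' across samples, destroying any association with the category labels — and
#' fits a randomized-tree ensemble (ranger) classifying samples into
#' categories over real plus shadow features. A real gene scores a hit when
#' its impurity importance exceeds the maximum shadow importance of that
#' iteration. Genes whose hit count beats the upper tail of a
#' Binomial(n_iter, 1/2) at level `alpha` are Confirmed and returned in
#' descending hit order. The whole procedure is driven by a single seed and
#' is reproducible bit for bit.
#'
#' @param expr Expression matrix (genes x samples).
#' @param meta Metadata data.frame with `category`.
#' @param n_iter Number of shadow iterations (>= 10; default 100).
#' @param alpha Upper-tail significance level for the binomial test on hit
#'   counts (default 0.05).
#' @param seed Integer seed controlling permutations and tree growth.
#' @param num_trees Trees per ensemble (default 100).
#' @return A selection object with `method = "shadow_feature"`; its `curve`
#'   holds per-gene hit counts in the `f_value` column.
#' @export
shadow_feature_select <- function(expr, meta, n_iter = 100, alpha = 0.05,
                                  seed = 1, num_trees = 100) {
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  if (n_iter < 10L) txc_stop("n_iter must be >= 10")
  y <- factor(meta$category)
  if (nlevels(y) < 2L) txc_stop("need at least 2 categories")
  G <- nrow(expr)
  X <- t(expr)                       # samples x genes
  real_names <- paste0("g", seq_len(G))
  colnames(X) <- real_names

  hits <- withr::with_seed(seed, {
    h <- integer(G)
    for (i in seq_len(n_iter)) {
      shadow <- apply(X, 2L, sample)
      colnames(shadow) <- paste0("s", seq_len(G))
      fit <- ranger::ranger(x = cbind(X, shadow), y = y,
                            num.trees = num_trees, importance = "impurity",
                            seed = sample.int(.Machine$integer.max, 1L),
                            num.threads = 1L)
      imp <- fit$variable.importance
      h <- h + (imp[real_names] > max(imp[-seq_len(G)]))
    }
    h
  })

  pval <- stats::pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  confirmed <- which(pval <= alpha)
  if (!length(confirmed))
    txc_stop(paste0("no gene confirmed by shadow-feature selection; ",
                    "increase n_iter, relax alpha, or check that the labels ",
                    "carry signal"))
  ord_all <- order(-hits, rownames(expr), method = "radix")
  curve <- data.frame(gene = rownames(expr)[ord_all], f_value = hits[ord_all],
                      rank = seq_len(G), stringsAsFactors = FALSE)
  ord_sel <- order(-hits[confirmed], rownames(expr)[confirmed], method = "radix")
  new_selection("shadow_feature", rownames(expr)[confirmed][ord_sel], curve,
                params = list(n_iter = n_iter, alpha = alpha, seed = seed,
                              num_trees = num_trees, importance = "impurity"))
}
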