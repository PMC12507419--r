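#' Leave-one-out cross-validation of the selection + classification chain
#'
#' Each unit (dataset column after replicate collapse, or raw sample column)
#' is held out in turn: gene selection is rerun on the remaining reference
#' only — the held-out unit never influences the gene set, so there is no
#' selection leakage — and the held-out unit is classified against that
#' reference. A fold whose removal would leave its category empty is
#' skipped with a warning and excluded from the accuracy denominator; a
#' fold whose selected gene set is too small to correlate over counts as
#' incorrect (an abstention) with a warning.
#'
#' @param expr Expression matrix of the reference (genes x samples).
#' @param meta Metadata data.frame for the reference.
#' @param selector List naming the gene selector and its parameters, e.g.
#'   `list(method = "f_elbow")` or
#'   `list(method = "variance_topk", k = 500)`; see [select_genes()].
#' @param mode `"dataset"` (default) collapses replicates and leaves out
#'   whole datasets; `"sample"` leaves out single columns.
#' @return An evaluation object: `folds` (unit, true, assigned, correct,
#'   ambiguous, n_selected), `accuracy`, per-category `recall`, `mode`,
#'   `selector`, and `selections` (the per-fold selected gene sets).
#' @export
loocv <- function(expr, meta, selector = list(method = "f_elbow"),
                  mode = c("dataset", "sample")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  if (mode == "dataset") {
    coll <- collapse_to_datasets(expr, meta)
    expr <- coll$expr
    meta <- coll$meta
  }
  n <- ncol(expr)
  if (n < 3L) txc_stop("LOOCV needs at least 3 units, got %d", n)
  cat_counts <- table(meta$category)

  folds <- vector("list", n)
  selections <- vector("list", n)
  names(selections) <- colnames(expr)
  for (i in seq_len(n)) {
    true_cat <- meta$category[i]
    if (cat_counts[[true_cat]] <= 1L) {
      txc_warn("skipping fold for '%s': category '%s' would be empty without it",
               colnames(expr)[i], true_cat)
      next
    }
    rest <- expr[, -i, drop = FALSE]
    rest_meta <- meta[-i, , drop = FALSE]
    sel <- run_selector(rest, rest_meta, selector)
    selections[[i]] <- sel$selected_genes
    # a fold whose selected set is too small to correlate over is an
    # abstention: counted as incorrect, not fatal
    cls <- tryCatch(classify_query(expr[, i], rest, rest_meta,
                                   sel$selected_genes),
                    error = function(e) {
                      txc_warn("fold '%s' could not be classified: %s",
                               colnames(expr)[i], conditionMessage(e))
                      NULL
                    })
    folds[[i]] <- data.frame(unit = colnames(expr)[i], true = true_cat,
                             assigned = if (is.null(cls)) NA_character_ else
                               cls$assigned[1L],
                             correct = !is.null(cls) &&
                               cls$assigned[1L] == true_cat,
                             ambiguous = if (is.null(cls)) NA else cls$ambiguous,
                             n_selected = length(sel$selected_genes),
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  if (is.null(folds)) txc_stop("no usable LOOCV folds")
  recall <- vapply(split(folds$correct, folds$true), mean, numeric(1L))
  structure(list(mode = mode, folds = folds,
                 accuracy = mean(folds$correct),
                 recall = recall, selector = selector,
                 selections = selections),
            class = "txc_evaluation")
}

run_selector <- function(expr, meta, selector) {
  args <- selector
  args$method <- NULL
  # selection inside folds operates on already-collapsed columns
  do.call(select_genes,
          c(list(expr = expr, meta = meta, method = selector$method,
                 level = "sample"), args))
}

#' @export
print.txc_evaluation <- function(x, ...) {
  cat(sprintf("LOOCV (%s level, selector %s): accuracy %.3f over %d folds\n",
              x$mode, x$selector$method, x$accuracy, nrow(x$folds)))
  invisible(x)
}

#' Reference-subsampling robustness of classification accuracy
#'
#' For each proportion and repeat, a stratified random subsample of the
#' reference units is drawn (per category, round-half-up of
#' proportion x size, minimum 1 unit so no category vanishes) and full
#' LOOCV is run on the subsample. Proportion 1.0 reproduces plain LOOCV
#' exactly for every repeat. Summarizes mean and SD of accuracy per
#' proportion; accuracy degrading as the reference shrinks quantifies how
#' much reference data the classifier needs.
#'
#' @inheritParams loocv
#' @param proportions Proportions of reference units to keep (default
#'   `c(1, 0.8, 0.6, 0.4, 0.2)`).
#' @param repeats Random subsamples per proportion (default 10).
#' @param seed Integer seed for the subsampling.
#' @return An object with `robustness` (proportion, repeat, accuracy,
#'   subsample size and smallest per-category count; accuracy is `NA` for a
#'   subsample too small to yield any usable fold), `summary`
#'   (per-proportion mean/sd), `loocv_accuracy` (the full-data accuracy),
#'   `selector`, `mode`, `seed`.
#' @export
subsample_robustness <- function(expr, meta, selector = list(method = "f_elbow"),
                                 proportions = c(1, 0.8, 0.6, 0.4, 0.2),
                                 repeats = 10, mode = c("dataset", "sample"),
                                 seed = 1) {
  mode <- match.arg(mode)
  if (any(proportions <= 0 | proportions > 1))
    txc_stop("proportions must be in (0, 1]")
  validate_expression(expr)
  meta <- match_meta(meta, colnames(expr))
  if (mode == "dataset") {
    coll <- collapse_to_datasets(expr, meta)
    expr <- coll$expr
    meta <- coll$meta
  }
  full <- loocv(expr, meta, selector, mode = "sample")

  rows <- withr::with_seed(seed, {
    out <- list()
    for (p in proportions) {
      for (r in seq_len(repeats)) {
        if (p == 1) {
          acc <- full$accuracy
          keep <- seq_len(ncol(expr))
        } else {
          keep <- unlist(lapply(split(seq_len(ncol(expr)), meta$category),
                                function(idx) {
            k <- max(1L, round_half_up(p * length(idx)))
            if (k >= length(idx)) idx else sample(idx, k)
          }), use.names = FALSE)
          keep <- sort(keep)
          # a subsample too small for any usable fold yields NA, not an abort
          acc <- tryCatch(suppressWarnings(
            loocv(expr[, keep, drop = FALSE], meta[keep, , drop = FALSE],
                  selector, mode = "sample")$accuracy),
            error = function(e) NA_real_)
        }
        out[[length(out) + 1L]] <- data.frame(
          proportion = p, rep = r, accuracy = acc,
          n_units = length(keep),
          min_per_category = min(table(meta$category[keep])))
      }
    }
    do.call(rbind, out)
  })
  agg <- do.call(rbind, lapply(split(rows, rows$proportion), function(d) {
    data.frame(proportion = d$proportion[1L],
               mean_accuracy = mean(d$accuracy, na.rm = TRUE),
               sd_accuracy = stats::sd(d$accuracy, na.rm = TRUE))
  }))
  agg <- agg[order(-agg$proportion), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(robustness = rows, summary = agg,
                 loocv_accuracy = full$accuracy, selector = selector,
                 mode = mode, seed = seed),
            class = "txc_robustness")
}

#' @export
print.txc_robustness <- function(x, ...) {
  cat(sprintf("Reference-subsampling robustness (%s level, selector %s, seed %d)\n",
              x$mode, x$selector$method, x$seed))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
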