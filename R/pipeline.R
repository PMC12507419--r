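# One-stop pipeline entry points mirroring the interactive workflow:
# select an optimal gene set, classify a query, evaluate robustness.
# Each run writes its tables plus a JSON manifest sufficient to re-execute.

write_manifest <- function(out_dir, step, params) {
  manifest <- list(step = step, params = params,
                   package_version = as.character(utils::packageVersion("txclass")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

load_reference <- function(counts_path, metadata_path, delimiter = "\t",
                           normalize = TRUE, batch_correct = TRUE,
                           min_count = 1, min_fraction = 0.8,
                           uq_datasets = character()) {
  counts <- read_count_matrix(counts_path, delimiter)
  meta <- read_metadata(metadata_path)
  al <- align_samples(counts, meta)
  expr <- preprocess_counts(al$counts, al$meta, min_count = min_count,
                            min_fraction = min_fraction, normalize = normalize,
                            batch_correct = batch_correct,
                            uq_datasets = uq_datasets)
  list(expr = expr, meta = al$meta, counts = al$counts)
}

#' Run gene selection end to end from count and metadata files
#'
#' Reads, aligns, preprocesses, selects (elbow by default), and writes
#' `selection.tsv` (gene, f_value, rank, selected, method) plus a JSON
#' manifest with the elbow index, parameters, and seed.
#'
#' @param counts_path,metadata_path Input TSV paths.
#' @param out_dir Output directory (created if needed).
#' @param selector Selector configuration list, see [loocv()].
#' @param mode Analysis level, `"dataset"` or `"sample"`.
#' @param normalize,batch_correct,min_count,min_fraction,uq_datasets
#'   Preprocessing switches, see [preprocess_counts()].
#' @param delimiter Count-file field separator.
#' @return The selection object, invisibly.
#' @export
run_select <- function(counts_path, metadata_path, out_dir,
                       selector = list(method = "f_elbow"),
                       mode = "dataset", normalize = TRUE, batch_correct = TRUE,
                       min_count = 1, min_fraction = 0.8,
                       uq_datasets = character(), delimiter = "\t") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_reference(counts_path, metadata_path, delimiter, normalize,
                        batch_correct, min_count, min_fraction, uq_datasets)
  args <- selector; args$method <- NULL
  sel <- do.call(select_genes,
                 c(list(expr = ref$expr, meta = ref$meta,
                        method = selector$method, level = mode), args))
  tab <- sel$curve
  tab$selected <- tab$gene %in% sel$selected_genes
  tab$method <- sel$method
  utils::write.table(tab, file.path(out_dir, "selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "select",
                 list(counts = counts_path, metadata = metadata_path,
                      selector = selector, mode = mode, normalize = normalize,
                      batch_correct = batch_correct, min_count = min_count,
                      min_fraction = min_fraction,
                      elbow_index = sel$elbow_index,
                      n_selected = length(sel$selected_genes),
                      params = sel$params))
  invisible(sel)
}

#' Classify a query transcriptome end to end
#'
#' Preprocesses reference and query together (the query column passes
#' through the same transform chain, with size factors computed against the
#' pooled gene geometry), selects genes on the reference, classifies the
#' query by Spearman correlation, embeds reference + query jointly, and
#' writes `classification.tsv`, `sample_rho.tsv`, `embedding.tsv`.
#'
#' @inheritParams run_select
#' @param query_path TSV with the query count column(s); the first column
#'   of counts is used as the query.
#' @param seed Seed recorded in the manifest (selection methods that use
#'   randomness read it from `selector`).
#' @return A list with the classification and embedding objects, invisibly.
#' @export
run_classify <- function(counts_path, metadata_path, query_path, out_dir,
                         selector = list(method = "f_elbow"), mode = "dataset",
                         normalize = TRUE, batch_correct = TRUE,
                         min_count = 1, min_fraction = 0.8,
                         delimiter = "\t", seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_reference(counts_path, metadata_path, delimiter, normalize,
                        batch_correct, min_count, min_fraction)
  args <- selector; args$method <- NULL
  sel <- do.call(select_genes,
                 c(list(expr = ref$expr, meta = ref$meta,
                        method = selector$method, level = mode), args))

  qcounts <- read_count_matrix(query_path, delimiter, min_samples = 1L)
  qid <- colnames(qcounts)[1L]
  shared <- intersect(rownames(ref$counts), rownames(qcounts))
  q <- qcounts[shared, 1L]
  qexpr <- if (normalize) {
    # size factor against the reference's gene geometric means
    ref_pos <- rowSums(ref$counts[shared, , drop = FALSE] > 0) == ncol(ref$counts)
    use <- ref_pos & q > 0
    loggeo <- rowMeans(log(ref$counts[shared, , drop = FALSE][use, , drop = FALSE]))
    sf <- exp(stats::median(log(q[use]) - loggeo))
    log2(q / sf + 1)
  } else log2(q + 1)
  names(qexpr) <- shared

  level_expr <- if (mode == "dataset") {
    coll <- collapse_to_datasets(ref$expr, ref$meta)
    coll
  } else list(expr = ref$expr, meta = ref$meta)

  cls <- classify_query(qexpr, level_expr$expr, level_expr$meta,
                        sel$selected_genes)
  emb <- project_query(qexpr, level_expr$expr, level_expr$meta,
                       sel$selected_genes, query_id = qid)

  summ <- cls$summary
  summ$assigned <- summ$category %in% cls$assigned
  utils::write.table(summ, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cls$sample_rho, file.path(out_dir, "sample_rho.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  etab <- data.frame(sample = rownames(emb$points), emb$points,
                     category = c(level_expr$meta$category, NA),
                     is_query = c(rep(FALSE, nrow(emb$points) - 1L), TRUE),
                     check.names = FALSE)
  utils::write.table(etab, file.path(out_dir, "embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "classify",
                 list(counts = counts_path, metadata = metadata_path,
                      query = query_path, selector = selector, mode = mode,
                      normalize = normalize, batch_correct = batch_correct,
                      seed = seed, n_selected = length(sel$selected_genes),
                      n_genes_used = cls$n_genes_used,
                      placement = "joint"))
  invisible(list(classification = cls, embedding = emb, selection = sel))
}

#' Run the LOOCV + subsampling evaluation end to end
#'
#' @inheritParams run_select
#' @param proportions,repeats,seed Passed to [subsample_robustness()].
#' @return A list with the LOOCV and robustness objects, invisibly.
#' @export
run_evaluate <- function(counts_path, metadata_path, out_dir,
                         selector = list(method = "f_elbow"), mode = "dataset",
                         proportions = c(1, 0.8, 0.6, 0.4, 0.2), repeats = 10,
                         seed = 1, normalize = TRUE, batch_correct = TRUE,
                         min_count = 1, min_fraction = 0.8, delimiter = "\t") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- load_reference(counts_path, metadata_path, delimiter, normalize,
                        batch_correct, min_count, min_fraction)
  cv <- loocv(ref$expr, ref$meta, selector, mode = mode)
  rob <- subsample_robustness(ref$expr, ref$meta, selector,
                              proportions = proportions, repeats = repeats,
                              mode = mode, seed = seed)
  utils::write.table(cv$folds, file.path(out_dir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rob$robustness, file.path(out_dir, "robustness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "evaluate",
                 list(counts = counts_path, metadata = metadata_path,
                      selector = selector, mode = mode, seed = seed,
                      proportions = proportions, repeats = repeats,
                      accuracy = cv$accuracy, recall = as.list(cv$recall)))
  invisible(list(loocv = cv, robustness = rob))
}

#' Write a simulated scenario to disk
#'
#' @param spec A spec from [synthetic_spec()].
#' @param out_dir Output directory; writes counts.tsv, metadata.tsv,
#'   truth.json.
#' @return The directory, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(spec)
  write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  write_metadata(sim$meta, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(list(spec = unclass(spec), informative = sim$truth),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
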