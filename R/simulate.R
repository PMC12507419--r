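#' Specify a synthetic multi-category RNA-seq experiment
#'
#' Describes a reference collection with known ground truth: categories of
#' physiological states, datasets (replicate groups, one per publication or
#' GEO series) nested in categories, negative-binomial counts with a shared
#' dispersion, category-specific log-scale shifts on planted informative
#' genes, additive log-scale batch offsets, and per-sample library-size
#' factors drawn log-uniformly over `libsize_log_range`.
#'
#' `effect_size` is measured in units of a gene's within-group SD on the log
#' scale (delta-method: `sqrt(1/mu + dispersion)`), so 2 means planted genes
#' shift by twice their replicate noise.
#'
#' @param n_categories Number of state categories.
#' @param datasets_per_category Datasets per category.
#' @param replicates_per_dataset Replicate samples per dataset.
#' @param n_genes Total genes.
#' @param n_informative_per_category Planted informative genes per category
#'   (disjoint across categories).
#' @param effect_size Planted shift in within-group-SD units (log scale).
#' @param nb_dispersion Negative-binomial dispersion shared by all genes.
#' @param baseline_log_mean_range Range (natural log) for baseline means.
#' @param batch_effect_sd SD of the additive log-scale batch offsets.
#' @param n_batches Number of batches; datasets are assigned to batches
#'   round-robin so batch stays balanced across categories.
#' @param libsize_log_range Range (natural log) of library-size factors.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A spec object (list) for [simulate_counts()].
#' @export
synthetic_spec <- function(n_categories = 3, datasets_per_category = 9,
                           replicates_per_dataset = 3, n_genes = 5000,
                           n_informative_per_category = 100, effect_size = 2,
                           nb_dispersion = 0.1,
                           baseline_log_mean_range = c(log(5), log(500)),
                           batch_effect_sd = 0.1, n_batches = 3,
                           libsize_log_range = c(-0.3, 0.3), seed = 1042) {
  spec <- list(n_categories = n_categories,
               datasets_per_category = datasets_per_category,
               replicates_per_dataset = replicates_per_dataset,
               n_genes = n_genes,
               n_informative_per_category = n_informative_per_category,
               effect_size = effect_size, nb_dispersion = nb_dispersion,
               baseline_log_mean_range = baseline_log_mean_range,
               batch_effect_sd = batch_effect_sd, n_batches = n_batches,
               libsize_log_range = libsize_log_range, seed = seed)
  counts_of_things <- c("n_categories", "datasets_per_category",
                        "replicates_per_dataset", "n_genes", "n_batches")
  for (f in counts_of_things)
    if (spec[[f]] < 1) txc_stop("%s must be >= 1", f)
  if (spec$n_informative_per_category < 0)
    txc_stop("n_informative_per_category must be >= 0")
  if (spec$effect_size < 0) txc_stop("effect_size must be >= 0")
  if (spec$nb_dispersion <= 0) txc_stop("nb_dispersion must be > 0")
  if (spec$batch_effect_sd < 0) txc_stop("batch_effect_sd must be >= 0")
  if (n_categories * n_informative_per_category > n_genes)
    txc_stop("more informative genes requested than genes available")
  structure(spec, class = "txc_spec")
}

#' The default synthetic reference scenario
#'
#' Three categories of nine datasets with three replicates each (81 samples,
#' 27 datasets — shaped like a multi-study longevity reference), 5000 genes
#' with 100 informative genes planted per category at effect size 2
#' within-group SDs, three batches, fixed seed. Every property test and the
#' parameter-recovery benchmarks reference this fixture.
#'
#' @return A spec object.
#' @export
default_scenario <- function() synthetic_spec()

#' Simulate counts, metadata, and ground truth from a spec
#'
#' Counts are drawn gene by sample from a negative binomial with mean
#' `exp(base_g + effect_(g, cat(s)) + batch_(b(s)) + libsize_s)` and shared
#' dispersion. Informative genes for a category shift up or down (sign
#' drawn per gene) by `effect_size` within-group SDs on the log scale;
#' informative sets are disjoint across categories.
#'
#' @param spec A spec from [synthetic_spec()].
#' @return A list: `counts` (integer matrix), `meta` (metadata data.frame),
#'   `truth` (data.frame gene, category, direction, lfc_log2 — the realized
#'   log2 fold change — plus attributes `batch_offsets`, `lib_factors`).
#' @export
simulate_counts <- function(spec) {
  if (!inherits(spec, "txc_spec")) txc_stop("spec must come from synthetic_spec()")
  withr::with_seed(spec$seed, {
    G <- spec$n_genes
    n_ds <- spec$n_categories * spec$datasets_per_category
    N <- n_ds * spec$replicates_per_dataset

    categories <- paste0("cat", seq_len(spec$n_categories))
    ds_cat <- rep(categories, each = spec$datasets_per_category)
    ds_id <- sprintf("d%02d", seq_len(n_ds))
    # round-robin over datasets within category keeps batch balanced
    ds_batch <- paste0("batch", ((seq_len(n_ds) - 1L) %% spec$n_batches) + 1L)

    s_ds <- rep(seq_len(n_ds), each = spec$replicates_per_dataset)
    meta <- data.frame(
      sample = paste0(ds_id[s_ds], "_r", sequence(rep(spec$replicates_per_dataset, n_ds))),
      category = ds_cat[s_ds], dataset = ds_id[s_ds], batch = ds_batch[s_ds],
      is_control = FALSE, stringsAsFactors = FALSE)

    gene_ids <- sprintf("g%05d", seq_len(G))
    base <- stats::runif(G, spec$baseline_log_mean_range[1L],
                         spec$baseline_log_mean_range[2L])
    sigma <- sqrt(1 / exp(base) + spec$nb_dispersion)  # within-group log SD

    n_inf <- spec$n_informative_per_category
    inf_idx <- if (n_inf > 0) sample.int(G, spec$n_categories * n_inf) else integer()
    inf_cat <- rep(categories, each = n_inf)
    direction <- sample(c(-1, 1), length(inf_idx), replace = TRUE)

    # per-gene, per-category log shift
    shift <- matrix(0, G, spec$n_categories, dimnames = list(NULL, categories))
    if (length(inf_idx))
      shift[cbind(inf_idx, match(inf_cat, categories))] <-
        direction * spec$effect_size * sigma[inf_idx]

    batch_off <- stats::setNames(
      stats::rnorm(spec$n_batches, 0, spec$batch_effect_sd),
      paste0("batch", seq_len(spec$n_batches)))
    lib <- exp(stats::runif(N, spec$libsize_log_range[1L],
                            spec$libsize_log_range[2L]))

    log_mu <- outer(base, rep(1, N)) + shift[, meta$category, drop = FALSE]
    log_mu <- sweep(log_mu, 2L, batch_off[meta$batch] + log(lib), "+")
    counts <- matrix(stats::rnbinom(G * N, mu = exp(log_mu),
                                    size = 1 / spec$nb_dispersion),
                     G, N, dimnames = list(gene_ids, meta$sample))

    truth <- data.frame(gene = gene_ids[inf_idx], category = inf_cat,
                        direction = direction,
                        lfc_log2 = direction * spec$effect_size *
                          sigma[inf_idx] / log(2),
                        stringsAsFactors = FALSE)
    attr(truth, "batch_offsets") <- batch_off
    attr(truth, "lib_factors") <- stats::setNames(lib, meta$sample)
    list(counts = counts, meta = meta, truth = truth)
  })
}
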