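# Small in-code fixtures shared across test files. Heavier simulated
# scenarios are computed once per session and cached.

toy_counts <- function() {
  m <- matrix(c(10, 20, 30, 40,
                5, 0, 15, 20,
                0, 0, 0, 1), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(c("gA", "gB", "gC"), paste0("s", 1:4))
  m
}

toy_meta <- function(categories = c("x", "x", "y", "y"),
                     samples = paste0("s", seq_along(categories)),
                     dataset = samples, batch = "b0") {
  data.frame(sample = samples, category = categories, dataset = dataset,
             batch = batch, is_control = FALSE, stringsAsFactors = FALSE)
}

# Expression matrix with gaussian noise and an optional planted shift.
toy_expr <- function(G = 20, n_per = 3, categories = c("x", "y"),
                     shift_genes = integer(), shift = 0, seed = 1) {
  withr::with_seed(seed, {
    N <- n_per * length(categories)
    expr <- matrix(rnorm(G * N), G, N,
                   dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:N)))
    meta <- toy_meta(rep(categories, each = n_per),
                     samples = colnames(expr))
    for (g in shift_genes)
      expr[g, meta$category == categories[2]] <-
        expr[g, meta$category == categories[2]] + shift
    list(expr = expr, meta = meta)
  })
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# The default simulated scenario, preprocessed once.
default_fixture <- function() {
  cached("default", function() {
    sim <- simulate_counts(default_scenario())
    expr <- preprocess_counts(sim$counts, sim$meta)
    c(sim, list(expr = expr))
  })
}

# Shuffle the category labels at dataset level (replicates stay consistent).
shuffle_dataset_labels <- function(meta, seed) {
  withr::with_seed(seed, {
    ds <- unique(meta$dataset)
    cat_of <- meta$category[match(ds, meta$dataset)]
    new_cat <- sample(cat_of)
    meta$category <- new_cat[match(meta$dataset, ds)]
    meta
  })
}
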