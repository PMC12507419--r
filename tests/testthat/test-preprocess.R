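test_that("prefilter keeps genes detected in at least the required fraction", {
  # per-gene nonzero fractions {1.0, 0.9, 0.8, 0.5, 0.2, 0} over 10 samples
  fr <- c(1, 0.9, 0.8, 0.5, 0.2, 0)
  m <- t(vapply(fr, function(p) c(rep(1, round(10 * p)), rep(0, 10 - round(10 * p))),
                numeric(10)))
  dimnames(m) <- list(paste0("g", seq_along(fr)), paste0("s", 1:10))
  kept <- prefilter_genes(m, min_count = 1, min_fraction = 0.8)
  expect_identical(rownames(kept), c("g1", "g2", "g3"))  # 3 survive, boundary inclusive

  # gene >= 1 in exactly 4 of 5 samples passes at 0.8; all-zero gene dropped
  m2 <- rbind(gA = c(1, 2, 3, 4, 0), gB = rep(0, 5))
  colnames(m2) <- paste0("s", 1:5)
  expect_identical(rownames(prefilter_genes(m2)), "gA")

  # idempotence, and never grows
  expect_identical(prefilter_genes(kept), kept)
  expect_lte(nrow(kept), nrow(m))

  expect_error(prefilter_genes(m2[2, , drop = FALSE] + 0 * m2[2, ], min_count = 1),
               "no genes pass")
})

test_that("size factors follow the median-of-ratios estimator", {
  m <- toy_counts()[1:2, ]  # all-positive rows exist
  expect_equal(unname(size_factors(cbind(a = m[, 1], b = m[, 1]))), c(1, 1))

  doubled <- cbind(m, dbl = 2 * m[, 2])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["dbl"] / sf["s2"]), 2)

  withr::with_seed(42, {
    m4 <- matrix(rpois(15, 50) + 1, 5, 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  })
  expect_equal(size_factors(m4), oracle_size_factors(m4))

  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(m4)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m4)))
})

test_that("size factors recover exact column scalings up to a constant", {
  withr::with_seed(7, base <- rpois(30, 100) + 1)
  scal <- c(0.5, 1, 2, 4)
  m <- vapply(scal, function(s) round(base * s), numeric(30))
  dimnames(m) <- list(paste0("g", 1:30), paste0("s", 1:4))
  sf <- size_factors(m)
  expect_equal(unname(sf / sf[2]), scal, tolerance = 0.02)

  never_shared <- matrix(c(0, 1, 1, 0), 2, 2,
                         dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(size_factors(never_shared), "prefilter")
})

test_that("upper-quartile normalization equalizes the nonzero upper quartile", {
  m <- toy_counts()[1:2, ]
  same <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  expect_equal(upper_quartile_normalize(same), same)

  tripled <- cbind(a = m[, 1], b = m[, 1] * 3)
  uq <- upper_quartile_normalize(tripled)
  expect_equal(uq[, "a"], uq[, "b"])

  # per-sample quartiles {100, 200, 300} -> factors {2, 1, 2/3}
  m3 <- matrix(rep(c(100, 200, 300), each = 3), 3, 3, byrow = FALSE,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  out <- upper_quartile_normalize(m3)
  expect_equal(out / m3, matrix(rep(c(2, 1, 2 / 3), each = 3), 3, 3,
                                dimnames = dimnames(m3)))

  allzero <- matrix(c(0, 0, 1, 2), 2, 2,
                    dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(upper_quartile_normalize(allzero), "upper quartile")
})

test_that("shifted-log transform is exact, monotone, and scale-invariant", {
  m <- matrix(c(3, 0, 7, 1), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- c(s1 = 1, s2 = 1)
  v <- vst_transform(m, sf)
  expect_equal(v["g1", "s1"], 2)       # log2(3/1 + 1)
  expect_equal(v["g2", "s1"], 0)       # zero count at default pseudocount

  # strictly increasing in counts for fixed factor
  cnts <- cbind(a = 0:50, b = 0:50); rownames(cnts) <- paste0("g", 0:50)
  vt <- vst_transform(cnts, c(a = 1, b = 2))
  expect_true(all(diff(vt[, "a"]) > 0) && all(diff(vt[, "b"]) > 0))

  # doubling a sample's counts and its factor leaves the column unchanged
  v2 <- vst_transform(cbind(m, s3 = 2 * m[, "s2"]), c(sf, s3 = 2))
  expect_equal(v2[, "s3"], v2[, "s2"])
})

test_that("batch correction removes an additive offset on a balanced design", {
  # batch-clean base matrix: batch-2 columns duplicate batch-1 columns, so
  # its estimated batch coefficient is exactly zero
  fx <- toy_expr(G = 30, n_per = 4, seed = 3)
  meta <- fx$meta
  meta$batch <- rep(c("b1", "b2"), times = 4)   # balanced within category
  base <- fx$expr
  base[, meta$batch == "b2"] <- base[, meta$batch == "b1"]
  delta <- 1.7
  perturbed <- base
  perturbed[, meta$batch == "b2"] <- perturbed[, meta$batch == "b2"] + delta
  corrected <- remove_batch_effect(perturbed, meta)
  expect_equal(corrected, base, tolerance = 1e-8)

  # between-category mean differences survive correction on generic data
  pert2 <- fx$expr
  pert2[, meta$batch == "b2"] <- pert2[, meta$batch == "b2"] + delta
  corr2 <- remove_batch_effect(pert2, meta)
  gap <- function(e) rowMeans(e[, meta$category == "y"]) -
    rowMeans(e[, meta$category == "x"])
  expect_equal(gap(corr2), gap(fx$expr), tolerance = 1e-8)

  # agrees with limma's residualization up to a per-gene constant
  skip_if_not_installed("limma")
  lim <- limma::removeBatchEffect(pert2, batch = factor(meta$batch),
                                  design = model.matrix(~ factor(meta$category)))
  diffs <- corr2 - lim
  expect_lt(max(abs(diffs - rowMeans(diffs))), 1e-8)
})

test_that("batch correction handles single-batch and confounded designs", {
  fx <- toy_expr(seed = 4)
  expect_identical(remove_batch_effect(fx$expr, fx$meta), fx$expr)

  meta <- fx$meta
  meta$batch <- meta$category          # perfectly confounded
  expect_error(remove_batch_effect(fx$expr, meta), "confounded")
})

test_that("replicates collapse to dataset means", {
  fx <- toy_expr(G = 5, n_per = 2, seed = 5)
  meta <- fx$meta
  meta$dataset <- c("d1", "d1", "d2", "d2")
  coll <- collapse_to_datasets(fx$expr, meta)
  expect_equal(coll$expr[, "d1"], rowMeans(fx$expr[, 1:2]))
  expect_equal(coll$meta$category, c("x", "y"))

  # single-replicate dataset passes through; [1,3] averages to 2
  m <- matrix(c(1, 3, 5), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  meta3 <- toy_meta(c("x", "x", "y"), samples = c("a", "b", "c"),
                    dataset = c("d1", "d1", "d2"))
  out <- collapse_to_datasets(m, meta3)
  expect_equal(unname(out$expr[1, ]), c(2, 5))

  meta_bad <- meta
  meta_bad$dataset <- "d1"
  expect_error(collapse_to_datasets(fx$expr, meta_bad), "mixes categories")
})
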