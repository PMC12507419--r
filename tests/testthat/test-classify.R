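test_that("pairwise-complete Spearman matches base R on vectors with NAs", {
  withr::with_seed(70, {
    x <- rnorm(8); y <- 0.6 * x + rnorm(8, sd = 0.4)
    x[c(2, 5)] <- NA; y[7] <- NA
  })
  expect_equal(spearman_pairwise_complete(x, y),
               cor(x, y, method = "spearman", use = "pairwise.complete.obs"))

  # tie handling via mid-ranks
  a <- c(1, 2, 2, 3, NA, 4, 4, 4)
  b <- c(2, 1, 3, 3, 5, NA, 6, 6)
  expect_equal(spearman_pairwise_complete(a, b),
               cor(a, b, method = "spearman", use = "pairwise.complete.obs"))

  z <- rnorm(6)
  expect_equal(spearman_pairwise_complete(z, z), 1)
  expect_equal(spearman_pairwise_complete(z, -z), -1)
})

test_that("Spearman rho is invariant to strictly monotone transforms", {
  withr::with_seed(71, { x <- rnorm(12); y <- rnorm(12) })
  base_rho <- spearman_pairwise_complete(x, y)
  expect_equal(spearman_pairwise_complete(exp(x), y), base_rho)
  expect_equal(spearman_pairwise_complete(x, 5 * y - 2), base_rho)
  expect_equal(spearman_pairwise_complete(x^3, atan(y)), base_rho)
})

test_that("Spearman degenerate inputs follow the documented contract", {
  expect_error(spearman_pairwise_complete(c(1, 2, NA, NA), c(1, NA, 2, 3)),
               "fewer than 3 complete pairs")
  expect_warning(r <- spearman_pairwise_complete(rep(1, 5), rnorm(5)),
                 "zero rank variance")
  expect_true(is.na(r))
  expect_error(spearman_pairwise_complete(1:3, 1:4), "equal length")
})

test_that("an exact copy of a reference column classifies to its category", {
  fx <- toy_expr(G = 50, n_per = 4, categories = c("a", "b"),
                 shift_genes = 1:10, shift = 3, seed = 72)
  genes <- rownames(fx$expr)
  q <- fx$expr[, 5]                    # a category-b column
  cls <- classify_query(q, fx$expr, fx$meta, genes)
  expect_identical(cls$assigned[1L], "b")
  expect_equal(max(cls$sample_rho$rho), 1)
  expect_false(cls$ambiguous)
  expect_true(all(c("mean_rho", "sem", "n_ref") %in% names(cls$summary)))
  # SEM is sd/sqrt(n) over that category's reference columns
  b_rho <- cls$sample_rho$rho[cls$sample_rho$category == "b"]
  expect_equal(cls$summary$sem[cls$summary$category == "b"],
               sd(b_rho) / sqrt(length(b_rho)))
})

test_that("insufficient gene overlap raises an error naming the fraction", {
  fx <- toy_expr(G = 50, n_per = 3, seed = 73)
  q <- fx$expr[1:20, 1]                # 40% of the selected genes
  expect_error(classify_query(q, fx$expr, fx$meta, rownames(fx$expr)),
               "40.0% of the 50 selected genes")
})

test_that("an uncorrelated query gets near-zero rho and a consistent ambiguity flag", {
  checks <- vapply(1:10, function(s) withr::with_seed(700 + s, {
    fx <- toy_expr(G = 200, n_per = 5, seed = 7000 + s)
    q <- setNames(rnorm(200), rownames(fx$expr))
    cls <- classify_query(q, fx$expr, fx$meta, rownames(fx$expr))
    gap <- cls$summary$mean_rho[1] - cls$summary$mean_rho[2]
    c(near_zero = max(abs(cls$summary$mean_rho)) < 0.2,
      flag_consistent = cls$ambiguous == (gap < 0.01))
  }), logical(2))
  expect_true(all(checks["near_zero", ]))
  # the flag fires exactly when the top-two means sit within the margin
  expect_true(all(checks["flag_consistent", ]))
})

test_that("classification is invariant to monotone per-sample transforms", {
  fx <- default_fixture()
  coll <- collapse_to_datasets(fx$expr, fx$meta)
  sel <- elbow_select(f_values(fx$expr, fx$meta, level = "dataset"))
  q <- coll$expr[, 1]
  ref <- coll$expr[, -1]; meta <- coll$meta[-1, ]
  c1 <- classify_query(q, ref, meta, sel$selected_genes)
  warped <- apply(ref, 2, function(col) col^3 + 2)  # strictly monotone per column
  dimnames(warped) <- dimnames(ref)
  c2 <- classify_query(exp(q), warped, meta, sel$selected_genes)
  expect_identical(c1$assigned, c2$assigned)
  expect_equal(c1$summary$mean_rho, c2$summary$mean_rho, tolerance = 1e-12)
})

test_that("joint query projection places the query sensibly", {
  fx <- toy_expr(G = 30, n_per = 4, categories = c("a", "b"),
                 shift_genes = 1:8, shift = 4, seed = 75)
  genes <- rownames(fx$expr)

  # query equal to a reference column lands on it
  q <- fx$expr[, 3]
  emb <- project_query(q, fx$expr, fx$meta, genes)
  d <- as.matrix(dist(emb$points))
  expect_lt(d["query", "s03"], 1e-8)
  expect_equal(emb$placement, "joint")

  # query at the centroid of two columns embeds between them
  q2 <- (fx$expr[, 1] + fx$expr[, 5]) / 2
  emb2 <- project_query(q2, fx$expr, fx$meta, genes)
  d2 <- as.matrix(dist(emb2$points))
  expect_lt(d2["query", "s01"], d2["s01", "s05"])
  expect_lt(d2["query", "s05"], d2["s01", "s05"])

  # a query off the reference plane perturbs reference pairwise embedding
  # distances by < 10%: build an exactly 2D reference so its embedding is
  # lossless, then push the query out along an orthogonal direction
  withr::with_seed(76, {
    basis <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
    ref2d <- basis[, 1:2] %*% matrix(rnorm(2 * 8, sd = 3), 2, 8)
  })
  dimnames(ref2d) <- list(paste0("g", 1:30), paste0("s", 1:8))
  meta2d <- toy_meta(rep(c("a", "b"), each = 4), samples = colnames(ref2d))
  diam <- max(dist(t(ref2d)))
  q3 <- ref2d[, 1] + basis[, 3] * 0.5 * diam
  emb3 <- project_query(q3, ref2d, meta2d, rownames(ref2d))
  dr <- as.matrix(dist(t(ref2d)))
  dj <- as.matrix(dist(emb3$points[colnames(ref2d), ]))
  off <- upper.tri(dr)
  expect_lt(max(abs(dj[off] - dr[off]) / dr[off]), 0.1)
})
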