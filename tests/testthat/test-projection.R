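test_that("euclidean distances match the brute-force double loop", {
  fx <- toy_expr(G = 3, n_per = 2, seed = 40)
  d <- euclidean_distance_matrix(fx$expr)
  for (i in 1:4) for (j in 1:4)
    expect_equal(d[i, j], sqrt(sum((fx$expr[, i] - fx$expr[, j])^2)))
  expect_equal(diag(d), setNames(rep(0, 4), colnames(fx$expr)))

  # identical columns and a single-gene case
  m <- cbind(a = c(1, 2), b = c(1, 2)); rownames(m) <- c("g1", "g2")
  expect_true(all(euclidean_distance_matrix(m) == 0))
  m1 <- rbind(g1 = c(a = 0, b = 3))
  expect_equal(euclidean_distance_matrix(m1)["a", "b"], 3)

  expect_error(euclidean_distance_matrix(m, character()), "empty gene subset")
  expect_error(euclidean_distance_matrix(m, "nope"), "not in expression")
})

test_that("classical MDS recovers planted 2D configurations isometrically", {
  withr::with_seed(50, pts <- matrix(rnorm(2 * 12), 12, 2))
  rownames(pts) <- paste0("s", 1:12)
  emb <- classical_mds(as.matrix(dist(pts)), dims = 2)
  expect_lt(procrustes_residual(pts, emb$points), 1e-8)
  expect_lt(emb$stress, 1e-8)
  expect_true(all(diff(emb$eigenvalues) <= 1e-8))

  # agrees with R's own cmdscale up to per-axis sign
  ref <- stats::cmdscale(as.matrix(dist(pts)), k = 2)
  for (j in 1:2)
    expect_true(max(abs(emb$points[, j] - ref[, j])) < 1e-8 ||
                max(abs(emb$points[, j] + ref[, j])) < 1e-8)
})

test_that("MDS handles the equilateral simplex and coincident points", {
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  emb <- classical_mds(d3, dims = 2)
  expect_equal(as.matrix(dist(emb$points)), d3, tolerance = 1e-10)

  d0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(unname(classical_mds(d0)$points), matrix(0, 4, 2))

  bad <- d3; bad[1, 2] <- 5
  expect_error(classical_mds(bad), "not symmetric")
  expect_error(classical_mds(d3, dims = 3), "dims")
})

test_that("MDS axis orientation is deterministic", {
  withr::with_seed(51, pts <- matrix(rnorm(20), 10, 2))
  rownames(pts) <- paste0("s", 1:10)
  e1 <- classical_mds(as.matrix(dist(pts)))
  e2 <- classical_mds(as.matrix(dist(pts)))
  expect_identical(e1$points, e2$points)
  for (j in 1:2) expect_gt(e1$points[which.max(abs(e1$points[, j])), j], 0)
})

test_that("clustering score equals the brute-force silhouette", {
  coords <- rbind(c(0, 0), c(0.2, 0), c(0, 0.2), c(5, 5), c(5.2, 5), c(5, 5.2))
  rownames(coords) <- paste0("s", 1:6)
  meta <- toy_meta(rep(c("u", "v"), each = 3), samples = rownames(coords))
  expect_equal(clustering_score(coords, meta),
               oracle_silhouette(coords, meta$category))
  expect_gt(clustering_score(coords, meta), 0.9)  # tight, far-separated clouds

  # invariance under rigid motion
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- coords %*% R + 3
  rownames(moved) <- rownames(coords)
  expect_equal(clustering_score(moved, meta), clustering_score(coords, meta),
               tolerance = 1e-10)

  # singleton category contributes zero, matching the oracle
  meta1 <- toy_meta(c("u", "u", "u", "v", "v", "w"), samples = rownames(coords))
  expect_equal(clustering_score(coords, meta1),
               oracle_silhouette(coords, meta1$category))

  expect_error(clustering_score(coords, toy_meta(rep("u", 6),
                                                 samples = rownames(coords))),
               "2 categories")
})

test_that("random labels on one cloud give near-zero clustering score", {
  scores <- vapply(1:10, function(s) withr::with_seed(600 + s, {
    coords <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
    meta <- toy_meta(sample(rep(c("u", "v"), each = 10)),
                     samples = rownames(coords))
    clustering_score(coords, meta)
  }), numeric(1))
  expect_true(all(abs(scores) < 0.1))
})

test_that("distance from control matches direct computation", {
  fx <- toy_expr(G = 4, n_per = 2, seed = 60)
  meta <- fx$meta
  meta$is_control <- meta$category == "x"
  dfc <- distance_from_control(fx$expr, meta)
  ctrl_mean <- rowMeans(fx$expr[, meta$is_control])
  for (s in names(dfc))
    expect_equal(dfc[[s]], sqrt(sum((fx$expr[, s] - ctrl_mean)^2)))

  # sample equal to the control mean is at distance 0; a unit offset is 1
  expr <- cbind(fx$expr, mean_copy = ctrl_mean, unit = ctrl_mean + c(1, 0, 0, 0))
  meta2 <- rbind(meta, data.frame(sample = c("mean_copy", "unit"), category = "z",
                                  dataset = c("mean_copy", "unit"), batch = "b0",
                                  is_control = FALSE))
  d2 <- distance_from_control(expr, meta2)
  expect_equal(unname(d2["mean_copy"]), 0)
  expect_equal(unname(d2["unit"]), 1)

  expect_error(distance_from_control(fx$expr, fx$meta), "no control")
})
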