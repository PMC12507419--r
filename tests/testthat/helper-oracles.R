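# Independent brute-force oracles used to check the package's fast paths.

# One-way ANOVA F through R's linear-model machinery.
oracle_f <- function(values, groups) {
  fit <- stats::lm(values ~ factor(groups))
  stats::anova(fit)[1L, "F value"]
}

# Exhaustive elbow search: scalar loop, point-to-line distance computed by
# projecting onto the chord and measuring the rejection.
oracle_elbow <- function(f) {
  n <- length(f)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- range(f)
  y <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else rep(0, n)
  a <- c(x[1], y[1]); b <- c(x[n], y[n])
  u <- (b - a) / sqrt(sum((b - a)^2))
  d <- numeric(n)
  for (i in seq_len(n)) {
    v <- c(x[i], y[i]) - a
    proj <- sum(v * u) * u
    d[i] <- sqrt(sum((v - proj)^2))
  }
  which.max(d)
}

# Silhouette by the definition, one sample at a time.
oracle_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Residual after optimally rotating/translating Y onto X (orthogonal
# Procrustes), as a fraction of X's centered norm.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  R <- sv$v %*% t(sv$u)
  sqrt(sum((Xc - Yc %*% R)^2) / sum(Xc^2))
}

# Median-of-ratios estimator, spelled out gene by gene.
oracle_size_factors <- function(counts) {
  ref <- apply(counts, 1L, function(r) all(r > 0))
  geo <- apply(counts[ref, , drop = FALSE], 1L, function(r) exp(mean(log(r))))
  apply(counts[ref, , drop = FALSE], 2L, function(col) median(col / geo))
}
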