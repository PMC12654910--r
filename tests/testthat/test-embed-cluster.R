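test_that("standardization centers, scales, and guards degenerate input", {
  m <- cbind(whitespace_fraction = c(1, 2, 3, 4, 5, 6, 7, 8),
             color_score = rep(5, 8),
             complexity_score = c(2, 4, 6, 8, 1, 3, 5, 7),
             vis_count = 1:8)
  z <- standardize_metrics(m)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z[, c(1, 3, 4)], 2, sd)), rep(1, 3),
               tolerance = 1e-9)
  expect_equal(unname(z[, "color_score"]), rep(0, 8))  # constant column

  # analytic three-point column with sample sd
  zc <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  expect_equal(unname(zc), c(-1, 0, 1))

  expect_error(standardize_metrics(m[1:5, ]), "relative")
})

test_that("random matrices standardize to exact unit moments", {
  set.seed(8)
  m <- matrix(rnorm(80, 10, 4), 20, 4,
              dimnames = list(NULL, metric_cols <- c(
                "whitespace_fraction", "color_score",
                "complexity_score", "vis_count")))
  z <- standardize_metrics(m)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
})

test_that("embedding is reproducible under a fixed seed", {
  z <- strata_z()
  e1 <- embed_all(z, seed = 7)
  e2 <- embed_all(z, seed = 7)
  expect_identical(e1, e2)
  for (m in c("pca", "tsne", "umap")) {
    expect_equal(dim(e1[[m]]), c(20L, 2L))
    expect_true(all(is.finite(e1[[m]])))
  }
})

test_that("PCA reproduces pairwise distances of intrinsically 2-D data", {
  set.seed(21)
  scores2d <- matrix(rnorm(24), 12, 2)
  v <- qr.Q(qr(matrix(rnorm(8), 4, 2)))      # orthonormal 4x2 loading
  x <- scores2d %*% t(v)
  x <- sweep(x, 2, colMeans(x))              # centered, rank 2
  colnames(x) <- c("whitespace_fraction", "color_score",
                   "complexity_score", "vis_count")
  coords <- medvis:::embed_pca(x)
  expect_equal(as.vector(dist(coords)), as.vector(dist(x)),
               tolerance = 1e-6)
})

test_that("all three embedding methods succeed at the minimum corpus size", {
  set.seed(31)
  z8 <- matrix(rnorm(32), 8, 4,
               dimnames = list(NULL, c("whitespace_fraction", "color_score",
                                       "complexity_score", "vis_count")))
  e <- embed_all(z8, seed = 3)
  for (m in c("pca", "tsne", "umap")) expect_equal(nrow(e[[m]]), 8L)
  expect_error(embed_all(z8[1:7, ], seed = 3), "at least 8")
})

test_that("binary clustering matches an exhaustive k-means oracle", {
  # two well-separated blobs of 5 points each; blob A has lower badness
  set.seed(55)
  emb <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 10, 0.1), 5, 2))
  z <- cbind(whitespace_fraction = c(rep(-1, 5), rep(1, 5)),
             color_score = c(rep(1, 5), rep(-1, 5)),
             complexity_score = c(rep(-1, 5), rep(1, 5)),
             vis_count = c(rep(-1, 5), rep(1, 5)))
  votes <- binary_cluster(emb, z, seed = 2)
  expect_equal(votes, c(rep(0L, 5), rep(1L, 5)))

  # oracle: enumerate all 2-partitions, take minimal within-cluster SS
  best <- NULL; best_ss <- Inf
  for (code in 1:(2^9 - 1)) {
    part <- c(0L, as.integer(intToBits(code))[1:9])
    ss <- 0
    for (g in 0:1) {
      pts <- emb[part == g, , drop = FALSE]
      if (nrow(pts) == 0) next
      ctr <- colMeans(pts)
      ss <- ss + sum(sweep(pts, 2, ctr)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- part }
  }
  # orient the oracle partition by mean badness
  b <- z[, 1] + z[, 3] + z[, 4] - z[, 2]
  oracle_bad <- as.integer(best == which.max(tapply(b, best, mean)) - 1L)
  expect_equal(votes, oracle_bad)
})

test_that("clustering is deterministic and guards degenerate embeddings", {
  z <- strata_z()
  emb <- embed_all(z, seed = 5)$pca
  expect_identical(binary_cluster(emb, z, seed = 9),
                   binary_cluster(emb, z, seed = 9))
  flat <- matrix(1, nrow(z), 2)
  expect_warning(v <- binary_cluster(flat, z, seed = 1), "identical")
  expect_equal(v, rep(0L, nrow(z)))
})

test_that("additive consensus follows the 0-3 vote-sum rule", {
  res <- consensus_votes(c(0, 1, 1, 1), c(0, 1, 0, 1), c(0, 0, 0, 1))
  expect_equal(res$vote_sum, c(0L, 2L, 1L, 3L))
  expect_equal(res$label, c("good", "not_good", "good", "not_good"))
  expect_error(consensus_votes(c(0, 1), c(0, 1, 0), c(0, 0)), "equal length")
})

test_that("flipping one method's vote moves the sum by exactly one", {
  set.seed(77)
  for (rep in 1:20) {
    v <- lapply(1:3, function(i) rbinom(6, 1, 0.5))
    base <- consensus_votes(v[[1]], v[[2]], v[[3]])$vote_sum
    meth <- sample(3, 1); fig <- sample(6, 1)
    v[[meth]][fig] <- 1L - v[[meth]][fig]
    new <- consensus_votes(v[[1]], v[[2]], v[[3]])$vote_sum
    expect_equal(sum(abs(new - base)), 1L)
    expect_true(all(new %in% 0:3))
  }
})

test_that("consensus recovers well-separated synthetic strata exactly", {
  corpus <- strata_corpus()
  fit <- strata_fit()
  truth <- corpus$truth$stratum[match(fit$labels$figure_id,
                                      corpus$truth$figure_id)]
  expect_equal(fit$labels$label,
               ifelse(truth == "good", "good", "not_good"))
  # strata are separated by >= 3 pooled standard deviations
  m <- fit$scores[, c("whitespace_fraction", "color_score",
                      "complexity_score", "vis_count")]
  sep <- vapply(m, function(col) {
    a <- col[truth == "good"]; b <- col[truth == "bad"]
    pooled <- sqrt((var(a) + var(b)) / 2)
    if (pooled == 0) Inf else abs(mean(a) - mean(b)) / pooled
  }, numeric(1))
  expect_true(any(sep >= 3))
})
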