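#' Standardize a metric matrix
#'
#' Centers each metric column to mean 0 and scales to sample standard
#' deviation 1 before embedding, so that metrics on incommensurate scales
#' (fractions, intensity units, densities, counts) contribute comparably.
#' Constant columns map to all-zero columns. The scoring method is relative,
#' so a minimum corpus size is enforced: a single figure in isolation lacks
#' the context to be called good or bad.
#'
#' @param metric_matrix Numeric matrix or data frame, figures x metrics
#'   (columns `whitespace_fraction`, `color_score`, `complexity_score`,
#'   `vis_count` in the standard pipeline).
#' @param min_n Minimum number of figures (default 8).
#' @return Numeric matrix of z-scores, same dimensions and dimnames.
#' @export
standardize_metrics <- function(metric_matrix, min_n = 8L) {
  m <- as.matrix(metric_matrix)
  storage.mode(m) <- "double"
  if (nrow(m) < min_n)
    stop_medvis("need at least ", min_n, " figures: scoring is relative and ",
                "a figure cannot be judged in isolation")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  z <- sweep(m, 2L, mu, "-")
  keep <- sdv > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2L, sdv[keep], "/")
  z[, !keep] <- 0
  z
}

#' Embed a standardized metric matrix with PCA, t-SNE and UMAP
#'
#' Produces the three two-dimensional embeddings the consensus classifier
#' votes over. PCA is deterministic, with the sign convention that the
#' largest-magnitude loading of each component is positive. t-SNE perplexity
#' is clamped to `min(30, floor((n-1)/3))` and UMAP neighbours to
#' `min(15, n-1)` so small corpora embed without error. All stochastic steps
#' are driven by sub-seeds derived from `seed`; identical seed gives
#' identical output.
#'
#' @param z_matrix Standardized n x 4 matrix from [standardize_metrics()].
#' @param seed Integer seed.
#' @return Object of class `embedding_set`: list with `pca`, `tsne`, `umap`
#'   (each an n x 2 matrix) and `seed`.
#' @export
embed_all <- function(z_matrix, seed = 1L) {
  z <- as.matrix(z_matrix)
  n <- nrow(z)
  if (n < 8L)
    stop_medvis("need at least 8 figures to embed (got ", n, ")")
  seeds <- derive_seeds(seed, 3L)

  pca <- embed_pca(z)

  perplexity <- min(30, floor((n - 1) / 3))
  if (perplexity < 1)
    stop_medvis("t-SNE requires at least 8 points for perplexity >= 2")
  tsne <- with_seed(seeds[2], {
    Rtsne::Rtsne(z, dims = 2L, perplexity = perplexity, theta = 0,
                 pca = FALSE, check_duplicates = FALSE, max_iter = 500L,
                 verbose = FALSE, num_threads = 1L)$Y
  })

  n_neighbors <- min(15L, n - 1L)
  umap <- with_seed(seeds[3], {
    uwot::umap(z, n_components = 2L, n_neighbors = n_neighbors,
               n_threads = 1L, n_sgd_threads = 0L, init = "pca",
               verbose = FALSE)
  })

  dimnames(tsne) <- dimnames(umap) <- list(rownames(z), c("dim1", "dim2"))
  structure(list(pca = pca, tsne = tsne, umap = umap, seed = seed),
            class = "embedding_set")
}

# First two principal components with a deterministic sign convention.
embed_pca <- function(z) {
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- z %*% rot
  if (k < 2L) coords <- cbind(coords, 0)
  dimnames(coords) <- list(rownames(z), c("dim1", "dim2"))
  coords
}

#' Two-group clustering of one embedding, oriented by metric badness
#'
#' Runs seeded k-means with k = 2 (25 restarts) on a 2-D embedding and
#' orients the two clusters: the badness composite
#' `b = z_whitespace + z_complexity + z_count - z_color` is averaged within
#' each cluster, and the cluster with the higher mean badness receives the
#' "bad" vote (1). If the means tie exactly, the first-indexed cluster is
#' labelled good. A degenerate embedding in which every point coincides
#' yields all-good votes with a warning.
#'
#' @param embedding n x 2 coordinate matrix.
#' @param z_matrix The standardized metric matrix (used for orientation).
#' @param seed Integer seed for the k-means restarts.
#' @param k Number of clusters (default 2; with k > 2 the `ceiling(k/2)`
#'   highest-badness clusters vote bad).
#' @return Integer vector of votes in `{0, 1}`, one per figure.
#' @export
binary_cluster <- function(embedding, z_matrix, seed = 1L, k = 2L) {
  emb <- as.matrix(embedding)
  z <- as.matrix(z_matrix)
  stopifnot(nrow(emb) == nrow(z))
  if (nrow(emb) < 8L)
    stop_medvis("need at least 8 figures to cluster")
  b <- badness_composite(z)

  if (all(apply(emb, 2L, function(col) max(col) - min(col)) < 1e-12)) {
    warning("all embedded points identical; voting all figures good",
            call. = FALSE)
    return(rep(0L, nrow(emb)))
  }

  km <- with_seed(seed, stats::kmeans(emb, centers = k, nstart = 25L,
                                      iter.max = 50L))
  cl_badness <- tapply(b, km$cluster, mean)
  ord <- order(cl_badness, seq_along(cl_badness))  # ties: first cluster best
  n_bad <- ceiling(k / 2)
  bad_clusters <- as.integer(names(cl_badness))[ord][(k - n_bad + 1L):k]
  as.integer(km$cluster %in% bad_clusters)
}

# Higher = worse: much whitespace, high complexity, many panels, little color.
badness_composite <- function(z) {
  z[, "whitespace_fraction"] + z[, "complexity_score"] +
    z[, "vis_count"] - z[, "color_score"]
}

#' Additive consensus over the three per-embedding votes
#'
#' Sums the binary bad-votes from the PCA, t-SNE and UMAP clusterings into a
#' consensus level 0--3 and binarises: levels 0 and 1 are "good", levels 2
#' and 3 "not good".
#'
#' @param votes_pca,votes_tsne,votes_umap Equal-length binary vectors.
#' @return Data frame with columns `vote_pca`, `vote_tsne`, `vote_umap`,
#'   `vote_sum` (0--3) and `label` (`"good"`/`"not_good"`).
#' @export
consensus_votes <- function(votes_pca, votes_tsne, votes_umap) {
  n <- length(votes_pca)
  if (length(votes_tsne) != n || length(votes_umap) != n)
    stop_medvis("vote vectors must have equal length")
  stopifnot(all(c(votes_pca, votes_tsne, votes_umap) %in% 0:1))
  vote_sum <- as.integer(votes_pca + votes_tsne + votes_umap)
  data.frame(
    vote_pca = as.integer(votes_pca),
    vote_tsne = as.integer(votes_tsne),
    vote_umap = as.integer(votes_umap),
    vote_sum = vote_sum,
    label = ifelse(vote_sum <= 1L, "good", "not_good"),
    stringsAsFactors = FALSE
  )
}

#' Run the full consensus classification
#'
#' Convenience wrapper: standardize, embed with all three methods, cluster
#' each embedding, and combine the votes.
#'
#' @param metric_matrix Figures x 4 metric matrix or data frame.
#' @param seed Integer seed.
#' @param k Clusters per embedding (default 2).
#' @return List with `z` (standardized matrix), `embeddings`
#'   (an `embedding_set`) and `consensus` (the [consensus_votes()] frame).
#' @export
consensus_classify <- function(metric_matrix, seed = 1L, k = 2L) {
  z <- standardize_metrics(metric_matrix)
  emb <- embed_all(z, seed)
  seeds <- derive_seeds(seed, 6L)[4:6]
  v_pca <- binary_cluster(emb$pca, z, seeds[1], k)
  v_tsne <- binary_cluster(emb$tsne, z, seeds[2], k)
  v_umap <- binary_cluster(emb$umap, z, seeds[3], k)
  list(z = z, embeddings = emb,
       consensus = consensus_votes(v_pca, v_tsne, v_umap))
}
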