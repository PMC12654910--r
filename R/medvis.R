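#' Score and classify a corpus of figures
#'
#' The main entry point: scores every figure on the four quality metrics
#' (white-space fraction, color score, edge complexity, visualization
#' count), standardizes the metric matrix, embeds it with PCA, t-SNE and
#' UMAP, clusters each embedding into two groups with seeded k-means,
#' combines the three bad-votes additively into a consensus level 0--3
#' (0--1 = good, 2--3 = not good), and derives quartile thresholds with
#' per-figure advice. The method is relative: it needs at least 8 figures,
#' and all scores and labels are meaningful only within the corpus.
#'
#' @param figures A [figure_set()], e.g. from [load_figure_set()] or
#'   [generate_corpus()].
#' @param seed Integer seed driving every stochastic step (t-SNE, UMAP,
#'   k-means restarts). Identical seed and corpus give identical output.
#' @param k Clusters per embedding (default 2).
#' @param white_threshold Whiteness threshold in 0--255 (default 250).
#' @param gradient_threshold Edge binarization fraction (default 0.10).
#' @param connectivity 4 or 8 (default 8) for edge components.
#' @param quantile_config Per-metric quantile/direction overrides, see
#'   [default_quantile_config()].
#' @return Object of class `medvis`: list with `scores`, `z`, `embeddings`,
#'   `labels`, `thresholds`, `reports`, `consensus` and `config`.
#' @examples
#' corpus <- generate_corpus(12, seed = 42)
#' fit <- medvis(corpus$figures, seed = 42)
#' fit
#' summary(fit)
#' @export
medvis <- function(figures, seed = 1L, k = 2L, white_threshold = 250,
                   gradient_threshold = 0.10, connectivity = 8L,
                   quantile_config = default_quantile_config()) {
  stopifnot(inherits(figures, "figure_set"))
  cfg <- list(seed = as.integer(seed), k = as.integer(k),
              white_threshold = white_threshold,
              gradient_threshold = gradient_threshold,
              connectivity = as.integer(connectivity))

  scores <- score_corpus(figures, config = cfg)
  m <- scores[, metric_names()]
  rownames(m) <- scores$figure_id

  cls <- consensus_classify(m, seed = cfg$seed, k = cfg$k)
  emb <- cls$embeddings
  embeddings <- data.frame(
    figure_id = scores$figure_id,
    pca_x = emb$pca[, 1], pca_y = emb$pca[, 2],
    tsne_x = emb$tsne[, 1], tsne_y = emb$tsne[, 2],
    umap_x = emb$umap[, 1], umap_y = emb$umap[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  labels <- cbind(data.frame(figure_id = scores$figure_id,
                             stringsAsFactors = FALSE),
                  cls$consensus)

  thresholds <- compute_thresholds(m, quantile_config)
  attr(thresholds, "ranges") <- lapply(
    stats::setNames(metric_names(), metric_names()),
    function(met) range(m[[met]]))
  reports <- lapply(seq_len(nrow(scores)), function(i)
    evaluate_figure(scores[i, ], thresholds))

  structure(list(
    scores = scores,
    z = cls$z,
    embeddings = embeddings,
    labels = labels,
    thresholds = thresholds,
    reports = reports,
    config = c(cfg, list(quantile_config = quantile_config))
  ), class = "medvis")
}

#' @export
print.medvis <- function(x, ...) {
  n <- nrow(x$scores)
  n_good <- sum(x$labels$label == "good")
  cat("<medvis> consensus figure-quality fit\n")
  cat("  figures:", n, " (good:", n_good, ", not good:", n - n_good, ")\n")
  cat("  seed:", x$config$seed, " k:", x$config$k, "\n")
  cat("  consensus vote sums:",
      paste(sprintf("%d:%d", 0:3, tabulate(x$labels$vote_sum + 1L, 4L)),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.medvis <- function(object, ...) {
  m <- object$scores[, metric_names()]
  structure(list(
    n = nrow(object$scores),
    metric_summary = do.call(rbind, lapply(m, summary)),
    thresholds = object$thresholds,
    label_table = table(object$labels$label),
    n_flagged = vapply(object$reports,
                       function(r) sum(r$metrics$flag), integer(1))
  ), class = "summary.medvis")
}

#' @export
print.summary.medvis <- function(x, ...) {
  cat("medvis fit over", x$n, "figures\n\nMetric distributions:\n")
  print(round(x$metric_summary, 4))
  cat("\nThresholds:\n")
  print(as.data.frame(x$thresholds), row.names = FALSE)
  cat("\nConsensus labels:\n")
  print(x$label_table)
  cat("\nFigures with 0/1/2/3/4 flagged metrics:",
      paste(tabulate(x$n_flagged + 1L, 5L), collapse = "/"), "\n")
  invisible(x)
}

#' @export
labels.medvis <- function(object, ...) {
  stats::setNames(object$labels$label, object$labels$figure_id)
}

#' Plot the three embeddings of a fitted corpus
#'
#' One panel per reduction method, points colored by the consensus label.
#'
#' @param x A fitted `medvis` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.medvis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- ifelse(x$labels$label == "good", "#2166ac", "#b2182b")
  for (method in c("pca", "tsne", "umap")) {
    graphics::plot(x$embeddings[[paste0(method, "_x")]],
                   x$embeddings[[paste0(method, "_y")]],
                   col = cols, pch = 19, xlab = "dim 1", ylab = "dim 2",
                   main = toupper(method), ...)
  }
  graphics::legend("topright", legend = c("good", "not good"),
                   col = c("#2166ac", "#b2182b"), pch = 19, bty = "n")
  invisible(x)
}

#' Run the full scoring pipeline on a figure directory
#'
#' Load -> score -> embed -> cluster -> consensus -> thresholds ->
#' advice/gauges -> write, all under one seed, plus the weight-sensitivity
#' analysis and (when ratings or annotations are present) the validation
#' reports. All outputs land in `out_dir` (see [write_results()]); the
#' sensitivity table is written as `sensitivity.csv` with
#' `sensitivity_summary.json`, and validation as `validation_report.json`
#' with `confusion.csv` and `vote_table.csv`.
#'
#' @param images_dir Directory of raster figures.
#' @param captions_source Captions directory or table (see
#'   [load_figure_set()]).
#' @param out_dir Output directory.
#' @param annotations,ratings Optional CSV paths (see [load_figure_set()]).
#' @param seed Integer seed.
#' @param gauges Render gauge charts (default TRUE).
#' @param delta,levels Sensitivity grid parameters (defaults 0.10 and 3).
#' @param classify_quantile Quantile split for flip counting (default 0.5).
#' @param ... Further arguments to [medvis()].
#' @return The fitted `medvis` object, invisibly; attribute `"manifest"`
#'   holds the manifest path.
#' @export
run_pipeline <- function(images_dir, captions_source = NULL, out_dir,
                         annotations = NULL, ratings = NULL, seed = 1L,
                         gauges = TRUE, delta = 0.10, levels = 3L,
                         classify_quantile = 0.5, ...) {
  figures <- load_figure_set(images_dir, captions_source,
                             annotations = annotations, ratings = ratings)
  fit <- medvis(figures, seed = seed, ...)
  manifest <- write_results(fit, out_dir, gauges = gauges)

  base <- weight_config()
  sens <- stability_summary(fit$z, base,
                            grid = weight_grid(base, delta, levels),
                            classify_quantile = classify_quantile)
  write_csv_stable(sens$per_config, file.path(out_dir, "sensitivity.csv"))
  jsonlite::write_json(sens$summary,
                       file.path(out_dir, "sensitivity_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(figures$ratings)) {
    rep <- label_agreement_report(labels(fit), figures$ratings)
    jsonlite::write_json(
      list(accuracy = rep$accuracy,
           precision = as.list(rep$precision),
           recall = as.list(rep$recall)),
      file.path(out_dir, "validation_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(rep$confusion),
                     file.path(out_dir, "confusion.csv"), row.names = FALSE)
    write_csv_stable(rep$per_figure, file.path(out_dir, "vote_table.csv"))
  }
  if (!is.null(figures$annotations)) {
    ids <- intersect(fit$scores$figure_id, names(figures$annotations))
    if (length(ids) >= 2L) {
      chi <- count_agreement_chisq(
        fit$scores$vis_count[match(ids, fit$scores$figure_id)],
        figures$annotations[ids])
      jsonlite::write_json(chi, file.path(out_dir, "count_validation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  attr(fit, "manifest") <- manifest
  invisible(fit)
}
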