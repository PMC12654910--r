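#' Construct a metric weight configuration
#'
#' Non-negative weights for the four metrics, normalized to sum to 1.
#'
#' @param w_complexity,w_color,w_whitespace,w_count Non-negative reals.
#' @return Object of class `weight_config`: named numeric vector summing to 1.
#' @export
weight_config <- function(w_complexity = 1, w_color = 1,
                          w_whitespace = 1, w_count = 1) {
  w <- c(w_complexity = w_complexity, w_color = w_color,
         w_whitespace = w_whitespace, w_count = w_count)
  if (any(!is.finite(w)) || any(w < 0))
    stop_medvis("weights must be finite and non-negative")
  s <- sum(w)
  if (s <= 0) stop_medvis("at least one weight must be positive")
  structure(w / s, class = "weight_config")
}

#' Full-factorial weight perturbation grid
#'
#' Varies each of the four metric weights over `levels` multiplicative
#' levels spanning `1 - delta` to `1 + delta` (for `levels = 3`:
#' multipliers 1-delta, 1, 1+delta), taking the full factorial over the four
#' weights. Each perturbed configuration is renormalized to sum to 1. With
#' the defaults (delta = 0.10, levels = 3) the grid has 3^4 = 81
#' configurations, the unperturbed baseline among them.
#'
#' @param base Baseline [weight_config()].
#' @param delta Relative perturbation in (0, 1) (default 0.10).
#' @param levels Odd integer >= 1: levels per weight (default 3). An even
#'   value is rejected because the baseline must be a grid point.
#' @return List of `levels^4` `weight_config`s; attribute `multipliers` holds
#'   the `levels^4 x 4` multiplier matrix, attribute `baseline_index` the
#'   position of the all-ones configuration.
#' @export
weight_grid <- function(base = weight_config(), delta = 0.10, levels = 3L) {
  stopifnot(inherits(base, "weight_config"))
  if (delta <= 0 || delta >= 1) stop_medvis("delta must be in (0, 1)")
  levels <- as.integer(levels)
  if (levels < 1L) stop_medvis("levels must be >= 1")
  if (levels %% 2L == 0L)
    stop_medvis("levels must be odd so the baseline is a grid point")
  mult <- if (levels == 1L) 1 else 1 + delta * seq(-1, 1, length.out = levels)
  grid <- as.matrix(expand.grid(m_complexity = mult, m_color = mult,
                                m_whitespace = mult, m_count = mult,
                                KEEP.OUT.ATTRS = FALSE))
  configs <- lapply(seq_len(nrow(grid)), function(i) {
    w <- unname(unclass(base) * grid[i, ])
    weight_config(w[1], w[2], w[3], w[4])
  })
  structure(configs,
            multipliers = grid,
            baseline_index = which(rowSums(abs(grid - 1)) < 1e-12)[1])
}

#' Weighted composite desirability scores and ranks
#'
#' The composite desirability of a figure weighs its standardized metrics
#' with favorable directions signed: low complexity, high color, low
#' whitespace and few panels are desirable, so
#' `d = -w_cx * z_complexity + w_col * z_color - w_ws * z_whitespace -
#' w_ct * z_count`. Ranks are 1 = most desirable, ties averaged.
#'
#' @param z_matrix Standardized metric matrix from [standardize_metrics()].
#' @param weights A [weight_config()].
#' @return Data frame with columns `score` and `rank`, one row per figure.
#' @export
composite_scores <- function(z_matrix, weights = weight_config()) {
  stopifnot(inherits(weights, "weight_config"))
  z <- as.matrix(z_matrix)
  score <- -weights[["w_complexity"]] * z[, "complexity_score"] +
    weights[["w_color"]] * z[, "color_score"] -
    weights[["w_whitespace"]] * z[, "whitespace_fraction"] -
    weights[["w_count"]] * z[, "vis_count"]
  data.frame(score = unname(score),
             rank = rank(-score, ties.method = "average"),
             row.names = rownames(z))
}

#' Weight-sensitivity analysis of the composite ranking
#'
#' Recomputes composite scores, ranks and a quantile-split classification
#' under every configuration of a perturbation grid, and summarizes how far
#' each departs from the baseline: rank divergence (1 - Spearman correlation
#' with the baseline ranking), mean absolute rank shift, and the number of
#' classification flips (figures whose good/not-good label changes).
#'
#' @param z_matrix Standardized metric matrix.
#' @param base Baseline [weight_config()].
#' @param grid Perturbation grid from [weight_grid()]; defaults to the
#'   81-configuration grid at delta = 0.10.
#' @param classify_quantile Quantile of the composite score above which (>=)
#'   a figure is classified good (default 0.5, the median split).
#' @param min_n Minimum corpus size (default 8).
#' @return Object of class `medvis_sensitivity`: list with `per_config`
#'   (data frame: config_id, the four multipliers, divergence,
#'   mean_abs_rank_shift, flips) and `summary` (median and range of
#'   divergence, median rank shift, median and max flips).
#' @export
stability_summary <- function(z_matrix, base = weight_config(),
                              grid = weight_grid(base),
                              classify_quantile = 0.5, min_n = 8L) {
  z <- as.matrix(z_matrix)
  if (nrow(z) < min_n)
    stop_medvis("need at least ", min_n, " figures for sensitivity analysis")
  base_cs <- composite_scores(z, base)
  base_lab <- quantile_classify(base_cs$score, classify_quantile)

  mult <- attr(grid, "multipliers")
  rows <- lapply(seq_along(grid), function(i) {
    cs <- composite_scores(z, grid[[i]])
    lab <- quantile_classify(cs$score, classify_quantile)
    data.frame(
      config_id = i,
      m_complexity = mult[i, "m_complexity"],
      m_color = mult[i, "m_color"],
      m_whitespace = mult[i, "m_whitespace"],
      m_count = mult[i, "m_count"],
      divergence = rank_divergence(base_cs$rank, cs$rank),
      mean_abs_rank_shift = mean(abs(cs$rank - base_cs$rank)),
      flips = sum(lab != base_lab)
    )
  })
  per_config <- do.call(rbind, rows)
  structure(list(
    per_config = per_config,
    summary = list(
      n_configs = nrow(per_config),
      median_divergence = stats::median(per_config$divergence),
      divergence_range = range(per_config$divergence),
      median_rank_shift = stats::median(per_config$mean_abs_rank_shift),
      median_flips = stats::median(per_config$flips),
      max_flips = max(per_config$flips)
    ),
    classify_quantile = classify_quantile,
    baseline = base
  ), class = "medvis_sensitivity")
}

# good iff composite score >= the corpus quantile of scores
quantile_classify <- function(score, q) {
  thr <- stats::quantile(score, q, type = 7)
  ifelse(score >= thr, "good", "not_good")
}

#' Rank divergence between two rankings
#'
#' One minus the Spearman correlation (average ranks for ties) of two rank
#' vectors of the same figures: 0 for identical rankings (up to tie
#' structure), 2 for exactly reversed ones.
#'
#' @param rank_a,rank_b Numeric rank vectors of equal length.
#' @return Divergence in `[0, 2]`.
#' @export
rank_divergence <- function(rank_a, rank_b) {
  stopifnot(length(rank_a) == length(rank_b))
  if (stats::sd(rank_a) == 0 || stats::sd(rank_b) == 0) return(0)
  1 - stats::cor(rank_a, rank_b, method = "spearman")
}

#' @export
print.medvis_sensitivity <- function(x, ...) {
  s <- x$summary
  cat("<medvis_sensitivity>", s$n_configs, "weight configurations\n")
  cat(sprintf("  rank divergence: median %.3g (range %.3g - %.3g)\n",
              s$median_divergence, s$divergence_range[1],
              s$divergence_range[2]))
  cat(sprintf("  mean absolute rank shift: median %.3g\n",
              s$median_rank_shift))
  cat(sprintf("  classification flips: median %g, max %g\n",
              s$median_flips, s$max_flips))
  invisible(x)
}
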