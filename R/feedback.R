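#' Default quantile/direction configuration for threshold feedback
#'
#' Each metric gets a corpus quantile and a flag direction. Defaults:
#' visualization count uses the first quartile and flags values above it
#' (more than a handful of panels is excessive); white-space fraction and
#' complexity use the third quartile and flag values above it; color score
#' uses the first quartile and flags values below it (too little color
#' differentiation). A value exactly at its threshold passes -- flags are
#' strict inequalities.
#'
#' @return Named list: per metric, `list(quantile =, flag_above =)`.
#' @export
default_quantile_config <- function() {
  list(
    whitespace_fraction = list(quantile = 0.75, flag_above = TRUE),
    color_score = list(quantile = 0.25, flag_above = FALSE),
    complexity_score = list(quantile = 0.75, flag_above = TRUE),
    vis_count = list(quantile = 0.25, flag_above = TRUE)
  )
}

#' Compute per-metric quantile thresholds over a corpus
#'
#' Quantiles are computed by linear interpolation between order statistics
#' (position `p * (n - 1)`, zero-based -- `stats::quantile(type = 7)`).
#'
#' @param metric_matrix Figures x metrics data frame or matrix containing the
#'   four metric columns.
#' @param quantile_config Named list as in [default_quantile_config()];
#'   entries override the defaults.
#' @param min_n Minimum corpus size (default 8).
#' @return Object of class `threshold_set`: data frame with columns
#'   `metric`, `threshold`, `quantile`, `flag_above`.
#' @export
compute_thresholds <- function(metric_matrix,
                               quantile_config = default_quantile_config(),
                               min_n = 8L) {
  m <- as.data.frame(metric_matrix)
  if (nrow(m) < min_n)
    stop_medvis("need at least ", min_n, " figures to set corpus thresholds")
  cfg <- utils::modifyList(default_quantile_config(), quantile_config)
  bad <- setdiff(names(cfg), metric_names())
  if (length(bad))
    stop_medvis("unknown metric in quantile_config: ",
                paste(bad, collapse = ", "))
  rows <- lapply(metric_names(), function(met) {
    q <- cfg[[met]]$quantile
    if (!is.numeric(q) || q <= 0 || q >= 1)
      stop_medvis("quantile for ", met, " must be in (0, 1)")
    data.frame(
      metric = met,
      threshold = unname(stats::quantile(m[[met]], q, type = 7)),
      quantile = q,
      flag_above = isTRUE(cfg[[met]]$flag_above),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), class = c("threshold_set", "data.frame"))
}

advice_templates <- function() {
  c(
    whitespace_fraction = paste0(
      "Reduce unused white space: crop margins or enlarge panels so the ",
      "figure area is used efficiently."),
    color_score = paste0(
      "Improve color differentiation: the figure is close to achromatic; ",
      "use distinct hues to separate data series or regions."),
    complexity_score = paste0(
      "Simplify layout complexity: the figure contains many distinct visual ",
      "elements; merge or remove panels and decorations."),
    vis_count = paste0(
      "Reduce the number of visualizations: split the figure or drop ",
      "subpanels so each figure carries one message.")
  )
}

#' Evaluate one figure against corpus thresholds
#'
#' Flags each metric that falls strictly on the unfavorable side of its
#' threshold and attaches the fixed advice string for every flagged metric.
#' Advice is a pure function of the flag pattern.
#'
#' @param metrics One-row data frame (or named list) with the four metric
#'   values, plus optionally `figure_id`.
#' @param thresholds A `threshold_set` from [compute_thresholds()].
#' @return Object of class `threshold_report`: list with `figure_id` and a
#'   data frame `metrics` (columns `metric`, `value`, `threshold`, `flag`,
#'   `advice`).
#' @export
evaluate_figure <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  fid <- if (!is.null(metrics$figure_id)) as.character(metrics$figure_id)
         else "figure"
  tmpl <- advice_templates()
  rows <- lapply(seq_len(nrow(thresholds)), function(i) {
    met <- thresholds$metric[i]
    val <- as.numeric(metrics[[met]])
    thr <- thresholds$threshold[i]
    flag <- if (thresholds$flag_above[i]) val > thr else val < thr
    data.frame(metric = met, value = val, threshold = thr, flag = flag,
               advice = if (flag) unname(tmpl[[met]]) else "",
               stringsAsFactors = FALSE)
  })
  structure(list(figure_id = fid, metrics = do.call(rbind, rows)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>", x$figure_id, "--",
      sum(x$metrics$flag), "of", nrow(x$metrics), "metrics flagged\n")
  print(x$metrics[, c("metric", "value", "threshold", "flag")], row.names = FALSE)
  invisible(x)
}

# Text content of an advice file: one line per flagged metric.
advice_text <- function(report) {
  flagged <- report$metrics$advice[report$metrics$flag]
  if (length(flagged) == 0L) "No issues detected." else flagged
}

#' Render gauge charts for one figure
#'
#' One dial per metric: the arc spans the corpus minimum to maximum for that
#' metric, the needle sits at the figure's value, and a red mark indicates
#' the threshold for acceptable performance. File names are
#' `<figure_id>_<metric>.png`; identical inputs render identical pixels.
#'
#' @param report A `threshold_report` from [evaluate_figure()].
#' @param thresholds The `threshold_set` used, which must carry the corpus
#'   ranges (see [medvis()]) -- otherwise ranges default to 0..max(value,
#'   threshold).
#' @param out_dir Output directory for the four PNG files.
#' @param width,height Image size in pixels (default 480 x 300).
#' @return Character vector of the four file paths, invisibly.
#' @export
render_gauges <- function(report, thresholds, out_dir,
                          width = 480, height = 300) {
  stopifnot(inherits(report, "threshold_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop_medvis("cannot create gauge directory: ", out_dir)
  }
  ranges <- attr(thresholds, "ranges")
  paths <- character(nrow(report$metrics))
  for (i in seq_len(nrow(report$metrics))) {
    row <- report$metrics[i, ]
    rng <- if (!is.null(ranges)) ranges[[row$metric]]
           else c(0, max(row$value, row$threshold))
    path <- file.path(out_dir, paste0(report$figure_id, "_", row$metric,
                                      ".png"))
    grDevices::png(path, width = width, height = height, res = 96)
    tryCatch(
      draw_gauge(row$value, row$threshold, rng[1], rng[2],
                 title = paste(report$figure_id, "-", row$metric),
                 flagged = row$flag),
      finally = grDevices::dev.off()
    )
    paths[i] <- path
  }
  invisible(paths)
}

# Draw one half-circle gauge on the current device.
draw_gauge <- function(value, threshold, lo, hi, title = "", flagged = FALSE) {
  if (hi <= lo) hi <- lo + 1        # degenerate corpus range
  frac <- function(v) (min(max(v, lo), hi) - lo) / (hi - lo)
  ang <- function(v) pi * (1 - frac(v))   # left (pi) = lo, right (0) = hi
  op <- graphics::par(mar = c(2, 1, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.15, 1.15), ylim = c(-0.25, 1.15),
                        asp = 1)
  th <- seq(pi, 0, length.out = 181)
  graphics::polygon(c(cos(th), rev(0.72 * cos(th))),
                    c(sin(th), rev(0.72 * sin(th))),
                    col = "grey92", border = "grey40")
  # tick marks
  for (tk in seq(lo, hi, length.out = 5)) {
    a <- ang(tk)
    graphics::segments(0.72 * cos(a), 0.72 * sin(a), cos(a), sin(a),
                       col = "grey60")
    graphics::text(1.08 * cos(a), 1.08 * sin(a), signif(tk, 3), cex = 0.7)
  }
  # threshold: red mark
  a_thr <- ang(threshold)
  graphics::segments(0.68 * cos(a_thr), 0.68 * sin(a_thr),
                     1.04 * cos(a_thr), 1.04 * sin(a_thr),
                     col = "red", lwd = 3)
  # needle
  a_val <- ang(value)
  graphics::arrows(0, 0, 0.88 * cos(a_val), 0.88 * sin(a_val),
                   length = 0.08, lwd = 3,
                   col = if (flagged) "firebrick" else "grey20")
  graphics::points(0, 0, pch = 16, cex = 1.4)
  graphics::text(0, -0.18, sprintf("value %.4g  |  threshold %.4g",
                                   value, threshold), cex = 0.8)
  graphics::title(main = title, cex.main = 0.9)
  invisible(NULL)
}
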