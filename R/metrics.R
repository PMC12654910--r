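#' White-space fraction of a figure
#'
#' Fraction of pixels whose three channels all reach the whiteness threshold.
#' The default threshold of 250/255 tolerates the near-white ringing JPEG
#' compression leaves around line art.
#'
#' @param image H x W x 3 array of 8-bit intensities.
#' @param white_threshold Intensity in 0--255 a channel must reach for the
#'   pixel to count as white (default 250).
#' @return Fraction in `[0, 1]`.
#' @seealso [white_mask()] for the underlying boolean mask.
#' @export
whitespace_fraction <- function(image, white_threshold = 250) {
  mean(white_mask(image, white_threshold))
}

#' White-pixel mask
#'
#' Boolean H x W mask of the pixels [whitespace_fraction()] counts as white,
#' exposed so white regions can be overlaid on the figure for inspection.
#'
#' @inheritParams whitespace_fraction
#' @return Logical H x W matrix.
#' @export
white_mask <- function(image, white_threshold = 250) {
  check_raster(image)
  stopifnot(white_threshold >= 0, white_threshold <= 255)
  image[, , 1] >= white_threshold &
    image[, , 2] >= white_threshold &
    image[, , 3] >= white_threshold
}

#' Colorfulness score of a figure
#'
#' Per pixel, the mean of the three pairwise absolute channel differences
#' |R-G|, |G-B|, |R-B|; the score is the mean over all pixels. Achromatic
#' images (R = G = B everywhere) score 0; a saturated primary such as pure
#' red scores (255 + 0 + 255)/3 = 170, the maximum attainable.
#'
#' @inheritParams whitespace_fraction
#' @return Score in `[0, 170]`, in 8-bit intensity units.
#' @export
color_score <- function(image) {
  check_raster(image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mean((abs(r - g) + abs(g - b) + abs(r - b)) / 3)
}

#' Structural complexity score of a figure
#'
#' Edge-based segmentation density: the image is converted to luminance
#' (0.299 R + 0.587 G + 0.114 B), gradient magnitude is computed with 3 x 3
#' horizontal/vertical Sobel kernels, the magnitude is binarised at
#' `gradient_threshold` times the maximum attainable magnitude, and connected
#' components of the resulting edge mask are counted. The score is components
#' per megapixel, so it is invariant to uniform downscaling of busy content.
#'
#' @inheritParams whitespace_fraction
#' @param gradient_threshold Fraction in (0, 1) of the maximum attainable
#'   gradient magnitude (default 0.10).
#' @param connectivity 4 or 8 (default 8): pixel neighbourhood used when
#'   joining edge pixels into components.
#' @return Non-negative score (components per megapixel).
#' @export
complexity_score <- function(image, gradient_threshold = 0.10,
                             connectivity = 8L) {
  check_raster(image)
  stopifnot(gradient_threshold > 0, gradient_threshold < 1,
            connectivity %in% c(4L, 8L))
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g <- sobel_magnitude(lum)
  # Sobel row sums are 1+2+1 = 4, so each direction peaks at 4*255
  max_mag <- sqrt(2) * 4 * 255
  mask <- g >= gradient_threshold * max_mag
  n_comp <- count_components(mask, connectivity)
  n_comp / (prod(dim(lum)) / 1e6)
}

# 3x3 Sobel gradient magnitude with replicated borders.
sobel_magnitude <- function(lum) {
  h <- nrow(lum); w <- ncol(lum)
  up    <- lum[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down  <- lum[c(seq_len(h - 1L) + 1L, h), , drop = FALSE]
  pad_lr <- function(m) {
    left  <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
    right <- m[, c(seq_len(w - 1L) + 1L, w), drop = FALSE]
    list(left = left, right = right)
  }
  lr  <- pad_lr(lum); ulr <- pad_lr(up); dlr <- pad_lr(down)
  # gx: horizontal derivative; gy: vertical derivative
  gx <- (ulr$right - ulr$left) + 2 * (lr$right - lr$left) +
    (dlr$right - dlr$left)
  gy <- (dlr$left - ulr$left) + 2 * (down - up) + (dlr$right - ulr$right)
  sqrt(gx^2 + gy^2)
}

# Count connected components of a logical mask (4- or 8-connectivity)
# via the component structure of the pixel-adjacency graph.
count_components <- function(mask, connectivity = 8L) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  h <- nrow(mask); w <- ncol(mask)
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)

  edge_pairs <- function(dr, dc) {
    rows <- seq_len(h); cols <- seq_len(w)
    r1 <- if (dr >= 0) rows[rows + dr <= h] else rows[rows + dr >= 1L]
    c1 <- if (dc >= 0) cols[cols + dc <= w] else cols[cols + dc >= 1L]
    if (!length(r1) || !length(c1)) return(NULL)
    a <- mask[r1, c1, drop = FALSE]
    b <- mask[r1 + dr, c1 + dc, drop = FALSE]
    hit <- which(a & b)
    if (!length(hit)) return(NULL)
    rr <- r1[(hit - 1L) %% length(r1) + 1L]
    cc <- c1[(hit - 1L) %/% length(r1) + 1L]
    cbind(vid[(cc - 1L) * h + rr],
          vid[(cc + dc - 1L) * h + rr + dr])
  }

  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(shifts, function(s) edge_pairs(s[1], s[2])))

  if (is.null(edges) || nrow(edges) == 0L) return(length(idx))
  union_find_components(length(idx), edges)
}

# Weighted union-find with path halving; returns the number of components
# among n vertices given an edge matrix.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  n_comp <- n
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) {
      parent[rb] <- ra
      n_comp <- n_comp - 1L
    }
  }
  n_comp
}

#' Estimate the number of visualizations from a caption
#'
#' Multi-panel figures conventionally label their subpanels with
#' parenthesized letters -- "(A)", "(b)" and so on. The count is the number
#' of distinct case-folded single letters found this way. Captions without
#' any such identifier fall back to a count of 1 so the figure remains
#' scoreable, flagged by `count_source = "fallback"`.
#'
#' @param caption Character scalar (may be empty or `NA`).
#' @return List with `vis_count` (integer >= 1), `count_source`
#'   (`"parsed"` or `"fallback"`), and `labels` (the distinct lower-case
#'   letters found, possibly empty).
#' @export
count_visualizations <- function(caption) {
  if (length(caption) != 1L) stop_medvis("`caption` must be a single string")
  if (is.na(caption)) caption <- ""
  m <- gregexpr("\\(([A-Za-z])\\)", caption)[[1]]
  if (m[1] == -1L) {
    return(list(vis_count = 1L, count_source = "fallback",
                labels = character(0)))
  }
  hits <- regmatches(caption, gregexpr("\\(([A-Za-z])\\)", caption))[[1]]
  letters_found <- sort(unique(tolower(substr(hits, 2L, 2L))))
  list(vis_count = length(letters_found), count_source = "parsed",
       labels = letters_found)
}

#' Score one figure on all four metrics
#'
#' Composes [whitespace_fraction()], [color_score()], [complexity_score()]
#' and [count_visualizations()] into one metric vector.
#'
#' @param figure A [figure_record()].
#' @param config Optional list overriding metric parameters:
#'   `white_threshold`, `gradient_threshold`, `connectivity`.
#' @return A one-row data frame with columns `figure_id`,
#'   `whitespace_fraction`, `color_score`, `complexity_score`, `vis_count`,
#'   `count_source`.
#' @export
score_figure <- function(figure, config = list()) {
  stopifnot(inherits(figure, "figure_record"))
  cfg <- utils::modifyList(default_metric_config(), config)
  res <- tryCatch({
    cnt <- count_visualizations(figure$caption)
    data.frame(
      figure_id = figure$figure_id,
      whitespace_fraction = whitespace_fraction(figure$image,
                                                cfg$white_threshold),
      color_score = color_score(figure$image),
      complexity_score = complexity_score(figure$image,
                                          cfg$gradient_threshold,
                                          cfg$connectivity),
      vis_count = cnt$vis_count,
      count_source = cnt$count_source,
      stringsAsFactors = FALSE
    )
  }, error = function(e)
    stop_medvis("scoring figure '", figure$figure_id, "': ",
                conditionMessage(e)))
  res
}

default_metric_config <- function() {
  list(white_threshold = 250, gradient_threshold = 0.10, connectivity = 8L)
}

#' Score every figure in a corpus
#'
#' @param figures A [figure_set()].
#' @inheritParams score_figure
#' @return Data frame with one row per figure, in corpus order.
#' @export
score_corpus <- function(figures, config = list()) {
  stopifnot(inherits(figures, "figure_set"))
  do.call(rbind, lapply(figures$records, score_figure, config = config))
}

#' Render a white-pixel overlay
#'
#' Marks every pixel counted as white in red, for visual auditing of the
#' white-space metric.
#'
#' @inheritParams whitespace_fraction
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
white_overlay <- function(image, path, white_threshold = 250) {
  mask <- white_mask(image, white_threshold)
  out <- image / 255
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[mask] <- 1; g[mask] <- 0; b[mask] <- 0
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  png::writePNG(out, path)
  invisible(path)
}
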