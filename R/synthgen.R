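#' Specification for one synthetic multi-panel figure
#'
#' Describes a figure the generator can draw with known ground truth: a
#' white canvas tiled into `panel_count` subpanels, each containing
#' `shape_density` disjoint filled shapes (rectangles and discs), with the
#' overall white-pixel fraction steered to `white_target`. Chromatic figures
#' use saturated colors; achromatic figures use grays (R = G = B), which
#' score exactly 0 on the color metric. The caption is auto-written with
#' parenthesized letter identifiers "(a)", "(b)", ... so the caption parser
#' recovers `panel_count`.
#'
#' @param panel_count Integer in 1..26 (letter labels).
#' @param white_target Target white-pixel fraction in `[0, 1]`.
#' @param palette_mode `"chromatic"` or `"achromatic"`.
#' @param shape_density Integer >= 0, shapes per panel.
#' @param canvas `c(H, W)` in pixels (default `c(240, 360)`).
#' @param seed Integer seed; the same spec always renders the same figure.
#' @return Object of class `figure_spec`.
#' @export
figure_spec <- function(panel_count, white_target,
                        palette_mode = c("chromatic", "achromatic"),
                        shape_density = 4L, canvas = c(240L, 360L),
                        seed = 1L) {
  palette_mode <- match.arg(palette_mode)
  panel_count <- as.integer(panel_count)
  shape_density <- as.integer(shape_density)
  stopifnot(panel_count >= 1L, panel_count <= 26L,
            white_target >= 0, white_target <= 1,
            shape_density >= 0L, length(canvas) == 2L,
            all(canvas >= 40L))
  structure(list(panel_count = panel_count, white_target = white_target,
                 palette_mode = palette_mode, shape_density = shape_density,
                 canvas = as.integer(canvas), seed = as.integer(seed)),
            class = "figure_spec")
}

#' Generate one synthetic figure with ground truth
#'
#' Renders the figure described by a [figure_spec()]. Shapes are laid out on
#' a jittered sub-grid inside each panel so they stay disjoint (each extra
#' shape adds its own edge component, making the complexity metric strictly
#' increasing in shape density), and their size is adjusted by bisection
#' (at most 20 rounds) until the white-pixel fraction is within 0.02 of
#' `white_target`; an unreachable target raises an error.
#'
#' @param spec A [figure_spec()].
#' @param figure_id Identifier for the record (default `"synthetic"`).
#' @return List with `record` (a [figure_record()]) and `truth` (one-row
#'   data frame: the spec fields plus `white_measured`).
#' @export
generate_figure <- function(spec, figure_id = "synthetic") {
  stopifnot(inherits(spec, "figure_spec"))
  H <- spec$canvas[1]; W <- spec$canvas[2]
  tol <- 0.02

  layout <- with_seed(spec$seed, plan_shapes(spec))

  if (spec$shape_density == 0L || nrow(layout) == 0L) {
    if (abs(1 - spec$white_target) > tol)
      stop_medvis("white_target ", spec$white_target,
                  " infeasible with shape_density 0")
    img <- array(255, dim = c(H, W, 3L))
    wf <- 1
  } else {
    # bisection on the shape scale: white fraction decreases as shapes grow
    lo <- 0.02; hi <- 1
    wf_hi <- paint_white_fraction(layout, H, W, hi)
    wf_lo <- paint_white_fraction(layout, H, W, lo)
    if (wf_hi > spec$white_target + tol)
      stop_medvis("white_target ", spec$white_target, " infeasible: even ",
                  "maximal shapes leave white fraction ", round(wf_hi, 3))
    if (wf_lo < spec$white_target - tol)
      stop_medvis("white_target ", spec$white_target, " infeasible: even ",
                  "minimal shapes cover too much (white fraction ",
                  round(wf_lo, 3), ")")
    s <- NA_real_
    best <- c(scale = hi, err = abs(wf_hi - spec$white_target))
    if (abs(wf_lo - spec$white_target) < best["err"])
      best <- c(scale = lo, err = abs(wf_lo - spec$white_target))
    for (iter in seq_len(20L)) {
      s <- (lo + hi) / 2
      wf <- paint_white_fraction(layout, H, W, s)
      err <- abs(wf - spec$white_target)
      if (err < best["err"]) best <- c(scale = s, err = err)
      if (err <= tol / 2) break
      if (wf > spec$white_target) lo <- s else hi <- s
    }
    if (best["err"] > tol)
      stop_medvis("could not reach white_target ", spec$white_target,
                  " within 20 adjustment rounds (best off by ",
                  round(best["err"], 3), ")")
    img <- paint_canvas(layout, H, W, best["scale"])
    wf <- mean(img[, , 1] == 255 & img[, , 2] == 255 & img[, , 3] == 255)
  }

  caption <- synth_caption(figure_id, spec$panel_count)
  record <- figure_record(figure_id, img, caption)
  truth <- data.frame(
    figure_id = figure_id,
    panel_count = spec$panel_count,
    white_target = spec$white_target,
    palette_mode = spec$palette_mode,
    shape_density = spec$shape_density,
    seed = spec$seed,
    white_measured = wf,
    stringsAsFactors = FALSE
  )
  list(record = record, truth = truth)
}

synth_caption <- function(figure_id, panel_count) {
  labs <- letters[seq_len(panel_count)]
  paste0("Synthetic figure ", figure_id, ". ",
         paste0("(", labs, ") Panel ", labs, ".", collapse = " "))
}

# Decide, under the caller's RNG, where every shape goes and what it looks
# like; sizes are resolved later by the scale parameter.
plan_shapes <- function(spec) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  pc <- spec$panel_count
  n_rows <- max(1L, floor(sqrt(pc)))
  n_cols <- ceiling(pc / n_rows)
  ph <- H %/% n_rows; pw <- W %/% n_cols
  gap <- 6L

  rows <- list()
  for (p in seq_len(pc)) {
    pr <- (p - 1L) %/% n_cols; pcid <- (p - 1L) %% n_cols
    top <- pr * ph + 1L; left <- pcid * pw + 1L
    d <- spec$shape_density
    if (d == 0L) next
    g <- shape_grid(d, ph, pw)
    ch <- (ph - gap) %/% g[1]; cw <- (pw - gap) %/% g[2]
    if (ch < 5L || cw < 5L)
      stop_medvis("shape_density ", d, " too high for panel size ",
                  ph, "x", pw)
    cells <- sample(g[1] * g[2], d)    # which sub-cells hold a shape
    for (cell in cells) {
      cr <- (cell - 1L) %/% g[2]; cc <- (cell - 1L) %% g[2]
      # cell interior, gap/2 margin on each side keeps shapes disjoint
      cy0 <- top + gap %/% 2L + cr * ch
      cx0 <- left + gap %/% 2L + cc * cw
      max_hh <- (ch - gap) %/% 2L
      max_hw <- (cw - gap) %/% 2L
      if (max_hh < 1L || max_hw < 1L)
        stop_medvis("shape_density ", d, " too high for panel size ",
                    ph, "x", pw)
      jit_y <- sample.int(3L, 1L) - 2L   # -1, 0, or 1
      jit_x <- sample.int(3L, 1L) - 2L
      cy <- cy0 + ch %/% 2L + jit_y
      cx <- cx0 + cw %/% 2L + jit_x
      col <- if (spec$palette_mode == "achromatic") {
        rep(sample(30:180, 1L), 3L)
      } else {
        synth_color()
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cy = cy, cx = cx, max_hh = max_hh, max_hw = max_hw,
        # per-shape rounding phases so shape sizes step at different
        # scales, keeping the white-fraction curve smooth in the scale
        u_h = stats::runif(1), u_w = stats::runif(1),
        type = sample(c("rect", "disc"), 1L),
        r = col[1], g = col[2], b = col[3]
      )
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

# Pick a rows x cols sub-grid for d shapes in a ph x pw panel: fewest
# wasted cells first, then the most nearly square cells, so the paintable
# area (hence the reachable white range) is as large as possible.
shape_grid <- function(d, ph, pw) {
  best <- NULL; best_key <- c(Inf, Inf)
  for (gr in seq_len(d)) {
    gc <- ceiling(d / gr)
    waste <- gr * gc - d
    cell_aspect <- abs(log((ph / gr) / (pw / gc)))
    key <- c(waste, cell_aspect)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- c(gr, gc); best_key <- key
    }
  }
  as.integer(best)
}

# A saturated, clearly non-white color with large channel spread.
synth_color <- function() {
  hue <- sample(6L, 1L)
  hi <- sample(200:255, 1L); lo <- sample(0:60, 1L); mid <- sample(60:180, 1L)
  switch(hue,
         c(hi, lo, mid), c(hi, mid, lo), c(lo, hi, mid),
         c(mid, hi, lo), c(lo, mid, hi), c(mid, lo, hi))
}

paint_canvas <- function(layout, H, W, scale) {
  img <- array(255, dim = c(H, W, 3L))
  for (i in seq_len(nrow(layout))) {
    sh <- layout[i, ]
    hh <- max(1L, min(sh$max_hh,
                      as.integer(floor(scale * sh$max_hh + sh$u_h))))
    hw <- max(1L, min(sh$max_hw,
                      as.integer(floor(scale * sh$max_hw + sh$u_w))))
    col <- c(sh$r, sh$g, sh$b)
    if (sh$type == "rect") {
      rr <- max(1L, sh$cy - hh):min(H, sh$cy + hh)
      cc <- max(1L, sh$cx - hw):min(W, sh$cx + hw)
      for (ch in 1:3) img[rr, cc, ch] <- col[ch]
    } else {
      # disc drawn as the ellipse inscribed in the shape's extent box
      rr <- max(1L, sh$cy - hh):min(H, sh$cy + hh)
      cc <- max(1L, sh$cx - hw):min(W, sh$cx + hw)
      dmask <- outer(((rr - sh$cy) / hh)^2, ((cc - sh$cx) / hw)^2,
                     "+") <= 1
      for (ch in 1:3) {
        sub <- img[rr, cc, ch]
        sub[dmask] <- col[ch]
        img[rr, cc, ch] <- sub
      }
    }
  }
  img
}

paint_white_fraction <- function(layout, H, W, scale) {
  img <- paint_canvas(layout, H, W, scale)
  mean(img[, , 1] == 255 & img[, , 2] == 255 & img[, , 3] == 255)
}

#' Default two-stratum study conditions
#'
#' The conditions used throughout the package's recovery experiments: a
#' "good" stratum (low whitespace, two colorful panels, few shapes) and a
#' "bad" stratum (mostly empty, six achromatic panels, many shapes),
#' separated far beyond the corpus noise so consensus classification should
#' recover the strata exactly.
#'
#' @return List of two strata, each `list(template = <args for
#'   figure_spec>, proportion = 0.5)`.
#' @export
default_strata <- function() {
  list(
    good = list(template = list(panel_count = 2L, white_target = 0.55,
                                palette_mode = "chromatic",
                                shape_density = 3L),
                proportion = 0.5),
    bad = list(template = list(panel_count = 6L, white_target = 0.85,
                               palette_mode = "achromatic",
                               shape_density = 12L),
               proportion = 0.5)
  )
}

#' Generate a synthetic corpus from stratum templates
#'
#' Draws `n` figures from the given strata (figure counts by largest
#' remainder, so proportions are honoured exactly as possible), applying a
#' small per-figure jitter to the white target so figures within a stratum
#' are not identical. Deterministic under `seed`; changing the seed changes
#' the jitter but never the stratum sizes.
#'
#' @param n Corpus size (>= 8, the pipeline minimum).
#' @param strata List of strata as in [default_strata()].
#' @param seed Integer seed.
#' @param canvas Canvas size passed to every figure.
#' @return List with `figures` (a [figure_set()]) and `truth` (data frame
#'   with one row per figure, including `stratum`).
#' @export
generate_corpus <- function(n, strata = default_strata(), seed = 1L,
                            canvas = c(240L, 360L)) {
  n <- as.integer(n)
  if (n < 8L) stop_medvis("need n >= 8 (pipeline minimum)")
  props <- vapply(strata, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9)
    stop_medvis("stratum proportions must sum to 1")
  counts <- largest_remainder(props * n)

  strat_names <- if (!is.null(names(strata))) names(strata)
                 else paste0("stratum", seq_along(strata))
  jitters <- with_seed(seed, stats::runif(n, -0.02, 0.02))
  sub_seeds <- derive_seeds(seed, n)

  records <- vector("list", n)
  truths <- vector("list", n)
  i <- 0L
  for (s in seq_along(strata)) {
    tmpl <- strata[[s]]$template
    for (k in seq_len(counts[s])) {
      i <- i + 1L
      fid <- sprintf("fig%03d", i)
      wt <- min(max(tmpl$white_target + jitters[i], 0.05), 0.97)
      spec <- figure_spec(
        panel_count = tmpl$panel_count,
        white_target = wt,
        palette_mode = tmpl$palette_mode,
        shape_density = tmpl$shape_density,
        canvas = canvas,
        seed = sub_seeds[i]
      )
      gen <- generate_figure(spec, figure_id = fid)
      records[[i]] <- gen$record
      truths[[i]] <- cbind(gen$truth, stratum = strat_names[s],
                           stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truths)
  truth <- truth[order(truth$figure_id, method = "radix"), ]
  rownames(truth) <- NULL
  list(figures = figure_set(records), truth = truth)
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x))) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

#' Write a synthetic corpus to disk
#'
#' Writes each figure as a PNG with a sidecar caption `.txt`, plus
#' `truth.csv` -- a layout [load_figure_set()] reads back directly.
#'
#' @param corpus Result of [generate_corpus()] (or a list with `figures` and
#'   optionally `truth`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_medvis("cannot create directory: ", dir)
  for (rec in corpus$figures$records) {
    png::writePNG(rec$image / 255,
                  file.path(dir, paste0(rec$figure_id, ".png")))
    writeLines(rec$caption, file.path(dir, paste0(rec$figure_id, ".txt")))
  }
  if (!is.null(corpus$truth))
    utils::write.csv(corpus$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  invisible(dir)
}
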