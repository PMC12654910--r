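test_that("whitespace fraction matches analytic and brute-force values", {
  expect_equal(whitespace_fraction(uniform_raster(255, 255, 255)), 1)
  expect_equal(whitespace_fraction(uniform_raster(0, 0, 0)), 0)

  # top half white, bottom half mid-gray
  img <- uniform_raster(128, 128, 128, h = 100, w = 100)
  img[1:50, , ] <- 255
  expect_equal(whitespace_fraction(img, 250), 0.5)

  # brute-force per-pixel oracle on a random raster
  img <- random_raster(17, 23, seed = 4)
  thr <- 200
  n_white <- 0L
  for (r in 1:17) for (c in 1:23)
    if (all(img[r, c, ] >= thr)) n_white <- n_white + 1L
  expect_equal(whitespace_fraction(img, thr), n_white / (17 * 23))

  # white + non-white fractions partition the image exactly
  expect_equal(whitespace_fraction(img, 250) + mean(!white_mask(img, 250)), 1)
})

test_that("whitespace errors on an empty or malformed raster", {
  expect_error(whitespace_fraction(array(0, dim = c(0, 5, 3))), "empty")
  expect_error(whitespace_fraction(matrix(0, 3, 3)), "H x W x 3")
})

test_that("color score matches the channel-difference formula", {
  expect_equal(color_score(uniform_raster(90, 90, 90)), 0)
  expect_equal(color_score(uniform_raster(255, 0, 0)), 170)

  img <- random_raster(11, 13, seed = 7)
  acc <- 0
  for (r in 1:11) for (c in 1:13) {
    v <- img[r, c, ]
    acc <- acc + (abs(v[1] - v[2]) + abs(v[2] - v[3]) + abs(v[1] - v[3])) / 3
  }
  expect_equal(color_score(img), acc / (11 * 13), tolerance = 1e-9)
})

test_that("color score is invariant to channel permutations", {
  img <- random_raster(9, 9, seed = 12)
  base <- color_score(img)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(color_score(img[, , perm]), base)
  }
})

test_that("complexity counts disjoint shapes as separate components", {
  expect_equal(complexity_score(uniform_raster(200, 200, 200)), 0)

  # three disjoint dark rectangles on white: three edge rings
  img <- rect_raster(100, 100, list(c(10, 25, 10, 25),
                                    c(10, 25, 60, 80),
                                    c(60, 85, 30, 55)))
  expect_equal(complexity_score(img), 3 / (100 * 100 / 1e6))

  # flood-fill oracle: count components of the same edge mask directly
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  # build the mask the same way the metric does, then count by flood fill
  flood_count <- function(mask) {
    n <- 0L
    while (any(mask)) {
      n <- n + 1L
      seed_px <- which(mask, arr.ind = TRUE)[1, ]
      frontier <- matrix(seed_px, ncol = 2)
      mask[seed_px[1], seed_px[2]] <- FALSE
      while (nrow(frontier) > 0) {
        nxt <- NULL
        for (i in seq_len(nrow(frontier))) {
          for (dr in -1:1) for (dc in -1:1) {
            r <- frontier[i, 1] + dr; c <- frontier[i, 2] + dc
            if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
                mask[r, c]) {
              mask[r, c] <- FALSE
              nxt <- rbind(nxt, c(r, c))
            }
          }
        }
        frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 2) else nxt
      }
    }
    n
  }
  g <- medvis:::sobel_magnitude(lum)
  mask <- g >= 0.10 * sqrt(2) * 4 * 255
  expect_equal(flood_count(mask), 3)
})

test_that("complexity increases with the number of disjoint shapes", {
  mk <- function(k) {
    g <- ceiling(sqrt(k))
    rects <- list()
    for (i in seq_len(k)) {
      r0 <- ((i - 1) %/% g) * 30 + 5
      c0 <- ((i - 1) %% g) * 30 + 5
      rects[[i]] <- c(r0, r0 + 12, c0, c0 + 12)
    }
    rect_raster(95, 95, rects)
  }
  scores <- vapply(c(1, 4, 9), function(k) complexity_score(mk(k)),
                   numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("complexity is invariant to 180-degree rotation", {
  img <- strata_corpus()$figures$records[[1]]$image
  rot <- img[rev(seq_len(dim(img)[1])), rev(seq_len(dim(img)[2])), ]
  expect_equal(complexity_score(rot), complexity_score(img))
})

test_that("caption parsing counts distinct case-folded subpanel letters", {
  # a caption with four labelled subpanels, mirroring multi-panel figures
  cap <- paste("A Comparison of visualization tool scores and their",
               "metrics. (a) The Rating definition for the Customizability",
               "Score. (b) The rating definition of the ease of use",
               "criterion. (c) The rating definition of the financial",
               "score. (d) A visual bar graph of the scores.")
  res <- count_visualizations(cap)
  expect_equal(res$vis_count, 4L)
  expect_equal(res$count_source, "parsed")
  expect_equal(res$labels, c("a", "b", "c", "d"))

  res <- count_visualizations("Overall distribution of scores.")
  expect_equal(res$vis_count, 1L)
  expect_equal(res$count_source, "fallback")

  res <- count_visualizations("(A) setup. (b) result. (B) zoom.")
  expect_equal(res$vis_count, 2L)
  expect_equal(res$count_source, "parsed")

  # depends only on the set of distinct case-folded letters
  expect_equal(count_visualizations("(a)(b)(c)")$vis_count,
               count_visualizations("(C) x (b) y (A) z (c)(B)")$vis_count)
  expect_equal(count_visualizations("")$vis_count, 1L)
  expect_equal(count_visualizations(NA_character_)$count_source, "fallback")
  # multi-character or numeric identifiers are not panel letters
  expect_equal(count_visualizations("(ab) (1) (iv)")$count_source, "fallback")
})

test_that("score_figure composes the four metrics", {
  rec <- figure_record("blank", uniform_raster(255, 255, 255, 20, 20), "")
  v <- score_figure(rec)
  expect_equal(v$whitespace_fraction, 1)
  expect_equal(v$color_score, 0)
  expect_equal(v$complexity_score, 0)
  expect_equal(v$vis_count, 1L)
  expect_equal(v$count_source, "fallback")

  # corpus scoring is order-stable and one row per figure
  corpus <- strata_corpus()
  sc <- score_corpus(corpus$figures)
  expect_equal(sc$figure_id, figure_ids(corpus$figures))
  expect_equal(nrow(sc), 20L)
})

test_that("scoring errors carry the figure id", {
  rec <- structure(list(figure_id = "oops",
                        image = array(0, dim = c(0, 3, 3)), caption = ""),
                   class = "figure_record")
  expect_error(score_figure(rec), "oops")
})
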