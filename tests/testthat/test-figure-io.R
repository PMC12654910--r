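test_that("a written synthetic corpus round-trips through load_figure_set", {
  corpus <- generate_corpus(8, seed = 5, canvas = c(160L, 200L))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)

  loaded <- load_figure_set(dir, dir)
  expect_s3_class(loaded, "figure_set")
  expect_length(loaded, 8L)
  expect_equal(figure_ids(loaded), figure_ids(corpus$figures))
  for (i in seq_len(8)) {
    expect_equal(loaded$records[[i]]$image, corpus$figures$records[[i]]$image)
    expect_equal(loaded$records[[i]]$caption,
                 corpus$figures$records[[i]]$caption)
  }
})

test_that("corpus ids are sorted regardless of file creation order", {
  dir <- withr::local_tempdir()
  img <- uniform_raster(100, 150, 200, 6, 6)
  for (nm in c("zebra", "alpha", "mid")) {
    png::writePNG(img / 255, file.path(dir, paste0(nm, ".png")))
    writeLines(paste("caption for", nm), file.path(dir, paste0(nm, ".txt")))
  }
  fs <- load_figure_set(dir, dir)
  expect_equal(figure_ids(fs), c("alpha", "mid", "zebra"))
})

test_that("alpha channels composite over white like the brute-force oracle", {
  # 4x4 RGBA toy raster with a fully transparent margin
  set.seed(3)
  rgba <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  rgba[1, , 4] <- 0          # transparent margin row
  rgba[, 1, 4] <- 0
  rgba <- round(rgba * 255) / 255    # quantize as the PNG file will
  dir <- withr::local_tempdir()
  png::writePNG(rgba, file.path(dir, "toy.png"))
  fs <- suppressWarnings(load_figure_set(dir))
  got <- fs$records[[1]]$image

  oracle <- array(0, dim = c(4, 4, 3))
  for (r in 1:4) for (c in 1:4) for (ch in 1:3) {
    a <- rgba[r, c, 4]
    oracle[r, c, ch] <- round((rgba[r, c, ch] * a + 1 - a) * 255)
  }
  expect_equal(got, oracle)
  # the transparent margin is white, so it counts as whitespace downstream
  expect_true(all(white_mask(got)[1, ]))
})

test_that("grayscale images are expanded to three equal channels", {
  dir <- withr::local_tempdir()
  g <- matrix(seq(0, 1, length.out = 25), 5, 5)
  png::writePNG(g, file.path(dir, "gray.png"))
  fs <- suppressWarnings(load_figure_set(dir))
  img <- fs$records[[1]]$image
  expect_equal(img[, , 1], img[, , 2])
  expect_equal(img[, , 2], img[, , 3])
  expect_equal(color_score(img), 0)
})

test_that("captions can come from a delimited table; missing ones warn", {
  dir <- withr::local_tempdir()
  img <- uniform_raster(10, 20, 30, 5, 5)
  png::writePNG(img / 255, file.path(dir, "one.png"))
  png::writePNG(img / 255, file.path(dir, "two.png"))
  cap_csv <- file.path(dir, "caps.csv")
  writeLines(c("figure_id,caption", "one,\"has (a) and (b)\""), cap_csv)

  expect_warning(fs <- load_figure_set(dir, cap_csv), "two")
  expect_equal(fs$records[[1]]$caption, "has (a) and (b)")
  expect_equal(fs$records[[2]]$caption, "")
  sc <- score_corpus(fs)
  expect_equal(sc$count_source, c("parsed", "fallback"))
  expect_equal(sc$vis_count, c(2L, 1L))
})

test_that("corpus loading errors are informative", {
  dir <- withr::local_tempdir()
  expect_error(load_figure_set(dir), "empty corpus")
  writeLines("not a png", file.path(dir, "bad.png"))
  expect_error(load_figure_set(dir), "bad.png")
  expect_error(figure_set(list(
    figure_record("dup", uniform_raster(1, 2, 3)),
    figure_record("dup", uniform_raster(1, 2, 3))
  )), "duplicate")
})

test_that("oversized rasters are downscaled before metric extraction", {
  dir <- withr::local_tempdir()
  img <- matrix(1, 64, 48)
  png::writePNG(img, file.path(dir, "big.png"))
  fs <- suppressWarnings(load_figure_set(dir, max_dim = 16L))
  d <- dim(fs$records[[1]]$image)
  expect_lte(max(d[1:2]), 16L)
  expect_equal(whitespace_fraction(fs$records[[1]]$image), 1)
})

test_that("write_results produces the packaged folder deterministically", {
  fit <- strata_fit()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_results(fit, out1, gauges = FALSE)
  write_results(fit, out2, gauges = FALSE)

  expect_true(file.exists(file.path(out1, "scores.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_equal(length(list.files(file.path(out1, "advice"))), 20L)
  expect_equal(readLines(file.path(out1, "scores.csv")),
               readLines(file.path(out2, "scores.csv")))
  expect_equal(readLines(file.path(out1, "labels.csv")),
               readLines(file.path(out2, "labels.csv")))
  expect_equal(readLines(file.path(out1, "embeddings.csv")),
               readLines(file.path(out2, "embeddings.csv")))

  scores <- utils::read.csv(file.path(out1, "scores.csv"))
  expect_equal(names(scores),
               c("figure_id", "whitespace_fraction", "color_score",
                 "complexity_score", "vis_count", "count_source"))
  labels <- utils::read.csv(file.path(out1, "labels.csv"))
  expect_equal(names(labels),
               c("figure_id", "vote_pca", "vote_tsne", "vote_umap",
                 "vote_sum", "label"))
})

test_that("gauge charts are one file per figure and metric", {
  fit <- strata_fit()
  out <- withr::local_tempdir()
  # restrict to 8 figures to keep rendering fast
  small <- fit
  small$reports <- fit$reports[1:8]
  write_results(small, out, gauges = TRUE)
  expect_equal(length(list.files(file.path(out, "gauges"))), 8L * 4L)
})

test_that("writing an empty report list errors", {
  fit <- strata_fit()
  broken <- fit
  broken$reports <- list()
  expect_error(write_results(broken, withr::local_tempdir()), "empty")
})
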