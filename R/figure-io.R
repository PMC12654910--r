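#' Construct a figure record
#'
#' A figure record bundles one raster figure with its identifier and caption.
#' Rasters are stored as H x W x 3 arrays of 8-bit channel intensities
#' (0--255), the working representation used by all metric functions.
#'
#' @param figure_id Character scalar; unique identifier (usually the file stem).
#' @param image H x W x 3 numeric array with values in 0--255.
#' @param caption Character scalar; may be empty.
#' @return An object of class `figure_record`.
#' @export
figure_record <- function(figure_id, image, caption = "") {
  stopifnot(is.character(figure_id), length(figure_id) == 1L, nzchar(figure_id))
  check_raster(image)
  if (min(image) < 0 || max(image) > 255)
    stop_medvis("channel intensities must lie in [0, 255]")
  if (is.na(caption)) caption <- ""
  structure(list(figure_id = figure_id, image = image,
                 caption = as.character(caption)),
            class = "figure_record")
}

#' Construct a figure set
#'
#' A figure set is an ordered corpus of [figure_record()]s, optionally carrying
#' human annotations (per-figure visualization counts) and per-figure rater
#' votes used by the validation utilities. Records are kept in lexicographic
#' `figure_id` order so the corpus order never depends on how files were
#' enumerated on disk.
#'
#' @param records List of `figure_record` objects.
#' @param annotations Optional named integer vector: `figure_id` -> human
#'   visualization count.
#' @param ratings Optional named list: `figure_id` -> character vector of
#'   votes in `c("Good", "Bad")`.
#' @return An object of class `figure_set`.
#' @export
figure_set <- function(records, annotations = NULL, ratings = NULL) {
  stopifnot(is.list(records), length(records) >= 1L)
  ok <- vapply(records, inherits, logical(1), "figure_record")
  if (!all(ok)) stop_medvis("all records must be figure_record objects")
  ids <- vapply(records, `[[`, character(1), "figure_id")
  if (anyDuplicated(ids))
    stop_medvis("duplicate figure_id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- records[order(ids, method = "radix")]
  ids <- sort(ids, method = "radix")
  if (!is.null(annotations)) {
    bad <- setdiff(names(annotations), ids)
    if (length(bad)) stop_medvis("annotation ids not in corpus: ",
                                 paste(bad, collapse = ", "))
  }
  if (!is.null(ratings)) {
    bad <- setdiff(names(ratings), ids)
    if (length(bad)) stop_medvis("rating ids not in corpus: ",
                                 paste(bad, collapse = ", "))
  }
  structure(list(records = records, annotations = annotations,
                 ratings = ratings),
            class = "figure_set")
}

#' @export
length.figure_set <- function(x) length(x$records)

#' @export
print.figure_set <- function(x, ...) {
  cat("<figure_set> of", length(x$records), "figures\n")
  ids <- figure_ids(x)
  show <- utils::head(ids, 6L)
  cat("  ids:", paste(show, collapse = ", "),
      if (length(ids) > 6L) "..." else "", "\n")
  if (!is.null(x$annotations))
    cat("  annotations:", length(x$annotations), "figures\n")
  if (!is.null(x$ratings))
    cat("  ratings:", length(x$ratings), "figures\n")
  invisible(x)
}

#' Figure identifiers of a corpus
#' @param figures A `figure_set`.
#' @return Character vector of ids in corpus order.
#' @export
figure_ids <- function(figures) {
  vapply(figures$records, `[[`, character(1), "figure_id")
}

# ---- raster decoding -------------------------------------------------------

# Decode a raster file to an H x W x C array in [0, 1].
decode_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop_medvis("BMP decoding requires the EBImage package")
      # EBImage stores images x-major; transpose back to row-major
      e <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(e)) == 2L) t(e) else aperm(e, c(2L, 1L, 3L))
    },
    stop_medvis("unsupported image format: ", basename(path))
  )
  img
}

# Normalise any decoded raster to H x W x 3 in 0..255.
# Grayscale is replicated to three channels; alpha is composited over white
# (figures are presumed to sit on a white page).
to_rgb255 <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  d <- dim(img)
  if (d[3] == 1L) img <- array(img[, , 1L], dim = c(d[1], d[2], 3L))
  if (dim(img)[3] == 2L) {        # gray + alpha
    g <- img[, , 1L]; a <- img[, , 2L]
    g <- g * a + (1 - a)
    img <- array(g, dim = c(d[1], d[2], 3L))
  }
  if (dim(img)[3] == 4L) {        # RGB + alpha
    a <- img[, , 4L]
    img <- array(
      as.vector(img[, , 1:3]) * as.vector(a) + (1 - as.vector(a)),
      dim = c(d[1], d[2], 3L))
  }
  img <- img[, , 1:3, drop = FALSE]
  round(pmin(pmax(img, 0), 1) * 255)
}

# Downscale so max(H, W) <= max_dim, by integer-block averaging.
# Metrics are area-normalised, so this only bounds runtime.
downscale_raster <- function(image, max_dim = 2048L) {
  d <- dim(image)
  f <- ceiling(max(d[1], d[2]) / max_dim)
  if (f <= 1L) return(image)
  nh <- ceiling(d[1] / f); nw <- ceiling(d[2] / f)
  out <- array(0, dim = c(nh, nw, 3L))
  ri <- pmin((seq_len(d[1]) - 1L) %/% f + 1L, nh)
  ci <- pmin((seq_len(d[2]) - 1L) %/% f + 1L, nw)
  cnt <- tabulate(ri, nh) %o% tabulate(ci, nw)
  for (ch in 1:3) {
    s <- rowsum(image[, , ch], ri)
    s <- t(rowsum(t(s), ci))
    out[, , ch] <- s / cnt
  }
  round(out)
}

#' Load a figure corpus from disk
#'
#' Reads every decodable raster (PNG/JPEG/TIFF/BMP) in `images_dir` and pairs
#' each with a caption. Captions come either from sidecar text files
#' (`<stem>.txt` next to, or in, `captions_source` when it is a directory) or
#' from a delimited table with header columns `figure_id,caption`. Grayscale
#' images are replicated to three channels and alpha channels are composited
#' over white, so transparent margins count as white pixels downstream.
#' Figures with no matching caption are kept with an empty caption (and a
#' warning), not dropped.
#'
#' @param images_dir Directory containing the raster files.
#' @param captions_source Directory of sidecar `.txt` files, or path to a
#'   CSV/TSV table with columns `figure_id` and `caption`. `NULL` leaves all
#'   captions empty.
#' @param annotations Optional path to a CSV with columns
#'   `figure_id,human_count`.
#' @param ratings Optional path to a CSV with columns
#'   `figure_id,rater_id,vote` (votes `Good`/`Bad`).
#' @param max_dim Rasters larger than this on either side are block-averaged
#'   down before metric extraction (default 2048).
#' @return A [figure_set()].
#' @export
load_figure_set <- function(images_dir, captions_source = NULL,
                            annotations = NULL, ratings = NULL,
                            max_dim = 2048L) {
  if (!dir.exists(images_dir))
    stop_medvis("images_dir does not exist: ", images_dir)
  files <- list.files(images_dir,
                      pattern = "\\.(png|jpe?g|tiff?|bmp)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop_medvis("empty corpus: no raster files found in ", images_dir)
  files <- sort(files, method = "radix")

  captions <- read_captions(captions_source)

  records <- vector("list", length(files))
  missing_caption <- character(0)
  for (i in seq_along(files)) {
    f <- files[[i]]
    stem <- tools::file_path_sans_ext(basename(f))
    img <- tryCatch(to_rgb255(decode_raster(f)),
                    error = function(e)
                      stop_medvis("unreadable image '", basename(f), "': ",
                                  conditionMessage(e)))
    img <- downscale_raster(img, max_dim)
    cap <- captions[[stem]]
    if (is.null(cap)) {
      cap <- ""
      missing_caption <- c(missing_caption, stem)
    }
    records[[i]] <- figure_record(stem, img, cap)
  }
  if (length(missing_caption))
    warning("no caption found for: ",
            paste(missing_caption, collapse = ", "),
            "; using empty caption (fallback visualization count)",
            call. = FALSE)

  ann <- if (!is.null(annotations)) read_annotations(annotations) else NULL
  rat <- if (!is.null(ratings)) read_ratings(ratings) else NULL
  figure_set(records, annotations = ann, ratings = rat)
}

read_captions <- function(captions_source) {
  if (is.null(captions_source)) return(list())
  if (dir.exists(captions_source)) {
    txts <- list.files(captions_source, pattern = "\\.txt$",
                       ignore.case = TRUE, full.names = TRUE)
    caps <- lapply(txts, function(f)
      paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
    names(caps) <- tools::file_path_sans_ext(basename(txts))
    return(caps)
  }
  if (!file.exists(captions_source))
    stop_medvis("captions_source not found: ", captions_source)
  sep <- if (grepl("\\.tsv$", captions_source, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(captions_source, header = TRUE, sep = sep,
                           quote = "\"", stringsAsFactors = FALSE,
                           comment.char = "", encoding = "UTF-8")
  if (!all(c("figure_id", "caption") %in% names(tab)))
    stop_medvis("caption table must have columns figure_id, caption")
  stats::setNames(as.list(as.character(tab$caption)),
                  as.character(tab$figure_id))
}

read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("figure_id", "human_count") %in% names(tab)))
    stop_medvis("annotations CSV must have columns figure_id, human_count")
  stats::setNames(as.integer(tab$human_count), as.character(tab$figure_id))
}

read_ratings <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("figure_id", "rater_id", "vote") %in% names(tab)))
    stop_medvis("ratings CSV must have columns figure_id, rater_id, vote")
  if (!all(tab$vote %in% c("Good", "Bad")))
    stop_medvis("votes must be 'Good' or 'Bad'")
  split(tab$vote, as.character(tab$figure_id))
}

# ---- results folder --------------------------------------------------------

#' Write a pipeline results folder
#'
#' Packages all outputs of a fitted corpus analysis into one folder:
#' `scores.csv`, `labels.csv`, `embeddings.csv`, per-figure advice text files
#' under `advice/`, gauge charts under `gauges/`, and a `manifest.json`
#' echoing the seed and configuration. Re-running with identical inputs
#' reproduces the tables byte-identically.
#'
#' @param fit A fitted `medvis` object.
#' @param out_dir Output directory (created if needed).
#' @param gauges Render gauge charts (default `TRUE`; four PNGs per figure).
#' @return The manifest path, invisibly.
#' @export
write_results <- function(fit, out_dir, gauges = TRUE) {
  stopifnot(inherits(fit, "medvis"))
  if (length(fit$reports) == 0L)
    stop_medvis("empty report list; nothing to write")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_medvis("cannot create output directory: ", out_dir)

  write_csv_stable(fit$scores, file.path(out_dir, "scores.csv"))
  write_csv_stable(fit$labels, file.path(out_dir, "labels.csv"))
  write_csv_stable(fit$embeddings, file.path(out_dir, "embeddings.csv"))

  adv_dir <- file.path(out_dir, "advice")
  dir.create(adv_dir, showWarnings = FALSE)
  for (rep in fit$reports)
    writeLines(advice_text(rep), file.path(adv_dir,
                                           paste0(rep$figure_id, ".txt")))

  if (isTRUE(gauges)) {
    g_dir <- file.path(out_dir, "gauges")
    dir.create(g_dir, showWarnings = FALSE)
    for (rep in fit$reports)
      render_gauges(rep, fit$thresholds, g_dir)
  }

  manifest <- list(
    package = "medvis",
    version = as.character(utils::packageVersion("medvis")),
    seed = fit$config$seed,
    config = fit$config[setdiff(names(fit$config), "seed")],
    n_figures = nrow(fit$scores),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}
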