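#' @keywords internal
"_PACKAGE"

# Derive independent sub-seeds from one user-visible seed.
# Kept below 2^31 - 1 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 100000L) * 10000L + 7919L * seq_len(n) %% 10000L
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_medvis <- function(..., call. = FALSE) stop(..., call. = call.)

check_raster <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_medvis("`image` must be an H x W x 3 array of 8-bit intensities")
  d <- dim(image)
  if (d[1] < 1L || d[2] < 1L || length(image) == 0L)
    stop_medvis("empty raster")
  invisible(d)
}

metric_names <- function() {
  c("whitespace_fraction", "color_score", "complexity_score", "vis_count")
}
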