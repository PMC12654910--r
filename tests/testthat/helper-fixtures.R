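# Shared fixtures, built in code. The standard two-strata corpus and its fit
# are computed once per test run and reused.

uniform_raster <- function(r, g, b, h = 10L, w = 10L) {
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}

# White canvas with filled dark axis-aligned rectangles.
# rects: list of c(r1, r2, c1, c2)
rect_raster <- function(h, w, rects, value = 0) {
  img <- array(255, dim = c(h, w, 3L))
  for (rc in rects)
    for (ch in 1:3) img[rc[1]:rc[2], rc[3]:rc[4], ch] <- value
  img
}

random_raster <- function(h, w, seed = 1L) {
  set.seed(seed)
  array(sample(0:255, h * w * 3L, replace = TRUE), dim = c(h, w, 3L))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

strata_corpus <- function() cached("corpus", generate_corpus(20, seed = 101))

strata_fit <- function() cached("fit", medvis(strata_corpus()$figures,
                                              seed = 101))

# Standardized z-matrix of the shared corpus.
strata_z <- function() strata_fit()$z
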