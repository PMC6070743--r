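# In-code fixtures: hand-built slabs and quantized slabs for texture tests.

# Build an roi_slab directly from parallel lists of intensity and mask
# matrices (bypasses NIfTI I/O for unit tests).
make_test_slab <- function(intensity, mask = NULL, spacing = c(1, 1, 1)) {
  if (is.matrix(intensity)) intensity <- list(intensity)
  if (is.null(mask)) mask <- lapply(intensity, function(m) {
    mm <- matrix(1L, nrow(m), ncol(m)); mm
  })
  if (is.matrix(mask)) mask <- list(mask)
  structure(
    list(intensity = intensity, mask = mask,
         indices = seq_along(intensity),
         center_index = (length(intensity) + 1L) %/% 2L,
         n_slices = length(intensity),
         empty_slices = integer(0), spacing = spacing, sagittal_axis = 1L),
    class = "roi_slab")
}

# Build a quantized_slab directly from integer level matrices (0 = out of
# ROI sentinel).
make_test_qslab <- function(levels, n_levels = max(unlist(levels))) {
  if (is.matrix(levels)) levels <- list(levels)
  structure(
    list(slices = lapply(levels, function(m) {
           storage.mode(m) <- "integer"; m
         }),
         n_levels = as.integer(n_levels),
         level_edges = seq(0, n_levels, length.out = n_levels + 1),
         degenerate = FALSE),
    class = "quantized_slab")
}

# Random single-slice ROI: levels 1..L inside a random mask, sentinel 0
# outside.
random_qslab <- function(nr = 12, nc = 12, L = 5, roi_prob = 0.85,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(nr * nc, 1, roi_prob), nr, nc)
  q <- matrix(sample.int(L, nr * nc, replace = TRUE), nr, nc) * m
  make_test_qslab(q, n_levels = L)
}

# A small volume/mask pair built from a cuboid ROI (for I/O and slab tests).
make_test_volume <- function(shape = c(16, 16, 16), value = NULL,
                             spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  data <- if (is.null(value)) array(rnorm(prod(shape)), shape)
          else array(value, shape)
  ccradiomics:::new_intensity_volume(data, spacing)
}

make_box_mask <- function(shape, xr, yr, zr, spacing = c(1, 1, 1)) {
  m <- array(0L, shape)
  m[xr, yr, zr] <- 1L
  ccradiomics:::new_roi_mask(m, spacing)
}
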