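# Gray-level run-length matrices and their feature block.
#
# A run is a maximal sequence of in-ROI pixels with identical gray level
# spaced exactly `step` pixels apart along a scan direction. Out-of-ROI
# (sentinel-0) pixels break runs. For step d > 1 every scan line splits
# into d independent residue-class lanes. Runs are counted per 2D slice
# and pooled over the slab.

# Scan-line decomposition of one slice for (angle, step): returns the pixel
# values ordered lane by lane plus a lane id per pixel. Within a lane the
# traversal order steps exactly `d` pixels along the angle's direction.
.rlm_lanes <- function(Q, angle, d) {
  nr <- nrow(Q); nc <- ncol(Q)
  r <- as.vector(row(Q)); c <- as.vector(col(Q)); v <- as.vector(Q)
  if (angle == 0L) {        # along columns within a row
    key1 <- r;      key2 <- c %% d; pos <- c
  } else if (angle == 90L) { # along rows within a column
    key1 <- c;      key2 <- r %% d; pos <- r
  } else if (angle == 45L) { # anti-diagonal: (r, c) -> (r - d, c + d)
    key1 <- r + c;  key2 <- c %% d; pos <- c
  } else if (angle == 135L) { # main diagonal: (r, c) -> (r + d, c + d)
    key1 <- r - c;  key2 <- c %% d; pos <- c
  } else stop("angle must be one of 0, 45, 90, 135")
  ord <- order(key1, key2, pos)
  k1 <- key1[ord]; k2 <- key2[ord]
  lane <- cumsum(c(TRUE, k1[-1] != k1[-length(k1)] |
                         k2[-1] != k2[-length(k2)]))
  list(values = v[ord], lane = lane)
}

#' Gray-level run-length matrix of a quantized slab
#'
#' @param qslab a `quantized_slab`.
#' @param angle scan direction, one of 0, 45, 90, 135 degrees.
#' @param step run step d in pixels (pixels exactly d apart with equal
#'   level continue a run; d = 1 is the classic run-length matrix).
#' @return an `rlm_matrix`: `r` (gray level x run length counts, integer),
#'   `angle`, `step`, `n_r` (total run count).
#' @export
rlm <- function(qslab, angle, step = 1L) {
  stopifnot(inherits(qslab, "quantized_slab"), step >= 1)
  L <- qslab$n_levels
  d <- as.integer(step)
  maxlen <- max(vapply(qslab$slices, function(Q) max(dim(Q)), numeric(1)))
  counts <- matrix(0L, L, maxlen)
  for (Q in qslab$slices) {
    lanes <- .rlm_lanes(Q, angle, d)
    # encode (lane, value) so a single rle finds maximal same-level runs
    # that never cross lane boundaries
    enc <- lanes$lane * (L + 1L) + lanes$values
    runs <- rle(enc)
    lev <- runs$values %% (L + 1L)
    keep <- lev > 0L
    if (!any(keep)) next
    idx <- cbind(lev[keep], runs$lengths[keep])
    tab <- tabulate((idx[, 2] - 1L) * L + idx[, 1], nbins = L * maxlen)
    counts <- counts + matrix(tab, L, maxlen)
  }
  structure(
    list(r = counts, angle = angle, step = d, n_r = sum(counts)),
    class = "rlm_matrix"
  )
}

# The ten run-length features of one matrix; n_r = 0 returns all zeros.
.rlm_features <- function(R) {
  nm <- c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
          "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
          "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
          "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
          "LongRunHighGreyLevelEmphasis")
  r <- R$r
  n_r <- R$n_r
  if (n_r == 0) return(setNames(numeric(10), nm))
  i <- row(r); j <- col(r)
  setNames(c(
    sum(r / j^2),
    sum(r * j^2),
    sum(rowSums(r)^2),
    sum(colSums(r)^2),
    sum(r / i^2),
    sum(r * i^2),
    sum(r / (i^2 * j^2)),
    sum(r * i^2 / j^2),
    sum(r * j^2 / i^2),
    sum(r * i^2 * j^2)
  ) / n_r, nm)
}

#' Run-length feature block (10 features x 6 variants x steps)
#'
#' Computes the ten base run-length features per angle and step, then the
#' AllDirection mean and population SD across the four angles, yielding
#' 10 x 6 x length(steps) named values (180 at the default steps).
#'
#' @param qslab a `quantized_slab`.
#' @param steps run steps in pixels (default `c(1, 4, 7)`).
#' @param angles scan directions in degrees.
#' @return named numeric vector in catalogue order.
#' @export
rlm_feature_block <- function(qslab, steps = c(1L, 4L, 7L),
                              angles = c(0L, 45L, 90L, 135L)) {
  base <- c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
            "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
            "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
            "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
            "LongRunHighGreyLevelEmphasis")
  out <- numeric(0)
  for (d in steps) {
    per_angle <- vapply(angles, function(a) .rlm_features(rlm(qslab, a, d)),
                        numeric(length(base)))
    for (f in base)
      out <- c(out, .direction_variants(per_angle[f, ], f, angles, d))
  }
  out
}
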