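# ---- intensity volumes and ROI masks -----------------------------------

new_intensity_volume <- function(data, spacing, sagittal_axis = 1L) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be finite and > 0")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         sagittal_axis = as.integer(sagittal_axis)),
    class = "intensity_volume"
  )
}

new_roi_mask <- function(data, spacing, sagittal_axis = 1L) {
  v <- unique(as.vector(data))
  if (!all(v %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  if (sum(data) < 1) stop("mask has no nonzero voxel")
  structure(
    list(data = array(as.integer(data), dim(data)),
         spacing = as.numeric(spacing),
         sagittal_axis = as.integer(sagittal_axis)),
    class = "roi_mask"
  )
}

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1 image as an `intensity_volume`: a 3D scalar array plus the
#' physical voxel spacing from the header. The sagittal (left-right) axis is
#' identified from the image xform as the grid axis whose world direction has
#' the dominant x component; if no xform is stored, axis 1 is assumed.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return an `intensity_volume` with fields `data`, `spacing` (mm),
#'   `sagittal_axis`.
#' @details Non-finite voxels are a hard error (the count of affected voxels
#'   is reported) because every downstream texture operator assumes finite
#'   intensities.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D scalar image, got ", length(dim(arr)), " dimensions")
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s); refusing to load")
  sp <- RNifti::pixdim(img)[1:3]
  new_intensity_volume(arr, sp, sagittal_axis = .sagittal_axis(img))
}

# Dominant left-right axis from the xform: the column of the rotation part
# with the largest absolute x (RAS) component.
.sagittal_axis <- function(img) {
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (is.null(xf)) return(1L)
  rot <- abs(xf[1, 1:3])
  if (all(rot == 0)) return(1L)
  as.integer(which.max(rot))
}

#' Write a volume or mask to NIfTI
#'
#' @param x an `intensity_volume` or `roi_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, c("intensity_volume", "roi_mask")))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary ROI mask
#'
#' @param path path to a NIfTI mask; values must be 0/1 (any unsigned
#'   integer coding with exactly two values 0 and 1).
#' @param volume optional paired `intensity_volume`; if given, the mask shape
#'   must match.
#' @return an `roi_mask`.
#' @export
load_mask <- function(path, volume = NULL) {
  v <- load_volume(path)
  if (!is.null(volume) && !identical(dim(v$data), dim(volume$data)))
    stop("mask shape ", paste(dim(v$data), collapse = "x"),
         " does not match volume shape ",
         paste(dim(volume$data), collapse = "x"))
  new_roi_mask(v$data, v$spacing,
               if (is.null(volume)) v$sagittal_axis else volume$sagittal_axis)
}

# ---- sagittal slab extraction ------------------------------------------

# Slice a 3D array perpendicular to `axis` at index i, as a 2D matrix.
.slice3 <- function(arr, axis, i) {
  switch(axis, arr[i, , ], arr[, i, ], arr[, , i])
}

#' Extract the sagittal ROI slab
#'
#' Selects `n_slices` contiguous sagittal sections centred on the slice with
#' the largest mask area (ties break to the lower index), mirroring the
#' protocol of delineating the mid-sagittal section plus an equal number of
#' neighbours to each side. The slab is clipped (with a warning) where it
#' would cross the volume boundary.
#'
#' @param volume an `intensity_volume`.
#' @param mask the paired `roi_mask`.
#' @param n_slices odd number of sagittal sections (default 9).
#' @return an `roi_slab`: lists of 2D intensity and mask slices, the slice
#'   indices covered, the centre index, and flags for empty-mask slices.
#' @export
extract_slab <- function(volume, mask, n_slices = 9L) {
  stopifnot(inherits(volume, "intensity_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask shapes differ")
  if (n_slices %% 2L == 0L) stop("n_slices must be odd")
  ax <- volume$sagittal_axis
  nx <- dim(volume$data)[ax]
  areas <- vapply(seq_len(nx), function(i) sum(.slice3(mask$data, ax, i)),
                  numeric(1))
  if (all(areas == 0)) stop("mask is empty")
  center <- which.max(areas)              # which.max ties -> lowest index
  half <- (n_slices - 1L) %/% 2L
  lo <- center - half
  hi <- center + half
  if (lo < 1L || hi > nx) {
    warning("slab clipped at volume boundary (requested ", lo, ":", hi,
            " of ", nx, " sagittal slices)")
    lo <- max(1L, lo)
    hi <- min(nx, hi)
  }
  idx <- lo:hi
  structure(
    list(
      intensity = lapply(idx, function(i) .slice3(volume$data, ax, i)),
      mask = lapply(idx, function(i) .slice3(mask$data, ax, i)),
      indices = idx,
      center_index = center,
      n_slices = length(idx),
      empty_slices = idx[areas[idx] == 0],
      spacing = volume$spacing,
      sagittal_axis = ax
    ),
    class = "roi_slab"
  )
}

# Pooled in-ROI intensities across all slab slices.
.slab_roi_values <- function(slab) {
  unlist(lapply(seq_along(slab$intensity), function(k) {
    slab$intensity[[k]][slab$mask[[k]] == 1L]
  }), use.names = FALSE)
}

#' Discretise slab intensities to gray levels
#'
#' Equal-width binning of the pooled in-ROI intensity range into `n_levels`
#' gray levels 1..L. The pooled maximum maps to level L (closed upper bin);
#' a constant ROI collapses to level 1 and is flagged degenerate.
#' Out-of-ROI pixels carry the reserved sentinel level 0, which every
#' texture operator skips.
#'
#' @param slab an `roi_slab`.
#' @param n_levels integer number of gray levels L >= 2 (default 16).
#' @return a `quantized_slab`: integer-level slices, `n_levels`,
#'   `level_edges` (L+1 bin boundaries), and a `degenerate` flag.
#' @export
quantize <- function(slab, n_levels = 16L) {
  stopifnot(inherits(slab, "roi_slab"))
  if (n_levels < 2L) stop("n_levels must be >= 2")
  vals <- .slab_roi_values(slab)
  if (length(vals) == 0L) stop("slab contains no in-ROI pixel")
  lo <- min(vals); hi <- max(vals)
  degenerate <- !(lo < hi)
  if (degenerate) {
    edges <- lo + seq(0, 1, length.out = n_levels + 1L)  # nominal 1-wide span
    slices <- lapply(seq_along(slab$intensity), function(k) {
      m <- slab$mask[[k]]
      q <- matrix(0L, nrow(m), ncol(m))
      q[m == 1L] <- 1L
      q
    })
  } else {
    edges <- seq(lo, hi, length.out = n_levels + 1L)
    w <- (hi - lo) / n_levels
    slices <- lapply(seq_along(slab$intensity), function(k) {
      m <- slab$mask[[k]]
      x <- slab$intensity[[k]]
      q <- matrix(0L, nrow(m), ncol(m))
      inr <- m == 1L
      lev <- pmin(floor((x[inr] - lo) / w) + 1L, n_levels)
      q[inr] <- as.integer(lev)
      q
    })
  }
  structure(
    list(slices = slices, n_levels = as.integer(n_levels),
         level_edges = edges, degenerate = degenerate),
    class = "quantized_slab"
  )
}
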