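# The fixed 385-feature catalogue and the end-to-end extractor.

.glcm_base_names <- c("Energy", "Entropy", "Inertia", "Correlation",
                      "InverseDifferenceMoment", "ClusterShade",
                      "ClusterProminence", "HaralickCorrelation")
.rlm_base_names <- c("ShortRunEmphasis", "LongRunEmphasis",
                     "GreyLevelNonuniformity", "RunLengthNonuniformity",
                     "LowGreyLevelRunEmphasis", "HighGreyLevelRunEmphasis",
                     "ShortRunLowGreyLevelEmphasis",
                     "ShortRunHighGreyLevelEmphasis",
                     "LongRunLowGreyLevelEmphasis",
                     "LongRunHighGreyLevelEmphasis")
.haralick_names <- c("SumAverage", "SumVariance", "SumEntropy",
                     "DifferenceVariance", "DifferenceEntropy",
                     "InformationMeasureCorrelation1",
                     "InformationMeasureCorrelation2", "MaximumProbability",
                     "Autocorrelation", "Dissimilarity")
.formfactor_names <- c("Volume", "SurfaceArea", "SurfaceVolumeRatio",
                       "Sphericity", "Compactness1", "Compactness2",
                       "SphericalDisproportion", "Maximum3DDiameter",
                       "Elongation")

.block_names <- function(base, offsets, angles = c(0L, 45L, 90L, 135L)) {
  unlist(lapply(offsets, function(d) {
    unlist(lapply(base, function(f) c(
      paste0(f, "_angle", angles, "_offset", d),
      paste0(f, "_AllDirection_offset", d),
      paste0(f, "_AllDirection_offset", d, "_SD")
    )))
  }))
}

#' The canonical feature catalogue
#'
#' Names of all features, in the fixed extraction order: 42 first-order
#' histogram statistics, 9 formfactor (3D shape) descriptors, the
#' co-occurrence block (8 features x 4 angles + AllDirection mean/SD x
#' offsets), 10 secondary Haralick features at AllDirection offset 1, and
#' the run-length block (10 features x the same 6 variants x steps). With
#' the default offsets `c(1, 4, 7)` this is 42 + 9 + 144 + 10 + 180 = 385
#' names.
#'
#' @param offsets texture displacements/steps (default `c(1, 4, 7)`).
#' @return character vector of feature names.
#' @export
feature_catalogue <- function(offsets = c(1L, 4L, 7L)) {
  c(
    c(.histogram_stat_names, paste0("P", .histogram_percentiles)),
    .formfactor_names,
    .block_names(.glcm_base_names, offsets),
    paste0(.haralick_names, "_AllDirection_offset", offsets[1]),
    .block_names(.rlm_base_names, offsets)
  )
}

#' Extract the full feature vector for one subject
#'
#' Runs the whole per-subject pipeline: sagittal slab extraction, gray-level
#' quantization, and the five feature families, returning one named vector
#' in canonical catalogue order. Deterministic: identical inputs give
#' bitwise-identical vectors.
#'
#' @param volume an `intensity_volume`.
#' @param mask the paired `roi_mask`.
#' @param n_slices sagittal slab thickness (odd, default 9).
#' @param n_levels gray levels for quantization (default 16).
#' @param offsets texture displacements/steps (default `c(1, 4, 7)`).
#' @return named numeric vector (385 entries at defaults). The attribute
#'   `degenerate` records whether the quantizer hit a constant ROI.
#' @export
extract_all <- function(volume, mask, n_slices = 9L, n_levels = 16L,
                        offsets = c(1L, 4L, 7L)) {
  slab <- extract_slab(volume, mask, n_slices)
  qs <- quantize(slab, n_levels)
  out <- c(
    histogram_features(slab),
    formfactor_features(mask),
    glcm_feature_block(qs, offsets),
    haralick_block(qs, offset = offsets[1]),
    rlm_feature_block(qs, offsets)
  )
  expected <- feature_catalogue(offsets)
  if (!identical(names(out), expected))
    stop("internal error: feature vector does not match the catalogue")
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(names(out)[bad], collapse = ", "))
  attr(out, "degenerate") <- qs$degenerate
  out
}

#' Extract features for a cohort into a feature table
#'
#' @param subjects list of entries with fields `subject_id`, `volume`
#'   (`intensity_volume`), `mask` (`roi_mask`), `label` (1 = case/AD,
#'   0 = control/HC).
#' @param ... passed to [extract_all()].
#' @return a `data.frame` with columns `subject_id`, `label`, then the
#'   catalogue features in order.
#' @export
extract_cohort <- function(subjects, ...) {
  rows <- lapply(subjects, function(s) {
    fv <- tryCatch(extract_all(s$volume, s$mask, ...),
                   error = function(e) stop("subject ", s$subject_id, ": ",
                                            conditionMessage(e)))
    data.frame(subject_id = s$subject_id, label = s$label,
               as.list(fv), check.names = FALSE)
  })
  do.call(rbind, rows)
}
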