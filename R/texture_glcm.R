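# Gray-level co-occurrence matrices and their feature block.
#
# Co-occurrences are counted in 2D within each sagittal slice (the four
# canonical in-plane angles), pooled over the slab's slices, symmetrised and
# normalised. Level 0 is the out-of-ROI sentinel and never co-occurs.

# Unit displacement (row, col) per angle. Rows grow downward, so 45 deg is
# the up-right diagonal; symmetrised counting makes the sign immaterial.
.angle_step <- function(angle) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(1L, 0L),
         "135" = c(1L, 1L),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix of a quantized slab
#'
#' Counts pairs of in-ROI pixels separated by `offset` pixel steps along
#' `angle` within each 2D sagittal slice, sums the counts over all slices of
#' the slab, symmetrises (both orderings of each pair) and normalises to a
#' joint probability matrix.
#'
#' @param qslab a `quantized_slab`.
#' @param angle one of 0, 45, 90, 135 (degrees, in-plane).
#' @param offset displacement in pixels (d >= 1).
#' @return a `glcm_matrix`: `p` (L x L joint probabilities), `angle`,
#'   `offset`, `pair_count` (symmetrised raw count total), `degenerate`.
#' @export
glcm <- function(qslab, angle, offset) {
  stopifnot(inherits(qslab, "quantized_slab"), offset >= 1)
  L <- qslab$n_levels
  step <- .angle_step(angle) * as.integer(offset)
  counts <- matrix(0, L, L)
  for (Q in qslab$slices) {
    nr <- nrow(Q); nc <- ncol(Q)
    rs <- seq_len(nr); rs <- rs[rs + step[1] >= 1L & rs + step[1] <= nr]
    cs <- seq_len(nc); cs <- cs[cs + step[2] >= 1L & cs + step[2] <= nc]
    if (length(rs) == 0L || length(cs) == 0L) next
    A <- Q[rs, cs, drop = FALSE]
    B <- Q[rs + step[1], cs + step[2], drop = FALSE]
    ok <- A > 0L & B > 0L
    if (!any(ok)) next
    idx <- (A[ok] - 1L) * L + B[ok]
    counts <- counts + matrix(tabulate(idx, nbins = L * L), L, L, byrow = TRUE)
  }
  counts <- counts + t(counts)
  total <- sum(counts)
  structure(
    list(p = if (total > 0) counts / total else counts,
         angle = angle, offset = as.integer(offset),
         pair_count = total, degenerate = total == 0),
    class = "glcm_matrix"
  )
}

# The eight co-occurrence features of one matrix. Degenerate (pair-free)
# matrices return all zeros; zero marginal variance maps Correlation and
# HaralickCorrelation to 0.
.glcm_features <- function(G) {
  nm <- c("Energy", "Entropy", "Inertia", "Correlation",
          "InverseDifferenceMoment", "ClusterShade", "ClusterProminence",
          "HaralickCorrelation")
  if (G$degenerate) return(setNames(numeric(8), nm))
  p <- G$p
  L <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  pe <- p[p > 0]
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 0
  # Haralick correlation in the ITK convention: moments of the (unweighted)
  # marginal-probability vector itself.
  mm <- mean(px)
  mv <- sum((px - mm)^2) / L
  hc <- if (mv > 0) (sum(i * j * p) - mm^2) / mv else 0
  setNames(c(
    sum(p^2),
    -sum(pe * log(pe)),
    sum((i - j)^2 * p),
    corr,
    sum(p / (1 + (i - j)^2)),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    hc
  ), nm)
}

# Aggregate per-angle feature values into the six naming variants:
# the four angles, their mean (AllDirection) and population SD over angles.
.direction_variants <- function(per_angle, feature, angles, offset) {
  m <- mean(per_angle)
  s <- sqrt(mean((per_angle - m)^2))
  vals <- c(per_angle, m, s)
  names(vals) <- c(
    paste0(feature, "_angle", angles, "_offset", offset),
    paste0(feature, "_AllDirection_offset", offset),
    paste0(feature, "_AllDirection_offset", offset, "_SD")
  )
  vals
}

#' Co-occurrence feature block (8 features x 6 variants x offsets)
#'
#' Computes the eight base GLCM features per angle and offset, then the
#' AllDirection mean and population SD across the four angles, yielding
#' 8 x 6 x length(offsets) named values (144 at the default offsets).
#' Features are computed per angle and then aggregated, matching the
#' `_AllDirection` / `_SD` naming convention.
#'
#' @param qslab a `quantized_slab`.
#' @param offsets pixel displacements (default `c(1, 4, 7)`).
#' @param angles in-plane angles in degrees (fixed canonical default).
#' @return named numeric vector in catalogue order.
#' @export
glcm_feature_block <- function(qslab, offsets = c(1L, 4L, 7L),
                               angles = c(0L, 45L, 90L, 135L)) {
  base <- c("Energy", "Entropy", "Inertia", "Correlation",
            "InverseDifferenceMoment", "ClusterShade", "ClusterProminence",
            "HaralickCorrelation")
  out <- numeric(0)
  for (d in offsets) {
    per_angle <- vapply(angles, function(a) .glcm_features(glcm(qslab, a, d)),
                        numeric(length(base)))   # features x angles
    for (f in base)
      out <- c(out, .direction_variants(per_angle[f, ], f, angles, d))
  }
  out
}

#' Haralick secondary features on the angle-averaged offset-1 matrix
#'
#' Averages the four normalised offset-1 co-occurrence matrices into a
#' single AllDirection matrix and computes ten secondary Haralick
#' statistics on it (sum/difference histograms, information measures of
#' correlation, maximum probability, autocorrelation, dissimilarity).
#' Entropies use the natural logarithm.
#'
#' @param qslab a `quantized_slab`.
#' @param offset pixel displacement for the matrix (default 1).
#' @param angles in-plane angles averaged over.
#' @return named numeric vector of 10 features.
#' @export
haralick_block <- function(qslab, offset = 1L, angles = c(0L, 45L, 90L, 135L)) {
  nm <- c("SumAverage", "SumVariance", "SumEntropy", "DifferenceVariance",
          "DifferenceEntropy", "InformationMeasureCorrelation1",
          "InformationMeasureCorrelation2", "MaximumProbability",
          "Autocorrelation", "Dissimilarity")
  nm_full <- paste0(nm, "_AllDirection_offset", offset)
  mats <- lapply(angles, function(a) glcm(qslab, a, offset))
  ok <- !vapply(mats, `[[`, logical(1), "degenerate")
  if (!any(ok)) return(setNames(numeric(10), nm_full))
  p <- Reduce(`+`, lapply(mats[ok], `[[`, "p")) / sum(ok)
  L <- nrow(p)
  i <- row(p); j <- col(p)
  # sum histogram over k = i + j, difference histogram over k = |i - j|
  ps <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), numeric(1))
  pd <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  sa <- sum(ks * ps)
  mu_d <- sum(kd * pd)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  px <- rowSums(p)
  hx <- ent(px)
  hxy <- ent(p)
  pij <- outer(px, px)
  pos <- p > 0 & pij > 0
  hxy1 <- -sum(p[pos] * log(pij[pos]))
  hxy2 <- ent(pij)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  setNames(c(
    sa,
    sum((ks - sa)^2 * ps),
    ent(ps),
    sum((kd - mu_d)^2 * pd),
    ent(pd),
    imc1,
    imc2,
    max(p),
    sum(i * j * p),
    sum(abs(i - j) * p)
  ), nm_full)
}
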