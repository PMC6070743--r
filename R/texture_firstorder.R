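# First-order (histogram) statistics and 3D shape (formfactor) descriptors.

.histogram_stat_names <- c(
  "Min", "Max", "Range", "Sum", "Mean", "Median", "Mode", "StdDev",
  "Variance", "CoefficientOfVariation", "Skewness", "Kurtosis", "Energy",
  "Entropy", "Uniformity", "RootMeanSquare", "MeanAbsoluteDeviation",
  "MedianAbsoluteDeviation", "InterquartileRange", "TrimmedMean10",
  "VoxelCount"
)
.histogram_percentiles <- c(1, seq(5, 95, by = 5), 99)

#' First-order histogram features of the ROI slab
#'
#' 42 statistics of the raw (unquantized) in-ROI intensities pooled across
#' the slab's slices: 21 summary statistics plus 21 percentiles
#' (P1, P5, P10, ..., P95, P99). Variance and SD use the n-1 denominator;
#' skewness and excess kurtosis use population moment ratios and are 0 by
#' convention for zero-variance input. Entropy (natural log) and Uniformity
#' are computed on a 16-bin equal-width histogram of the ROI range.
#'
#' @param slab an `roi_slab`.
#' @return named numeric vector of 42 features.
#' @export
histogram_features <- function(slab) {
  x <- .slab_roi_values(slab)
  if (length(x) == 0L) stop("empty ROI: no in-ROI voxel in slab")
  n <- length(x)
  m <- mean(x)
  v <- if (n > 1) var(x) else 0
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  # 16-bin occupancy distribution for entropy/uniformity and the fallback mode
  rng <- range(x)
  if (rng[1] < rng[2]) {
    br <- seq(rng[1], rng[2], length.out = 17L)
    h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), 16L), 16L)
    p <- h / n
    mids <- (br[-1] + br[-17]) / 2
  } else {
    p <- 1
    mids <- rng[1]
  }
  pe <- p[p > 0]
  tab <- table(x)
  mode_val <- if (max(tab) > 1L) {
    min(as.numeric(names(tab)[tab == max(tab)]))
  } else {
    mids[which.max(p)]   # all values unique: densest-bin midpoint
  }
  qs <- quantile(x, .histogram_percentiles / 100, names = FALSE, type = 7)
  stats <- c(
    rng[1], rng[2], diff(rng), sum(x), m, median(x), mode_val,
    sqrt(v), v,
    if (m != 0) sqrt(v) / m else 0,
    skew, kurt,
    sum(x^2),
    -sum(pe * log(pe)),
    sum(p^2),
    sqrt(mean(x^2)),
    mean(abs(x - m)),
    median(abs(x - median(x))),
    quantile(x, 0.75, names = FALSE) - quantile(x, 0.25, names = FALSE),
    mean(x, trim = 0.1),
    n
  )
  setNames(c(stats, qs),
           c(.histogram_stat_names, paste0("P", .histogram_percentiles)))
}

# Exposed-face count per axis via neighbour shifts; out-of-bounds counts
# as exposed.
.exposed_faces <- function(mask) {
  d <- dim(mask)
  shift_cmp <- function(axis, dir) {
    idx <- lapply(d, seq_len)
    src <- idx; src[[axis]] <- seq_len(d[axis]) + dir
    inside <- src[[axis]] >= 1L & src[[axis]] <= d[axis]
    nb <- array(0L, d)
    dst <- idx; dst[[axis]] <- which(inside)
    srcok <- src; srcok[[axis]] <- src[[axis]][inside]
    nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[srcok[[1]], srcok[[2]], srcok[[3]]]
    sum(mask == 1L & nb == 0L)
  }
  vapply(1:3, function(a) shift_cmp(a, -1L) + shift_cmp(a, 1L), numeric(1))
}

# Largest pairwise distance between rows of a coordinate matrix, chunked to
# bound memory.
.max_pairwise_dist <- function(xyz, chunk = 512L) {
  n <- nrow(xyz)
  if (n < 2L) return(0)
  best <- 0
  sq <- rowSums(xyz^2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    cross <- xyz[s:e, , drop = FALSE] %*% t(xyz)
    d2 <- outer(sq[s:e], rep(1, n)) + outer(rep(1, e - s + 1L), sq) - 2 * cross
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3D shape (formfactor) features of an ROI mask
#'
#' Nine descriptors of the mask's three-dimensional size and shape.
#' Volume is voxel count times voxel volume; SurfaceArea counts exposed
#' voxel faces weighted by their physical area. Sphericity, the two
#' compactness variants and SphericalDisproportion compare the surface
#' to that of an equal-volume sphere. Maximum3DDiameter is the largest
#' distance between boundary-voxel centres; Elongation is
#' sqrt(lambda2/lambda1) of the principal moments of the voxel-centre
#' cloud (1 for a single voxel).
#'
#' @param mask an `roi_mask`.
#' @param spacing optional mm spacing override (defaults to the mask's).
#' @return named numeric vector of 9 features.
#' @export
formfactor_features <- function(mask, spacing = mask$spacing) {
  m <- mask$data
  n <- sum(m)
  if (n < 1) stop("empty mask")
  vox_vol <- prod(spacing)
  V <- n * vox_vol
  faces <- .exposed_faces(m)
  face_area <- vox_vol / spacing           # area of the face normal to axis k
  A <- sum(faces * face_area)
  ind <- which(m == 1L, arr.ind = TRUE)
  xyz <- sweep(ind, 2, spacing, `*`)
  # boundary voxels: at least one exposed face
  nb_sum <- array(0L, dim(m))
  d <- dim(m)
  for (a in 1:3) for (dir in c(-1L, 1L)) {
    idx <- lapply(d, seq_len)
    src <- idx; src[[a]] <- pmin(pmax(seq_len(d[a]) + dir, 1L), d[a])
    shifted <- m[src[[1]], src[[2]], src[[3]]]
    # clamped shift duplicates the border plane; mark border voxels exposed
    edge <- idx; edge[[a]] <- if (dir == -1L) 1L else d[a]
    shifted[edge[[1]], edge[[2]], edge[[3]]] <- 0L
    nb_sum <- nb_sum + shifted
  }
  boundary <- m == 1L & nb_sum < 6L
  bxyz <- sweep(which(boundary, arr.ind = TRUE), 2, spacing, `*`)
  maxdiam <- .max_pairwise_dist(bxyz)
  R_eq <- (3 * V / (4 * pi))^(1 / 3)
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    elong <- if (ev[1] > 0) sqrt(max(ev[2], 0) / ev[1]) else 1
  } else elong <- 1
  c(Volume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = sph,
    Compactness1 = V / (sqrt(pi) * A^1.5),
    Compactness2 = 36 * pi * V^2 / A^3,
    SphericalDisproportion = A / (4 * pi * R_eq^2),
    Maximum3DDiameter = maxdiam,
    Elongation = elong)
}
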