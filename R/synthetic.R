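# Synthetic desk-scale cohorts: arch-shaped corpus-callosum-like masks in
# the mid-sagittal plane, class-dependent in-ROI texture, and covariates
# matched to the study cohort's summary statistics (78 AD / 44 HC).

#' Texture parameters of a synthetic class
#'
#' @param base_mean,base_sd in-ROI intensity mean and SD (arbitrary units).
#' @param correlation_length Gaussian smoothing scale in voxels controlling
#'   texture coarseness (0 = i.i.d. voxel noise).
#' @param heterogeneity variance of a multiplicative low-frequency field
#'   (0 = stationary texture).
#' @return a `texture_params` list.
#' @export
texture_params <- function(base_mean = 100, base_sd = 10,
                           correlation_length = 0, heterogeneity = 0) {
  stopifnot(base_sd >= 0, correlation_length >= 0, heterogeneity >= 0)
  structure(list(base_mean = base_mean, base_sd = base_sd,
                 correlation_length = correlation_length,
                 heterogeneity = heterogeneity),
            class = "texture_params")
}

#' Cohort specification
#'
#' Defaults mirror the study cohort: 78 cases and 44 controls.
#'
#' @param n_ad,n_hc group sizes (>= 2 each).
#' @param ad_params,hc_params `texture_params` per class.
#' @param shape volume grid (sagittal axis first; minimum `c(32, 64, 64)`).
#' @param spacing voxel size in mm.
#' @param seed master RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_ad = 78L, n_hc = 44L,
                        ad_params = texture_params(correlation_length = 2),
                        hc_params = texture_params(correlation_length = 0),
                        shape = c(32L, 64L, 64L), spacing = c(1, 1, 1),
                        seed = 1L) {
  stopifnot(n_ad >= 2, n_hc >= 2)
  structure(list(n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
                 ad_params = ad_params, hc_params = hc_params,
                 shape = as.integer(shape), spacing = spacing,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Arch-shaped corpus-callosum-like mask
#'
#' A half-annulus (arch) in the in-plane coordinates of the mid-sagittal
#' slice, with seeded smooth boundary perturbations, extruded across
#' exactly `thickness` central sagittal slices.
#'
#' @param shape 3D grid, sagittal axis first; each entry at least
#'   `c(32, 64, 64)`.
#' @param thickness number of sagittal slices carrying the mask (default 9).
#' @param seed RNG seed for the boundary perturbation.
#' @param spacing voxel size in mm.
#' @return an `roi_mask`.
#' @export
make_cc_mask <- function(shape = c(32L, 64L, 64L), thickness = 9L,
                         seed = 1L, spacing = c(1, 1, 1)) {
  if (length(shape) != 3 || any(shape < c(32, 64, 64)))
    stop("shape must be >= c(32, 64, 64)")
  set.seed(seed)
  ny <- shape[2]; nz <- shape[3]
  cy <- ny / 2 + 0.5
  cz <- 0.40 * nz
  r_out <- 0.32 * min(ny, nz)
  r_in <- 0.60 * r_out
  # smooth seeded ripple of the two radii
  a <- runif(4, -1, 1)
  ph <- runif(2, 0, 2 * pi)
  y <- matrix(seq_len(ny), ny, nz)
  z <- matrix(seq_len(nz), ny, nz, byrow = TRUE)
  phi <- atan2(z - cz, y - cy)
  rr <- sqrt((y - cy)^2 + (z - cz)^2)
  ro <- r_out + a[1] * sin(2 * phi + ph[1]) + a[2] * sin(3 * phi + ph[2])
  ri <- r_in + a[3] * sin(2 * phi + ph[1]) + a[4] * sin(3 * phi + ph[2])
  plane <- z >= cz & rr >= ri & rr <= ro
  mode(plane) <- "integer"
  arr <- array(0L, shape)
  cx <- (shape[1] + 1L) %/% 2L
  half <- (thickness - 1L) %/% 2L
  for (x in (cx - half):(cx + half)) arr[x, , ] <- plane
  new_roi_mask(arr, spacing, sagittal_axis = 1L)
}

# Row-normalized Gaussian band matrix for separable in-plane smoothing.
.gauss_band <- function(n, sigma) {
  i <- seq_len(n)
  W <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
  W / rowSums(W)
}

.gblur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .gauss_band(nrow(m), sigma) %*% m %*% t(.gauss_band(ncol(m), sigma))
}

#' Synthesise one subject volume
#'
#' Background: a smooth brain-like intensity blob plus voxel noise. Inside
#' the ROI, each sagittal slice carries a Gaussian random field with the
#' class's mean and SD, smoothed in-plane at `correlation_length` voxels
#' (preserving unit variance before scaling) and optionally modulated by a
#' multiplicative low-frequency heterogeneity field. Fully determined by
#' `seed`.
#'
#' @param mask an `roi_mask` (defines grid, spacing and ROI).
#' @param params a `texture_params`.
#' @param seed RNG seed.
#' @return an `intensity_volume`.
#' @export
make_subject <- function(mask, params, seed = 1L) {
  stopifnot(inherits(mask, "roi_mask"), inherits(params, "texture_params"))
  set.seed(seed)
  shape <- dim(mask$data)
  ny <- shape[2]; nz <- shape[3]
  # smooth deterministic background blob + mild noise
  gy <- exp(-((seq_len(ny) - ny / 2)^2) / (2 * (0.35 * ny)^2))
  gz <- exp(-((seq_len(nz) - nz / 2)^2) / (2 * (0.35 * nz)^2))
  gx <- exp(-((seq_len(shape[1]) - shape[1] / 2)^2) /
              (2 * (0.35 * shape[1])^2))
  bg <- outer(gx, outer(gy, gz)) * (0.5 * params$base_mean)
  vol <- bg + array(rnorm(prod(shape), sd = 0.02 * max(params$base_mean, 1)),
                    shape)
  roi_slices <- which(apply(mask$data, 1, sum) > 0)
  cl <- params$correlation_length
  for (x in roi_slices) {
    field <- matrix(rnorm(ny * nz), ny, nz)
    if (cl > 0) {
      field <- .gblur2d(field, cl)
      field <- (field - mean(field)) / sd(field)   # restore unit variance
    }
    tex <- params$base_mean + params$base_sd * field
    if (params$heterogeneity > 0) {
      het <- .gblur2d(matrix(rnorm(ny * nz), ny, nz), max(ny, nz) / 8)
      het <- (het - mean(het)) / sd(het)
      tex <- tex * (1 + sqrt(params$heterogeneity) * het)
    }
    sl <- vol[x, , ]
    inr <- mask$data[x, , ] == 1L
    sl[inr] <- tex[inr]
    vol[x, , ] <- sl
  }
  new_intensity_volume(vol, mask$spacing, sagittal_axis = 1L)
}

# Truncated-normal draws via inverse-CDF (deterministic given the RNG state).
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_ad + n_hc` subjects, each with its own seeded mask
#' perturbation (independent of class, so shape carries no signal) and
#' class-dependent in-ROI texture, plus a covariate table drawn from the
#' study cohort's summary statistics: age, education, MMSE (truncated at
#' the diagnostic inclusion bounds: cases <= 24, controls in [28, 30]) and
#' sex.
#'
#' @param spec a `cohort_spec`.
#' @param imaging generate volumes and masks (default `TRUE`); `FALSE`
#'   draws the covariate table only, e.g. for large-n calibration checks.
#' @return list with `subjects` (list of `subject_id`, `volume`, `mask`,
#'   `label`; `NULL` when `imaging = FALSE`) and `covariates` (data frame).
#' @export
make_cohort <- function(spec, imaging = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_ad + spec$n_hc
  labels <- c(rep(1L, spec$n_ad), rep(0L, spec$n_hc))
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- if (imaging) vector("list", n) else NULL
  for (i in if (imaging) seq_len(n) else integer(0)) {
    prm <- if (labels[i] == 1L) spec$ad_params else spec$hc_params
    # double arithmetic: integer products overflow for large master seeds
    mseed <- as.integer((as.numeric(spec$seed) * 10007 + i) %%
                          .Machine$integer.max)
    vseed <- as.integer((as.numeric(spec$seed) * 20011 + i) %%
                          .Machine$integer.max)
    mask <- make_cc_mask(spec$shape, thickness = 9L, seed = mseed,
                         spacing = spec$spacing)
    vol <- make_subject(mask, prm, seed = vseed)
    subjects[[i]] <- list(subject_id = ids[i], volume = vol, mask = mask,
                          label = labels[i])
  }
  set.seed(spec$seed)
  ad <- labels == 1L
  age <- edu <- mmse <- numeric(n); sex <- character(n)
  age[ad] <- rnorm(sum(ad), 69.18, 12.23)
  age[!ad] <- rnorm(sum(!ad), 65.43, 9.70)
  edu[ad] <- rnorm(sum(ad), 7.54, 4.16)
  edu[!ad] <- rnorm(sum(!ad), 7.09, 3.38)
  mmse[ad] <- .rtruncnorm(sum(ad), 16.94, 5.94, lo = 0, hi = 24)
  mmse[!ad] <- .rtruncnorm(sum(!ad), 29.14, 0.77, lo = 28, hi = 30)
  sex[ad] <- ifelse(rbinom(sum(ad), 1, 25 / 78) == 1, "M", "F")
  sex[!ad] <- ifelse(rbinom(sum(!ad), 1, 20 / 44) == 1, "M", "F")
  covariates <- data.frame(subject_id = ids, label = labels, age = age,
                           education = edu, mmse = mmse, sex = sex)
  list(subjects = subjects, covariates = covariates)
}

#' Effect-size sweep of end-to-end discrimination
#'
#' For each texture-coarseness gap, builds a cohort whose control class has
#' `correlation_length` equal to the case class's value plus the gap, runs
#' the full pipeline (extraction, selection cascade, logistic fit) and
#' records the test-partition AUC.
#'
#' @param base_spec a `cohort_spec`; its `ad_params` anchor the sweep.
#' @param deltas numeric vector of correlation-length gaps.
#' @param ... passed to [run_selection()].
#' @return data frame with one row per delta: `delta`, `auc_test`.
#' @export
effect_size_sweep <- function(base_spec, deltas, ...) {
  rows <- lapply(deltas, function(dl) {
    prm <- base_spec$ad_params
    hc <- texture_params(prm$base_mean, prm$base_sd,
                         prm$correlation_length + dl, prm$heterogeneity)
    spec <- cohort_spec(base_spec$n_ad, base_spec$n_hc, prm, hc,
                        base_spec$shape, base_spec$spacing, base_spec$seed)
    coh <- make_cohort(spec)
    tab <- extract_cohort(coh$subjects)
    sel <- run_selection(tab, seed = spec$seed, ...)
    model <- fit_logistic(sel$train)
    rep <- evaluate(model, sel$test)
    data.frame(delta = dl, auc_test = rep$metrics[["auc"]])
  })
  do.call(rbind, rows)
}

#' Write a synthetic cohort to disk
#'
#' NIfTI volume and mask per subject, a `covariates.csv`, and a
#' `manifest.json` listing `(subject_id, volume, mask, label)` suitable for
#' [run_all()].
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    vpath <- file.path(dir, paste0(s$subject_id, "_vol.nii.gz"))
    mpath <- file.path(dir, paste0(s$subject_id, "_mask.nii.gz"))
    write_volume(s$volume, vpath)
    write_volume(s$mask, mpath)
    data.frame(subject_id = s$subject_id, volume = vpath, mask = mpath,
               label = s$label)
  })
  manifest <- do.call(rbind, rows)
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, dataframe = "rows", pretty = TRUE)
  invisible(mpath)
}
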