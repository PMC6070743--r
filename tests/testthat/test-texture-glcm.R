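test_that("single-level constant ROI gives p(1,1) = 1 and limit features", {
  qs <- make_test_qslab(matrix(1L, 2, 2), n_levels = 1)
  G <- glcm(qs, 0, 1)
  expect_equal(G$p, matrix(1, 1, 1))
  blk <- glcm_feature_block(qs, offsets = 1)
  for (a in c(0, 45, 90, 135)) {
    expect_equal(blk[[paste0("InverseDifferenceMoment_angle", a, "_offset1")]], 1)
    expect_equal(blk[[paste0("ClusterShade_angle", a, "_offset1")]], 0)
    expect_equal(blk[[paste0("Entropy_angle", a, "_offset1")]], 0)
    expect_equal(blk[[paste0("Energy_angle", a, "_offset1")]], 1)
  }
  sd_names <- grep("_SD$", names(blk), value = TRUE)
  expect_true(all(blk[sd_names] == 0))
})

test_that("hand-enumerated 6-pixel slice matches known probabilities", {
  # levels (1-based): rows [1,1,2] / [2,3,3]
  q <- rbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  qs <- make_test_qslab(q, n_levels = 3)
  G <- glcm(qs, 0, 1)
  expect_equal(sum(G$p), 1)
  expect_equal(G$p[1, 1], 0.25)
  expect_equal(G$p[1, 2], 0.125)
  expect_equal(G$p[2, 1], 0.125)
  expect_equal(G$p[2, 3], 0.125)
  expect_equal(G$p[3, 3], 0.25)
  blk <- glcm_feature_block(qs, offsets = 1)
  expect_equal(blk[["InverseDifferenceMoment_angle0_offset1"]], 0.75)
})

test_that("co-occurrence matrices are symmetric and normalised", {
  for (seed in 1:5) {
    qs <- random_qslab(10, 14, L = 4, seed = seed)
    for (a in c(0, 45, 90, 135)) for (d in c(1, 3)) {
      G <- glcm(qs, a, d)
      if (G$degenerate) next
      expect_equal(sum(G$p), 1, tolerance = 1e-12)
      expect_equal(G$p, t(G$p))
      idm <- sum(G$p / (1 + (row(G$p) - col(G$p))^2))
      expect_gt(idm, 0)
      expect_lte(idm, 1)
    }
  }
})

test_that("IDM equals 1 exactly when all co-occurring pairs agree", {
  # two separated constant patches: all pairs have i == j
  q <- matrix(0L, 5, 5)
  q[1:2, 1:2] <- 1L
  q[4:5, 4:5] <- 3L
  qs <- make_test_qslab(q, n_levels = 3)
  blk <- glcm_feature_block(qs, offsets = 1)
  expect_equal(blk[["InverseDifferenceMoment_angle0_offset1"]], 1)
})

test_that("transposing a slice swaps the 0- and 90-degree features", {
  qs <- random_qslab(9, 13, L = 5, seed = 42)
  qt <- make_test_qslab(t(qs$slices[[1]]), n_levels = 5)
  b1 <- glcm_feature_block(qs, offsets = c(1, 2))
  b2 <- glcm_feature_block(qt, offsets = c(1, 2))
  for (f in c("Energy", "Entropy", "Inertia", "ClusterShade")) {
    for (d in c(1, 2)) {
      expect_equal(b1[[paste0(f, "_angle0_offset", d)]],
                   b2[[paste0(f, "_angle90_offset", d)]])
      expect_equal(b1[[paste0(f, "_angle90_offset", d)]],
                   b2[[paste0(f, "_angle0_offset", d)]])
    }
  }
})

test_that("feature block matches the brute-force oracle on random ROIs", {
  for (seed in 1:5) {
    qs <- random_qslab(12, 12, L = 5, seed = 100 + seed)
    blk <- glcm_feature_block(qs, offsets = c(1, 4))
    orc <- oracle_block(qs, offsets = c(1, 4), family = "glcm")
    expect_equal(blk, orc[names(blk)], tolerance = 1e-12)
  }
})

test_that("directional SD is small for isotropic random texture", {
  qs <- random_qslab(40, 40, L = 4, roi_prob = 1, seed = 9)
  blk <- glcm_feature_block(qs, offsets = 1)
  expect_lt(blk[["Energy_AllDirection_offset1_SD"]],
            0.2 * blk[["Energy_AllDirection_offset1"]])
})

test_that("secondary Haralick features match literal formulas", {
  qs <- random_qslab(12, 12, L = 4, seed = 7)
  hb <- haralick_block(qs, offset = 1)
  mats <- lapply(c(0, 45, 90, 135),
                 function(a) oracle_glcm(qs$slices, 4, a, 1))
  pbar <- Reduce(`+`, mats) / 4
  orc <- oracle_haralick(pbar)
  expect_equal(unname(hb), unname(orc), tolerance = 1e-12)

  # hand arithmetic: uniform p over 2x2 levels
  qu <- make_test_qslab(matrix(c(1L, 2L), 2, 12), n_levels = 2)
  G <- glcm(qu, 90, 1)   # vertical neighbours alternate 1/2 exactly
  expect_equal(max(G$p), 0.5)
  hb2 <- haralick_block(qu, offset = 1)
  expect_equal(hb2[["Dissimilarity_AllDirection_offset1"]],
               oracle_haralick(Reduce(`+`, lapply(c(0, 45, 90, 135),
                 function(a) oracle_glcm(qu$slices, 2, a, 1))) / 4)[["Dissimilarity"]])

  # constant ROI: single entry at (1,1)
  qc <- make_test_qslab(matrix(1L, 3, 3), n_levels = 2)
  hb3 <- haralick_block(qc, offset = 1)
  expect_equal(hb3[["MaximumProbability_AllDirection_offset1"]], 1)
  expect_equal(hb3[["Dissimilarity_AllDirection_offset1"]], 0)
  expect_equal(hb3[["SumAverage_AllDirection_offset1"]], 2)
})
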