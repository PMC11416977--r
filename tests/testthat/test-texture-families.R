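test_that("GLCM on the worked 2x2 single-slice example", {
  # levels [[1,1],[1,2]], one in-plane direction, symmetric:
  # pair counts {(1,1):2, (1,2):1, (2,1):1}, normalized by 4
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[1, 2, 1] <- 1L
  lev[2, 1, 1] <- 1L; lev[2, 2, 1] <- 2L
  counts <- timeradiomics:::cpp_glcm_counts(lev, 2L,
                                            matrix(c(0L, 1L, 0L), 1))
  P <- counts[, , 1] / sum(counts[, , 1])
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2))
  f <- timeradiomics:::glcm_single(P, 2L)
  expect_equal(f[["JointEnergy"]], 0.375)
  expect_equal(f[["JointEntropy"]], 1.5)
})

test_that("GLCM degenerate and conservation properties", {
  const <- make_droi(array(1L, c(3, 3, 3)))
  f <- glcm_features(const)
  expect_equal(f[["MaximumProbability"]], 1)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Correlation"]], 1)
  expect_equal(f[["MCC"]], 1)
  expect_equal(f[["JointEntropy"]], 0)
  # normalization: each direction's matrix sums to 1
  dr <- random_droi(c(4, 4, 4), 3, seed = 21)
  counts <- timeradiomics:::cpp_glcm_counts(dr$levels, dr$ng, dirs13())
  for (k in seq_len(dim(counts)[3])) {
    tot <- sum(counts[, , k])
    if (tot > 0) expect_equal(sum(counts[, , k] / tot), 1)
  }
})

test_that("GLRLM on the worked 1D run example", {
  lev <- array(c(1L, 1L, 2L), c(1, 1, 3))
  dr <- make_droi(lev)
  counts <- timeradiomics:::cpp_glrlm_counts(lev, 2L,
                                             matrix(c(0L, 0L, 1L), 1))
  P <- counts[, , 1]
  expect_equal(P[1, 2], 1)  # level 1, run length 2
  expect_equal(P[2, 1], 1)  # level 2, run length 1
  expect_equal(sum(P), 2)
  nr <- sum(P)
  sre <- (1 / 4 + 1) / 2
  expect_equal(sum(colSums(P) / seq_len(ncol(P))^2) / nr, sre)
})

test_that("GLRLM degenerate case and run-voxel conservation", {
  const <- make_droi(array(2L, c(3, 3, 3)) - 1L + 1L)
  # constant ROI along any single direction: one run per line
  lev <- array(1L, c(4, 1, 1))
  counts <- timeradiomics:::cpp_glrlm_counts(lev, 1L,
                                             matrix(c(1L, 0L, 0L), 1))
  expect_equal(sum(counts), 1)          # exactly one run
  expect_equal(counts[1, 4, 1], 1)      # of length 4
  # conservation: sum(runs x length) = voxel count, per direction
  dr <- random_droi(c(5, 4, 3), 4, seed = 31)
  cc <- timeradiomics:::cpp_glrlm_counts(dr$levels, dr$ng, dirs13())
  for (k in seq_len(dim(cc)[3])) {
    P <- cc[, , k]
    expect_equal(sum(P %*% seq_len(ncol(P))), dr$n_voxels)
  }
})

test_that("GLSZM zones match hand labelling and conserve voxels", {
  lev <- array(c(1L, 1L, 2L), c(1, 1, 3))
  zones <- timeradiomics:::cpp_glszm_zones(lev)
  zones <- zones[order(zones[, 1]), , drop = FALSE]
  expect_equal(zones, cbind(c(1L, 2L), c(2L, 1L)), ignore_attr = TRUE)
  f <- glszm_features(make_droi(lev))
  expect_equal(f[["SizeZoneNonUniformity"]], 1)  # (1^2 + 1^2) / 2
  # constant ROI: one zone covering everything
  fc <- glszm_features(make_droi(array(1L, c(3, 3, 3))))
  expect_equal(fc[["ZonePercentage"]], 1 / 27)
  # conservation
  dr <- random_droi(c(5, 5, 4), 3, seed = 41)
  z <- timeradiomics:::cpp_glszm_zones(dr$levels)
  expect_equal(sum(z[, 2]), dr$n_voxels)
})

test_that("NGTDM sums match direct neighbour averaging on a checkerboard", {
  lev <- array(NA_integer_, c(3, 3, 1))
  lev[, , 1] <- (matrix(c(1, 2, 1, 2, 1, 2, 1, 2, 1), 3))
  dr <- make_droi(lev)
  M <- timeradiomics:::cpp_ngtdm(lev, 2L)
  expect_equal(M, bf_ngtdm(lev, 2L), ignore_attr = TRUE)
  # constant ROI: all s_i = 0
  fc <- ngtdm_features(make_droi(array(1L, c(3, 3, 3))))
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["Complexity"]], 0)
  expect_equal(fc[["Coarseness"]], 1e6)
})

test_that("level-shift after discretization leaves NGTDM-family values stable", {
  dr <- random_droi(c(4, 4, 4), 3, seed = 51)
  shifted <- make_droi(dr$levels + 2L)
  f1 <- ngtdm_features(dr)
  f2 <- ngtdm_features(shifted)
  # Contrast/Busyness depend only on level differences and proportions;
  # Coarseness and Strength are difference-based too
  expect_equal(f1[["Contrast"]], f2[["Contrast"]], tolerance = 1e-9)
  expect_equal(f1[["Coarseness"]], f2[["Coarseness"]], tolerance = 1e-9)
  expect_equal(f1[["Complexity"]], f2[["Complexity"]], tolerance = 1e-9)
  expect_equal(f1[["Strength"]], f2[["Strength"]], tolerance = 1e-9)
})

test_that("GLDM census on a constant cube matches the hand count", {
  lev <- array(1L, c(3, 3, 3))
  f <- gldm_features(make_droi(lev))
  # 8 corners with 7 neighbours, 12 edges with 11, 6 faces with 17,
  # 1 centre with 26; dependence size = count + 1
  expect_equal(f[["DependenceNonUniformityNormalized"]],
               (8^2 + 12^2 + 6^2 + 1^2) / 27^2)
  # single-voxel ROI: one entry in the dependence-0 column
  s <- array(NA_integer_, c(3, 3, 3)); s[2, 2, 2] <- 1L
  fs <- gldm_features(make_droi(s))
  expect_equal(fs[["LargeDependenceEmphasis"]], 1)  # size (0 + 1)^2
  expect_true(all(is.finite(fs)))
})

test_that("every texture matrix equals brute-force enumeration on fuzz grids", {
  for (seed in 1:8) {
    dims <- sample(2:5, 3, replace = TRUE)
    ng <- sample(2:4, 1)
    dr <- random_droi(dims, ng, seed = 100 + seed)
    lev <- dr$levels
    offs <- dirs13()
    cg <- timeradiomics:::cpp_glcm_counts(lev, dr$ng, offs)
    cr <- timeradiomics:::cpp_glrlm_counts(lev, dr$ng, offs)
    for (k in seq_len(nrow(offs))) {
      expect_equal(cg[, , k], bf_glcm(lev, offs[k, ], dr$ng),
                   ignore_attr = TRUE, tolerance = 1e-12)
      bfr <- bf_glrlm(lev, offs[k, ], dr$ng)
      got <- cr[, , k]
      expect_equal(got[, seq_len(ncol(bfr)), drop = FALSE], bfr,
                   ignore_attr = TRUE, tolerance = 1e-12)
      if (ncol(got) > ncol(bfr))
        expect_true(all(got[, (ncol(bfr) + 1):ncol(got)] == 0))
    }
    z <- timeradiomics:::cpp_glszm_zones(lev)
    z <- z[order(z[, 1], z[, 2]), , drop = FALSE]
    expect_equal(z, bf_glszm(lev), ignore_attr = TRUE)
    expect_equal(timeradiomics:::cpp_ngtdm(lev, dr$ng),
                 bf_ngtdm(lev, dr$ng), ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(timeradiomics:::cpp_gldm_counts(lev, dr$ng, 0L),
                 bf_gldm(lev, dr$ng, 0), ignore_attr = TRUE,
                 tolerance = 1e-12)
    # GLDM conservation: entries sum to the ROI voxel count
    expect_equal(sum(timeradiomics:::cpp_gldm_counts(lev, dr$ng, 0L)),
                 dr$n_voxels)
  }
})
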