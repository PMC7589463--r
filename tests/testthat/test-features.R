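test_that("fixed-bin-number discretisation maps edge cases as defined", {
  expect_error(discretise(numeric(0)), "empty")
  expect_error(discretise(1:5, n_bins = 1), ">= 2")
  const <- discretise(rep(3.5, 10), 32)
  expect_true(all(const$levels == 1L))
  ident <- discretise(0:31, 32)
  expect_identical(ident$levels, 1:32)
  four <- discretise(c(0, 10, 20, 30), 4)
  expect_identical(four$levels, 1:4)
  # maximum value lands in the top bin, not one past it
  expect_equal(max(discretise(c(0, 1), 8)$levels), 8L)
})

test_that("intensity statistics match hand computation on {1,2,3,4}", {
  f <- statistical_features(c(1, 2, 3, 4))
  expect_length(f, 18)
  expect_equal(unname(f["stat_mean"]), 2.5)
  expect_equal(unname(f["stat_var"]), 1.25) # population variance
  expect_equal(unname(f["stat_energy"]), 30)
  expect_equal(unname(f["stat_rms"]), sqrt(7.5))
  expect_equal(unname(f["stat_range"]), 3)
  expect_equal(unname(f["stat_mad"]), 1)
})

test_that("constant ROIs give defined degenerate statistics", {
  rimcore_log_clear()
  f <- statistical_features(rep(7, 20))
  expect_equal(unname(f["stat_mean"]), 7)
  expect_equal(unname(f["stat_var"]), 0)
  expect_equal(unname(f["stat_skew"]), 0)
  expect_equal(unname(f["stat_kurt"]), 0)
  expect_equal(unname(f["stat_energy"]), 20 * 49)
  expect_true(any(grepl("zero variance", rimcore_log())))
})

test_that("histogram features: two balanced levels and constants", {
  vals <- c(rep(0, 10), rep(10, 10))
  dr <- discretise(vals, 2)
  f <- histogram_features(dr, vals)
  expect_length(f, 38)
  expect_equal(unname(f["ih_uniformity"]), 0.5)
  expect_equal(unname(f["ih_entropy"]), 1) # one bit
  cf <- histogram_features(discretise(rep(5, 8), 32), rep(5, 8))
  expect_equal(unname(cf["ih_entropy"]), 0)
  expect_equal(unname(cf["ih_uniformity"]), 1)
  expect_equal(unname(cf["ivh_diff_v10_v90"]), 0)
  expect_equal(unname(cf["ivh_diff_i10_i90"]), 0)
})

test_that("IVH fractions follow their definitions on a linear ROI", {
  vals <- as.numeric(0:99)
  f <- histogram_features(discretise(vals, 32), vals)
  # V(gamma): fraction of voxels at or above min + gamma * range
  expect_equal(unname(f["ivh_v10"]), mean(vals >= 9.9))
  expect_equal(unname(f["ivh_v90"]), mean(vals >= 89.1))
  # I(x): smallest value v with fraction(values >= v) <= x
  expect_equal(unname(f["ivh_i10"]), min(vals[sapply(
    vals, function(b) mean(vals >= b)
  ) <= 0.10]))
  expect_equal(
    unname(f["ivh_diff_v10_v90"]),
    unname(f["ivh_v10"] - f["ivh_v90"])
  )
})

test_that("texture matrices equal brute-force enumeration on the 2x2 block", {
  lev <- array(0L, c(2, 2, 1))
  lev[, , 1] <- matrix(c(1L, 3L, 2L, 4L), 2, 2)
  d <- dim(lev)
  glcm <- rimcore:::.cpp_glcm(as.integer(lev), as.integer(d), 4L)
  glrlm <- rimcore:::.cpp_glrlm(as.integer(lev), as.integer(d), 4L)
  for (dd in seq_len(13)) {
    expect_equal(
      matrix(glcm[, , dd], 4, 4),
      brute_glcm(lev, 4, DIRS13[dd, ]),
      ignore_attr = TRUE
    )
    expect_equal(
      glrlm[, seq_len(max(d)), dd],
      brute_glrlm(lev, 4, DIRS13[dd, ])[, seq_len(max(d))],
      ignore_attr = TRUE
    )
  }
})

test_that("all matrix accumulators equal brute force on random small ROIs", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      d <- c(4, 4, 4)
      lev <- array(sample(0:3, prod(d), replace = TRUE), d)
      ng <- 3L
      glcm <- rimcore:::.cpp_glcm(as.integer(lev), as.integer(d), ng)
      glrlm <- rimcore:::.cpp_glrlm(as.integer(lev), as.integer(d), ng)
      for (dd in seq_len(13)) {
        expect_equal(matrix(glcm[, , dd], ng, ng),
          brute_glcm(lev, ng, DIRS13[dd, ]),
          ignore_attr = TRUE
        )
        expect_equal(glrlm[, 1:4, dd],
          brute_glrlm(lev, ng, DIRS13[dd, ])[, 1:4],
          ignore_attr = TRUE
        )
      }
      # zones: multiset of (level, size) must agree
      dist <- rimcore:::.cpp_manhattan_dist(
        as.integer(lev > 0), as.integer(d)
      )
      zones <- rimcore:::.cpp_zones(as.integer(lev), as.integer(d), dist)
      got <- sort(paste(zones[, 1], zones[, 2]))
      want <- sort(vapply(
        brute_zones(lev),
        function(z) paste(z$level, z$size), character(1)
      ))
      expect_identical(got, want)
      # dependence counts (alpha = 0, 26-neighbourhood)
      ngldm <- rimcore:::.cpp_ngldm(as.integer(lev), as.integer(d), ng, 0L)
      nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      nb <- nb[rowSums(abs(nb)) > 0, ]
      want_m <- matrix(0, ng, 27)
      for (t in which(lev > 0)) {
        k <- (t - 1) %/% 16 + 1
        j <- ((t - 1) %/% 4) %% 4 + 1
        i <- (t - 1) %% 4 + 1
        dep <- 0
        for (r in seq_len(nrow(nb))) {
          p <- c(i, j, k) + nb[r, ]
          if (any(p < 1) || any(p > 4)) next
          if (lev[p[1], p[2], p[3]] == lev[i, j, k]) dep <- dep + 1
        }
        want_m[lev[i, j, k], dep + 1] <- want_m[lev[i, j, k], dep + 1] + 1
      }
      expect_equal(unclass(ngldm), want_m, ignore_attr = TRUE)
      # grey-tone difference accumulation
      ngtdm <- rimcore:::.cpp_ngtdm(as.integer(lev), as.integer(d), ng)
      want_t <- matrix(0, ng, 2)
      for (t in which(lev > 0)) {
        k <- (t - 1) %/% 16 + 1
        j <- ((t - 1) %/% 4) %% 4 + 1
        i <- (t - 1) %% 4 + 1
        nbv <- c()
        for (r in seq_len(nrow(nb))) {
          p <- c(i, j, k) + nb[r, ]
          if (any(p < 1) || any(p > 4)) next
          v <- lev[p[1], p[2], p[3]]
          if (v > 0) nbv <- c(nbv, v)
        }
        if (length(nbv) == 0) next
        a <- lev[i, j, k]
        want_t[a, 1] <- want_t[a, 1] + 1
        want_t[a, 2] <- want_t[a, 2] + abs(a - mean(nbv))
      }
      expect_equal(unclass(ngtdm), want_t, ignore_attr = TRUE)
    })
  }
})

test_that("texture features on a constant ROI take their defined values", {
  lev <- array(0L, c(6, 6, 6))
  lev[2:5, 2:5, 2:5] <- 1L
  f <- texture_features(lev, 4)
  expect_length(f, 95)
  expect_equal(unname(f["glcm_joint_max"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["ngt_coarseness"]), 1e6) # capped maximum
  expect_equal(unname(f["glszm_glnun"]), 1)
  # single-voxel ROI is degenerate but defined
  one <- array(0L, c(3, 3, 3))
  one[2, 2, 2] <- 1L
  f1 <- texture_features(one, 4)
  expect_true(all(is.finite(f1)))
  expect_equal(unname(f1["glcm_contrast"]), 0)
})

test_that("morphology of a digital sphere matches the analytic ball", {
  m <- sphere_mask(15)
  f <- morphology_features(m)
  expect_length(f, 28)
  expect_gte(unname(f["morph_sphericity"]), 0.97)
  expect_lte(unname(f["morph_sphericity"]), 1.0)
  expect_equal(unname(f["morph_vol_mesh"]), 4 / 3 * pi * 15^3,
    tolerance = 0.02
  )
  expect_equal(unname(f["morph_vol_voxel"]), sum(m))
  expect_equal(unname(f["morph_diam"]), 30, tolerance = 0.05)
  expect_equal(unname(f["morph_elongation"]), 1, tolerance = 0.02)
  expect_equal(unname(f["morph_flatness"]), 1, tolerance = 0.02)
  expect_equal(unname(f["morph_pca_major"]),
    4 * sqrt(15^2 / 5), # uniform ball: lambda = R^2 / 5
    tolerance = 0.02
  )
  expect_equal(unname(f["morph_vdens_aabb"]), pi / 6, tolerance = 0.05)
})

test_that("morphology of a voxel cube reflects the smoothed-mesh estimator", {
  cube <- array(0L, c(16, 16, 16))
  cube[4:13, 4:13, 4:13] <- 1L
  f <- morphology_features(roi_mask(cube, 1))
  expect_equal(unname(f["morph_vol_voxel"]), 1000)
  # mesh smoothing rounds the 8 corners: volume and area sit a little
  # below the sharp-cube values (frozen measured behaviour)
  expect_equal(unname(f["morph_vol_mesh"]), 963, tolerance = 0.02)
  expect_equal(unname(f["morph_area_mesh"]), 539, tolerance = 0.03)
  # diameter comes from the convex hull, not the smoothed mesh
  expect_gt(unname(f["morph_diam"]), 9 * sqrt(3))
  expect_lt(unname(f["morph_diam"]), 10 * sqrt(3) + 0.1)
})

test_that("shape features ignore intensities; the intensity quartet reacts", {
  withr::with_seed(12, {
    ph <- generate_phantom(phantom_spec(tumour_axes_mm = 8, seed = 1), z = 0.6)
    img2 <- image_volume(
      unclass(ph$image) + array(rnorm(length(ph$image), 0, 20), dim(ph$image)),
      1
    )
    f1 <- morphology_features(ph$mask, ph$image, ph$mask)
    f2 <- morphology_features(ph$mask, img2, ph$mask)
    quartet <- c("morph_integ_int", "morph_moran_i", "morph_geary_c",
      "morph_com_shift")
    shape <- setdiff(names(f1), quartet)
    expect_equal(f1[shape], f2[shape], tolerance = 1e-12)
    expect_false(isTRUE(all.equal(f1[quartet], f2[quartet])))
  })
})

test_that("extraction yields the full 1538-column contract deterministically", {
  ph <- generate_phantom(phantom_spec(tumour_axes_mm = 7), z = 0.5)
  fv <- extract_features(ph$image, ph$mask)
  man <- feature_manifest()
  expect_length(fv, 1538)
  expect_identical(names(fv), man$name)
  expect_equal(
    as.vector(table(man$family)[c(
      "statistical", "histogram", "texture", "morphology"
    )]),
    c(18L, 38L, 95L, 28L) * c(10L, 10L, 10L, 1L)
  )
  expect_identical((18 + 38 + 95) * 10 + 28, 1538)
  fv2 <- extract_features(ph$image, ph$mask)
  expect_identical(fv, fv2)
  # composition consistency with the direct family call
  reseg <- resegment(ph$image, ph$mask)
  vals <- unclass(ph$image)[unclass(reseg) > 0]
  direct <- statistical_features(vals)
  expect_equal(
    unname(fv[paste0("base_", names(direct))]), unname(direct)
  )
})

test_that("discretised-domain features are shift invariant; the mean shifts", {
  ph <- generate_phantom(phantom_spec(tumour_axes_mm = 6, seed = 2), z = 0.3)
  img_shift <- image_volume(unclass(ph$image) + 40, 1)
  a <- extract_features(ph$image, ph$mask,
    transforms = "base", hu_window = c(-1e6, 1e6)
  )
  b <- extract_features(img_shift, ph$mask,
    transforms = "base", hu_window = c(-1e6, 1e6)
  )
  tex <- grep("^base_(glcm|glrlm|glszm|gldzm|ngt|ngl)", names(a), value = TRUE)
  ih <- grep("^base_ih_", names(a), value = TRUE)
  expect_equal(a[tex], b[tex], tolerance = 1e-8)
  expect_equal(a[ih], b[ih], tolerance = 1e-8)
  expect_equal(
    unname(b["base_stat_mean"] - a["base_stat_mean"]), 40,
    tolerance = 1e-9
  )
})

test_that("direction-averaged texture features survive 90-degree rotation", {
  ph <- generate_phantom(phantom_spec(tumour_axes_mm = c(8, 6, 7), seed = 5),
    z = 0.8
  )
  rot <- function(a) {
    # 90 degrees about the z axis
    d <- dim(a)
    aperm(a, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  img_r <- image_volume(rot(unclass(ph$image)), 1)
  msk_r <- roi_mask(rot(unclass(ph$mask)), 1)
  a <- extract_features(ph$image, ph$mask,
    transforms = "base", families = "texture"
  )
  b <- extract_features(img_r, msk_r, transforms = "base", families = "texture")
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("whole-voxel translation leaves every feature unchanged", {
  ph <- generate_phantom(phantom_spec(tumour_axes_mm = 5, seed = 9), z = 0.2)
  d <- dim(ph$image)
  shift1 <- function(a) {
    out <- array(a[1], d)
    out[2:d[1], 2:d[2], 2:d[3]] <- a[1:(d[1] - 1), 1:(d[2] - 1), 1:(d[3] - 1)]
    out
  }
  img_t <- image_volume(shift1(unclass(ph$image)), 1)
  msk_t <- roi_mask(shift1(unclass(ph$mask)), 1)
  a <- extract_features(ph$image, ph$mask,
    transforms = "base", families = c("statistical", "texture", "morphology")
  )
  b <- extract_features(img_t, msk_t,
    transforms = "base", families = c("statistical", "texture", "morphology")
  )
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("an unextractable ROI is omitted with a log record", {
  rimcore_log_clear()
  img <- image_volume(array(-1000, c(8, 8, 8)), 1)
  msk <- roi_mask(array(1L, c(8, 8, 8)), 1)
  expect_null(extract_features(img, msk, transforms = "base"))
  expect_true(any(grepl("row omitted", rimcore_log())))
  tab <- extract_all(img, list(entire = msk), transforms = "base")
  expect_equal(nrow(tab), 0)
})
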