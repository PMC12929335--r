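uniform_phantom <- function(liver_hu = 42.8, spleen_hu = 34.2, texture_sd = 0,
                            crop_fraction = 0, seed = 1) {
  cfg <- phantom_config(
    grid_shape = c(40, 40, 30),
    liver_ellipsoid = list(center = c(14, 20, 15), semiaxes = c(9, 11, 10)),
    spleen_ellipsoid = list(center = c(31, 20, 15), semiaxes = c(5, 6, 8)),
    liver_hu = liver_hu, spleen_hu = spleen_hu,
    texture_sd = texture_sd, crop_fraction = crop_fraction, seed = seed
  )
  simulate_phantom(cfg)
}

test_that("masked mean matches uniform phantoms and hand arithmetic", {
  vol <- uniform_phantom()
  expect_equal(masked_mean(vol, 1L)$mean_hu, 42.8)
  expect_equal(masked_mean(vol, 2L)$mean_hu, 34.2)

  img <- array(0, c(3, 3, 3))
  msk <- array(0L, c(3, 3, 3))
  img[1, 1, 1] <- 10; img[2, 2, 2] <- 20; img[3, 3, 3] <- 60
  msk[1, 1, 1] <- 1L; msk[2, 2, 2] <- 1L; msk[3, 3, 3] <- 1L
  small <- phantom_volume(img, msk)
  res <- masked_mean(small, 1L)
  expect_equal(res$mean_hu, 30)
  expect_equal(res$n_voxels, 3L)

  expect_error(masked_mean(small, 2L), "label 2")
})

test_that("masked mean on cropped noisy phantoms equals the voxel-loop oracle", {
  vol <- uniform_phantom(texture_sd = 8, crop_fraction = 0.4, seed = 5)
  for (label in 1:2) {
    expect_equal(masked_mean(vol, label)$mean_hu, oracle_masked_mean(vol, label),
                 tolerance = 1e-12)
  }
})

test_that("masked and ROI means agree with brute-force oracles on random grids", {
  for (s in 1:100) {
    vol <- random_test_volume(s)
    for (label in 0:2) {
      if (any(vol$mask == label)) {
        expect_equal(masked_mean(vol, label)$mean_hu,
                     oracle_masked_mean(vol, label), tolerance = 1e-12)
      }
    }
    # one random in-bounds ROI per grid
    d <- dim(vol$image)
    r_mm <- max(vol$spacing[1:2]) * 1.5
    roi <- roi_spec(c(runif(1, 3.5, d[1] - 2.5), runif(1, 3.5, d[2] - 2.5),
                      sample(d[3], 1)), r_mm)
    expect_equal(roi_mean(vol, list(roi))$mean_hu,
                 oracle_roi_mean(vol, list(roi)), tolerance = 1e-12)
  }
})

test_that("masked mean ignores other labels and the background value", {
  vol <- uniform_phantom(texture_sd = 8, seed = 9)
  base <- masked_mean(vol, 1L)

  relabeled <- vol
  relabeled$mask[relabeled$mask == 2L] <- 0L      # drop the spleen label
  relabeled$image[relabeled$mask == 0L] <- 3000   # rewrite background
  expect_equal(masked_mean(relabeled, 1L), base)
})

test_that("ROI means pool pixels across ROIs rather than averaging per-ROI means", {
  # two uniform patches with different disc sizes: pooled mean is
  # count-weighted, not the midpoint of the per-ROI means
  img <- array(40, c(60, 60, 3))
  img[31:60, , ] <- 60
  vol <- phantom_volume(img, array(0L, dim(img)))
  roi_small <- roi_spec(c(15, 30, 2), 3)
  roi_big <- roi_spec(c(45, 30, 2), 9)

  m_small <- roi_mean(vol, list(roi_small))
  m_big <- roi_mean(vol, list(roi_big))
  expect_equal(m_small$mean_hu, 40)
  expect_equal(m_big$mean_hu, 60)

  pooled <- roi_mean(vol, list(roi_small, roi_big))
  n1 <- m_small$n_pixels; n2 <- m_big$n_pixels
  expect_gt(n2, n1)
  expect_equal(pooled$mean_hu, (40 * n1 + 60 * n2) / (n1 + n2))
  expect_equal(pooled$n_pixels, n1 + n2)
  # pooled mean sits between the per-ROI means, away from the midpoint
  expect_gt(pooled$mean_hu, 50)
  expect_lt(pooled$mean_hu, 60)
})

test_that("multi-ROI pooled means match the pixel-loop oracle on noisy phantoms", {
  vol <- uniform_phantom(texture_sd = 10, seed = 13)
  # eight liver discs on two slices, echoing the manual placement convention
  rois <- c(
    lapply(c(10, 14, 18, 22), function(x) roi_spec(c(x, 17, 12), 2.5)),
    lapply(c(10, 14, 18, 22), function(x) roi_spec(c(x, 23, 18), 2.5))
  )
  res <- roi_mean(vol, rois)
  expect_equal(res$mean_hu, oracle_roi_mean(vol, rois), tolerance = 1e-9)

  per_roi <- vapply(rois, function(r) roi_mean(vol, list(r))$mean_hu, numeric(1))
  expect_gte(res$mean_hu, min(per_roi))
  expect_lte(res$mean_hu, max(per_roi))
})

test_that("out-of-bounds ROIs are rejected with their index", {
  vol <- uniform_phantom()
  good <- roi_spec(c(14, 20, 15), 3)
  bad <- roi_spec(c(39, 39, 15), 5)
  expect_error(roi_mean(vol, list(good, bad)), "ROI 2")
})

test_that("attenuation records derive difference and ratio with a spleen guard", {
  rec <- derive_record("S1", "non-contrast", 42.8, 34.2)
  expect_equal(rec$liver_minus_spleen, 8.6)
  expect_equal(rec$liver_spleen_ratio, 42.8 / 34.2)
  expect_equal(round(rec$liver_spleen_ratio, 4), 1.2515)

  rec2 <- derive_record("S2", "venous", 50, 50)
  expect_equal(rec2$liver_minus_spleen, 0)
  expect_equal(rec2$liver_spleen_ratio, 1)

  expect_warning(rec3 <- derive_record("S3", "arterial", 30, 0), "undefined")
  expect_true(is.na(rec3$liver_spleen_ratio))
  expect_equal(rec3$liver_minus_spleen, 30)
})

test_that("phantom volumes round-trip through NIfTI with sidecar labels", {
  vol <- uniform_phantom(texture_sd = 5, seed = 21)
  img_path <- withr::local_tempfile(fileext = ".nii")
  msk_path <- withr::local_tempfile(fileext = ".nii")
  paths <- write_phantom_nifti(vol, img_path, msk_path)

  back <- read_phantom_nifti(img_path, msk_path)
  expect_equal(back$image, vol$image, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(as.integer(back$mask), as.integer(vol$mask))
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6, ignore_attr = TRUE)

  sidecar <- jsonlite::read_json(paths[["sidecar"]])
  expect_equal(sidecar$labels$`1`, "liver")
})
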