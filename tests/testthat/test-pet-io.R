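test_that("NIfTI round trip preserves voxels, spacing and mask binarization", {
  cfg <- cohort_config(grid_voxels = 24)
  p <- simulate_patient("relapse", scanner_profiles("discovery_mi"),
                        rng_seed = 5, config = cfg, patient_id = "rt")
  dir <- withr::local_tempdir()
  paths <- list(pet = file.path(dir, "pet.nii.gz"),
                ct = file.path(dir, "ct.nii.gz"),
                mask = file.path(dir, "mask.nii.gz"))
  write_patient(p$volume, paths)
  back <- read_patient(paths, "rt")
  expect_equal(back$pet, p$volume$pet, tolerance = 1e-6)
  expect_equal(back$ct, p$volume$ct, tolerance = 1e-6)
  expect_identical(back$mask, p$volume$mask)
  expect_equal(back$spacing, p$volume$spacing, tolerance = 1e-5)

  # a {0, 255}-valued mask binarizes to {0, 1}
  m255 <- RNifti::asNifti(array(c(0, 255)[p$volume$mask + 1],
                                dim(p$volume$mask)))
  RNifti::pixdim(m255) <- p$volume$spacing
  RNifti::writeNifti(m255, paths$mask)
  back2 <- read_patient(paths, "rt")
  expect_identical(sort(unique(as.vector(back2$mask))), c(0L, 1L))
  expect_identical(back2$mask, p$volume$mask)
})

test_that("mismatching grids are rejected with the offending pair named", {
  expect_error(
    patient_volume(array(0, c(4, 4, 4)), array(0, c(5, 4, 4)),
                   array(0, c(4, 4, 4)), c(1, 1, 1)),
    "shape mismatch.*CT")
  expect_error(
    patient_volume(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                   array(0, c(4, 4, 5)), c(1, 1, 1)),
    "shape mismatch.*mask")
})

test_that("PET metrics match hand computations", {
  # SUVs {2, 4, 6} at 1 mL voxels, 41% threshold: cutoff 2.46 keeps {4, 6}
  m <- compute_pet_metrics(toy_volume(c(2, 4, 6)), 0.41)
  expect_equal(m$suv_max, 6)
  expect_equal(m$mtv_ml, 2)
  expect_equal(m$suv_mean, 5)
  expect_equal(m$tlg, 10)

  # uniform SUV 5 over 8 voxels of 0.5 mL
  pet <- array(5, c(2, 2, 2)); mask <- array(1L, c(2, 2, 2))
  v <- patient_volume(pet, pet * 0, mask, c(10, 10, 5))
  for (frac in c(0.2, 0.41, 1)) {
    mu <- compute_pet_metrics(v, frac)
    expect_equal(mu$suv_max, 5)
    expect_equal(mu$mtv_ml, 4)
    expect_equal(mu$suv_mean, 5)
    expect_equal(mu$tlg, 20)
  }

  # threshold 0 keeps the full mask
  m0 <- compute_pet_metrics(toy_volume(c(2, 4, 6)), 0)
  expect_equal(m0$mtv_ml, 3)
  expect_equal(m0$suv_mean, 4)

  expect_error(compute_pet_metrics(
    patient_volume(pet, pet * 0, mask * 0L, c(10, 10, 5))), "empty")
})

test_that("PET metrics are permutation invariant and MTV monotone", {
  set.seed(8)
  vals <- runif(20, 1, 12)
  v1 <- toy_vals <- function(vv) {
    pet <- array(0, c(20, 2, 2)); mask <- array(0L, c(20, 2, 2))
    pet[1:20, 1, 1] <- vv; mask[1:20, 1, 1] <- 1L
    patient_volume(pet, pet * 0, mask, c(10, 10, 10))
  }
  m_a <- compute_pet_metrics(toy_vals(vals), 0.41)
  m_b <- compute_pet_metrics(toy_vals(sample(vals)), 0.41)
  expect_equal(m_a$suv_max, m_b$suv_max)
  expect_equal(m_a$mtv_ml, m_b$mtv_ml)
  expect_equal(m_a$tlg, m_b$tlg)

  fracs <- seq(0, 1, by = 0.1)
  mtvs <- vapply(fracs,
                 function(f) compute_pet_metrics(toy_vals(vals), f)$mtv_ml,
                 numeric(1))
  expect_true(all(diff(mtvs) <= 0))
  # tlg = suv_mean * mtv by construction
  m <- compute_pet_metrics(toy_vals(vals), 0.41)
  expect_equal(m$tlg, m$suv_mean * m$mtv_ml, tolerance = 1e-12)
})

test_that("ROI cropping centres the lesion and is exact on constants", {
  cfg <- cohort_config(grid_voxels = 24)
  p <- simulate_patient("nonrelapse", scanner_profiles("discovery_mi"),
                        rng_seed = 9, config = cfg)
  v <- p$volume
  # constant PET: resampling must reproduce the constant exactly in-grid
  vc <- patient_volume(array(3, dim(v$pet)), v$ct, v$mask, v$spacing)
  roi <- crop_resample(vc, side_mm = 40, out_voxels = 8)
  expect_true(all(abs(roi$data[1, , , ][roi$in_grid] - 3) < 1e-12))

  # a bright voxel at the mask centroid lands at the tensor centre
  idx <- which(v$mask > 0, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  vpk <- v
  vpk$pet[ctr[1], ctr[2], ctr[3]] <- 1e4
  roi2 <- crop_resample(patient_volume(vpk$pet, v$ct, v$mask, v$spacing),
                        side_mm = 40, out_voxels = 16)
  pk <- which(roi2$data[1, , , ] == max(roi2$data[1, , , ]),
              arr.ind = TRUE)[1, ]
  expect_true(all(abs(pk - (16 + 1) / 2) <= 1.6))
})

test_that("resampling matches a pointwise trilinear oracle with padding", {
  set.seed(21)
  vol <- array(runif(12^3), c(12, 12, 12))
  mask <- array(0L, c(12, 12, 12)); mask[6:8, 6:8, 6:8] <- 1L
  v <- patient_volume(vol, vol * 0.5, mask, c(2, 2, 2))
  n <- 10; side <- 60          # window extends far outside the 24 mm grid
  roi <- crop_resample(v, side_mm = side, out_voxels = n)

  centroid <- colMeans(which(mask > 0, arr.ind = TRUE) - 1)
  off <- (seq_len(n) - 1 - (n - 1) / 2) * side / n
  expect_false(all(roi$in_grid))
  expect_true(all(roi$data[1, , , ][!roi$in_grid] == 0))

  pts_checked <- 0
  set.seed(4)
  while (pts_checked < 10) {
    ijk <- sample(n, 3, replace = TRUE)
    p <- centroid + off[ijk] / 2       # voxel coords (spacing 2 mm)
    if (any(p < 0) || any(p > 11)) next
    expect_equal(roi$data[1, ijk[1], ijk[2], ijk[3]],
                 trilinear_oracle(vol, p), tolerance = 1e-6)
    pts_checked <- pts_checked + 1
  }
})

test_that("cropping is invariant to integer-voxel translation of the grid", {
  set.seed(31)
  vol <- array(runif(16^3), c(16, 16, 16))
  mask <- array(0L, c(16, 16, 16)); mask[7:9, 7:9, 7:9] <- 1L
  v1 <- patient_volume(vol, vol, mask, c(3, 3, 3))
  sh <- 2
  vol2 <- array(0, c(16, 16, 16)); mask2 <- array(0L, c(16, 16, 16))
  vol2[(1 + sh):16, , ] <- vol[1:(16 - sh), , ]
  mask2[(1 + sh):16, , ] <- mask[1:(16 - sh), , ]
  v2 <- patient_volume(vol2, vol2, mask2, c(3, 3, 3))
  r1 <- crop_resample(v1, side_mm = 24, out_voxels = 8)
  r2 <- crop_resample(v2, side_mm = 24, out_voxels = 8)
  expect_equal(r1$data, r2$data, tolerance = 1e-9)
})
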