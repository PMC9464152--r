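make_partition <- function(intens, roi_mask_arr, imat_arr) {
  vol <- ff_volume(intens, voxel_size_mm = c(1, 1, 3))
  roi <- roi_mask(roi_mask_arr, "fascia_lata")
  list(
    vol = vol, roi = roi,
    imat = roi_mask(imat_arr, "fascia_lata_imat"),
    mt = roi_mask(roi_mask_arr & !imat_arr, "fascia_lata_mt")
  )
}

test_that("volumes, fat fractions and ratios follow the voxel arithmetic", {
  # 1000 ROI voxels of 1x1x3 mm^3, 100 of them IMAT
  d <- c(10, 10, 10)
  roi_arr <- array(TRUE, dim = d)
  imat_arr <- array(FALSE, dim = d)
  imat_arr[seq_len(100)] <- TRUE
  intens <- array(40, dim = d)    # MT voxels at 40 per-mille
  intens[imat_arr] <- 900
  p <- make_partition(intens, roi_arr, imat_arr)
  q <- quantify_compartment(p$vol, p$roi, p$imat, p$mt)
  expect_equal(q$roi_volume_cm3, 3.0)
  expect_equal(q$imat_volume_cm3, 0.3)
  expect_equal(q$mt_volume_cm3, 2.7)
  expect_equal(q$imat_over_roi, 0.1)
  expect_equal(q$mt_ff_pct, 4.0)
  expect_equal(q$imat_volume_cm3 + q$mt_volume_cm3, q$roi_volume_cm3)
  expect_equal(q$imat_over_roi + q$mt_over_roi, 1)
})

test_that("empty MT mask reports missing fat fraction, not zero", {
  d <- c(4, 4, 1)
  roi_arr <- array(TRUE, dim = d)
  p <- make_partition(array(900, dim = d), roi_arr, roi_arr)
  q <- quantify_compartment(p$vol, p$roi, p$imat, p$mt)
  expect_true(is.na(q$mt_ff_pct))
  expect_true(is.na(q$imat_over_mt))
  expect_equal(q$imat_over_roi, 1)
})

test_that("non-partitioning masks are rejected", {
  d <- c(4, 4, 1)
  roi_arr <- array(TRUE, dim = d)
  imat_arr <- array(FALSE, dim = d); imat_arr[1] <- TRUE
  p <- make_partition(array(0, dim = d), roi_arr, imat_arr)
  # overlap
  bad_mt <- roi_mask(roi_arr, "mt")
  expect_error(quantify_compartment(p$vol, p$roi, p$imat, bad_mt), "partition")
})

test_that("phantom quantities match the per-voxel summation oracle", {
  ph <- generate_ff_phantom(phantom_spec(grid_shape = c(24, 24, 3), seed = 13))
  roi <- ph$roi_masks$fascia_lata
  seg <- segment_roi(ph$volume, roi)
  q <- quantify_compartment(ph$volume, roi, seg$imat, seg$mt)
  want <- brute_quantify(ph$volume$intensities, roi$mask, seg$imat$mask,
                         ph$volume$voxel_size_mm)
  expect_equal(q$roi_volume_cm3, want$roi_volume, tolerance = 1e-12)
  expect_equal(q$imat_volume_cm3, want$imat_volume, tolerance = 1e-12)
  expect_equal(q$mt_volume_cm3, want$mt_volume, tolerance = 1e-12)
  expect_equal(q$roi_ff_pct, want$roi_ff, tolerance = 1e-12)
  expect_equal(q$mt_ff_pct, want$mt_ff, tolerance = 1e-12)
})

test_that("scaling the voxel volume scales volumes and leaves ratios and FF alone", {
  d <- c(6, 6, 2)
  roi_arr <- array(TRUE, dim = d)
  imat_arr <- array(runif(prod(d)) < 0.2, dim = d)
  intens <- array(sample(0:1000, prod(d), TRUE), dim = d)
  q1 <- {
    p <- make_partition(intens, roi_arr, imat_arr)
    quantify_compartment(p$vol, p$roi, p$imat, p$mt)
  }
  vol2 <- ff_volume(intens, voxel_size_mm = c(1, 1, 6))  # doubled voxel volume
  p2 <- make_partition(intens, roi_arr, imat_arr)
  q2 <- quantify_compartment(vol2, p2$roi, p2$imat, p2$mt)
  expect_equal(q2$roi_volume_cm3, 2 * q1$roi_volume_cm3)
  expect_equal(q2$imat_volume_cm3, 2 * q1$imat_volume_cm3)
  expect_equal(q2$imat_over_roi, q1$imat_over_roi)
  expect_equal(q2$roi_ff_pct, q1$roi_ff_pct)
  expect_equal(q2$mt_ff_pct, q1$mt_ff_pct)
})

test_that("bilateral averaging matches symmetry, arithmetic and the pooled oracle", {
  ph <- generate_ff_phantom(phantom_spec(
    grid_shape = c(48, 48, 1), roi_geometry = "spine", imat_fraction = 0.15,
    seed = 21
  ))
  qs <- lapply(ph$roi_masks[c("psoas_left", "psoas_right")], function(roi) {
    seg <- segment_roi(ph$volume, roi, fallback_threshold_pct = 40)
    quantify_compartment(ph$volume, roi, seg$imat, seg$mt)
  })
  # symmetry: averaging a side with itself is the identity on shared columns
  same <- average_bilateral(qs[[1]], qs[[1]])
  expect_equal(same$imat_volume_cm3, qs[[1]]$imat_volume_cm3)
  expect_equal(same$mt_ff_pct, qs[[1]]$mt_ff_pct)
  expect_equal(same$site, "psoas")

  avg <- average_bilateral(qs[[1]], qs[[2]])
  expect_equal(avg$imat_volume_cm3,
               (qs[[1]]$imat_volume_cm3 + qs[[2]]$imat_volume_cm3) / 2)
  # volume-weighted MT FF equals recomputation from the pooled MT voxels
  pooled_ff <- (qs[[1]]$mt_ff_pct * qs[[1]]$mt_volume_cm3 +
                qs[[2]]$mt_ff_pct * qs[[2]]$mt_volume_cm3) /
               (qs[[1]]$mt_volume_cm3 + qs[[2]]$mt_volume_cm3)
  expect_equal(avg$mt_ff_pct_weighted, pooled_ff, tolerance = 1e-12)
  # ratios recomputed from averaged volumes
  expect_equal(avg$imat_over_roi, avg$imat_volume_cm3 / avg$roi_volume_cm3)

  expect_error(
    average_bilateral(
      dplyr::mutate(qs[[1]], site = "psoas_left"),
      dplyr::mutate(qs[[2]], site = "erector_right")
    ),
    "mismatch"
  )
})

test_that("simple left/right example averages volumes arithmetically", {
  l <- tibble::tibble(
    site = "erector_left", n_voxels = 10L, roi_volume_cm3 = 4,
    imat_volume_cm3 = 1.0, mt_volume_cm3 = 3.0, roi_ff_pct = 20,
    mt_ff_pct = 4, imat_over_roi = 0.25, mt_over_roi = 0.75,
    imat_over_mt = 1 / 3, single_slice = TRUE
  )
  r <- dplyr::mutate(l, site = "erector_right", imat_volume_cm3 = 2.0,
                     mt_volume_cm3 = 2.0, roi_ff_pct = 40, mt_ff_pct = 6)
  avg <- average_bilateral(l, r)
  expect_equal(avg$imat_volume_cm3, 1.5)
  expect_equal(avg$mt_ff_pct, 5)        # unweighted mean is primary
  expect_equal(avg$site, "erector")
})

test_that("normalization divides by covariates and respects missingness", {
  rec <- tibble::tibble(
    imat_volume_cm3 = c(67.2, 10), mt_ff_pct = c(4, 5),
    bmi = c(23.2, NA), asmm = c(67.2, 25)
  )
  out <- normalize_record(rec)
  expect_equal(out$imat_over_bmi[1], 67.2 / 23.2)
  expect_equal(out$imat_over_asmm[1], 1)         # asmm equals imat numerically
  expect_equal(out$mtff_over_bmi[1], 4 / 23.2)
  expect_true(is.na(out$imat_over_bmi[2]))       # missing covariate propagates
  expect_equal(out$imat_volume_cm3[2], 10)       # raw columns untouched
  # presentation scale factors are applied multiplicatively
  scaled <- normalize_record(rec, scale_factors = list(imat_over_bmi = 10))
  expect_equal(scaled$imat_over_bmi[1], 10 * 67.2 / 23.2)
  expect_error(normalize_record(dplyr::mutate(rec, bmi = -1)), "positive")
})
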