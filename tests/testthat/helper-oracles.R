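# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths.

# Naive per-voxel classification loop.
brute_classify <- function(intensities, mask, threshold_ff) {
  d <- dim(intensities)
  imat <- array(FALSE, dim = d)
  mt <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) {
      if (intensities[i, j, k] / 10 >= threshold_ff) {
        imat[i, j, k] <- TRUE
      } else {
        mt[i, j, k] <- TRUE
      }
    }
  }
  list(imat = imat, mt = mt)
}

# Per-voxel summation of compartment quantities.
brute_quantify <- function(intensities, mask, imat, voxel_size_mm) {
  vox_cm3 <- prod(voxel_size_mm) / 1000
  ff <- intensities / 10
  roi_ff <- ff[mask]
  mt_mask <- mask & !imat
  list(
    roi_volume = sum(mask) * vox_cm3,
    imat_volume = sum(imat) * vox_cm3,
    mt_volume = sum(mt_mask) * vox_cm3,
    roi_ff = sum(roi_ff) / length(roi_ff),
    mt_ff = if (any(mt_mask)) sum(ff[mt_mask]) / sum(mt_mask) else NA_real_
  )
}

# Small random FF volume + ROI for property tests.
random_case <- function(dim3 = c(6, 5, 4)) {
  intens <- array(sample(0:1000, prod(dim3), replace = TRUE), dim = dim3)
  mask <- array(runif(prod(dim3)) < 0.6, dim = dim3)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  list(
    volume = ff_volume(intens, voxel_size_mm = c(1, 1, 3)),
    roi = roi_mask(mask, "custom")
  )
}

# Two-spike fixture: n1 voxels at muscle_pct, n2 at fat_pct.
spike_volume <- function(n1 = 100, n2 = 50, muscle_pct = 4, fat_pct = 85) {
  vals <- c(rep(muscle_pct * 10, n1), rep(fat_pct * 10, n2))
  n <- length(vals)
  side <- ceiling(sqrt(n))
  intens <- array(0, dim = c(side, side, 1))
  mask <- array(FALSE, dim = c(side, side, 1))
  intens[seq_len(n)] <- vals
  mask[seq_len(n)] <- TRUE
  list(
    volume = ff_volume(intens),
    roi = roi_mask(mask, "fascia_lata")
  )
}
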