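#' Classify ROI voxels into IMAT and muscle tissue
#'
#' Applies the fat-fraction threshold within the ROI: voxels with FF at or
#' above the threshold are intermuscular adipose tissue (IMAT), voxels
#' below it are muscle tissue (MT). The two output masks partition the ROI
#' exactly. Voxels exactly at the threshold count as IMAT.
#'
#' @param volume An [ff_volume()].
#' @param roi An [roi_mask()] congruent with `volume`.
#' @param threshold_ff Classification threshold in FF % (0--100), usually
#'   `hist$threshold_ff` from [compute_threshold()].
#' @return A list with [roi_mask()] elements `imat` and `mt`.
#' @examples
#' vol <- ff_volume(array(c(40, 40, 850, 40), dim = c(2, 2, 1)))
#' roi <- roi_mask(array(TRUE, dim = c(2, 2, 1)), "fascia_lata")
#' m <- classify_voxels(vol, roi, threshold_ff = 20)
#' sum(m$imat$mask)
#' @export
classify_voxels <- function(volume, roi, threshold_ff) {
  stopifnot(inherits(volume, "ff_volume"), inherits(roi, "roi_mask"))
  check_congruent(volume, roi)
  if (!is.numeric(threshold_ff) || length(threshold_ff) != 1 ||
      is.na(threshold_ff) || threshold_ff < 0 || threshold_ff > 100) {
    abort("`threshold_ff` must be a single FF percentage in [0, 100].")
  }
  ff_pct <- volume$intensities / 10
  imat <- roi$mask & (ff_pct >= threshold_ff)
  mt <- roi$mask & !imat
  list(
    imat = roi_mask(imat, name = paste0(roi$name, "_imat")),
    mt = roi_mask(mt, name = paste0(roi$name, "_mt"))
  )
}

#' Segment one ROI end to end
#'
#' Convenience chain: histogram, mode/minimum detection, threshold,
#' classification. Equivalent to calling [build_ff_histogram()],
#' [detect_modes_and_minimum()], [compute_threshold()] and
#' [classify_voxels()] in sequence.
#'
#' @inheritParams build_ff_histogram
#' @inheritParams detect_modes_and_minimum
#' @inheritParams compute_threshold
#' @return A list with elements `histogram` (the finalised `ff_histogram`),
#'   `imat` and `mt` masks.
#' @export
segment_roi <- function(volume, roi, bin_width_pct = 1, smoothing_window = 5L,
                        fraction_below = 0.5, fallback_threshold_pct = NULL,
                        tie_break = "midpoint") {
  h <- build_ff_histogram(volume, roi, bin_width_pct = bin_width_pct)
  h <- detect_modes_and_minimum(h, smoothing_window = smoothing_window,
                                tie_break = tie_break)
  h <- compute_threshold(h, fraction_below = fraction_below,
                         fallback_threshold_pct = fallback_threshold_pct)
  masks <- classify_voxels(volume, roi, h$threshold_ff)
  list(histogram = h, imat = masks$imat, mt = masks$mt)
}

#' Dice overlap between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [roi_mask()] objects (or logical arrays) on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  stopifnot(identical(dim(ma), dim(mb)))
  denom <- sum(ma) + sum(mb)
  if (denom == 0) return(1)
  2 * sum(ma & mb) / denom
}
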