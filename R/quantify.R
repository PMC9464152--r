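#' Quantify a segmented muscle compartment
#'
#' Turns an ROI and its IMAT/MT partition into the standard myosteatosis
#' measurands: compartment volumes (cm^3), mean fat fractions (%), and the
#' volume ratios IMAT/ROI, MT/ROI and IMAT/MT. Volumes are voxel count
#' times voxel volume; fat fractions convert the per-mille intensities to
#' percent. For a single-slice acquisition the "volume" is the one-slice
#' volume (area times slice thickness) and `single_slice` is `TRUE`.
#'
#' @param volume An [ff_volume()].
#' @param roi The compartment [roi_mask()].
#' @param imat_mask,mt_mask Classification masks from [classify_voxels()];
#'   they must partition `roi` exactly (checked).
#' @return One-row tibble with columns `site`, `n_voxels`,
#'   `roi_volume_cm3`, `imat_volume_cm3`, `mt_volume_cm3`, `roi_ff_pct`,
#'   `mt_ff_pct` (`NA` when the MT mask is empty, not 0), `imat_over_roi`,
#'   `mt_over_roi`, `imat_over_mt` (`NA` when MT is empty) and
#'   `single_slice`.
#' @examples
#' vol <- ff_volume(array(c(rep(40, 3), 850), dim = c(2, 2, 1)))
#' roi <- roi_mask(array(TRUE, dim = c(2, 2, 1)), "fascia_lata")
#' m <- classify_voxels(vol, roi, 20)
#' quantify_compartment(vol, roi, m$imat, m$mt)
#' @export
quantify_compartment <- function(volume, roi, imat_mask, mt_mask) {
  stopifnot(
    inherits(volume, "ff_volume"), inherits(roi, "roi_mask"),
    inherits(imat_mask, "roi_mask"), inherits(mt_mask, "roi_mask")
  )
  check_congruent(volume, roi)
  if (!any(roi$mask)) abort(sprintf("ROI '%s' is empty.", roi$name))
  if (any(imat_mask$mask & mt_mask$mask) ||
      !identical(imat_mask$mask | mt_mask$mask, roi$mask)) {
    abort("`imat_mask` and `mt_mask` must partition the ROI exactly.")
  }
  voxel_cm3 <- prod(volume$voxel_size_mm) / 1000
  n_roi <- sum(roi$mask)
  n_imat <- sum(imat_mask$mask)
  n_mt <- n_roi - n_imat
  ff <- volume$intensities / 10
  mt_ff <- if (n_mt > 0) mean(ff[mt_mask$mask]) else NA_real_
  tibble(
    site = roi$name,
    n_voxels = n_roi,
    roi_volume_cm3 = n_roi * voxel_cm3,
    imat_volume_cm3 = n_imat * voxel_cm3,
    mt_volume_cm3 = n_mt * voxel_cm3,
    roi_ff_pct = mean(ff[roi$mask]),
    mt_ff_pct = mt_ff,
    imat_over_roi = n_imat / n_roi,
    mt_over_roi = n_mt / n_roi,
    imat_over_mt = if (n_mt > 0) n_imat / n_mt else NA_real_,
    single_slice = dim(volume$intensities)[3] == 1L
  )
}

#' Average left and right compartments of a bilateral muscle
#'
#' Paraspinal results are reported as the average of the left and right
#' muscle. Volumes are averaged arithmetically and the ratios are
#' recomputed from the averaged volumes. For fat fractions the unweighted
#' mean of the two sides is the primary value (`roi_ff_pct`, `mt_ff_pct`);
#' the volume-weighted mean, identical to pooling the voxels of both
#' sides, is reported alongside (`*_ff_pct_weighted`).
#'
#' @param left,right One-row tibbles from [quantify_compartment()]. Their
#'   `site` labels must agree after stripping a `_left`/`_right` suffix.
#' @return One-row tibble like [quantify_compartment()]'s, with the common
#'   site name and additional `roi_ff_pct_weighted` / `mt_ff_pct_weighted`
#'   columns.
#' @export
average_bilateral <- function(left, right) {
  strip_side <- function(s) sub("_(left|right)$", "", s)
  site_l <- strip_side(left$site)
  site_r <- strip_side(right$site)
  if (!identical(site_l, site_r)) {
    abort(sprintf(
      "Site mismatch: '%s' vs '%s' are not two sides of one muscle.",
      left$site, right$site
    ))
  }
  wmean <- function(x, w) {
    if (anyNA(x) || sum(w) == 0) NA_real_ else sum(x * w) / sum(w)
  }
  roi_v <- (left$roi_volume_cm3 + right$roi_volume_cm3) / 2
  imat_v <- (left$imat_volume_cm3 + right$imat_volume_cm3) / 2
  mt_v <- (left$mt_volume_cm3 + right$mt_volume_cm3) / 2
  tibble(
    site = site_l,
    n_voxels = left$n_voxels + right$n_voxels,
    roi_volume_cm3 = roi_v,
    imat_volume_cm3 = imat_v,
    mt_volume_cm3 = mt_v,
    roi_ff_pct = (left$roi_ff_pct + right$roi_ff_pct) / 2,
    mt_ff_pct = (left$mt_ff_pct + right$mt_ff_pct) / 2,
    roi_ff_pct_weighted = wmean(
      c(left$roi_ff_pct, right$roi_ff_pct),
      c(left$roi_volume_cm3, right$roi_volume_cm3)
    ),
    mt_ff_pct_weighted = wmean(
      c(left$mt_ff_pct, right$mt_ff_pct),
      c(left$mt_volume_cm3, right$mt_volume_cm3)
    ),
    imat_over_roi = imat_v / roi_v,
    mt_over_roi = mt_v / roi_v,
    imat_over_mt = if (mt_v > 0) imat_v / mt_v else NA_real_,
    single_slice = left$single_slice || right$single_slice
  )
}

#' Normalize IMAT volume and muscle fat fraction by body composition
#'
#' Adds the four body-composition-normalized measures to a table of
#' subject records: IMAT volume and MT fat fraction, each divided by BMI
#' (kg/m^2) and by appendicular skeletal muscle mass (ASMM, kg). These
#' normalizations make cross-sectional age trends comparable across body
#' sizes. Rows with a missing covariate get `NA` in the corresponding
#' normalized columns; nothing else is touched.
#'
#' The published axes for the BMI-normalized variables carry presentation
#' scale factors (10^4 for volume/BMI in cm^5/kg, 10^2 for FF/BMI in
#' cm^2/kg); numerically those axes equal the plain quotients computed
#' here, so the default `scale_factors` are all 1 and the factors live in
#' the unit strings.
#'
#' @param records Data frame with columns `imat_volume_cm3`, `mt_ff_pct`
#'   and the covariates `bmi` and/or `asmm`.
#' @param scale_factors Named list of multipliers applied to the quotients
#'   (`imat_over_bmi`, `imat_over_asmm`, `mtff_over_bmi`, `mtff_over_asmm`).
#' @return `records` with the four normalized columns added.
#' @export
normalize_record <- function(records,
                             scale_factors = list(
                               imat_over_bmi = 1, imat_over_asmm = 1,
                               mtff_over_bmi = 1, mtff_over_asmm = 1
                             )) {
  stopifnot(is.data.frame(records))
  need <- c("imat_volume_cm3", "mt_ff_pct")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` lacks column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  bmi <- if ("bmi" %in% names(records)) records$bmi else NA_real_
  asmm <- if ("asmm" %in% names(records)) records$asmm else NA_real_
  if (any(!is.na(bmi) & bmi <= 0) || any(!is.na(asmm) & asmm <= 0)) {
    abort("`bmi` and `asmm` must be positive where present.")
  }
  sf <- utils::modifyList(
    list(imat_over_bmi = 1, imat_over_asmm = 1,
         mtff_over_bmi = 1, mtff_over_asmm = 1),
    scale_factors
  )
  dplyr::mutate(
    as_tibble(records),
    imat_over_bmi = .data$imat_volume_cm3 / bmi * sf$imat_over_bmi,
    imat_over_asmm = .data$imat_volume_cm3 / asmm * sf$imat_over_asmm,
    mtff_over_bmi = .data$mt_ff_pct / bmi * sf$mtff_over_bmi,
    mtff_over_asmm = .data$mt_ff_pct / asmm * sf$mtff_over_asmm
  )
}
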