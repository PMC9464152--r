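#' Fat-fraction image volume
#'
#' Container for a Dixon fat-fraction (FF) image. Intensities are stored
#' per-mille: integer values in \[0, 1000\] encode FF 0--100%, the native
#' scale of quantitative Dixon reconstructions. A single-slice acquisition
#' (e.g. one axial slice at vertebral level L2) is represented as a volume
#' of depth 1.
#'
#' @param intensities Numeric 3D array (or a matrix, promoted to depth 1)
#'   of per-mille fat-fraction values in \[0, 1000\].
#' @param voxel_size_mm Positive numeric vector of length 3: voxel spacing
#'   in mm along each array dimension.
#' @return An object of class `ff_volume`: a list with elements
#'   `intensities`, `voxel_size_mm` and `grid_shape`.
#' @examples
#' vol <- ff_volume(array(40, dim = c(4, 4, 2)), voxel_size_mm = c(1, 1, 3))
#' vol
#' @export
ff_volume <- function(intensities, voxel_size_mm = c(1, 1, 3)) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array (use depth 1 for a single slice).")
  }
  if (anyNA(intensities)) {
    abort("`intensities` must not contain missing values.")
  }
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 1000) {
    abort(sprintf(
      "FF intensities must lie in [0, 1000] per-mille; found range [%g, %g].",
      rng[1], rng[2]
    ))
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive spacings in mm.")
  }
  structure(
    list(
      intensities = intensities,
      voxel_size_mm = voxel_size_mm,
      grid_shape = dim(intensities)
    ),
    class = "ff_volume"
  )
}

#' @export
print.ff_volume <- function(x, ...) {
  cat(sprintf(
    "<ff_volume> %s voxels @ %s mm, FF %.1f-%.1f%%\n",
    paste(x$grid_shape, collapse = "x"),
    paste(format(x$voxel_size_mm, trim = TRUE), collapse = "x"),
    min(x$intensities) / 10, max(x$intensities) / 10
  ))
  invisible(x)
}

#' Region-of-interest mask
#'
#' A named binary mask on the same voxel grid as an [ff_volume()]. Typical
#' compartments are the fascia lata interior of the thigh and the left/right
#' psoas and erector spinae (the latter including multifidus) at L2.
#'
#' @param mask Logical (or 0/1 numeric) array congruent with the paired
#'   volume; a matrix is promoted to depth 1.
#' @param name Compartment label, e.g. `"fascia_lata"`, `"psoas_left"`,
#'   `"erector_right"`, or any custom label.
#' @return An object of class `roi_mask` with elements `name` and `mask`
#'   (logical array).
#' @examples
#' roi <- roi_mask(array(TRUE, dim = c(4, 4, 2)), name = "fascia_lata")
#' sum(roi$mask)
#' @export
roi_mask <- function(mask, name = "custom") {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("`mask` must be a 3D array (use depth 1 for a single slice).")
  }
  if (is.numeric(mask)) {
    vals <- unique(as.vector(mask))
    if (!all(vals %in% c(0, 1))) {
      abort(sprintf(
        "Mask '%s' is not binary: contains values other than 0/1 (%s).",
        name, paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", ")
      ))
    }
    mask <- array(mask == 1, dim = dim(mask))
  }
  if (!is.logical(mask) || anyNA(mask)) {
    abort(sprintf("Mask '%s' must be logical without missing values.", name))
  }
  structure(list(name = name, mask = mask), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf(
    "<roi_mask> '%s': %d of %d voxels set\n",
    x$name, sum(x$mask), length(x$mask)
  ))
  invisible(x)
}

# Stops unless mask grid matches the volume grid.
check_congruent <- function(volume, roi) {
  if (!identical(dim(volume$intensities), dim(roi$mask))) {
    abort(sprintf(
      "Grid mismatch: volume is %s but mask '%s' is %s.",
      paste(dim(volume$intensities), collapse = "x"),
      roi$name, paste(dim(roi$mask), collapse = "x")
    ))
  }
  invisible(TRUE)
}
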