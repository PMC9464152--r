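#' Read and write fat-fraction volumes and ROI masks as NIfTI
#'
#' Volumes are stored with their native per-mille intensities; voxel
#' spacing is taken from (written to) the NIfTI header. Intensities
#' outside \[0, 1000\] and non-binary masks are rejected on read.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return `read_ff_volume()` an [ff_volume()]; `read_roi_mask()` an
#'   [roi_mask()].
#' @export
read_ff_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  rng <- range(arr)
  if (rng[1] < 0 || rng[2] > 1000) {
    abort(sprintf(
      "'%s' has intensities in [%g, %g]; FF volumes must lie in [0, 1000].",
      path, rng[1], rng[2]
    ))
  }
  ff_volume(arr, voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_ff_volume
#' @param volume An [ff_volume()] to write.
#' @export
write_ff_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ff_volume"))
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_ff_volume
#' @param name Compartment label for the mask being read.
#' @export
read_roi_mask <- function(path, name = "custom") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  roi_mask(arr, name = name)
}

#' @rdname read_ff_volume
#' @param roi An [roi_mask()] to write (stored as 0/1 integers).
#' @param voxel_size_mm Spacing recorded in the mask header.
#' @export
write_roi_mask <- function(roi, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(roi, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(roi$mask), dim = dim(roi$mask)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation and trend stages with its
#' default. The configuration round-trips losslessly through JSON
#' ([write_config()] / [read_config()]).
#'
#' @param bin_width_pct Histogram bin width, FF percentage points.
#' @param smoothing_window_bins Moving-average window, bins.
#' @param threshold_fraction_below Fraction of the histogram-minimum FF
#'   subtracted to place the threshold (0.5 = threshold at half the
#'   minimum FF).
#' @param fallback_threshold_pct Absolute FF % threshold used when a
#'   histogram is not bimodal; `NULL` (default) makes that an error.
#' @param min_tie_break Tie rule for a flat histogram valley (see
#'   [detect_modes_and_minimum()]): `"midpoint"` (default), `"lowest"` or
#'   `"highest"`.
#' @param alpha Significance level for trend gating.
#' @param ref_age Reference age (years) for annual percent change.
#' @param scale_factors Presentation multipliers for the normalized
#'   measures (see [normalize_record()]).
#' @param site Analysis mode: `"thigh"` (one 3D fascia ROI) or
#'   `"spine_L2"` (bilateral single-slice psoas/erector ROIs, averaged).
#' @param seed Integer seed recorded in provenance and used for any
#'   stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bin_width_pct = 1,
                            smoothing_window_bins = 5L,
                            threshold_fraction_below = 0.5,
                            fallback_threshold_pct = NULL,
                            min_tie_break = c("midpoint", "lowest", "highest"),
                            alpha = 0.05,
                            ref_age = 20,
                            scale_factors = list(
                              imat_over_bmi = 1, imat_over_asmm = 1,
                              mtff_over_bmi = 1, mtff_over_asmm = 1
                            ),
                            site = c("thigh", "spine_L2"),
                            seed = 1L) {
  site <- match.arg(site)
  min_tie_break <- match.arg(min_tie_break)
  if (bin_width_pct <= 0 || bin_width_pct > 100) {
    abort("`bin_width_pct` must be in (0, 100].")
  }
  if (smoothing_window_bins < 1) abort("`smoothing_window_bins` must be >= 1.")
  if (threshold_fraction_below < 0 || threshold_fraction_below > 1) {
    abort("`threshold_fraction_below` must be in [0, 1].")
  }
  if (!is.null(fallback_threshold_pct) &&
      (fallback_threshold_pct < 0 || fallback_threshold_pct > 100)) {
    abort("`fallback_threshold_pct` must be in [0, 100].")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  structure(
    list(
      bin_width_pct = bin_width_pct,
      smoothing_window_bins = as.integer(smoothing_window_bins),
      threshold_fraction_below = threshold_fraction_below,
      fallback_threshold_pct = fallback_threshold_pct,
      min_tie_break = min_tie_break,
      alpha = alpha,
      ref_age = ref_age,
      scale_factors = scale_factors,
      site = site,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full quantification pipeline over a subject manifest
#'
#' For each subject: build the within-ROI FF histogram, detect the modes
#' and local minimum, derive the threshold, classify IMAT vs muscle
#' tissue, and quantify the compartment; in `spine_L2` mode the bilateral
#' psoas and erector compartments are segmented per side and averaged.
#' Body-composition normalizations are added where `bmi`/`asmm` are
#' present, and when at least three subjects survive with ages the linear
#' trend table is fitted across subjects.
#'
#' A subject whose segmentation fails (e.g. a unimodal histogram with no
#' configured fallback) is dropped with a message and counted in the
#' provenance; the cohort stage runs on the survivors.
#'
#' @param manifest Data frame, one row per subject, with `subject_id`,
#'   optionally `age`, `bmi`, `asmm`, and either list-columns `volume`
#'   ([ff_volume()]) and `rois` (named list of [roi_mask()]), or path
#'   columns `volume_path` and `roi_paths` (named list of NIfTI paths).
#' @param config A [pipeline_config()].
#' @return A list of class `imatq_results`: `results` (tibble, one row per
#'   subject x compartment), `trends` (tibble or `NULL`), `subject_errors`
#'   (named character), and `provenance` (config, config hash, counts,
#'   per-subject thresholds, package version).
#' @export
run_pipeline <- function(manifest, config = pipeline_config()) {
  stopifnot(is.data.frame(manifest), inherits(config, "pipeline_config"))
  if (nrow(manifest) == 0) abort("`manifest` is empty: nothing to analyze.")
  if (!"subject_id" %in% names(manifest)) {
    abort("`manifest` needs a `subject_id` column.")
  }

  load_subject <- function(row) {
    if ("volume" %in% names(row) && !is.null(row$volume[[1]])) {
      list(volume = row$volume[[1]], rois = row$rois[[1]])
    } else {
      vol <- read_ff_volume(row$volume_path)
      paths <- row$roi_paths[[1]]
      rois <- purrr::imap(paths, function(p, nm) read_roi_mask(p, name = nm))
      list(volume = vol, rois = rois)
    }
  }

  segment_one <- function(volume, roi) {
    segment_roi(
      volume, roi,
      bin_width_pct = config$bin_width_pct,
      smoothing_window = config$smoothing_window_bins,
      fraction_below = config$threshold_fraction_below,
      fallback_threshold_pct = config$fallback_threshold_pct,
      tie_break = config$min_tie_break
    )
  }

  process_subject <- function(row) {
    inp <- load_subject(row)
    segs <- purrr::imap(inp$rois, function(roi, nm) segment_one(inp$volume, roi))
    quants <- purrr::imap(segs, function(s, nm) {
      quantify_compartment(inp$volume, inp$rois[[nm]], s$imat, s$mt)
    })
    if (config$site == "spine_L2") {
      quants <- average_bilateral_pairs(quants)
    }
    q <- dplyr::bind_rows(quants)
    q$subject_id <- row$subject_id
    for (cov in c("age", "bmi", "asmm")) {
      q[[cov]] <- if (cov %in% names(row)) row[[cov]] else NA_real_
    }
    list(
      quant = q,
      thresholds = purrr::map_dbl(segs, function(s) s$histogram$threshold_ff)
    )
  }

  errors <- character(0)
  thresholds <- list()
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sid <- row$subject_id
    res <- tryCatch(process_subject(row), error = function(e) e)
    if (inherits(res, "error")) {
      errors[sid] <- conditionMessage(res)
      message(sprintf("Subject '%s' skipped: %s", sid, conditionMessage(res)))
    } else {
      rows[[sid]] <- res$quant
      thresholds[[sid]] <- res$thresholds
    }
  }
  if (length(rows) == 0) abort("Every subject failed; no results produced.")

  results <- dplyr::bind_rows(rows)
  results <- normalize_record(results, scale_factors = config$scale_factors)
  results <- dplyr::relocate(results, "subject_id")

  trends <- NULL
  n_aged <- length(unique(results$subject_id[!is.na(results$age)]))
  if ("age" %in% names(results) && n_aged >= 3) {
    trends <- results |>
      dplyr::group_by(.data$site) |>
      dplyr::group_modify(function(d, key) {
        measures <- intersect(
          c("roi_volume_cm3", "imat_volume_cm3", "mt_volume_cm3",
            "roi_ff_pct", "mt_ff_pct", "imat_over_roi", "mt_over_roi",
            "imat_over_mt", "imat_over_bmi", "imat_over_asmm",
            "mtff_over_bmi", "mtff_over_asmm"),
          names(d)[colSums(!is.na(d)) >= 3]
        )
        if (length(measures) == 0) return(tibble())
        build_trend_table(d, measures = measures, alpha = config$alpha,
                          ref_age = config$ref_age)
      }) |>
      dplyr::ungroup()
  }

  structure(
    list(
      results = results,
      trends = trends,
      subject_errors = errors,
      provenance = list(
        package = "imatq",
        version = as.character(utils::packageVersion("imatq")),
        config = unclass(config),
        config_hash = rlang::hash(unclass(config)),
        n_subjects_input = nrow(manifest),
        n_subjects_analyzed = length(rows),
        thresholds_ff_pct = thresholds
      )
    ),
    class = "imatq_results"
  )
}

# Collapse left/right compartments into bilateral averages; unpaired
# compartments pass through unchanged.
average_bilateral_pairs <- function(quants) {
  nms <- names(quants)
  base <- sub("_(left|right)$", "", nms)
  out <- list()
  for (b in unique(base)) {
    members <- quants[base == b]
    if (length(members) == 2L) {
      out[[b]] <- average_bilateral(members[[1]], members[[2]])
    } else {
      out[[b]] <- members[[1]]
    }
  }
  out
}

#' @export
print.imatq_results <- function(x, ...) {
  cat(sprintf(
    "<imatq_results> %d subjects analyzed (%d input), %d result rows\n",
    x$provenance$n_subjects_analyzed, x$provenance$n_subjects_input,
    nrow(x$results)
  ))
  if (!is.null(x$trends)) {
    cat(sprintf("  trend table: %d measure rows\n", nrow(x$trends)))
  }
  invisible(x)
}

#' Write a results bundle to disk
#'
#' One JSON per subject (compartment quantities, thresholds, provenance),
#' a cohort-level CSV (one row per subject x compartment), and the trend
#' table as CSV when present.
#'
#' @param bundle An `imatq_results` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "imatq_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sid in unique(bundle$results$subject_id)) {
    p <- file.path(dir, paste0(sid, ".json"))
    sub <- bundle$results[bundle$results$subject_id == sid, ]
    jsonlite::write_json(
      list(
        subject_id = sid,
        compartments = sub,
        thresholds_ff_pct = bundle$provenance$thresholds_ff_pct[[sid]],
        provenance = bundle$provenance[c("package", "version", "config_hash")]
      ),
      p, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows"
    )
    paths <- c(paths, p)
  }
  cohort_csv <- file.path(dir, "cohort.csv")
  utils::write.csv(bundle$results, cohort_csv, row.names = FALSE)
  paths <- c(paths, cohort_csv)
  if (!is.null(bundle$trends)) {
    trend_csv <- file.path(dir, "trends.csv")
    utils::write.csv(bundle$trends, trend_csv, row.names = FALSE)
    paths <- c(paths, trend_csv)
  }
  invisible(paths)
}
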