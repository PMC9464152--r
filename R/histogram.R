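#' Within-ROI fat-fraction histogram
#'
#' Bins the fat-fraction values of all voxels inside an ROI on a regular
#' grid tiling 0--100% FF. This is the patient-specific distribution on
#' which the bimodal local-minimum threshold is determined: muscle voxels
#' form a low-FF mode and adipose voxels a high-FF mode.
#'
#' Bins are left-closed, `[edge, edge + width)`, with the final bin closed
#' on both sides so FF = 100% is counted. A bin is referred to by its lower
#' edge throughout (`bin_ff`).
#'
#' @param volume An [ff_volume()].
#' @param roi An [roi_mask()] congruent with `volume`; must be non-empty.
#' @param bin_width_pct Bin width in FF percentage points (default 1).
#' @return An object of class `ff_histogram` with fields `bin_edges`,
#'   `bin_ff` (lower edges), `raw_counts`, `smoothed_counts` (filled by
#'   [detect_modes_and_minimum()]), mode/minimum/threshold slots (initially
#'   `NA`), `bimodal` flag, `n_voxels` and `roi_name`.
#' @seealso [detect_modes_and_minimum()], [compute_threshold()],
#'   [classify_voxels()]
#' @examples
#' vol <- ff_volume(array(c(40, 40, 850, 40), dim = c(2, 2, 1)))
#' roi <- roi_mask(array(TRUE, dim = c(2, 2, 1)), "fascia_lata")
#' h <- build_ff_histogram(vol, roi)
#' sum(h$raw_counts)
#' @export
build_ff_histogram <- function(volume, roi, bin_width_pct = 1) {
  stopifnot(inherits(volume, "ff_volume"), inherits(roi, "roi_mask"))
  check_congruent(volume, roi)
  if (!any(roi$mask)) {
    abort(sprintf("ROI '%s' is empty: cannot build a histogram.", roi$name))
  }
  if (!is.numeric(bin_width_pct) || length(bin_width_pct) != 1 ||
      bin_width_pct <= 0) {
    abort("`bin_width_pct` must be a single positive FF percentage.")
  }
  edges <- seq(0, 100, by = bin_width_pct)
  if (edges[length(edges)] < 100) edges <- c(edges, 100)
  ff <- volume$intensities[roi$mask] / 10
  # left-closed bins; FF exactly 100 goes in the last bin
  idx <- findInterval(ff, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(
    list(
      bin_edges = edges,
      bin_ff = edges[-length(edges)],
      raw_counts = counts,
      smoothed_counts = NULL,
      muscle_mode_ff = NA_real_,
      fat_mode_ff = NA_real_,
      minimum_ff = NA_real_,
      threshold_ff = NA_real_,
      bimodal = NA,
      smoothing_window = NA_integer_,
      n_voxels = length(ff),
      bin_width_pct = bin_width_pct,
      roi_name = roi$name
    ),
    class = "ff_histogram"
  )
}

# Centered moving average; partial windows at the edges.
moving_average <- function(x, window) {
  if (window <= 1L) return(as.numeric(x))
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Local maxima of a vector with plateau handling: runs of equal values are
# collapsed and a run is a peak if strictly above both neighbouring runs
# (boundary runs need only beat their single neighbour). Returns for each
# peak a representative index (middle of the run) and its height.
find_local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- starts + (r$lengths - 1L) %/% 2L
  is_peak <- vapply(seq_len(k), function(j) {
    left_ok <- j == 1L || r$values[j] > r$values[j - 1L]
    right_ok <- j == k || r$values[j] > r$values[j + 1L]
    left_ok && right_ok
  }, logical(1))
  list(index = mids[is_peak], height = r$values[is_peak])
}

# Topographic prominence of each candidate peak: height above the higher of
# the two valley floors separating it from nearer higher terrain (or from
# the signal boundary when no higher point exists on that side).
peak_prominence <- function(x, peak_index) {
  vapply(peak_index, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    right <- if (i < length(x)) x[(i + 1L):length(x)] else numeric(0)
    higher_left <- which(left > h)
    lmin <- if (length(left) == 0) h else if (length(higher_left) > 0) {
      min(left[(max(higher_left) + 1L):length(left)])
    } else min(left)
    higher_right <- which(right > h)
    rmin <- if (length(right) == 0) h else if (length(higher_right) > 0) {
      min(right[seq_len(min(higher_right) - 1L)])
    } else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect muscle and fat modes and the interior local minimum
#'
#' Smooths the raw histogram with a centered moving average, then locates
#' the two highest-prominence local maxima. The lower-FF mode is taken as
#' muscle, the higher as (intermuscular) adipose tissue, and the local
#' minimum is the bin with the lowest smoothed count strictly between the
#' two modes.
#'
#' When several bins tie for the lowest count — typical when the two modes
#' are so well separated that the valley is an empty plateau — the
#' reported minimum is, by default, the middle bin of the tied set, the
#' unbiased representative of a flat valley. `tie_break = "lowest"` or
#' `"highest"` instead takes the lowest- or highest-FF tied bin; note that
#' the threshold is a fraction *of* the minimum FF, so a lower tie gives a
#' lower threshold and a *larger* IMAT compartment, and vice versa.
#'
#' A histogram with fewer than two maxima of nonzero prominence is flagged
#' `bimodal = FALSE` rather than raising an error; [compute_threshold()]
#' then requires an explicit fallback.
#'
#' @param hist An `ff_histogram` from [build_ff_histogram()].
#' @param smoothing_window Moving-average window in bins (default 5). Use 1
#'   for no smoothing.
#' @param tie_break How to resolve ties for the lowest between-mode count:
#'   `"midpoint"` (default), `"lowest"` or `"highest"` FF.
#' @return The histogram with `smoothed_counts`, `muscle_mode_ff`,
#'   `fat_mode_ff`, `minimum_ff` and `bimodal` filled in.
#' @export
detect_modes_and_minimum <- function(hist, smoothing_window = 5L,
                                     tie_break = c("midpoint", "lowest",
                                                   "highest")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(hist, "ff_histogram"))
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L) abort("`smoothing_window` must be >= 1 bin.")
  s <- moving_average(hist$raw_counts, smoothing_window)
  hist$smoothed_counts <- s
  hist$smoothing_window <- smoothing_window

  peaks <- find_local_maxima(s)
  if (length(peaks$index) > 0) {
    prom <- peak_prominence(s, peaks$index)
    keep <- prom > 0
    peaks$index <- peaks$index[keep]
    prom <- prom[keep]
  } else {
    prom <- numeric(0)
  }

  if (length(peaks$index) < 2L) {
    hist$bimodal <- FALSE
    hist$muscle_mode_ff <- NA_real_
    hist$fat_mode_ff <- NA_real_
    hist$minimum_ff <- NA_real_
    return(hist)
  }

  top2 <- peaks$index[order(prom, decreasing = TRUE)][1:2]
  lo <- min(top2)
  hi <- max(top2)
  hist$bimodal <- TRUE
  hist$muscle_mode_ff <- hist$bin_ff[lo]
  hist$fat_mode_ff <- hist$bin_ff[hi]
  between <- (lo + 1L):(hi - 1L)
  tied <- between[s[between] == min(s[between])]
  pick <- switch(tie_break,
    lowest = tied[1],
    highest = tied[length(tied)],
    midpoint = tied[ceiling(length(tied) / 2)]
  )
  hist$minimum_ff <- hist$bin_ff[pick]
  hist
}

#' Derive the classification threshold from the histogram minimum
#'
#' The separation threshold is placed a configurable fraction below the FF
#' at the interior local minimum: `threshold = (1 - fraction_below) *
#' minimum_ff`. The default `fraction_below = 0.5` puts the threshold at
#' half the FF of the minimum ("50% below the minimum"); `fraction_below =
#' 0.2` reproduces the 20%-below variant used in earlier T1-based work, and
#' `fraction_below = 0` thresholds at the minimum itself.
#'
#' @param hist An `ff_histogram` processed by [detect_modes_and_minimum()].
#' @param fraction_below Fraction of the minimum FF subtracted (default 0.5).
#' @param fallback_threshold_pct Absolute FF % threshold applied when the
#'   histogram is not bimodal. Without it, a unimodal histogram is an error:
#'   silently guessing a threshold would corrupt downstream cohort
#'   statistics.
#' @return The histogram with `threshold_ff` set.
#' @export
compute_threshold <- function(hist, fraction_below = 0.5,
                              fallback_threshold_pct = NULL) {
  stopifnot(inherits(hist, "ff_histogram"))
  if (!is.numeric(fraction_below) || fraction_below < 0 || fraction_below > 1) {
    abort("`fraction_below` must be in [0, 1].")
  }
  if (is.na(hist$bimodal)) {
    abort("Run `detect_modes_and_minimum()` before `compute_threshold()`.")
  }
  if (!hist$bimodal) {
    if (is.null(fallback_threshold_pct)) {
      abort(paste(
        "Histogram is not bimodal: no interior local minimum found.",
        "Supply `fallback_threshold_pct` (an absolute FF % threshold)",
        "to classify this ROI anyway."
      ))
    }
    if (fallback_threshold_pct < 0 || fallback_threshold_pct > 100) {
      abort("`fallback_threshold_pct` must be an FF percentage in [0, 100].")
    }
    hist$threshold_ff <- fallback_threshold_pct
    return(hist)
  }
  hist$threshold_ff <- (1 - fraction_below) * hist$minimum_ff
  hist
}

#' @export
print.ff_histogram <- function(x, ...) {
  cat(sprintf(
    "<ff_histogram> ROI '%s': %d voxels, %g%%-wide bins\n",
    x$roi_name, x$n_voxels, x$bin_width_pct
  ))
  if (!is.na(x$bimodal)) {
    if (x$bimodal) {
      cat(sprintf(
        "  modes: muscle %.1f%%, fat %.1f%%; minimum %.1f%%\n",
        x$muscle_mode_ff, x$fat_mode_ff, x$minimum_ff
      ))
    } else {
      cat("  not bimodal\n")
    }
  }
  if (!is.na(x$threshold_ff)) {
    cat(sprintf("  threshold: %.2f%% FF\n", x$threshold_ff))
  }
  invisible(x)
}

#' @describeIn build_ff_histogram Bin-level view: one row per bin with
#'   lower edge, raw and (if computed) smoothed counts.
#' @param x An `ff_histogram`.
#' @param ... Unused.
#' @export
tidy.ff_histogram <- function(x, ...) {
  tibble(
    bin_ff = x$bin_ff,
    raw_count = x$raw_counts,
    smoothed_count = if (is.null(x$smoothed_counts)) NA_real_ else x$smoothed_counts
  )
}

#' Plot a within-ROI fat-fraction histogram
#'
#' Raw counts as bars, smoothed counts as a line, with the detected modes,
#' local minimum and threshold marked when available.
#'
#' @param object An `ff_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ff_histogram <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_ff + object$bin_width_pct / 2)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$raw_count),
      width = object$bin_width_pct, fill = "grey70"
    ) +
    ggplot2::labs(
      x = "Fat fraction (%)", y = "Voxels",
      title = sprintf("FF histogram: %s", object$roi_name)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$smoothed_counts)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$smoothed_count),
      colour = "black"
    )
  }
  marks <- c(
    muscle_mode = object$muscle_mode_ff,
    fat_mode = object$fat_mode_ff,
    minimum = object$minimum_ff,
    threshold = object$threshold_ff
  )
  marks <- marks[!is.na(marks)]
  if (length(marks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble(ff = unname(marks), what = names(marks)),
      ggplot2::aes(xintercept = .data$ff, linetype = .data$what)
    )
  }
  p
}
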