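# Per-pixel random error of repeated depth measurements over a region of
# interest. For a static scene, the random error of pixel p is the RMS
# deviation of its depth samples from their mean over the analyzed frames,
#
#     re[p] = sqrt( sum_t (d[p,t] - mean_p)^2 / n ),
#
# a population-variance (divide by n, not n-1) dispersion in mm. Invalid
# samples (sentinel 0) are excluded from the mean and the sum; by default
# the divisor is the number of valid samples, so a pixel valid in a single
# frame has re = 0 and a pixel never valid is undefined.

#' Per-pixel random error over a region of interest
#'
#' @param stack A [depth_stack()].
#' @param roi A [roi()] lying inside the frame.
#' @param cut Number of initial frames to discard before analysis
#'   (default 60, two seconds at 30 fps, covering the tracker/sensor
#'   start-up transient).
#' @param denominator `"valid"` (default) divides each pixel's squared
#'   deviations by its own number of valid samples; `"analyzed"` divides by
#'   the fixed number of analyzed frames regardless of invalid samples
#'   (the literal fixed-denominator variant; it deflates `re` for pixels
#'   with many invalid frames).
#' @return A `random_error_map`: list with `re` (matrix, mm; `NA` where no
#'   valid sample exists), `valid_count`, `n_invalid` (total invalid samples
#'   in the region over analyzed frames), `region`, and
#'   `analyzed_frame_range` (1-based, inclusive).
#' @export
compute_random_error <- function(stack, roi, cut = 60,
                                 denominator = c("valid", "analyzed")) {
  stopifnot(inherits(stack, "depth_stack"), inherits(roi, "roi"))
  denominator <- match.arg(denominator)
  nt <- n_frames(stack)
  if (cut >= nt) stop("cut leaves no frames to analyze", call. = FALSE)
  idx <- roi_indices(roi, stack)
  frames <- (cut + 1L):nt
  sub <- stack$frames[idx$rows, idx$cols, frames, drop = FALSE]
  npx <- roi$height * roi$width
  m <- matrix(as.numeric(sub), npx, length(frames))
  valid <- m != stack$invalid_sentinel
  n_valid <- rowSums(valid)
  sums <- rowSums(m * valid)
  mean_p <- ifelse(n_valid > 0, sums / n_valid, NA_real_)
  dev2 <- (m - mean_p)^2 * valid
  ss <- rowSums(dev2)
  denom <- if (denominator == "valid") n_valid else length(frames)
  re <- ifelse(n_valid > 0, sqrt(ss / denom), NA_real_)
  structure(
    list(re = matrix(re, roi$height, roi$width),
         valid_count = matrix(as.integer(n_valid), roi$height, roi$width),
         n_invalid = sum(!valid),
         region = roi,
         analyzed_frame_range = c(cut + 1L, nt),
         denominator = denominator),
    class = "random_error_map"
  )
}

#' @export
print.random_error_map <- function(x, ...) {
  cat(sprintf(
    "<random_error_map> roi '%s' (%dx%d px), frames %d..%d, %d invalid sample(s)\n",
    x$region$name, x$region$height, x$region$width,
    x$analyzed_frame_range[1], x$analyzed_frame_range[2], x$n_invalid))
  defined <- x$re[!is.na(x$re)]
  if (length(defined) > 0L) {
    cat(sprintf("  re (mm): median %.3f, range [%.3f, %.3f], %d/%d px defined\n",
                stats::median(defined), min(defined), max(defined),
                length(defined), length(x$re)))
  }
  invisible(x)
}

#' Count invalid depth samples in a region
#'
#' Total number of sentinel-valued samples over the analyzed frames and the
#' region's pixels; invalid samples concentrate at object boundaries (mixed
#' fore/background signal) and weak-signal background.
#'
#' @inheritParams compute_random_error
#' @return Integer count.
#' @export
count_invalid <- function(stack, roi, cut = 60) {
  stopifnot(inherits(stack, "depth_stack"), inherits(roi, "roi"))
  nt <- n_frames(stack)
  if (cut >= nt) stop("cut leaves no frames to analyze", call. = FALSE)
  idx <- roi_indices(roi, stack)
  sub <- stack$frames[idx$rows, idx$cols, (cut + 1L):nt, drop = FALSE]
  sum(sub == stack$invalid_sentinel)
}

#' Summarize a random-error map
#'
#' Order statistics (min, quartiles, max; linear interpolation) over the
#' defined pixels of a [compute_random_error()] map.
#'
#' @param map A `random_error_map`.
#' @return A `depth_summary`: list with `min`, `q1`, `median`, `q3`, `max`
#'   (mm), `n_pixels_defined` and `n_invalid_values`.
#' @export
summarize_random_error <- function(map) {
  stopifnot(inherits(map, "random_error_map"))
  vals <- map$re[!is.na(map$re)]
  if (length(vals) == 0L) {
    stop("all pixels undefined: no valid depth samples in region",
         call. = FALSE)
  }
  s <- five_number(vals)
  structure(c(s, list(n_pixels_defined = length(vals),
                      n_invalid_values = map$n_invalid)),
            class = "depth_summary")
}

#' @export
print.depth_summary <- function(x, ...) {
  cat(sprintf(
    "<depth_summary> min %.2f, max %.2f, median %.2f [%.2f; %.2f] mm (%d px, %d invalid samples)\n",
    x$min, x$max, x$median, x$q1, x$q3, x$n_pixels_defined,
    x$n_invalid_values))
  invisible(x)
}
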