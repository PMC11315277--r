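# Joint-jitter metrics on tracking sequences.
#
# The mean distance error (MDE) of a joint is the per-frame Euclidean
# distance between the joint's position and a sliding-window centroid of
# its own trajectory, averaged over the analyzed frames. For a static pose
# it measures tracking jitter (not accuracy against ground truth). The
# centroid at frame t averages the 2N+1 frames [t-N, t+N]; at the sequence
# ends the window is clipped to the available frames.

#' Drop the initial start-up frames of a sequence
#'
#' Markerless trackers converge over the first frames of a recording; the
#' customary remedy is to discard the first 60 frames (two seconds at
#' 30 fps) and analyze the rest. Original frame indices are retained.
#'
#' @param seq A [tracking_sequence()].
#' @param n_cut Number of leading frames to remove (default 60).
#' @return The shortened `tracking_sequence`.
#' @export
cut_frames <- function(seq, n_cut = 60) {
  stopifnot(inherits(seq, "tracking_sequence"))
  n <- n_frames(seq)
  if (n_cut >= n) {
    stop(sprintf("cannot cut %d frames from a %d-frame sequence", n_cut, n),
         call. = FALSE)
  }
  if (n_cut == 0L) return(seq)
  keep <- (n_cut + 1L):n
  tracking_sequence(
    seq$positions[keep, , , drop = FALSE],
    frame_index = seq$frame_index[keep],
    fps = seq$fps,
    timestamp_usec = seq$timestamp_usec[keep],
    gaps = seq$gaps[seq$gaps > seq$frame_index[n_cut]]
  )
}

# Clipped-window running mean of a vector via cumulative sums.
running_mean <- function(x, N, normalize) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  t <- seq_len(n)
  lo <- pmax(1L, t - N)
  hi <- pmin(n, t + N)
  width <- if (normalize == "clip") hi - lo + 1L else 2L * N + 1L
  (cs[hi + 1L] - cs[lo]) / width
}

#' Sliding-window centroid of a joint trajectory
#'
#' Per-coordinate mean over the frames `[t - N, t + N]`, clipped to the
#' analyzed range at the sequence ends.
#'
#' @param seq A [tracking_sequence()] (already cut, if applicable).
#' @param joint Joint name.
#' @param N Window half-width in frames; by default coupled to the frame
#'   rate (`N = fps`), giving a two-second (2N+1 frame) window.
#' @param normalize `"clip"` (default) divides clipped end windows by their
#'   actual frame count; `"full"` always divides by `2N + 1`, which biases
#'   end centroids toward the origin and exists only for comparison.
#' @return A `centroid_series`: list with `joint`, `c` (frames x 3 matrix),
#'   `N`, `frame_index`, `normalize`.
#' @export
sliding_centroid <- function(seq, joint, N = seq$fps,
                             normalize = c("clip", "full")) {
  stopifnot(inherits(seq, "tracking_sequence"))
  normalize <- match.arg(normalize)
  assert_joints(joint, seq$joint_set)
  stopifnot(length(joint) == 1L, N >= 0)
  N <- as.integer(N)
  cmat <- sapply(1:3, function(k)
    running_mean(seq$positions[, joint, k], N, normalize))
  cmat <- matrix(cmat, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  structure(list(joint = joint, c = cmat, N = N,
                 frame_index = seq$frame_index, normalize = normalize),
            class = "centroid_series")
}

#' Per-frame distance of a joint to its centroid
#'
#' Euclidean distance (mm) between a joint's position and its sliding
#' centroid, frame by frame.
#'
#' @param seq A [tracking_sequence()].
#' @param centroids A `centroid_series` from [sliding_centroid()], computed
#'   on the same frame range.
#' @param squared If `TRUE`, return squared distances instead of distances.
#'   The root distance is canonical (it is what the mm-scale jitter tables
#'   of this metric report); the squared variant is provided for
#'   completeness.
#' @return Numeric vector, one value per frame.
#' @export
distance_to_centroid <- function(seq, centroids, squared = FALSE) {
  stopifnot(inherits(seq, "tracking_sequence"),
            inherits(centroids, "centroid_series"))
  if (!identical(seq$frame_index, centroids$frame_index)) {
    stop("sequence and centroid series cover different frame ranges",
         call. = FALSE)
  }
  diff <- seq$positions[, centroids$joint, , drop = TRUE] - centroids$c
  d2 <- rowSums(matrix(diff, ncol = 3L)^2)
  if (squared) d2 else sqrt(d2)
}

#' Mean distance error of joint trajectories
#'
#' For each requested joint: the sliding-window centroid, the per-frame
#' distance series, and its time average (the MDE, mm). When several joints
#' are requested the across-joint median and quartiles of the MDE values
#' are reported as well, mirroring the usual per-recording summary row.
#'
#' @param seq A [tracking_sequence()], typically after [cut_frames()].
#' @param joints Joint names to analyze (default: the 18-joint gait set of
#'   [included_joints()], intersected with the sequence's joint set).
#' @param N Centroid window half-width in frames (default `fps`).
#' @param normalize Passed to [sliding_centroid()].
#' @param squared Passed to [distance_to_centroid()].
#' @return An `mde_result`: list with `mde` (named numeric, mm), `se`
#'   (frames x joints matrix of per-frame distances), `summary`
#'   (median/q1/q3 across joints), `N`, `analyzed_frame_range`.
#' @export
compute_mde <- function(seq, joints = NULL, N = seq$fps,
                        normalize = c("clip", "full"), squared = FALSE) {
  stopifnot(inherits(seq, "tracking_sequence"))
  normalize <- match.arg(normalize)
  if (is.null(joints)) joints <- intersect(included_joints(), seq$joint_set)
  if (length(joints) == 0L) stop("empty joint list", call. = FALSE)
  assert_joints(joints, seq$joint_set)
  se <- sapply(joints, function(j) {
    distance_to_centroid(seq, sliding_centroid(seq, j, N, normalize),
                         squared = squared)
  })
  se <- matrix(se, ncol = length(joints), dimnames = list(NULL, joints))
  mde <- colMeans(se)
  q <- stats::quantile(mde, c(0.25, 0.5, 0.75), names = FALSE,
                       type = .QUANTILE_TYPE)
  structure(
    list(mde = mde, se = se,
         summary = list(median = q[2], q1 = q[1], q3 = q[3]),
         N = as.integer(N),
         analyzed_frame_range = range(seq$frame_index)),
    class = "mde_result"
  )
}

#' @export
print.mde_result <- function(x, ...) {
  cat(sprintf("<mde_result> %d joint(s), N = %d, frames %d..%d\n",
              length(x$mde), x$N, x$analyzed_frame_range[1],
              x$analyzed_frame_range[2]))
  cat(sprintf("  MDE median %.2f [%.2f; %.2f] mm\n",
              x$summary$median, x$summary$q1, x$summary$q3))
  invisible(x)
}

#' Per-frame distance between two joints
#'
#' Euclidean distance series between two joints, e.g. the left and right
#' ankles — the stance width of a static pose (step width in dynamic
#' trials) — with a boxplot-ready five-number summary.
#'
#' @param seq A [tracking_sequence()], typically after [cut_frames()].
#' @param a,b Distinct joint names.
#' @param squared If `TRUE`, squared distances (non-canonical; see
#'   [distance_to_centroid()]).
#' @return A `distance_series`: list with `joint_a`, `joint_b`, `d`
#'   (per-frame mm), `summary` (min/q1/median/q3/max), `frame_index`.
#' @export
joint_pair_distance <- function(seq, a, b, squared = FALSE) {
  stopifnot(inherits(seq, "tracking_sequence"))
  if (identical(a, b)) stop("joints a and b must differ", call. = FALSE)
  assert_joints(c(a, b), seq$joint_set)
  diff <- seq$positions[, a, , drop = TRUE] - seq$positions[, b, , drop = TRUE]
  d2 <- rowSums(matrix(diff, ncol = 3L)^2)
  d <- if (squared) d2 else sqrt(d2)
  structure(list(joint_a = a, joint_b = b, d = d,
                 summary = five_number(d), frame_index = seq$frame_index),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<distance_series> %s - %s: median %.1f [%.1f; %.1f] mm over %d frames\n",
    x$joint_a, x$joint_b, s$median, s$q1, s$q3, length(x$d)))
  invisible(x)
}
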