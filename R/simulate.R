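# Synthetic depth stacks and tracking sequences with the statistical
# structure the metrics assume: per-pixel Gaussian depth noise with
# invalid-pixel dropout and an optional moving drop-out blob; per-joint
# isotropic Gaussian jitter around a static pose with an optional start-up
# transient and transient position peaks.

#' Configure a synthetic depth-stack simulation
#'
#' @param base_depth Scene depth without noise, in mm: an `H x W` matrix or a
#'   scalar with `height`/`width` given.
#' @param sigma Per-pixel noise SD in mm (matrix or scalar, recycled).
#'   Indoor time-of-flight depth noise on a diffuse target at ~2 m is on the
#'   order of 1-3 mm.
#' @param invalid_prob Per-frame probability that a pixel returns no
#'   measurement (matrix or scalar). Elevated values along object boundaries
#'   emulate mixed fore/background signal.
#' @param n_frames Number of frames to simulate.
#' @param blob Optional moving drop-out blob, a list with `start_frame`,
#'   `end_frame` (1-based, inclusive), `radius` (px), `start` (`c(row, col)`,
#'   1-based), `velocity` (`c(drow, dcol)` px/frame). Pixels under the disk
#'   are set invalid; the disk may leave the frame (clipped).
#' @param height,width Frame geometry when `base_depth` is scalar.
#' @param fps Nominal frame rate.
#' @return An object of class `depth_sim_config`.
#' @export
depth_sim_config <- function(base_depth, sigma = 0, invalid_prob = 0,
                             n_frames, blob = NULL,
                             height = NULL, width = NULL, fps = 30) {
  if (!is.matrix(base_depth)) {
    if (is.null(height) || is.null(width)) {
      stop("scalar base_depth requires height and width", call. = FALSE)
    }
    base_depth <- matrix(base_depth, height, width)
  }
  h <- nrow(base_depth); w <- ncol(base_depth)
  expand <- function(x, what) {
    if (!is.matrix(x)) x <- matrix(x, h, w)
    if (!all(dim(x) == c(h, w))) {
      stop(what, " map must match base_depth dimensions", call. = FALSE)
    }
    x
  }
  sigma <- expand(sigma, "sigma")
  invalid_prob <- expand(invalid_prob, "invalid_prob")
  stopifnot(n_frames >= 1, all(sigma >= 0),
            all(invalid_prob >= 0), all(invalid_prob <= 1))
  if (!is.null(blob)) {
    req <- c("start_frame", "end_frame", "radius", "start", "velocity")
    if (!all(req %in% names(blob))) {
      stop("blob needs fields: ", paste(req, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(base_depth = base_depth, sigma = sigma,
                 invalid_prob = invalid_prob, n_frames = as.integer(n_frames),
                 blob = blob, fps = fps),
            class = "depth_sim_config")
}

# 1-based (row, col) pixels covered by a disk, clipped to the h x w frame.
disk_pixels <- function(center, radius, h, w) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(h, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(w, ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Simulate a depth-frame stack
#'
#' Each frame and pixel draws `round(base + eps)`, `eps ~ N(0, sigma)`;
#' with probability `invalid_prob` the pixel is set to the invalid sentinel
#' (0) instead. Negative simulated depths are clamped to invalid and
#' counted. A configured drop-out blob invalidates the pixels under a moving
#' disk. Identical seeds give identical stacks.
#'
#' @param cfg A [depth_sim_config()].
#' @param seed Integer seed; the simulation draws from its own RNG stream
#'   and leaves the caller's stream untouched.
#' @return A [depth_stack()]. Attribute `sim_counts` reports per-frame
#'   blob-invalidated pixel counts and the number of negative-depth clamps.
#' @export
simulate_depth <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "depth_sim_config"))
  h <- nrow(cfg$base_depth); w <- ncol(cfg$base_depth)
  npx <- h * w
  with_seed(seed, {
    arr <- array(0L, dim = c(h, w, cfg$n_frames))
    n_negative <- 0L
    blob_counts <- integer(cfg$n_frames)
    any_sigma <- any(cfg$sigma > 0)
    any_invalid <- any(cfg$invalid_prob > 0)
    for (t in seq_len(cfg$n_frames)) {
      fr <- cfg$base_depth
      if (any_sigma) fr <- fr + stats::rnorm(npx, sd = cfg$sigma)
      fr <- round(fr)
      neg <- fr < 0
      n_negative <- n_negative + sum(neg)
      fr[neg] <- 0
      if (any_invalid) {
        drop <- stats::runif(npx) < cfg$invalid_prob
        fr[drop] <- 0
      }
      if (!is.null(cfg$blob) &&
          t >= cfg$blob$start_frame && t <= cfg$blob$end_frame) {
        center <- cfg$blob$start + (t - cfg$blob$start_frame) * cfg$blob$velocity
        px <- disk_pixels(center, cfg$blob$radius, h, w)
        if (nrow(px) > 0L) fr[px] <- 0
        blob_counts[t] <- nrow(px)
      }
      arr[, , t] <- fr
    }
    out <- depth_stack(arr, fps = cfg$fps)
    attr(out, "sim_counts") <- list(blob_pixels = blob_counts,
                                    n_negative_clamped = n_negative)
    out
  })
}

#' Configure a synthetic tracking simulation
#'
#' Emulates a static pose observed by a markerless tracker: each joint
#' jitters isotropically around a fixed true position, optionally preceded
#' by a decaying start-up transient (trackers typically converge within the
#' first couple of seconds) and perturbed by a transient position peak such
#' as those caused by momentary depth drop-outs.
#'
#' @param true_positions Numeric `joints x 3` matrix (mm) with joint names as
#'   rownames, or a named list of length-3 vectors.
#' @param sigma Isotropic per-joint jitter SD in mm: a single value or a
#'   named vector covering every joint. Static-pose jitter of this tracker
#'   class is sub-millimetre at the pelvis and up to a few mm at the feet.
#' @param n_frames Number of frames.
#' @param transient Optional list `(length, offset, rate)`: an initial
#'   position offset (mm, length-3) applied to all joints, decaying
#'   geometrically by `exp(-rate * t / length)` so that with the default
#'   `rate = 5` the offset falls below 1% of its initial value within
#'   `length` frames (default 60).
#' @param peak Optional list `(joint, start_frame, duration, offset)`: adds
#'   `offset` (mm, length-3) to one joint for `duration` frames starting at
#'   `start_frame` (1-based).
#' @param ar1 Lag-1 autocorrelation of the jitter (default 0, i.e.
#'   frame-independent noise; the marginal SD stays `sigma` either way).
#'   Real tracking jitter is autocorrelated; enable to probe sensitivity.
#' @param fps Nominal frame rate.
#' @return An object of class `pose_sim_config`.
#' @export
pose_sim_config <- function(true_positions, sigma, n_frames,
                            transient = NULL, peak = NULL, ar1 = 0,
                            fps = 30) {
  if (is.list(true_positions) && !is.data.frame(true_positions)) {
    true_positions <- do.call(rbind, true_positions)
  }
  if (!is.matrix(true_positions) || ncol(true_positions) != 3L ||
      is.null(rownames(true_positions))) {
    stop("true_positions must be a joints x 3 matrix with joint rownames",
         call. = FALSE)
  }
  joints <- rownames(true_positions)
  assert_joints(joints)
  if (length(sigma) == 1L && is.null(names(sigma))) {
    sigma <- stats::setNames(rep(as.numeric(sigma), length(joints)), joints)
  }
  assert_joints(names(sigma))
  if (!all(joints %in% names(sigma))) {
    stop("sigma must cover every joint in true_positions", call. = FALSE)
  }
  sigma <- sigma[joints]
  stopifnot(all(sigma >= 0), n_frames >= 1, abs(ar1) < 1)
  if (!is.null(transient)) {
    transient$length <- transient$length %||% 60L
    transient$rate <- transient$rate %||% 5
    stopifnot(length(transient$offset) == 3L, transient$length >= 1)
  }
  if (!is.null(peak)) {
    assert_joints(peak$joint, joints, what = "peak joint")
    stopifnot(length(peak$offset) == 3L, peak$start_frame >= 1,
              peak$duration >= 1)
  }
  structure(list(true_positions = true_positions, sigma = sigma,
                 n_frames = as.integer(n_frames), transient = transient,
                 peak = peak, ar1 = ar1, fps = fps),
            class = "pose_sim_config")
}

#' Simulate a body-tracking sequence
#'
#' `position[j, t] = true[j] + transient(t) + peak(j, t) + eta`,
#' `eta ~ N3(0, sigma_j^2 I)` (optionally AR(1) across frames with the same
#' marginal SD). Seeded and reproducible.
#'
#' @param cfg A [pose_sim_config()].
#' @param seed Integer seed; drawn from its own RNG stream.
#' @return A [tracking_sequence()].
#' @export
simulate_tracking <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pose_sim_config"))
  joints <- rownames(cfg$true_positions)
  nj <- length(joints); nt <- cfg$n_frames
  with_seed(seed, {
    arr <- array(0, dim = c(nt, nj, 3L),
                 dimnames = list(NULL, joints, c("x", "y", "z")))
    for (j in seq_len(nj)) {
      s <- cfg$sigma[j]
      noise <- if (s == 0) matrix(0, nt, 3L) else {
        eps <- matrix(stats::rnorm(nt * 3L, sd = s), nt, 3L)
        if (cfg$ar1 != 0) {
          # AR(1) with stationary SD s: x_t = phi x_{t-1} + sqrt(1-phi^2) e_t
          phi <- cfg$ar1
          for (k in 1:3) {
            x <- numeric(nt)
            x[1] <- eps[1, k]
            sc <- sqrt(1 - phi^2)
            for (t in 2:nt) x[t] <- phi * x[t - 1] + sc * eps[t, k]
            eps[, k] <- x
          }
        }
        eps
      }
      arr[, j, ] <- matrix(cfg$true_positions[j, ], nt, 3L, byrow = TRUE) + noise
    }
    if (!is.null(cfg$transient)) {
      tr <- cfg$transient
      tt <- seq_len(nt) - 1L
      decay <- exp(-tr$rate * tt / tr$length)
      for (k in 1:3) arr[, , k] <- arr[, , k] + tr$offset[k] * decay
    }
    if (!is.null(cfg$peak)) {
      pk <- cfg$peak
      win <- pk$start_frame:min(nt, pk$start_frame + pk$duration - 1L)
      for (k in 1:3) arr[win, pk$joint, k] <- arr[win, pk$joint, k] + pk$offset[k]
    }
    tracking_sequence(arr, fps = cfg$fps)
  })
}

#' Standard standing-pose simulation conditions
#'
#' A static 18-joint standing pose (millimetres, camera space: x right,
#' y down, z forward) of a ~1.7 m figure about 1.9 m in front of a camera
#' mounted at chest height, with per-joint isotropic jitter SDs typical of
#' markerless tracking of a static figure: sub-millimetre at the pelvis and
#' trunk, around a millimetre at ankles and wrists, two to three
#' millimetres at the feet. Used as the default ground truth for synthetic
#' experiments.
#'
#' @param distance Scene depth of the pelvis in mm.
#' @return List with `true_positions` (18 x 3 matrix) and `sigma`
#'   (named per-joint jitter SD, mm).
#' @export
standing_pose <- function(distance = 1900) {
  z <- distance
  pos <- rbind(
    PELVIS         = c(   0,  420, z),
    SPINE_NAVEL    = c(   0,  280, z - 10),
    SPINE_CHEST    = c(   0,  140, z - 20),
    NECK           = c(   0, -120, z - 20),
    SHOULDER_LEFT  = c(-180, -100, z - 10),
    ELBOW_LEFT     = c(-220,  160, z),
    WRIST_LEFT     = c(-240,  400, z + 20),
    SHOULDER_RIGHT = c( 180, -100, z - 10),
    ELBOW_RIGHT    = c( 220,  160, z),
    WRIST_RIGHT    = c( 240,  400, z + 20),
    HIP_LEFT       = c( -90,  440, z),
    KNEE_LEFT      = c( -95,  850, z - 30),
    ANKLE_LEFT     = c(-100, 1240, z),
    FOOT_LEFT      = c(-105, 1290, z - 150),
    HIP_RIGHT      = c(  90,  440, z),
    KNEE_RIGHT     = c(  95,  850, z - 30),
    ANKLE_RIGHT    = c( 100, 1240, z),
    FOOT_RIGHT     = c( 105, 1290, z - 150)
  )
  sigma <- c(
    PELVIS = 0.39, SPINE_NAVEL = 0.43, SPINE_CHEST = 0.55, NECK = 0.70,
    SHOULDER_LEFT = 0.76, ELBOW_LEFT = 0.85, WRIST_LEFT = 1.62,
    SHOULDER_RIGHT = 0.68, ELBOW_RIGHT = 0.58, WRIST_RIGHT = 0.63,
    HIP_LEFT = 0.47, KNEE_LEFT = 0.57, ANKLE_LEFT = 1.06, FOOT_LEFT = 1.55,
    HIP_RIGHT = 0.47, KNEE_RIGHT = 0.53, ANKLE_RIGHT = 1.11,
    FOOT_RIGHT = 2.09
  )
  list(true_positions = pos, sigma = sigma[rownames(pos)])
}
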