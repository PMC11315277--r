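# Body-tracking sequences and their JSON serialization.
#
# The on-disk dialect mirrors the output of the body-tracking SDK's offline
# processor sample:
#
#   {
#     "joint_names":  ["PELVIS", ...],        # optional; SDK order if absent
#     "fps":          30,                     # optional, default 30
#     "frames": [
#       { "frame_id": 0, "timestamp_usec": 0, "num_bodies": 1,
#         "bodies": [ { "body_id": 0,
#                       "joint_positions": [[x, y, z], ...] } ] },
#       ...
#     ]
#   }
#
# Positions are millimetres in camera space: x points right of the focal
# point, y points down, z points forward. Files without an explicit
# "joint_names" list must carry exactly 32 positions per body, interpreted
# in SDK index order; files with an explicit list may carry any subset.

#' Construct a body-tracking sequence
#'
#' A `tracking_sequence` holds per-frame 3D positions (millimetres, camera
#' space) of a named joint set, plus the nominal frame rate and a record of
#' gap frames (frames in which no body was detected).
#'
#' @param positions Numeric array `frames x joints x 3`, with joint names as
#'   the second dimnames and `c("x","y","z")` as the third. All coordinates
#'   must be finite.
#' @param frame_index Integer vector of original frame indices (0-based),
#'   strictly increasing; defaults to `0:(n-1)`.
#' @param fps Nominal frame rate, frames/second.
#' @param timestamp_usec Optional numeric vector of per-frame device
#'   timestamps in microseconds.
#' @param gaps Integer vector of frame indices at which no body was detected;
#'   these frames carry no positions and are excluded from all metrics.
#' @return An object of class `tracking_sequence`.
#' @export
tracking_sequence <- function(positions, frame_index = NULL, fps = 30,
                              timestamp_usec = NULL, gaps = integer(0)) {
  if (!is.array(positions) || length(dim(positions)) != 3L ||
      dim(positions)[3] != 3L) {
    stop("positions must be a frames x joints x 3 array", call. = FALSE)
  }
  joint_set <- dimnames(positions)[[2]]
  if (is.null(joint_set) || anyDuplicated(joint_set)) {
    stop("positions must carry unique joint names as second dimnames",
         call. = FALSE)
  }
  assert_joints(joint_set)
  if (dim(positions)[1] < 1L) stop("sequence must have >= 1 frame", call. = FALSE)
  if (!all(is.finite(positions))) {
    stop("joint positions must be finite", call. = FALSE)
  }
  n <- dim(positions)[1]
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || is.unsorted(frame_index, strictly = TRUE)) {
    stop("frame_index must be strictly increasing, one per frame",
         call. = FALSE)
  }
  if (!is.null(timestamp_usec) && length(timestamp_usec) != n) {
    stop("timestamp_usec must have one entry per frame", call. = FALSE)
  }
  dimnames(positions)[[3]] <- c("x", "y", "z")
  structure(
    list(positions = positions, frame_index = frame_index, fps = fps,
         joint_set = joint_set, timestamp_usec = timestamp_usec,
         gaps = as.integer(gaps)),
    class = "tracking_sequence"
  )
}

#' @export
print.tracking_sequence <- function(x, ...) {
  cat(sprintf(
    "<tracking_sequence> %d frames, %d joints, %g fps, %d gap frame(s)\n",
    n_frames(x), length(x$joint_set), x$fps, length(x$gaps)))
  cat("  frame_index:", x$frame_index[1], "...",
      x$frame_index[n_frames(x)], "\n")
  invisible(x)
}

#' Number of frames in a sequence or depth stack
#' @param x A `tracking_sequence` or `depth_stack`.
#' @return Integer frame count (gap frames not included for sequences).
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.tracking_sequence <- function(x) dim(x$positions)[1]

#' Read body-tracking results from JSON
#'
#' Parses the JSON dialect written by the body-tracking SDK's offline
#' processor (and by [write_tracking_json()]). When a frame contains more
#' than one body the first is used, with a warning; frames with zero bodies
#' are recorded as gaps and excluded from all downstream statistics.
#'
#' @param path Path to a tracking JSON file.
#' @return A [tracking_sequence()]. The gap frames, if any, are listed in
#'   its `gaps` field.
#' @export
read_tracking_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty tracking file: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed tracking JSON in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  frames <- doc$frames
  if (is.null(frames) || length(frames) == 0L) {
    stop("tracking file has no frames: ", path, call. = FALSE)
  }
  joint_set <- if (!is.null(doc$joint_names)) {
    unlist(doc$joint_names, use.names = FALSE)
  } else {
    .KINECT_JOINTS
  }
  assert_joints(joint_set)
  n_joints <- length(joint_set)
  explicit_names <- !is.null(doc$joint_names)

  pos_rows <- vector("list", length(frames))
  frame_ids <- integer(length(frames))
  ts <- rep(NA_real_, length(frames))
  has_body <- logical(length(frames))
  warned_multi <- FALSE

  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    frame_ids[i] <- if (!is.null(fr$frame_id)) as.integer(fr$frame_id) else i - 1L
    if (!is.null(fr$timestamp_usec)) ts[i] <- as.numeric(fr$timestamp_usec)
    bodies <- fr$bodies
    nb <- length(bodies)
    if (nb == 0L) next
    if (nb > 1L && !warned_multi) {
      warning(sprintf(
        "frame %d contains %d bodies; using the first body in every frame",
        frame_ids[i], nb), call. = FALSE)
      warned_multi <- TRUE
    }
    jp <- bodies[[1]]$joint_positions
    if (is.null(jp)) {
      stop(sprintf("frame %d: body has no joint_positions", frame_ids[i]),
           call. = FALSE)
    }
    if (length(jp) != n_joints) {
      if (!explicit_names) {
        stop(sprintf(
          "frame %d: expected 32 joint positions (SDK order), found %d",
          frame_ids[i], length(jp)), call. = FALSE)
      }
      stop(sprintf("frame %d: expected %d joint positions, found %d",
                   frame_ids[i], n_joints, length(jp)), call. = FALSE)
    }
    v <- unlist(jp, use.names = FALSE)
    if (length(v) != 3L * n_joints || !all(is.finite(v))) {
      stop(sprintf("frame %d: joint positions must be finite [x, y, z] triples",
                   frame_ids[i]), call. = FALSE)
    }
    pos_rows[[i]] <- v
    has_body[i] <- TRUE
  }
  if (!any(has_body)) stop("no frames with a detected body in ", path,
                           call. = FALSE)
  # joint_positions come as [x,y,z] triples: joints vary fastest
  pos <- matrix(unlist(pos_rows[has_body], use.names = FALSE),
                ncol = 3L * n_joints, byrow = TRUE)
  arr <- array(NA_real_, dim = c(sum(has_body), n_joints, 3L),
               dimnames = list(NULL, joint_set, c("x", "y", "z")))
  for (k in 1:3) arr[, , k] <- pos[, seq(k, by = 3L, length.out = n_joints), drop = FALSE]
  ts_keep <- ts[has_body]
  tracking_sequence(
    arr,
    frame_index = frame_ids[has_body],
    fps = doc$fps %||% 30,
    timestamp_usec = if (all(is.na(ts_keep))) NULL else ts_keep,
    gaps = frame_ids[!has_body]
  )
}

#' Write a tracking sequence to JSON
#'
#' Serializes a [tracking_sequence()] to the dialect accepted by
#' [read_tracking_json()], with an explicit `joint_names` list so that joint
#' subsets round-trip. Gap frames are written with `num_bodies = 0`.
#'
#' @param seq A `tracking_sequence`.
#' @param path Output file path.
#' @param digits Significant digits for coordinates; the default `I(17)`
#'   writes full double precision so round-trips are exact.
#' @return `path`, invisibly.
#' @export
write_tracking_json <- function(seq, path, digits = I(17)) {
  stopifnot(inherits(seq, "tracking_sequence"))
  if (length(seq$joint_set) == 0L) {
    stop("cannot write a sequence with an empty joint set", call. = FALSE)
  }
  all_ids <- sort(c(seq$frame_index, seq$gaps))
  gap_set <- seq$gaps
  row_of <- match(all_ids, seq$frame_index)
  frames <- vector("list", length(all_ids))
  for (i in seq_along(all_ids)) {
    fid <- all_ids[i]
    if (fid %in% gap_set) {
      frames[[i]] <- list(frame_id = fid, num_bodies = 0L, bodies = list())
    } else {
      r <- row_of[i]
      jp <- lapply(seq_along(seq$joint_set), function(j) {
        unname(seq$positions[r, j, ])
      })
      fr <- list(frame_id = fid, num_bodies = 1L,
                 bodies = list(list(body_id = 0L, joint_positions = jp)))
      if (!is.null(seq$timestamp_usec)) fr$timestamp_usec <- seq$timestamp_usec[r]
      frames[[i]] <- fr
    }
  }
  doc <- list(joint_names = as.list(seq$joint_set), fps = seq$fps,
              frames = frames)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = digits,
                       always_decimal = FALSE)
  invisible(path)
}
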