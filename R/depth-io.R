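# Depth-frame stacks: T frames of H x W depth values in millimetres,
# 0 = invalid (no usable measurement). On disk a stack is a JSON manifest
# plus one losslessly stored 16-bit single-channel grayscale image per frame
# (TIFF written by this package; 16-bit PNG also accepted on read).

#' Construct a depth-frame stack
#'
#' @param frames Integer-valued array `height x width x n_frames` of depth
#'   values in millimetres. Values equal to `invalid_sentinel` mark pixels
#'   with no usable measurement and are normalized to 0.
#' @param fps Nominal frame rate.
#' @param invalid_sentinel Depth value meaning "no measurement" in `frames`
#'   (normalized to 0 in the returned object).
#' @return An object of class `depth_stack` with fields `frames` (sentinel
#'   normalized to 0), `fps` and `invalid_sentinel = 0`.
#' @export
depth_stack <- function(frames, fps = 30, invalid_sentinel = 0L) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("frames must be a height x width x n_frames array", call. = FALSE)
  }
  if (anyNA(frames) || any(frames < 0)) {
    stop("depth values must be non-negative millimetres (0 = invalid)",
         call. = FALSE)
  }
  if (any(frames > 65535)) {
    stop("depth values exceed the 16-bit range (65535 mm)", call. = FALSE)
  }
  frames <- round(frames)
  if (invalid_sentinel != 0) frames[frames == invalid_sentinel] <- 0
  storage.mode(frames) <- "integer"
  structure(list(frames = frames, fps = fps, invalid_sentinel = 0L),
            class = "depth_stack")
}

#' @export
n_frames.depth_stack <- function(x) dim(x$frames)[3]

#' @export
print.depth_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<depth_stack> %d frames of %dx%d px, %g fps, %.2f%% invalid\n",
              d[3], d[2], d[1], x$fps,
              100 * mean(x$frames == x$invalid_sentinel)))
  invisible(x)
}

#' Define a rectangular region of interest
#'
#' Pixel indices are 0-based with the origin at the top-left corner of the
#' frame, matching image coordinates. Typical regions for a standing figure
#' are the belly (57x57 px), a knee (15x15 px) and an ankle with some
#' surrounding background (25x25 px); their placement is scene-dependent and
#' user-supplied.
#'
#' @param name Label for the region.
#' @param row_start,col_start 0-based pixel indices of the top-left corner.
#' @param height,width Region extent in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(name, row_start, col_start, height, width) {
  stopifnot(row_start >= 0, col_start >= 0, height >= 1, width >= 1)
  structure(list(name = name, row_start = as.integer(row_start),
                 col_start = as.integer(col_start),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

# 1-based row/col index ranges of a roi within a stack; errors if outside.
roi_indices <- function(r, stack) {
  d <- dim(stack$frames)
  rows <- (r$row_start + 1L):(r$row_start + r$height)
  cols <- (r$col_start + 1L):(r$col_start + r$width)
  if (max(rows) > d[1] || max(cols) > d[2]) {
    stop(sprintf("roi '%s' (%dx%d at %d,%d) exceeds the %dx%d frame",
                 r$name, r$height, r$width, r$row_start, r$col_start,
                 d[1], d[2]), call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

read_depth_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 16L) {
      stop("depth image is not 16-bit: ", path, call. = FALSE)
    }
  } else if (ext == "png") {
    img <- png::readPNG(path)
    hdr <- readBin(path, "raw", n = 26L)
    if (length(hdr) >= 25L && as.integer(hdr[25]) != 16L) {
      stop("depth image is not 16-bit: ", path, call. = FALSE)
    }
  } else {
    stop("unsupported depth image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) != 2L) {
    stop("depth image is not single-channel: ", path, call. = FALSE)
  }
  round(img * 65535)
}

#' Read a depth-frame stack from a manifest
#'
#' @param dir_or_manifest Either a directory containing `manifest.json` or a
#'   path to the manifest itself. The manifest names `width`, `height`,
#'   `fps`, `invalid_sentinel` and an ordered list of 16-bit single-channel
#'   image files (paths relative to the manifest).
#' @return A [depth_stack()] with the sentinel normalized to 0.
#' @export
read_depth_stack <- function(dir_or_manifest) {
  manifest <- if (dir.exists(dir_or_manifest)) {
    file.path(dir_or_manifest, "manifest.json")
  } else dir_or_manifest
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  m <- jsonlite::fromJSON(manifest, simplifyVector = TRUE)
  if (is.null(m$files) || length(m$files) == 0L) {
    stop("manifest lists no frame files", call. = FALSE)
  }
  base <- dirname(manifest)
  imgs <- lapply(file.path(base, m$files), read_depth_image)
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != m$height) || any(dims[2, ] != m$width)) {
    stop(sprintf("frame size mismatch: manifest says %dx%d, files range %s",
                 m$height, m$width,
                 paste(unique(apply(dims, 2, paste, collapse = "x")),
                       collapse = ", ")), call. = FALSE)
  }
  arr <- array(unlist(imgs, use.names = FALSE),
               dim = c(m$height, m$width, length(imgs)))
  depth_stack(arr, fps = m$fps %||% 30,
              invalid_sentinel = m$invalid_sentinel %||% 0L)
}

#' Write a depth-frame stack to a manifest directory
#'
#' Each frame is stored as an uncompressed 16-bit grayscale TIFF so depth
#' values round-trip bit-exactly; `manifest.json` records the frame order
#' and geometry.
#'
#' @param stack A [depth_stack()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_depth_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "depth_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$frames)
  files <- sprintf("frame_%05d.tif", seq_len(d[3]))
  for (t in seq_len(d[3])) {
    tiff::writeTIFF(stack$frames[, , t] / 65535, file.path(dir, files[t]),
                    bits.per.sample = 16L, compression = "none")
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(width = d[2], height = d[1], fps = stack$fps,
         invalid_sentinel = 0L, format = "tiff16", files = files),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read condition metadata
#'
#' Condition metadata records, per recording, the lighting configuration and
#' the measured mean illuminance (lux) and infrared intensity (unitless).
#' Accepts a JSON array of records or a CSV with columns `label`,
#' `ceiling_light`, `infrared_lamp`, `blinds`, `mean_illuminance`,
#' `mean_infrared_intensity`.
#'
#' @param path Path to a JSON or CSV sidecar file.
#' @return A data.frame, one row per recording.
#' @export
read_condition_metadata <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("label", "mean_illuminance", "mean_infrared_intensity")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop("condition metadata lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$mean_illuminance < 0) || any(df$mean_infrared_intensity < 0)) {
    stop("illuminance and infrared intensity must be non-negative",
         call. = FALSE)
  }
  df
}
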