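#' Multi-animal pose track
#'
#' A `pose_track` holds per-frame 2-D pixel coordinates for every
#' (individual, body part) combination, with missing detections stored as
#' `NA` for both coordinates. Coordinates are image-pixel coordinates with
#' the origin at the top-left corner, x increasing rightward and y
#' increasing downward; frames are 0-based to match the pose-tool
#' ecosystem the files come from.
#'
#' @param coords Numeric array with dimensions
#'   `c(n_frames, n_individuals, n_bodyparts, 2)`; the last margin is
#'   `(x, y)`. A keypoint is missing iff both x and y are `NA`.
#' @param individuals Character vector of unique identity labels, one per
#'   slice of the second margin.
#' @param bodyparts Character vector of unique body-part labels (the same
#'   list for every individual), one per slice of the third margin.
#' @param confidence Optional numeric array `c(n_frames, n_individuals,
#'   n_bodyparts)` with values in `[0, 1]`; `NA` wherever the keypoint is
#'   missing.
#' @param frame_rate Optional frames/second, used for time-based frame
#'   range selection.
#'
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(coords, individuals, bodyparts, confidence = NULL,
                       frame_rate = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 4L || dim(coords)[4] != 2L)
    stop("`coords` must be an array of dimension (frames, individuals, bodyparts, 2)")
  individuals <- as.character(individuals)
  bodyparts <- as.character(bodyparts)
  if (dim(coords)[2] != length(individuals))
    stop("second margin of `coords` (", dim(coords)[2],
         ") does not match length(individuals) (", length(individuals), ")")
  if (dim(coords)[3] != length(bodyparts))
    stop("third margin of `coords` (", dim(coords)[3],
         ") does not match length(bodyparts) (", length(bodyparts), ")")
  if (anyDuplicated(individuals))
    stop("individual labels must be unique")
  if (anyDuplicated(bodyparts))
    stop("bodypart labels must be unique")
  storage.mode(coords) <- "double"
  # never half-missing: exactly one of (x, y) NA is invalid
  half <- xor(is.na(coords[, , , 1, drop = FALSE]),
              is.na(coords[, , , 2, drop = FALSE]))
  if (any(half))
    stop("half-missing keypoints: x and y must be both finite or both NA")
  if (!is.null(confidence)) {
    confidence <- array(as.double(confidence), dim = dim(coords)[1:3])
    bad <- !is.na(confidence) & (confidence < 0 | confidence > 1)
    if (any(bad)) stop("confidence values must lie in [0, 1]")
    # confidence for a MISSING keypoint is itself missing
    confidence[is.na(coords[, , , 1])] <- NA_real_
  }
  dimnames(coords) <- list(NULL, individuals, bodyparts, c("x", "y"))
  structure(
    list(coords = coords, individuals = individuals, bodyparts = bodyparts,
         confidence = confidence, frame_rate = frame_rate),
    class = "pose_track"
  )
}

#' @export
print.pose_track <- function(x, ...) {
  d <- dim(x$coords)
  miss <- sum(is.na(x$coords[, , , 1]))
  cat(sprintf(
    "<pose_track> %d frames x %d individuals x %d bodyparts (%d/%d keypoints missing)\n",
    d[1], d[2], d[3], miss, prod(d[1:3])))
  cat(" individuals:", paste(x$individuals, collapse = ", "), "\n")
  cat(" bodyparts:  ", paste(x$bodyparts, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pose_track
#' @param x Object to test.
#' @export
is_pose_track <- function(x) inherits(x, "pose_track")

#' Number of frames in a pose track
#' @param track A [pose_track()].
#' @return Integer frame count.
#' @export
n_frames <- function(track) {
  stopifnot(is_pose_track(track))
  dim(track$coords)[1]
}

#' Logical array of missing keypoints
#' @param track A [pose_track()].
#' @return Logical array `(frames, individuals, bodyparts)`; `TRUE` where
#'   the keypoint is missing.
#' @export
is_missing_kp <- function(track) {
  stopifnot(is_pose_track(track))
  m <- is.na(track$coords[, , , 1, drop = FALSE])
  dim(m) <- dim(track$coords)[1:3]
  dimnames(m) <- dimnames(track$coords)[1:3]
  m
}

# internal: fetch the (x, y) pair for one cell using 1-based frame index
kp_xy <- function(track, frame, individual, bodypart) {
  track$coords[frame, individual, bodypart, ]
}

#' Ground-truth scene
#'
#' Wraps a manually annotated [pose_track()] together with its position in
#' the source video. Identity-switch evaluation requires consecutive
#' frames.
#'
#' @param track A [pose_track()] of manual annotations.
#' @param frame_offset 0-based index of the first scene frame in the
#'   source video.
#' @param is_consecutive Logical; `TRUE` when the scene frames are
#'   consecutive video frames.
#' @return An object of class `gt_scene`.
#' @export
ground_truth_scene <- function(track, frame_offset = 0L, is_consecutive = TRUE) {
  stopifnot(is_pose_track(track))
  structure(
    list(track = track, frame_offset = as.integer(frame_offset),
         is_consecutive = isTRUE(is_consecutive)),
    class = "gt_scene"
  )
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("<gt_scene> offset %d, consecutive: %s\n",
              x$frame_offset, x$is_consecutive))
  print(x$track)
  invisible(x)
}
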