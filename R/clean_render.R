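#' Set selected keypoints and frame ranges to missing
#'
#' Rewrites the selected cells of a track to missing, leaving every other
#' cell bit-identical; the operation is idempotent. This is the cleaning
#' step used to drop stray or redundant keypoints (e.g. identity slots
#' whose animal has left the arena) before rendering marker videos.
#'
#' Frame ranges can be given directly (1-based indices) or as a time
#' interval with a frame rate, in which case the affected frames are
#' those whose timestamp `((frame - 1) / fps)` lies inside
#' `[time_range[1], time_range[2]]`.
#'
#' @param track A [pose_track()].
#' @param bodyparts Body-part labels (or indices) to clear; `NULL` = all.
#' @param individuals Individual labels (or indices) to clear; `NULL` =
#'   all.
#' @param frames Integer vector of 1-based frame indices; `NULL` = all
#'   (unless `time_range` is given).
#' @param time_range Length-2 numeric `(t_start, t_end)` in seconds,
#'   converted with `fps`.
#' @param fps Frames per second for `time_range`; defaults to the track's
#'   `frame_rate`.
#' @return The modified [pose_track()].
#' @export
delete_range <- function(track, bodyparts = NULL, individuals = NULL,
                         frames = NULL, time_range = NULL, fps = NULL) {
  stopifnot(is_pose_track(track))
  nf <- n_frames(track)
  if (!is.null(time_range)) {
    if (!is.null(frames)) stop("give either frames or time_range, not both")
    fps <- fps %||% track$frame_rate
    if (is.null(fps)) stop("time_range requires fps (or a track frame_rate)")
    frames <- time_to_frames(time_range, fps, nf)
  }
  if (is.null(frames)) frames <- seq_len(nf)
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > nf))
    stop("range error: frames outside 1..", nf, " (no partial application)")
  bp <- resolve_labels(bodyparts, track$bodyparts, "bodypart")
  ind <- resolve_labels(individuals, track$individuals, "individual")
  track$coords[frames, ind, bp, ] <- NA_real_
  if (!is.null(track$confidence))
    track$confidence[frames, ind, bp] <- NA_real_
  track
}

# frames whose timestamp (frame - 1)/fps falls inside [t0, t1] (1-based)
time_to_frames <- function(time_range, fps, nf) {
  t0 <- time_range[1]; t1 <- time_range[2]
  stopifnot(t0 <= t1)
  first <- ceiling(t0 * fps - 1e-9) + 1L
  last <- floor(t1 * fps + 1e-9) + 1L
  first <- max(1L, first); last <- min(nf, last)
  if (first > last) integer() else seq(first, last)
}

resolve_labels <- function(sel, labels, what) {
  if (is.null(sel)) return(seq_along(labels))
  idx <- if (is.numeric(sel)) as.integer(sel) else match(sel, labels)
  if (anyNA(idx) || any(idx < 1L | idx > length(labels)))
    stop("config error: unknown ", what, ": ",
         paste(sel[is.na(idx) | idx < 1L | idx > length(labels)],
               collapse = ", "))
  idx
}

#' Keep only the designated body parts
#'
#' Sets every body part outside `bodyparts` to missing for all
#' individuals and frames; the designated parts are untouched. This is
#' how a full pose track is reduced to its virtual-marker keypoints
#' before rendering a marker video.
#'
#' @param track A [pose_track()].
#' @param bodyparts Non-empty set of body-part labels (or indices) to
#'   keep.
#' @return The modified [pose_track()].
#' @export
keep_only <- function(track, bodyparts) {
  stopifnot(is_pose_track(track), length(bodyparts) >= 1L)
  keep <- resolve_labels(bodyparts, track$bodyparts, "bodypart")
  drop <- setdiff(seq_along(track$bodyparts), keep)
  if (length(drop) == 0L) return(track)
  delete_range(track, bodyparts = drop)
}

#' Built-in marker palettes
#'
#' Explicit RGB palettes (values in `[0, 1]`) approximating the palettes
#' commonly used by pose-tracking viewers; defined as fixed lists so
#' rendering is bit-exact and not tied to any plotting tool.
#'
#' @param name One of `"standard"`, `"alphabet"`, `"gray"`, `"rainbow"`.
#' @param n Number of colors required.
#' @return An `n` x 3 matrix of RGB values in `[0, 1]`.
#' @export
marker_palette <- function(name = c("standard", "alphabet", "gray",
                                    "rainbow"), n) {
  name <- match.arg(name)
  base <- switch(name,
    standard = matrix(c(
      1, 0, 0,   0, 1, 0,   0, 0, 1,   0, 1, 1,   1, 0, 1,   1, 1, 0,
      1, 0.5, 0, 0.5, 0, 1, 0, 0.5, 0, 0.5, 0.25, 0), ncol = 3, byrow = TRUE),
    alphabet = matrix(c(
      0.94, 0.64, 1,    0, 0.46, 0.86,  0.6, 0.25, 0,   0.3, 0, 0.36,
      0.1, 0.1, 0.1,    0, 0.36, 0.19,  0.17, 0.81, 0.28, 1, 0.8, 0.6,
      0.5, 0.5, 0.5,    0.58, 1, 0.71,  0.56, 0.49, 0,   0.62, 0.8, 0), ncol = 3,
      byrow = TRUE),
    gray = NULL, rainbow = NULL)
  if (name == "gray") {
    g <- if (n == 1) 0.5 else seq(0.15, 0.95, length.out = n)
    return(cbind(g, g, g, deparse.level = 0))
  }
  if (name == "rainbow") {
    h <- seq(0, 1 - 1 / n, length.out = n)
    return(t(vapply(h, function(hh) hsv_to_rgb(hh, 1, 1), numeric(3))))
  }
  if (n > nrow(base)) base <- base[((seq_len(n) - 1) %% nrow(base)) + 1, ,
                                   drop = FALSE]
  base[seq_len(n), , drop = FALSE]
}

hsv_to_rgb <- function(h, s, v) {
  c <- grDevices::hsv(h, s, v)
  as.numeric(grDevices::col2rgb(c)) / 255
}

#' Marker rendering specification
#'
#' @param marker_parts Body parts drawn as markers; `NULL` = all.
#' @param radius Marker radius in pixels (>= 1).
#' @param palette Palette name for [marker_palette()] or an explicit
#'   n x 3 RGB matrix.
#' @param color_by `"individual"` (marker video / identity colors) or
#'   `"bodypart"`.
#' @param draw_skeleton Reserved; must stay `FALSE` (no skeleton output).
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(marker_parts = NULL, radius = 2,
                        palette = "standard",
                        color_by = c("individual", "bodypart"),
                        draw_skeleton = FALSE) {
  stopifnot(radius >= 1)
  if (isTRUE(draw_skeleton)) stop("skeleton drawing is not supported")
  structure(list(marker_parts = marker_parts, radius = radius,
                 palette = palette, color_by = match.arg(color_by),
                 draw_skeleton = FALSE),
            class = "marker_spec")
}

#' Blank canvas frame source
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames.
#' @param bg Background RGB (length 3, values in `[0, 1]`).
#' @return List of `height x width x 3` arrays.
#' @export
blank_canvas <- function(width, height, n_frames = 1, bg = c(0, 0, 0)) {
  frame <- array(rep(bg, each = height * width), dim = c(height, width, 3))
  rep(list(frame), n_frames)
}

#' Render marker discs onto frames
#'
#' Draws a filled disc of each individual's (or body part's) color at
#' every non-missing designated keypoint. Centers are rounded to integer
#' pixels and no anti-aliasing is applied, so output pixels are exactly
#' the marker color within the radius and untouched beyond it; missing
#' keypoints draw nothing. Output frame count and size equal the input.
#'
#' @param frames List of `height x width x 3` RGB arrays (e.g. from
#'   [blank_canvas()] or [read_png_frames()]).
#' @param track A [pose_track()]; frame `f` of the track is drawn onto
#'   `frames[[f]]`; the track may not have more frames than the source.
#' @param spec A [marker_spec()].
#' @return List of rendered frames (same length and sizes as `frames`).
#' @export
render_markers <- function(frames, track, spec = marker_spec()) {
  stopifnot(is.list(frames), is_pose_track(track),
            inherits(spec, "marker_spec"))
  if (n_frames(track) > length(frames))
    stop("render error: track has more frames than the video source")
  dims <- dim(frames[[1]])
  if (any(!vapply(frames, function(f) identical(dim(f), dims), logical(1))))
    stop("render error: inconsistent frame sizes")
  h <- dims[1]; w <- dims[2]
  parts <- resolve_labels(spec$marker_parts, track$bodyparts, "bodypart")
  ni <- length(track$individuals)
  n_colors <- if (spec$color_by == "individual") ni else length(parts)
  pal <- if (is.matrix(spec$palette)) spec$palette
    else marker_palette(spec$palette, n_colors)
  if (nrow(pal) < n_colors) stop("palette has too few colors")
  r <- spec$radius
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  out <- frames
  for (f in seq_len(n_frames(track))) {
    fr <- out[[f]]
    for (i in seq_len(ni)) for (k in seq_along(parts)) {
      xy <- track$coords[f, i, parts[k], ]
      if (anyNA(xy)) next
      cx <- as.integer(round(xy[1])); cy <- as.integer(round(xy[2]))
      px <- cx + off$dx; py <- cy + off$dy
      ok <- px >= 0 & px < w & py >= 0 & py < h
      if (!any(ok)) next
      col <- pal[if (spec$color_by == "individual") i else k, ]
      # rows are y (0-based -> +1), columns x
      idx <- cbind(py[ok] + 1L, px[ok] + 1L)
      for (ch in 1:3) fr[cbind(idx, ch)] <- col[ch]
    }
    out[[f]] <- fr
  }
  out
}

#' Overlay tracking results onto frames
#'
#' Identical drawing to [render_markers()] with per-body-part coloring by
#' default, used to draw final tracking labels onto the original
#' marker-free video; marker pixel positions depend only on the track,
#' so overlaying onto the original or the marker video gives identical
#' positions.
#'
#' @inheritParams render_markers
#' @export
overlay_tracking <- function(frames, track, spec = marker_spec(
                               color_by = "bodypart")) {
  render_markers(frames, track, spec)
}

#' Write frames as a lossless PNG sequence
#' @param frames List of RGB arrays.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_png_frames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%05d.png", prefix,
                                  seq_along(frames) - 1L))
  for (k in seq_along(frames)) png::writePNG(frames[[k]], paths[k])
  invisible(paths)
}

#' Read a PNG frame sequence
#' @param paths PNG file paths in frame order.
#' @return List of `height x width x 3` RGB arrays.
#' @export
read_png_frames <- function(paths) {
  lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    if (dim(a)[3] > 3L)  # drop alpha channel
      a <- array(a[, , 1:3], dim = c(dim(a)[1:2], 3))
    a
  })
}
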