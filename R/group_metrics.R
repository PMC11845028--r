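#' Variance of adjacent-keypoint distances along a body axis
#'
#' For a chain of keypoints ordered head to tail, computes the population
#' variance of the adjacent-keypoint Euclidean distances. With equidistant
#' tracking along the body axis, non-uniform spacing signals inaccurate
#' tracking, so greater variance is read as lower accuracy. Any missing
#' chain keypoint makes the statistic missing for that frame.
#'
#' @param kp Numeric matrix (n x 2) of the chain keypoints of one animal
#'   in one frame, head first; `n >= 3`.
#' @return Variance in px^2, or `NA` when fewer than 3 keypoints are
#'   observed.
#' @export
adjacent_distance_variance <- function(kp) {
  kp <- matrix(as.numeric(kp), ncol = 2)
  if (nrow(kp) < 3L) stop("need at least 3 chain keypoints")
  if (anyNA(kp)) return(NA_real_)
  d <- sqrt(rowSums(diff(kp)^2))
  mean((d - mean(d))^2)   # population variance over the (n - 1) distances
}

#' Per-frame, per-individual chain-spacing variance for a whole track
#' @param track A [pose_track()] whose bodyparts are the ordered chain.
#' @return Numeric matrix (frames x individuals) of variances.
#' @export
track_adjacent_variance <- function(track) {
  stopifnot(is_pose_track(track))
  nf <- n_frames(track); ni <- length(track$individuals)
  out <- matrix(NA_real_, nf, ni, dimnames = list(NULL, track$individuals))
  for (f in seq_len(nf)) for (i in seq_len(ni))
    out[f, i] <- adjacent_distance_variance(
      matrix(track$coords[f, i, , ], ncol = 2))
  out
}

#' Upper-fence outlier threshold and per-individual outlier counts
#'
#' The outlier threshold is determined by the interquartile-range method
#' (type-7 linear-interpolation quantiles) on a pooled reference: upper
#' fence = Q3 + 1.5 IQR. Only the upper fence is used, since only large
#' spacing variance signals tracking failure. Per-individual counts are
#' the numbers of frames whose value strictly exceeds the fence.
#'
#' @param values Numeric matrix (frames x individuals) or vector per
#'   individual; `NA`s ignored in counting.
#' @param pooled_reference Numeric vector the fence is computed from
#'   (e.g. the values of all compared conditions pooled); `NA`s dropped.
#' @return List with `threshold` and `counts` (per individual).
#' @export
iqr_outlier_count <- function(values, pooled_reference) {
  pooled_reference <- pooled_reference[!is.na(pooled_reference)]
  if (length(pooled_reference) == 0L)
    stop("pooled reference has no observed values")
  q <- stats::quantile(pooled_reference, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  values <- as.matrix(values)
  counts <- colSums(values > fence, na.rm = TRUE)
  list(threshold = fence, counts = counts)
}

#' Heading angle from two anterior keypoints
#'
#' Angle, in radians in `(-pi, pi]`, of the vector from the second
#' keypoint to the anterior (head) keypoint, in standard mathematical
#' convention on raw pixel coordinates. All downstream metrics are
#' differences of angles, which are invariant to the image y-axis
#' pointing down, so no axis flip is applied.
#'
#' @param anterior,second Length-2 numeric `(x, y)` points.
#' @return Radians, or `NA` when either point is missing or the points
#'   coincide.
#' @export
heading_angle <- function(anterior, second) {
  if (anyNA(anterior) || anyNA(second)) return(NA_real_)
  dx <- anterior[1] - second[1]; dy <- anterior[2] - second[2]
  if (dx == 0 && dy == 0) return(NA_real_)
  atan2(dy, dx)
}

#' Per-frame, per-individual headings for a whole track
#' @param track A [pose_track()].
#' @param anterior_part,second_part Body-part names of the two anterior
#'   keypoints (defaults: the first two bodyparts).
#' @return Numeric matrix (frames x individuals) of angles in radians.
#' @export
track_headings <- function(track, anterior_part = NULL, second_part = NULL) {
  stopifnot(is_pose_track(track))
  a <- match(anterior_part %||% track$bodyparts[1], track$bodyparts)
  s <- match(second_part %||% track$bodyparts[2], track$bodyparts)
  nf <- n_frames(track); ni <- length(track$individuals)
  out <- matrix(NA_real_, nf, ni, dimnames = list(NULL, track$individuals))
  for (f in seq_len(nf)) for (i in seq_len(ni))
    out[f, i] <- heading_angle(track$coords[f, i, a, ],
                               track$coords[f, i, s, ])
  out
}

#' Group cosine similarity of headings for one frame
#'
#' Synchrony of swimming direction: the mean of `cos(theta_i - theta_j)`
#' over all unordered pairs of individuals with an observed heading.
#'
#' @param headings Numeric vector of per-individual heading angles
#'   (radians); `NA` individuals are dropped.
#' @return Value in `[-1, 1]`, or `NA` with fewer than 2 observed
#'   headings.
#' @export
group_cos_sim <- function(headings) {
  h <- headings[!is.na(headings)]
  n <- length(h)
  if (n < 2L) return(NA_real_)
  pr <- utils::combn(n, 2)
  mean(cos(h[pr[1, ]] - h[pr[2, ]]))
}

#' Count abrupt heading changes along a frame sequence
#'
#' Counts consecutive-frame pairs whose absolute angular difference,
#' wrapped to `[0, 180]` degrees, exceeds `limit`. Between-frame heading
#' flips beyond 90 degrees are rare in real swimming and indicate
#' tracking errors. Pairs involving a missing heading are skipped.
#'
#' @param angles Numeric vector of per-frame headings (radians),
#'   consecutive frames.
#' @param limit Limit in degrees (default 90).
#' @return Integer count.
#' @export
heading_flip_count <- function(angles, limit = 90) {
  if (length(angles) < 2L) return(0L)
  a <- angles[-length(angles)]; b <- angles[-1]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(0L)
  diff_deg <- abs(atan2(sin(b[keep] - a[keep]), cos(b[keep] - a[keep]))) *
    180 / pi
  sum(diff_deg > limit)
}

#' Standardized intra-pose distance matrix
#'
#' All pairwise Euclidean distances between one individual's keypoints in
#' one frame, with the observed upper-triangle entries standardized to
#' mean 0 and SD 1 (z-scored). Standardization makes the matrix invariant
#' to rigid motion and uniform scaling, so poses of differently sized
#' individuals become comparable. Missing keypoints propagate `NA`
#' entries which are excluded from the standardization.
#'
#' @param kp Numeric matrix (n x 2) of one individual's keypoints;
#'   `n >= 3` observed points required.
#' @return Symmetric n x n matrix of standardized distances, `NA`
#'   diagonal.
#' @export
standardized_distance_matrix <- function(kp) {
  kp <- matrix(as.numeric(kp), ncol = 2)
  n <- nrow(kp)
  obs <- !is.na(kp[, 1]) & !is.na(kp[, 2])
  if (sum(obs) < 3L)
    stop("need at least 3 observed keypoints for a distance matrix")
  D <- as.matrix(stats::dist(kp))
  diag(D) <- NA_real_
  up <- upper.tri(D)
  vals <- D[up]
  ok <- !is.na(vals)
  s <- stats::sd(vals[ok])
  if (!is.finite(s) || s < 1e-9 * mean(vals[ok]))
    stop("degenerate pose: all pairwise distances equal")
  z <- (vals - mean(vals[ok])) / s
  D[up] <- z
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

#' RMSD between two standardized distance matrices
#'
#' Root-mean-square difference over the upper-triangle entries present in
#' both matrices; the more similar two poses, the smaller the RMSD.
#'
#' @param matrix_a,matrix_b Matrices from
#'   [standardized_distance_matrix()] over identical keypoint sets.
#' @return Nonnegative value, or `NA` when no entry is present in both.
#' @export
pose_rmsd <- function(matrix_a, matrix_b) {
  stopifnot(identical(dim(matrix_a), dim(matrix_b)))
  up <- upper.tri(matrix_a)
  a <- matrix_a[up]; b <- matrix_b[up]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  sqrt(mean((a[ok] - b[ok])^2))
}

#' Mean pose RMSD across all individual pairs of one frame
#'
#' @param track A [pose_track()].
#' @param frame 1-based frame index.
#' @return List with `pairs` (data frame `a`, `b`, `rmsd`) and
#'   `mean_rmsd` over all unordered pairs (pairs with too few observed
#'   keypoints are `NA` and excluded from the mean).
#' @export
frame_mean_rmsd <- function(track, frame) {
  stopifnot(is_pose_track(track))
  ni <- length(track$individuals)
  mats <- vector("list", ni)
  for (i in seq_len(ni)) {
    mats[[i]] <- tryCatch(
      standardized_distance_matrix(matrix(track$coords[frame, i, , ],
                                          ncol = 2)),
      error = function(e) NULL)
  }
  pr <- utils::combn(ni, 2)
  rmsd <- apply(pr, 2, function(p) {
    if (is.null(mats[[p[1]]]) || is.null(mats[[p[2]]])) NA_real_
    else pose_rmsd(mats[[p[1]]], mats[[p[2]]])
  })
  list(pairs = data.frame(a = pr[1, ], b = pr[2, ], rmsd = rmsd),
       mean_rmsd = if (all(is.na(rmsd))) NA_real_ else mean(rmsd, na.rm = TRUE))
}

#' Overlap frequency of same-named keypoints of two individuals
#'
#' Fraction of frames in which the distance between the two individuals'
#' same-named keypoint is strictly less than the threshold. Frames where
#' either keypoint is missing are excluded from both numerator and
#' denominator. Used to quantify stray keypoints latching onto a
#' remaining animal when their own target has left the frame.
#'
#' @param track A [pose_track()].
#' @param id_pair Length-2 vector of individual labels or indices.
#' @param bodypart Body-part label.
#' @param threshold Pixels (default 10); strict `<` comparison.
#' @return Fraction in `[0, 1]`, or `NA` when no frame has both observed.
#' @export
overlap_frequency <- function(track, id_pair, bodypart, threshold = 10) {
  stopifnot(is_pose_track(track), length(id_pair) == 2L)
  ids <- if (is.numeric(id_pair)) as.integer(id_pair)
    else match(id_pair, track$individuals)
  if (anyNA(ids)) stop("unknown individual in id_pair")
  b <- if (is.numeric(bodypart)) as.integer(bodypart)
    else match(bodypart, track$bodyparts)
  if (is.na(b)) stop("config error: bodypart not present in track")
  p1 <- matrix(track$coords[, ids[1], b, ], ncol = 2)
  p2 <- matrix(track$coords[, ids[2], b, ], ncol = 2)
  d <- sqrt(rowSums((p1 - p2)^2))
  ok <- !is.na(d)
  if (!any(ok)) return(NA_real_)
  mean(d[ok] < threshold)
}

#' Tidy per-frame fish-school metrics for a track
#'
#' Computes, per frame: each individual's chain-spacing variance and
#' heading, the group cosine similarity, and per individual the heading
#' flip count over the whole sequence.
#'
#' @param track A [pose_track()] with chain-ordered bodyparts.
#' @param flip_limit Degrees for [heading_flip_count()] (default 90).
#' @return List with `variance` (frames x individuals), `headings`
#'   (frames x individuals), `cos_sim` (per frame), `flip_counts`
#'   (per individual).
#' @export
school_metrics <- function(track, flip_limit = 90) {
  v <- track_adjacent_variance(track)
  h <- track_headings(track)
  cs <- apply(h, 1, group_cos_sim)
  flips <- apply(h, 2, heading_flip_count, limit = flip_limit)
  list(variance = v, headings = h, cos_sim = cs, flip_counts = flips)
}
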