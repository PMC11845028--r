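#' Evaluation configuration
#'
#' Thresholds and body-part roles for keypoint and centroid evaluation.
#' Defaults follow the established convention for this evaluation scheme:
#' a 10-pixel keypoint match threshold and a 20-pixel centroid threshold
#' against the mid-body-axis ground-truth points. Threshold comparisons
#' are inclusive (distance <= threshold counts as "within").
#'
#' @param kp_threshold Keypoint match threshold in pixels (> 0).
#' @param centroid_threshold Centroid match threshold in pixels (> 0).
#' @param centroid_parts Body parts averaged into the predicted centroid;
#'   `NULL` means all body parts.
#' @param axis_parts Ground-truth body-axis parts a centroid is matched
#'   against; `NULL` means the 3 middle parts of the body-part list.
#' @param rmse_matches_only If `TRUE`, RMSE is computed over matches only
#'   instead of all non-missing predictions with annotated corresponding
#'   ground truth.
#' @return An `eval_config` list.
#' @export
eval_config <- function(kp_threshold = 10, centroid_threshold = 20,
                        centroid_parts = NULL, axis_parts = NULL,
                        rmse_matches_only = FALSE) {
  stopifnot(kp_threshold > 0, centroid_threshold > 0)
  structure(list(kp_threshold = kp_threshold,
                 centroid_threshold = centroid_threshold,
                 centroid_parts = centroid_parts, axis_parts = axis_parts,
                 rmse_matches_only = isTRUE(rmse_matches_only)),
            class = "eval_config")
}

verdict_levels <- c("MATCH", "FN", "DEVIATING_FP", "ID_MISMATCH_FP",
                    "BODYPART_MISMATCH_FP")

#' Classify every keypoint against ground truth
#'
#' Produces one verdict per annotated (ground-truth individual, body
#' part, frame) cell, after identities have been paired scene-globally:
#'
#' * missing prediction -> `FN`;
#' * within threshold of its corresponding ground-truth keypoint (same
#'   assigned identity, same body part) -> `MATCH`, even if other
#'   ground-truth keypoints are nearer (the corresponding point takes
#'   priority);
#' * otherwise the nearest ground-truth keypoint within threshold decides
#'   the false-positive subtype: same body part, different identity ->
#'   `ID_MISMATCH_FP`; different body part (any identity) ->
#'   `BODYPART_MISMATCH_FP`; distance ties broken by identity index then
#'   body-part index;
#' * within threshold of no ground-truth keypoint -> `DEVIATING_FP`.
#'
#' @param pred A [pose_track()] of predictions.
#' @param gt A [ground_truth_scene()] or [pose_track()].
#' @param assignment An `id_assignment` from [pair_ids()] covering the
#'   predicted individuals; `NULL` computes it.
#' @param cfg An [eval_config()].
#' @return Data frame with columns `frame` (1-based), `gt_individual`,
#'   `bodypart`, `pred_individual` (indices), `verdict`, `matched_ind`,
#'   `matched_bp` (the ground-truth keypoint used for evaluation; `NA`
#'   for `FN`/`DEVIATING_FP`), `distance` (px to the corresponding
#'   ground-truth keypoint) and `id_switch` (filled by
#'   [detect_id_switches()], `FALSE` here).
#' @export
classify_keypoints <- function(pred, gt, assignment = NULL,
                               cfg = eval_config()) {
  gt_track <- if (inherits(gt, "gt_scene")) gt$track else gt
  stopifnot(is_pose_track(pred), is_pose_track(gt_track),
            inherits(cfg, "eval_config"))
  if (!identical(pred$bodyparts, gt_track$bodyparts))
    stop("schema error: predicted and ground-truth bodypart lists differ")
  if (is.null(assignment)) assignment <- pair_ids(pred, gt_track)
  nf <- n_frames(gt_track)
  ng <- length(gt_track$individuals)
  nb <- length(gt_track$bodyparts)
  tau <- cfg$kp_threshold
  # pred individual serving each gt individual (NA when unassigned)
  pred_of_gt <- rep(NA_integer_, ng)
  pred_of_gt[assignment$pairs$gt] <- assignment$pairs$pred

  out <- vector("list", nf)
  # cell order within a frame: individual-major (j varies slower than b)
  cell_ind <- rep(seq_len(ng), each = nb)
  cell_bp <- rep(seq_len(nb), times = ng)
  for (f in seq_len(nf)) {
    # flatten frame f ground truth as (cell = (j, b)) rows, individual-major
    Gx <- gt_track$coords[f, , , 1, drop = FALSE]; dim(Gx) <- c(ng, nb)
    Gy <- gt_track$coords[f, , , 2, drop = FALSE]; dim(Gy) <- c(ng, nb)
    G <- cbind(as.vector(t(Gx)), as.vector(t(Gy)))
    annotated <- !is.na(G[, 1])
    P <- matrix(NA_real_, ng * nb, 2)
    ok <- !is.na(pred_of_gt[cell_ind])
    P[ok, 1] <- pred$coords[cbind(f, pred_of_gt[cell_ind[ok]], cell_bp[ok], 1L)]
    P[ok, 2] <- pred$coords[cbind(f, pred_of_gt[cell_ind[ok]], cell_bp[ok], 2L)]
    d0 <- sqrt(rowSums((P - G)^2))
    verdict <- rep(NA_character_, ng * nb)
    matched_ind <- rep(NA_integer_, ng * nb)
    matched_bp <- rep(NA_integer_, ng * nb)
    pred_missing <- is.na(P[, 1])
    verdict[pred_missing] <- "FN"
    is_match <- !pred_missing & !is.na(d0) & d0 <= tau
    verdict[is_match] <- "MATCH"
    matched_ind[is_match] <- cell_ind[is_match]
    matched_bp[is_match] <- cell_bp[is_match]
    todo <- which(annotated & is.na(verdict))
    if (length(todo)) {
      Gann <- G[annotated, , drop = FALSE]
      ann_idx <- which(annotated)
      for (cc in todo) {
        dd <- sqrt((Gann[, 1] - P[cc, 1])^2 + (Gann[, 2] - P[cc, 2])^2)
        within <- which(dd <= tau)
        if (length(within) == 0L) {
          verdict[cc] <- "DEVIATING_FP"
        } else {
          cand <- ann_idx[within]
          ordc <- order(dd[within], cell_ind[cand], cell_bp[cand])
          best <- cand[ordc[1]]
          matched_ind[cc] <- cell_ind[best]
          matched_bp[cc] <- cell_bp[best]
          verdict[cc] <- if (cell_bp[best] == cell_bp[cc])
            "ID_MISMATCH_FP" else "BODYPART_MISMATCH_FP"
        }
      }
    }
    keep <- annotated
    out[[f]] <- data.frame(
      frame = f,
      gt_individual = cell_ind[keep],
      bodypart = cell_bp[keep],
      pred_individual = pred_of_gt[cell_ind[keep]],
      verdict = verdict[keep],
      matched_ind = matched_ind[keep],
      matched_bp = matched_bp[keep],
      distance = d0[keep],
      id_switch = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gt_individual, res$bodypart, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag identity switches in a verdict sequence
#'
#' For each (ground-truth individual, body part) series ordered by frame,
#' a cell whose evaluation landed on a ground-truth keypoint (`MATCH`,
#' `ID_MISMATCH_FP`, `BODYPART_MISMATCH_FP`) is flagged as an identity
#' switch when its matched ground-truth identity differs from the most
#' recent earlier frame in which that cell had a matched identity;
#' intervening `FN` and `DEVIATING_FP` frames are carried across. The
#' first identified frame of a series is never a switch.
#'
#' @param verdicts Output of [classify_keypoints()].
#' @param consecutive Logical; scenes with non-consecutive frames cannot
#'   be evaluated for switches and raise an error.
#' @return `verdicts` with `id_switch` filled in.
#' @export
detect_id_switches <- function(verdicts, consecutive = TRUE) {
  if (!isTRUE(consecutive))
    stop("scene frames are not consecutive: identity switches not evaluable")
  verdicts <- verdicts[order(verdicts$gt_individual, verdicts$bodypart,
                             verdicts$frame), , drop = FALSE]
  key <- paste(verdicts$gt_individual, verdicts$bodypart)
  verdicts$id_switch <- FALSE
  for (series in split(seq_len(nrow(verdicts)), key)) {
    last <- NA_integer_
    for (r in series) {
      mi <- verdicts$matched_ind[r]
      if (!is.na(mi)) {
        if (!is.na(last) && mi != last) verdicts$id_switch[r] <- TRUE
        last <- mi
      }
    }
  }
  rownames(verdicts) <- NULL
  verdicts
}

#' Summarize a scene's verdicts into percentage metrics
#'
#' Ground-truth-denominated percentages (target match, FN, FP and the FP
#' subtypes, identity switches) use the number of annotated ground-truth
#' keypoints; prediction-denominated percentages (predicted match,
#' body-part match) use the number of non-missing predictions. RMSE is the
#' root-mean-square distance to the corresponding ground-truth keypoint
#' over all non-missing predictions (matches plus all FP subtypes), or
#' over matches only when the configuration says so.
#'
#' @param verdicts Output of [classify_keypoints()] /
#'   [detect_id_switches()].
#' @param n_pred Number of non-missing predictions; default: the non-`FN`
#'   verdict count.
#' @param cfg An [eval_config()] (for the RMSE convention).
#' @return A `scene_metrics` list.
#' @export
summarize_scene <- function(verdicts, n_pred = NULL, cfg = eval_config()) {
  n_gt <- nrow(verdicts)
  if (is.null(n_gt) || n_gt == 0L) stop("empty scene: no annotated ground truth")
  counts <- table(factor(verdicts$verdict, levels = verdict_levels))
  n_match <- counts[["MATCH"]]; n_fn <- counts[["FN"]]
  n_dev <- counts[["DEVIATING_FP"]]; n_idm <- counts[["ID_MISMATCH_FP"]]
  n_bpm <- counts[["BODYPART_MISMATCH_FP"]]
  n_fp <- n_dev + n_idm + n_bpm
  if (is.null(n_pred)) n_pred <- n_gt - n_fn
  rmse_set <- if (cfg$rmse_matches_only) verdicts$verdict == "MATCH"
    else verdicts$verdict != "FN"
  d <- verdicts$distance[rmse_set & !is.na(verdicts$distance)]
  structure(list(
    tgt_match_pct = 100 * n_match / n_gt,
    fn_pct = 100 * n_fn / n_gt,
    fp_pct = 100 * n_fp / n_gt,
    id_switch_pct = 100 * sum(verdicts$id_switch) / n_gt,
    deviating_fp_pct = 100 * n_dev / n_gt,
    id_mismatch_fp_pct = 100 * n_idm / n_gt,
    bodypart_mismatch_fp_pct = 100 * n_bpm / n_gt,
    pred_match_pct = if (n_pred > 0) 100 * n_match / n_pred else NA_real_,
    bodypart_match_pct = if (n_pred > 0) 100 * (n_match + n_idm) / n_pred
      else NA_real_,
    rmse = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    n_gt = n_gt, n_pred = n_pred
  ), class = "scene_metrics")
}

#' @export
print.scene_metrics <- function(x, ...) {
  cat("<scene_metrics>\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]], digits = 6)))
  invisible(x)
}

#' Evaluate a predicted scene against ground truth
#'
#' Convenience wrapper: pairs identities ([pair_ids()]), classifies every
#' keypoint ([classify_keypoints()]), flags identity switches
#' ([detect_id_switches()]) and summarizes ([summarize_scene()]).
#'
#' @inheritParams classify_keypoints
#' @return List with `assignment`, `verdicts`, `metrics`.
#' @export
evaluate_scene <- function(pred, gt, cfg = eval_config(), assignment = NULL) {
  gt_scene <- if (inherits(gt, "gt_scene")) gt else ground_truth_scene(gt)
  if (is.null(assignment)) assignment <- pair_ids(pred, gt_scene)
  v <- classify_keypoints(pred, gt_scene, assignment, cfg)
  if (gt_scene$is_consecutive) v <- detect_id_switches(v)
  list(assignment = assignment, verdicts = v,
       metrics = summarize_scene(v, cfg = cfg))
}

#' Centroid of designated keypoints
#'
#' Arithmetic mean of the non-missing designated keypoints of one animal
#' in one frame; with a single available keypoint that point itself is the
#' centroid; with none available the centroid is missing (a centroid FN).
#'
#' @param kp Numeric matrix (n x 2) of keypoint coordinates, `NA` rows for
#'   missing keypoints.
#' @return Length-2 numeric `(x, y)`, or `c(NA, NA)` when no keypoint is
#'   available.
#' @export
compute_centroid <- function(kp) {
  kp <- matrix(as.numeric(kp), ncol = 2)
  ok <- !is.na(kp[, 1]) & !is.na(kp[, 2])
  if (!any(ok)) return(c(NA_real_, NA_real_))
  colMeans(kp[ok, , drop = FALSE])
}

#' Classify predicted centroids against ground-truth body-axis points
#'
#' Per individual-frame: the predicted centroid (mean of the designated
#' `centroid_parts`) is a `MATCH` when within `centroid_threshold` of any
#' body-axis part of the corresponding ground-truth individual, an
#' `ID_MISMATCH_FP` when within threshold of another individual's axis
#' parts only, a `DEVIATING_FP` when beyond threshold of all, and an `FN`
#' when no designated keypoint was available. Body-part categories,
#' identity switches and RMSE do not apply to centroids.
#'
#' @inheritParams classify_keypoints
#' @return List with `verdicts` (data frame: `frame`, `gt_individual`,
#'   `verdict`, `distance` to the nearest corresponding axis point) and
#'   `metrics` (`tgt_match_pct`, `fn_pct`, `fp_pct`, `deviating_fp_pct`,
#'   `id_mismatch_fp_pct`, `pred_match_pct`, `n_gt`, `n_pred`).
#' @export
classify_centroids <- function(pred, gt, assignment = NULL,
                               cfg = eval_config()) {
  gt_track <- if (inherits(gt, "gt_scene")) gt$track else gt
  stopifnot(is_pose_track(pred), is_pose_track(gt_track))
  axis_parts <- cfg$axis_parts
  if (is.null(axis_parts)) {
    nb <- length(gt_track$bodyparts)
    mid <- ceiling(nb / 2)
    axis_parts <- gt_track$bodyparts[pmax(1, pmin(nb, mid + (-1):1))]
  }
  if (!all(axis_parts %in% gt_track$bodyparts))
    stop("config error: axis_parts not all present in ground-truth bodyparts")
  centroid_parts <- cfg$centroid_parts %||% pred$bodyparts
  if (!all(centroid_parts %in% pred$bodyparts))
    stop("config error: centroid_parts not all present in predicted bodyparts")
  if (is.null(assignment)) assignment <- pair_ids(pred, gt_track)
  ng <- length(gt_track$individuals)
  nf <- n_frames(gt_track)
  pred_of_gt <- rep(NA_integer_, ng)
  pred_of_gt[assignment$pairs$gt] <- assignment$pairs$pred
  cp_idx <- match(centroid_parts, pred$bodyparts)
  ax_idx <- match(axis_parts, gt_track$bodyparts)
  tau <- cfg$centroid_threshold
  rows <- list()
  for (f in seq_len(nf)) for (j in seq_len(ng)) {
    i <- pred_of_gt[j]
    cen <- if (is.na(i)) c(NA_real_, NA_real_) else
      compute_centroid(pred$coords[f, i, cp_idx, ])
    ax_self <- matrix(gt_track$coords[f, j, ax_idx, ], ncol = 2)
    d_self <- suppressWarnings(
      min(sqrt(rowSums((ax_self - rep(cen, each = nrow(ax_self)))^2)),
          na.rm = TRUE))
    if (!is.finite(d_self)) d_self <- NA_real_
    if (is.na(cen[1])) {
      verdict <- "FN"
    } else if (!is.na(d_self) && d_self <= tau) {
      verdict <- "MATCH"
    } else {
      d_other <- Inf
      for (j2 in seq_len(ng)[-j]) {
        ax <- matrix(gt_track$coords[f, j2, ax_idx, ], ncol = 2)
        dd <- sqrt(rowSums((ax - rep(cen, each = nrow(ax)))^2))
        d_other <- min(d_other, dd, na.rm = TRUE)
      }
      verdict <- if (is.finite(d_other) && d_other <= tau)
        "ID_MISMATCH_FP" else "DEVIATING_FP"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, gt_individual = j, verdict = verdict, distance = d_self)
  }
  v <- do.call(rbind, rows)
  n_gt <- nrow(v)
  counts <- table(factor(v$verdict,
                         levels = c("MATCH", "FN", "DEVIATING_FP",
                                    "ID_MISMATCH_FP")))
  n_match <- counts[["MATCH"]]; n_fn <- counts[["FN"]]
  n_dev <- counts[["DEVIATING_FP"]]; n_idm <- counts[["ID_MISMATCH_FP"]]
  n_pred <- n_gt - n_fn
  metrics <- list(
    tgt_match_pct = 100 * n_match / n_gt,
    fn_pct = 100 * n_fn / n_gt,
    fp_pct = 100 * (n_dev + n_idm) / n_gt,
    deviating_fp_pct = 100 * n_dev / n_gt,
    id_mismatch_fp_pct = 100 * n_idm / n_gt,
    pred_match_pct = if (n_pred > 0) 100 * n_match / n_pred else NA_real_,
    n_gt = n_gt, n_pred = n_pred)
  list(verdicts = v, metrics = metrics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
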