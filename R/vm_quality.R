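#' Identity match status of one virtual marker
#'
#' A virtual marker matches its animal's identity when it lies within the
#' threshold distance of ANY ground-truth keypoint of the same animal; it
#' mismatches otherwise. A missing marker is `ABSENT` and counts as a
#' mismatch in the identity-match rate, since it represents a marker that
#' should have been present.
#'
#' @param marker Length-2 numeric `(x, y)` or `c(NA, NA)` when missing.
#' @param gt_keypoints Numeric matrix (n x 2) of the same animal's
#'   ground-truth keypoints (rows with `NA` are ignored).
#' @param threshold Match threshold in pixels (default 10).
#' @return One of `"MATCHED"`, `"MISMATCHED"`, `"ABSENT"`.
#' @export
vm_id_match <- function(marker, gt_keypoints, threshold = 10) {
  gt_keypoints <- matrix(as.numeric(gt_keypoints), ncol = 2)
  gt_keypoints <- gt_keypoints[!is.na(gt_keypoints[, 1]) &
                               !is.na(gt_keypoints[, 2]), , drop = FALSE]
  if (nrow(gt_keypoints) == 0L)
    stop("empty ground-truth keypoint set")
  if (anyNA(marker)) return("ABSENT")
  d2 <- (gt_keypoints[, 1] - marker[1])^2 + (gt_keypoints[, 2] - marker[2])^2
  if (any(d2 <= threshold^2)) "MATCHED" else "MISMATCHED"
}

vm_patterns <- c("MATCH_TWO_VM", "MATCH_ONE_VM", "PARTIAL_MATCH_TWO_VM",
                 "NO_MATCH_TWO_VM", "NO_MATCH_ONE_VM", "MISSING_NO_VM")

#' Six-way virtual-marker assignment pattern for one animal-frame
#'
#' Combines the identity-match statuses of an animal's two designated
#' virtual markers (symmetric in argument order): both matched ->
#' `MATCH_TWO_VM`; one matched, one mismatched -> `PARTIAL_MATCH_TWO_VM`;
#' both mismatched -> `NO_MATCH_TWO_VM`; one absent and the other matched
#' -> `MATCH_ONE_VM`; one absent and the other mismatched ->
#' `NO_MATCH_ONE_VM`; both absent -> `MISSING_NO_VM`.
#'
#' @param status_a,status_b Statuses from [vm_id_match()].
#' @return The pattern label.
#' @export
classify_vm_pattern <- function(status_a, status_b) {
  s <- sort(c(match.arg(status_a, c("MATCHED", "MISMATCHED", "ABSENT")),
              match.arg(status_b, c("MATCHED", "MISMATCHED", "ABSENT"))))
  key <- paste(s, collapse = "+")
  switch(key,
    "MATCHED+MATCHED" = "MATCH_TWO_VM",
    "MATCHED+MISMATCHED" = "PARTIAL_MATCH_TWO_VM",
    "MISMATCHED+MISMATCHED" = "NO_MATCH_TWO_VM",
    "ABSENT+MATCHED" = "MATCH_ONE_VM",
    "ABSENT+MISMATCHED" = "NO_MATCH_ONE_VM",
    "ABSENT+ABSENT" = "MISSING_NO_VM")
}

#' Scene-level virtual-marker accuracy summary
#'
#' Classifies every animal-frame's two designated markers and reports the
#' per-pattern proportions plus the identity-matched marker percentage.
#' The denominator of `id_matched_vm_pct` is the expected marker count
#' (2 x animals x frames), so absent markers depress it.
#'
#' @param vm_track A [pose_track()] whose designated `marker_parts` carry
#'   the virtual markers; individuals must correspond one-to-one (by
#'   label order) to the ground-truth individuals unless `marker_map`
#'   overrides it.
#' @param gt A [ground_truth_scene()] or [pose_track()] of annotations.
#' @param marker_parts The two designated marker body parts (default
#'   `c("kp2", "kp4")`).
#' @param threshold Match threshold in pixels (default 10).
#' @param marker_map Integer vector: `marker_map[i]` is the ground-truth
#'   individual index for vm individual `i`; default identity.
#' @return A `vm_summary` list: `per_frame` data frame (`frame`,
#'   `individual`, `status_a`, `status_b`, `pattern`), `proportions`
#'   (named, sums to 1), `id_matched_vm_pct`.
#' @export
scene_vm_summary <- function(vm_track, gt, marker_parts = c("kp2", "kp4"),
                             threshold = 10, marker_map = NULL) {
  gt_track <- if (inherits(gt, "gt_scene")) gt$track else gt
  stopifnot(is_pose_track(vm_track), is_pose_track(gt_track),
            length(marker_parts) == 2L)
  if (!all(marker_parts %in% vm_track$bodyparts))
    stop("config error: marker bodyparts ",
         paste(setdiff(marker_parts, vm_track$bodyparts), collapse = ", "),
         " not present in the track")
  ni <- length(vm_track$individuals)
  nf <- n_frames(vm_track)
  if (is.null(marker_map)) marker_map <- seq_len(ni)
  mp <- match(marker_parts, vm_track$bodyparts)
  rows <- vector("list", nf * ni)
  k <- 0L
  for (f in seq_len(nf)) for (i in seq_len(ni)) {
    g <- marker_map[i]
    gt_kp <- matrix(gt_track$coords[f, g, , ], ncol = 2)
    sa <- vm_id_match(vm_track$coords[f, i, mp[1], ], gt_kp, threshold)
    sb <- vm_id_match(vm_track$coords[f, i, mp[2], ], gt_kp, threshold)
    k <- k + 1L
    rows[[k]] <- data.frame(frame = f, individual = i, status_a = sa,
                            status_b = sb,
                            pattern = classify_vm_pattern(sa, sb))
  }
  per_frame <- do.call(rbind, rows)
  tab <- table(factor(per_frame$pattern, levels = vm_patterns))
  proportions <- as.numeric(tab) / nrow(per_frame)
  names(proportions) <- vm_patterns
  n_matched <- sum(per_frame$status_a == "MATCHED") +
    sum(per_frame$status_b == "MATCHED")
  structure(list(per_frame = per_frame, proportions = proportions,
                 id_matched_vm_pct = 100 * n_matched / (2 * nrow(per_frame))),
            class = "vm_summary")
}

#' @export
print.vm_summary <- function(x, ...) {
  cat("<vm_summary> id-matched markers:",
      sprintf("%.1f%%", x$id_matched_vm_pct), "\n")
  print(round(x$proportions, 4))
  invisible(x)
}
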