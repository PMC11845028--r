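# Two individuals, two bodyparts; GT laid out far apart so only the
# deliberately placed predictions interact with thresholds.
two_mouse_gt <- function(nf = 1) {
  pts <- replicate(nf, list(
    list(list(c(0, 0), c(100, 0))),      # placeholder, rebuilt below
    list(list(c(0, 200), c(100, 200)))
  ), simplify = FALSE)
  co <- array(NA_real_, dim = c(nf, 2, 2, 2))
  for (f in seq_len(nf)) {
    co[f, 1, 1, ] <- c(0, 0);    co[f, 1, 2, ] <- c(100, 0)
    co[f, 2, 1, ] <- c(0, 200);  co[f, 2, 2, ] <- c(100, 200)
  }
  pose_track(co, c("A", "B"), c("kp1", "kp2"))
}

pred_like <- function(gt) {
  p <- gt
  p
}

test_that("verdict priority and FP subtyping follow the taxonomy", {
  gt <- two_mouse_gt()
  cfg <- eval_config(kp_threshold = 10)
  asg <- identity_assignment(2)

  # within threshold of corresponding GT -> MATCH even if another GT is nearer
  p <- pred_like(gt)
  p$coords[1, 1, 1, ] <- c(5, 0)           # 5 px from own, far from others
  v <- classify_keypoints(p, gt, asg, cfg)
  expect_equal(v$verdict[v$gt_individual == 1 & v$bodypart == 1], "MATCH")

  # corresponding takes priority when both are within threshold
  gt2 <- gt
  gt2$coords[1, 2, 1, ] <- c(8, 0)         # wrong-ID GT 3 px from prediction
  p2 <- pred_like(gt2)
  p2$coords[1, 1, 1, ] <- c(5, 0)          # 5 px from own, 3 px from wrong ID
  v2 <- classify_keypoints(p2, gt2, asg, cfg)
  expect_equal(v2$verdict[v2$gt_individual == 1 & v2$bodypart == 1], "MATCH")

  # beyond own, within same-bodypart other-ID -> ID_MISMATCH_FP
  p3 <- pred_like(gt)
  p3$coords[1, 1, 1, ] <- c(6, 200)        # 6 px from B kp1, >10 from own
  v3 <- classify_keypoints(p3, gt, asg, cfg)
  row <- v3[v3$gt_individual == 1 & v3$bodypart == 1, ]
  expect_equal(row$verdict, "ID_MISMATCH_FP")
  expect_equal(row$matched_ind, 2)
  expect_equal(row$matched_bp, 1)

  # beyond own, within wrong bodypart (any ID) -> BODYPART_MISMATCH_FP
  p4 <- pred_like(gt)
  p4$coords[1, 1, 1, ] <- c(97, 0)         # 3 px from own kp2
  v4 <- classify_keypoints(p4, gt, asg, cfg)
  expect_equal(v4$verdict[v4$gt_individual == 1 & v4$bodypart == 1],
               "BODYPART_MISMATCH_FP")

  # beyond every GT -> DEVIATING_FP; absent -> FN
  p5 <- pred_like(gt)
  p5$coords[1, 1, 1, ] <- c(50, 100)
  p5$coords[1, 2, 2, ] <- NA
  v5 <- classify_keypoints(p5, gt, asg, cfg)
  expect_equal(v5$verdict[v5$gt_individual == 1 & v5$bodypart == 1],
               "DEVIATING_FP")
  expect_equal(v5$verdict[v5$gt_individual == 2 & v5$bodypart == 2], "FN")

  # the boundary counts as within ("within 10 pixels" is inclusive)
  p6 <- pred_like(gt)
  p6$coords[1, 1, 1, ] <- c(10, 0)
  v6 <- classify_keypoints(p6, gt, asg, cfg)
  expect_equal(v6$verdict[v6$gt_individual == 1 & v6$bodypart == 1], "MATCH")
})

test_that("classify_keypoints agrees with the naive nested-loop oracle", {
  set.seed(61)
  for (k in 1:30) {
    ng <- sample(2:4, 1); nb <- sample(3:5, 1); nf <- sample(3:8, 1)
    sc <- rand_scene(ng, nb, nf)
    asg <- identity_assignment(ng)
    got <- classify_keypoints(sc$pred, sc$gt, asg, eval_config())
    want <- oracle_classify(sc$pred, sc$gt, seq_len(ng), 10)
    expect_equal(got$verdict, want$verdict)
    expect_equal(got$matched_ind, want$matched_ind)
    expect_equal(got$matched_bp, want$matched_bp)
  }
})

test_that("identity switches use the most recent matched identity, carried across FN and deviating frames", {
  gt <- two_mouse_gt(3)
  asg <- identity_assignment(2)
  cfg <- eval_config()

  seq_to_switches <- function(frame2_kind) {
    p <- pred_like(gt)
    # A's kp1 prediction lands on A (frame 1), then frame2_kind, then on B
    p$coords[1, 1, 1, ] <- c(0, 0)
    p$coords[2, 1, 1, ] <- switch(frame2_kind,
      own = c(0, 0), fn = c(NA, NA), deviating = c(50, 100), other = c(0, 200))
    p$coords[3, 1, 1, ] <- c(0, 200)     # lands on B kp1
    v <- detect_id_switches(classify_keypoints(p, gt, asg, cfg))
    v[v$gt_individual == 1 & v$bodypart == 1, ]
  }

  # A, A, B -> switch at frame 3 only
  s <- seq_to_switches("own")
  expect_equal(s$id_switch, c(FALSE, FALSE, TRUE))
  # A, FN, A-pattern with frame 3 on B still switches (carry across the FN)
  s2 <- seq_to_switches("fn")
  expect_equal(s2$id_switch, c(FALSE, FALSE, TRUE))
  # A, DEVIATING, B -> switch at frame 3 (carry across the deviating frame)
  s3 <- seq_to_switches("deviating")
  expect_equal(s3$id_switch, c(FALSE, FALSE, TRUE))
  # A, FN, A -> no switch
  p <- pred_like(gt)
  p$coords[2, 1, 1, ] <- c(NA, NA)
  v <- detect_id_switches(classify_keypoints(p, gt, asg, cfg))
  expect_false(any(v$id_switch))
  # first identified frame is never a switch
  p2 <- pred_like(gt)
  p2$coords[1, 1, 1, ] <- c(NA, NA)
  v2 <- detect_id_switches(classify_keypoints(p2, gt, asg, cfg))
  expect_false(any(v2$id_switch))
  # non-consecutive scenes refuse switch evaluation
  expect_error(detect_id_switches(v2, consecutive = FALSE),
               "not consecutive")
})

test_that("scene summaries do the percentage arithmetic and partition exactly", {
  # constructed verdict set: 100 GT cells = 80 MATCH, 10 FN, 10 FPs
  v <- data.frame(
    frame = 1, gt_individual = 1, bodypart = 1,
    verdict = rep(c("MATCH", "FN", "DEVIATING_FP", "ID_MISMATCH_FP"),
                  c(80, 10, 6, 4)),
    matched_ind = NA, matched_bp = NA,
    distance = c(rep(2, 80), rep(NA, 10), rep(40, 6), rep(15, 4)),
    id_switch = FALSE)
  m <- summarize_scene(v)
  expect_equal(m$tgt_match_pct, 80)
  expect_equal(m$fn_pct, 10)
  expect_equal(m$fp_pct, 10)
  expect_equal(m$pred_match_pct, 100 * 80 / 90, tolerance = 1e-12)
  expect_equal(m$tgt_match_pct + m$fn_pct + m$fp_pct, 100)
  expect_equal(m$deviating_fp_pct + m$id_mismatch_fp_pct +
                 m$bodypart_mismatch_fp_pct, m$fp_pct)
  expect_equal(m$bodypart_match_pct, 100 * 84 / 90, tolerance = 1e-12)
  # RMSE over non-FN cells
  expect_equal(m$rmse, sqrt(mean(c(rep(4, 80), rep(1600, 6), rep(225, 4)))))
  # matches-only RMSE variant
  m2 <- summarize_scene(v, cfg = eval_config(rmse_matches_only = TRUE))
  expect_equal(m2$rmse, 2)
  expect_error(summarize_scene(v[0, ]), "empty scene")
})

test_that("zero FNs make target match and predicted match identical", {
  set.seed(77)
  sc <- rand_scene(3, 5, 15, pred_miss = 0)
  m <- evaluate_scene(sc$pred, sc$gt)$metrics
  expect_equal(m$fn_pct, 0)
  expect_equal(m$tgt_match_pct, m$pred_match_pct)
})

test_that("raising the threshold never decreases the target match rate", {
  set.seed(78)
  sc <- rand_scene(3, 5, 20)
  taus <- c(2, 5, 10, 20, 40)
  rates <- vapply(taus, function(t) {
    evaluate_scene(sc$pred, sc$gt, eval_config(kp_threshold = t))$
      metrics$tgt_match_pct
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("centroids average available keypoints and degrade gracefully", {
  expect_equal(compute_centroid(rbind(c(0, 0), c(2, 2))), c(1, 1))
  expect_equal(compute_centroid(rbind(c(NA, NA), c(7, 3))), c(7, 3))
  expect_equal(compute_centroid(rbind(c(NA, NA), c(NA, NA))),
               c(NA_real_, NA_real_))
})

test_that("centroid classification follows the threshold-to-axis rule", {
  # 14-part-like track reduced to 5 parts; axis = middle 3 parts
  co <- array(NA_real_, dim = c(1, 2, 5, 2))
  for (b in 1:5) {
    co[1, 1, b, ] <- c(10 * b, 100)
    co[1, 2, b, ] <- c(10 * b, 400)
  }
  gt <- pose_track(co, c("A", "B"), paste0("kp", 1:5))
  cfg <- eval_config(centroid_threshold = 20,
                     axis_parts = c("kp2", "kp3", "kp4"))
  asg <- identity_assignment(2)

  run1 <- function(pred) classify_centroids(pred, gt, asg, cfg)
  # centroid 5 px from own mid-axis point -> MATCH
  p <- gt
  p$coords[1, 1, , 1] <- p$coords[1, 1, , 1]
  p$coords[1, 1, , 2] <- p$coords[1, 1, , 2] + 5
  r <- run1(p)
  expect_equal(r$verdicts$verdict[1], "MATCH")
  # centroid far from every axis point -> DEVIATING_FP
  p2 <- gt
  p2$coords[1, 1, , 2] <- 250   # 150 px from A's axis, 150 from B's
  r2 <- run1(p2)
  expect_equal(r2$verdicts$verdict[1], "DEVIATING_FP")
  # centroid within threshold of the OTHER individual's axis only -> ID_MISMATCH_FP
  p3 <- gt
  p3$coords[1, 1, , 2] <- 390   # 10 px from B's axis
  r3 <- run1(p3)
  expect_equal(r3$verdicts$verdict[1], "ID_MISMATCH_FP")
  # all designated keypoints missing -> FN, and metrics partition
  p4 <- gt
  p4$coords[1, 1, , ] <- NA
  r4 <- run1(p4)
  expect_equal(r4$verdicts$verdict[1], "FN")
  expect_equal(r4$metrics$tgt_match_pct + r4$metrics$fn_pct +
                 r4$metrics$fp_pct, 100)
  expect_error(classify_centroids(gt, gt, asg,
                                  eval_config(axis_parts = "nope")),
               "config error")
})
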