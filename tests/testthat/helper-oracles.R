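# Independent oracles and fixture builders used across the suite.

# all permutations of 1..n, one per row
perm_all <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- matrix(ifelse(sub >= i, sub + 1L, sub), nrow(sub))
    cbind(i, shifted)
  }))
}

# exhaustive minimum assignment cost over all permutations
min_cost_brute <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(min_cost_brute(t(cost)))
  perms <- perm_all(m)
  min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p[seq_len(n)])])))
}

# trivially-structured identity assignment for n individuals
identity_assignment <- function(n) {
  structure(list(pairs = data.frame(pred = seq_len(n), gt = seq_len(n)),
                 total_cost = 0, cost = matrix(0, n, n)),
            class = "id_assignment")
}

# naive nested-loop re-implementation of the keypoint verdict taxonomy:
# exhaustive search over every ground-truth keypoint per prediction
oracle_classify <- function(pred, gt_track, pred_of_gt, tau) {
  dims <- dim(gt_track$coords)
  nf <- dims[1]; ng <- dims[2]; nb <- dims[3]
  rows <- list()
  for (f in seq_len(nf)) for (j in seq_len(ng)) for (b in seq_len(nb)) {
    g <- gt_track$coords[f, j, b, ]
    if (anyNA(g)) next
    i <- pred_of_gt[j]
    p <- if (is.na(i)) c(NA_real_, NA_real_) else pred$coords[f, i, b, ]
    mi <- NA_integer_; mb <- NA_integer_
    if (anyNA(p)) {
      verdict <- "FN"
    } else if (sqrt(sum((p - g)^2)) <= tau) {
      verdict <- "MATCH"; mi <- j; mb <- b
    } else {
      best_d <- Inf; best <- NULL
      for (j2 in seq_len(ng)) for (b2 in seq_len(nb)) {
        g2 <- gt_track$coords[f, j2, b2, ]
        if (anyNA(g2)) next
        d <- sqrt(sum((p - g2)^2))
        if (d <= tau && d < best_d) { best_d <- d; best <- c(j2, b2) }
      }
      if (is.null(best)) {
        verdict <- "DEVIATING_FP"
      } else {
        mi <- best[1]; mb <- best[2]
        verdict <- if (mb == b) "ID_MISMATCH_FP" else "BODYPART_MISMATCH_FP"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f, gt_individual = j, bodypart = b, verdict = verdict,
      matched_ind = mi, matched_bp = mb)
  }
  out <- do.call(rbind, rows)
  out[order(out$gt_individual, out$bodypart, out$frame), , drop = FALSE]
}

# random prediction/ground-truth scene pair with noise, dropouts and
# large displacements
rand_scene <- function(ng, nb, nf, arena = 200, pred_sd = 6,
                       pred_miss = 0.1, displace_p = 0.1) {
  gt <- array(stats::runif(nf * ng * nb * 2, 0, arena),
              dim = c(nf, ng, nb, 2))
  pred <- gt + stats::rnorm(length(gt), 0, pred_sd)
  dm <- stats::runif(nf * ng * nb) < pred_miss
  dp <- stats::runif(nf * ng * nb) < displace_p & !dm
  for (d in 1:2) {
    plane <- pred[, , , d]
    plane[dm] <- NA_real_
    plane[dp] <- plane[dp] +
      sample(c(-1, 1), sum(dp), TRUE) * stats::runif(sum(dp), 30, 90)
    pred[, , , d] <- plane
  }
  inds <- paste0("ind", seq_len(ng)); bps <- paste0("bp", seq_len(nb))
  list(gt = pose_track(gt, inds, bps), pred = pose_track(pred, inds, bps))
}

# a tiny hand-buildable track from a frames x (x, y) spec per cell
track_from_points <- function(points, individuals, bodyparts) {
  # points: list indexed [[frame]][[individual]][[bodypart]] -> c(x, y) or NULL
  nf <- length(points)
  co <- array(NA_real_, dim = c(nf, length(individuals), length(bodyparts), 2))
  for (f in seq_len(nf)) for (i in seq_along(individuals))
    for (b in seq_along(bodyparts)) {
      p <- points[[f]][[i]][[b]]
      if (!is.null(p)) co[f, i, b, ] <- p
    }
  pose_track(co, individuals, bodyparts)
}
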