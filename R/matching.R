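#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the Hungarian
#' algorithm in its potentials / shortest-augmenting-path form, then
#' refines the solution so that, among all minimum-cost assignments, the
#' returned one is lexicographically smallest in (row index, column
#' index) — i.e. ties are broken by smallest predicted index, then
#' smallest ground-truth index.
#'
#' @param cost Nonnegative finite numeric matrix; rows are predicted
#'   identities, columns ground-truth identities. Rectangular matrices are
#'   allowed: the smaller side is fully assigned, the excess on the larger
#'   side stays unassigned.
#' @return An object of class `id_assignment`: list with `pairs` (data
#'   frame `pred`, `gt` of 1-based indices, sorted by `pred`),
#'   `total_cost`, and the `cost` matrix retained for audit.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (length(cost) == 0L) stop("empty cost matrix")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  if (any(cost < 0)) stop("cost matrix must be nonnegative")
  n <- nrow(cost); m <- ncol(cost)
  transposed <- n > m
  a <- if (transposed) t(cost) else cost
  match_cols <- hungarian_lex(a)   # for each row of `a`, its column
  pairs <- if (transposed)
    data.frame(pred = match_cols, gt = seq_along(match_cols))
  else
    data.frame(pred = seq_along(match_cols), gt = match_cols)
  pairs <- pairs[order(pairs$pred), , drop = FALSE]
  rownames(pairs) <- NULL
  total <- sum(cost[cbind(pairs$pred, pairs$gt)])
  structure(list(pairs = pairs, total_cost = total, cost = cost),
            class = "id_assignment")
}

#' @export
print.id_assignment <- function(x, ...) {
  cat("<id_assignment> total cost", format(x$total_cost), "\n")
  print(x$pairs)
  invisible(x)
}

# Hungarian core (rows <= cols). Returns, for each row, its assigned
# column, for the lexicographically smallest optimal assignment.
hungarian_lex <- function(a) {
  n <- nrow(a); m <- ncol(a)
  base <- hungarian_core(a)
  opt <- sum(a[cbind(seq_len(n), base)])
  tol <- 1e-9 * max(1, abs(opt))
  assigned <- integer(n)
  rows_left <- seq_len(n)
  cols_left <- seq_len(m)
  fixed_cost <- 0
  for (i in seq_len(n)) {
    rl <- rows_left[rows_left != i]
    for (j in sort(cols_left)) {
      cl <- cols_left[cols_left != j]
      rest <- if (length(rl) == 0) 0 else {
        sub <- a[rl, cl, drop = FALSE]
        sub_match <- hungarian_core(sub)
        sum(sub[cbind(seq_along(rl), sub_match)])
      }
      if (fixed_cost + a[i, j] + rest <= opt + tol) {
        assigned[i] <- j
        fixed_cost <- fixed_cost + a[i, j]
        cols_left <- cl
        break
      }
    }
    rows_left <- rl
  }
  assigned
}

# classic O(n^2 m) Hungarian with potentials; rows <= cols; returns the
# assigned column of each row (some optimum, not tie-broken)
hungarian_core <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)    # p[j + 1]: row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Pair predicted identities with ground-truth identities for a scene
#'
#' Builds the scene-global cost matrix — `cost[i, j]` is the mean
#' Euclidean distance over all (frame, bodypart) cells where both
#' predicted individual `i` and ground-truth individual `j` are observed —
#' and solves it with [solve_assignment()]. The pairing is scene-global
#' (one mapping for all frames): per-frame re-pairing would hide exactly
#' the identity switches the evaluation must expose. Pairs with no
#' co-observed cells receive a cost larger than any observed cost so they
#' are chosen only when forced.
#'
#' @param pred A [pose_track()] of predictions.
#' @param gt A [ground_truth_scene()] (or a bare [pose_track()]) covering
#'   the same frames and the same bodypart list.
#' @return An `id_assignment`; `pairs$pred` / `pairs$gt` index into
#'   `pred$individuals` / the ground-truth individuals.
#' @export
pair_ids <- function(pred, gt) {
  gt_track <- if (inherits(gt, "gt_scene")) gt$track else gt
  stopifnot(is_pose_track(pred), is_pose_track(gt_track))
  if (!identical(pred$bodyparts, gt_track$bodyparts))
    stop("predicted and ground-truth bodypart lists differ")
  if (n_frames(pred) != n_frames(gt_track))
    stop("alignment error: predicted and ground-truth frame ranges differ (",
         n_frames(pred), " vs ", n_frames(gt_track), " frames)")
  np <- length(pred$individuals); ng <- length(gt_track$individuals)
  cost <- matrix(NA_real_, np, ng)
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    dx <- pred$coords[, i, , 1] - gt_track$coords[, j, , 1]
    dy <- pred$coords[, i, , 2] - gt_track$coords[, j, , 2]
    d <- sqrt(dx^2 + dy^2)
    cost[i, j] <- if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  }
  if (all(is.na(cost)))
    stop("no co-observed cells between any predicted/ground-truth pair")
  fill <- max(cost, na.rm = TRUE) + 1
  cost[is.na(cost)] <- fill
  solve_assignment(cost)
}

#' Write an assignment to CSV for audit
#' @param assignment An `id_assignment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.csv(assignment$pairs, path, row.names = FALSE)
  invisible(path)
}
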