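#' Simulation configuration for synthetic body-axis tracks
#'
#' Describes a school/group of animals, each a chain of equidistant
#' keypoints along its body axis (head first), moving through a bounded
#' rectangular arena with a heading random walk. This mirrors the common
#' body-axis labelling schemes: fish tracked at 5 equidistant points from
#' head to tail tip, mice at 6 midline points from nose to tail base.
#'
#' @param n_animals Number of animals.
#' @param n_keypoints Keypoints per animal, ordered head to tail.
#' @param spacing Pixels between adjacent chain keypoints (> 0).
#' @param arena `c(width, height)` in pixels; must exceed twice the chain
#'   length so a full-margin start position exists.
#' @param n_frames Number of frames (>= 2).
#' @param speed_mean,speed_sd Per-frame speed distribution (px/frame),
#'   clipped at 0.
#' @param turn_sd Heading random-walk increment SD (radians/frame).
#' @param frame_rate Frames/second recorded on the output track.
#' @param seed Integer seed; the trajectory is deterministic given it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_animals = 10, n_keypoints = 5, spacing = 20,
                              arena = c(1228, 1030), n_frames = 300,
                              speed_mean = 4, speed_sd = 2,
                              turn_sd = 0.25, frame_rate = 30, seed = 1L) {
  stopifnot(n_animals >= 1, n_keypoints >= 2, spacing > 0, n_frames >= 2,
            length(arena) == 2, all(arena > 0))
  chain_len <- spacing * (n_keypoints - 1)
  if (min(arena) <= 2 * chain_len)
    stop("infeasible geometry: arena ", paste(arena, collapse = "x"),
         " cannot hold a chain of length ", chain_len,
         " with full-margin clearance (need min dimension > ", 2 * chain_len, ")")
  structure(list(n_animals = n_animals, n_keypoints = n_keypoints,
                 spacing = spacing, arena = arena, n_frames = n_frames,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 turn_sd = turn_sd, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file whose keys are [simulation_config()] arguments.
#' @return A `sim_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate ground-truth multi-animal body-axis trajectories
#'
#' Each animal's head follows a heading random walk (wrapped Gaussian turn
#' increments, Gaussian speed clipped at 0) inside the arena, with
#' reflective boundaries applied at a full chain-length margin; the body
#' chain is laid out backward from the head along the current heading, so
#' adjacent-keypoint distances equal `spacing` exactly in every frame and
#' every keypoint stays inside the arena.
#'
#' @param config A [simulation_config()].
#' @return A [pose_track()] with no missing keypoints; individuals are
#'   labelled `animal1..animalN`, bodyparts `kp1..kpK` (head = `kp1`).
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    na <- config$n_animals; nk <- config$n_keypoints; nf <- config$n_frames
    L <- config$spacing * (nk - 1)
    W <- config$arena[1]; H <- config$arena[2]
    co <- array(NA_real_, dim = c(nf, na, nk, 2))
    for (a in seq_len(na)) {
      hx <- stats::runif(1, L, W - L)
      hy <- stats::runif(1, L, H - L)
      th <- stats::runif(1, -pi, pi)
      for (f in seq_len(nf)) {
        if (f > 1) {
          th <- th + stats::rnorm(1, 0, config$turn_sd)
          th <- atan2(sin(th), cos(th))  # wrap to (-pi, pi]
          sp <- max(0, stats::rnorm(1, config$speed_mean, config$speed_sd))
          hx <- hx + sp * cos(th)
          hy <- hy + sp * sin(th)
          # reflective boundaries at a chain-length margin
          if (hx < L)     { hx <- 2 * L - hx;            th <- atan2(sin(th), -cos(th)) }
          if (hx > W - L) { hx <- 2 * (W - L) - hx;      th <- atan2(sin(th), -cos(th)) }
          if (hy < L)     { hy <- 2 * L - hy;            th <- atan2(-sin(th), cos(th)) }
          if (hy > H - L) { hy <- 2 * (H - L) - hy;      th <- atan2(-sin(th), cos(th)) }
        }
        k <- seq_len(nk) - 1
        co[f, a, , 1] <- hx - k * config$spacing * cos(th)
        co[f, a, , 2] <- hy - k * config$spacing * sin(th)
      }
    }
    pose_track(co, paste0("animal", seq_len(na)), paste0("kp", seq_len(nk)),
               frame_rate = config$frame_rate)
  })
}

#' Error-injection configuration
#'
#' Parameterizes the tracking-error phenomenology injected into a clean
#' simulated track: isotropic coordinate jitter, missing keypoints (false
#' negatives), displaced detections (deviating false positives), body-part
#' swaps within an animal, and identity-swap episodes.
#'
#' @param jitter_sd Gaussian SD (px) added independently to each
#'   coordinate of every keypoint.
#' @param fn_rate Probability per keypoint of deletion (false negative).
#' @param deviating_rate Probability per keypoint of displacement by at
#'   least `displacement_min` px in a uniformly random direction; the
#'   displaced point is guaranteed to clear `match_threshold` around
#'   every ground-truth keypoint of the frame, so the log is an exact
#'   oracle for deviating-FP recovery.
#' @param displacement_min Minimum displacement (px); must strictly exceed
#'   `match_threshold`.
#' @param bodypart_swap_rate Probability per animal-frame of exchanging
#'   the coordinates of two randomly chosen body parts of that animal.
#' @param id_swap_events Data frame (or list coercible to one) with
#'   columns `frame_start` (1-based), `duration`, `a`, `b` (individual
#'   indices); the two individuals' coordinates are exchanged on frames
#'   `frame_start .. frame_start + duration - 1`.
#' @param id_swap_rate Optional probability per frame of starting a swap
#'   episode between a random pair (duration drawn uniformly 10..30
#'   frames); used when `id_swap_events` is `NULL`.
#' @param match_threshold The keypoint match threshold (px) in force
#'   downstream; used to validate `displacement_min` and for clearance.
#' @param seed Integer seed for the error draw, independent of the
#'   trajectory seed.
#' @return An `error_config` list.
#' @export
error_config <- function(jitter_sd = 0, fn_rate = 0, deviating_rate = 0,
                         displacement_min = 30, bodypart_swap_rate = 0,
                         id_swap_events = NULL, id_swap_rate = 0,
                         match_threshold = 10, seed = 1L) {
  rates <- c(fn_rate, deviating_rate, bodypart_swap_rate, id_swap_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), jitter_sd >= 0)
  if (fn_rate + deviating_rate > 1)
    stop("fn_rate + deviating_rate must not exceed 1 (a cell receives at most one)")
  if ((deviating_rate > 0) && displacement_min <= match_threshold)
    stop("displacement_min (", displacement_min, ") must strictly exceed the ",
         "match threshold (", match_threshold, "): displaced points would be ",
         "unclassifiable fixtures")
  if (!is.null(id_swap_events)) id_swap_events <- as.data.frame(id_swap_events)
  structure(list(jitter_sd = jitter_sd, fn_rate = fn_rate,
                 deviating_rate = deviating_rate,
                 displacement_min = displacement_min,
                 bodypart_swap_rate = bodypart_swap_rate,
                 id_swap_events = id_swap_events, id_swap_rate = id_swap_rate,
                 match_threshold = match_threshold, seed = as.integer(seed)),
            class = "error_config")
}

#' Degrade a clean track with a logged error model
#'
#' Applies, in order: jitter, body-part swaps, deviating displacements,
#' false-negative deletions, identity-swap episodes. Every corrupted cell
#' is recorded in the returned log; with all rates and `jitter_sd` zero
#' the output equals the input and the log is empty.
#'
#' @param gt A [pose_track()] with no missing keypoints.
#' @param err An [error_config()].
#' @return A list with elements `track` (the degraded [pose_track()]),
#'   `log` (data frame: `kind`, `frame`, `individual`, `bodypart`,
#'   `partner` — partner bodypart for swaps, partner individual for id
#'   swaps), `swaps` (data frame of identity-swap episodes) and
#'   `identity_map` (n_frames x n_individuals matrix: the ground-truth
#'   individual index whose coordinates each predicted slot carries).
#' @export
inject_errors <- function(gt, err) {
  stopifnot(is_pose_track(gt), inherits(err, "error_config"))
  if (any(is_missing_kp(gt)))
    stop("inject_errors() requires a fully observed ground-truth track")
  with_seed(err$seed, {
    nf <- n_frames(gt)
    na <- length(gt$individuals); nk <- length(gt$bodyparts)
    co <- gt$coords
    log_rows <- list()
    add_log <- function(kind, frame, individual, bodypart = NA_integer_,
                        partner = NA_integer_) {
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        kind = kind, frame = frame, individual = individual,
        bodypart = bodypart, partner = partner)
    }

    # 1. jitter (global; recorded in config, not per cell)
    if (err$jitter_sd > 0)
      co <- co + array(stats::rnorm(length(co), 0, err$jitter_sd), dim = dim(co))

    # 2. bodypart swaps within an animal
    if (err$bodypart_swap_rate > 0 && nk >= 2) {
      hit <- matrix(stats::runif(nf * na) < err$bodypart_swap_rate, nf, na)
      for (f in seq_len(nf)) for (a in seq_len(na)) if (hit[f, a]) {
        bp <- sample.int(nk, 2)
        tmp <- co[f, a, bp[1], ]
        co[f, a, bp[1], ] <- co[f, a, bp[2], ]
        co[f, a, bp[2], ] <- tmp
        add_log("bodypart_swap", f, a, bp[1], partner = bp[2])
        add_log("bodypart_swap", f, a, bp[2], partner = bp[1])
      }
    }

    # 3/4. deviating displacement or FN deletion (at most one per cell)
    if (err$fn_rate > 0 || err$deviating_rate > 0) {
      u <- array(stats::runif(nf * na * nk), dim = c(nf, na, nk))
      for (f in seq_len(nf)) {
        gt_frame <- matrix(gt$coords[f, , , ], ncol = 2)  # all GT points, frame f
        for (a in seq_len(na)) for (b in seq_len(nk)) {
          uu <- u[f, a, b]
          if (uu < err$fn_rate) {
            co[f, a, b, ] <- NA_real_
            add_log("fn", f, a, b)
          } else if (uu < err$fn_rate + err$deviating_rate) {
            co[f, a, b, ] <- displace_clear(gt$coords[f, a, b, ], gt_frame,
                                            err$displacement_min,
                                            err$match_threshold)
            add_log("deviating", f, a, b)
          }
        }
      }
    }

    # 5. identity-swap episodes
    swaps <- err$id_swap_events
    if (is.null(swaps) && err$id_swap_rate > 0 && na >= 2) {
      starts <- which(stats::runif(nf) < err$id_swap_rate)
      swaps <- do.call(rbind, lapply(starts, function(f) {
        pr <- sample.int(na, 2)
        data.frame(frame_start = f,
                   duration = sample(10:30, 1), a = pr[1], b = pr[2])
      }))
    }
    if (is.null(swaps))
      swaps <- data.frame(frame_start = integer(), duration = integer(),
                          a = integer(), b = integer())
    identity_map <- matrix(rep(seq_len(na), each = nf), nf, na)
    if (nrow(swaps)) {
      for (s in seq_len(nrow(swaps))) {
        fr <- seq(swaps$frame_start[s],
                  min(nf, swaps$frame_start[s] + swaps$duration[s] - 1L))
        ia <- swaps$a[s]; ib <- swaps$b[s]
        tmp <- co[fr, ia, , , drop = FALSE]
        co[fr, ia, , ] <- co[fr, ib, , , drop = FALSE]
        co[fr, ib, , ] <- tmp
        m <- identity_map[fr, ia]
        identity_map[fr, ia] <- identity_map[fr, ib]
        identity_map[fr, ib] <- m
        for (f in fr) {
          add_log("id_swap", f, ia, partner = ib)
          add_log("id_swap", f, ib, partner = ia)
        }
      }
    }

    log <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(kind = character(), frame = integer(), individual = integer(),
                 bodypart = integer(), partner = integer())
    list(track = pose_track(co, gt$individuals, gt$bodyparts,
                            frame_rate = gt$frame_rate),
         log = log, swaps = swaps, identity_map = identity_map)
  })
}

# displace `pt` by >= dmin in a uniform direction such that the result
# clears `thr` around every row of gt_frame (rejection sampling)
displace_clear <- function(pt, gt_frame, dmin, thr) {
  for (attempt in 1:200) {
    ang <- stats::runif(1, -pi, pi)
    r <- dmin * stats::runif(1, 1, 2) * (1 + (attempt - 1) / 20)
    cand <- pt + r * c(cos(ang), sin(ang))
    d2 <- (gt_frame[, 1] - cand[1])^2 + (gt_frame[, 2] - cand[2])^2
    if (all(d2 > thr^2)) return(cand)
  }
  stop("could not place a deviating point clear of all ground-truth keypoints")
}

#' Write an error log to CSV
#' @param log The `log` data frame from [inject_errors()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_error_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
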