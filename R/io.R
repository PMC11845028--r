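#' Read a pose coordinate table
#'
#' Reads the stacked-header CSV coordinate tables produced by the pose
#' tracking ecosystem. Two dialects are supported: `single_flat` (3 header
#' rows: scorer / bodyparts / coords, one implicit individual) and
#' `multi_nested` (4 header rows: scorer / individuals / bodyparts /
#' coords). Empty coordinate cells become missing keypoints. Column order
#' is preserved into the `individuals` and `bodyparts` ordering.
#'
#' A `likelihood` column per keypoint, when present, is read into the
#' track's `confidence` array. No confidence-based filtering is applied on
#' read unless `confidence_min` is given, in which case keypoints below
#' the cutoff are set to missing.
#'
#' @param path Path to a CSV file.
#' @param dialect One of `"single_flat"`, `"multi_nested"`.
#' @param individual Label given to the single individual of a
#'   `single_flat` table (default `"individual1"`).
#' @param confidence_min Optional likelihood cutoff in `[0, 1]`; default
#'   `NULL` (off).
#' @param frame_rate Optional frames/second stored on the track.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, dialect = c("multi_nested", "single_flat"),
                            individual = "individual1",
                            confidence_min = NULL, frame_rate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  n_header <- if (dialect == "single_flat") 3L else 4L
  if (nrow(raw) < n_header)
    stop("malformed header: expected ", n_header,
         " header rows for dialect '", dialect, "', file has ", nrow(raw), " rows")
  labels <- c("scorer", if (dialect == "multi_nested") "individuals",
              "bodyparts", "coords")
  for (k in seq_len(n_header)) {
    if (!identical(raw[k, 1], labels[k]))
      stop("malformed header: row ", k, " should start with '", labels[k],
           "', found '", raw[k, 1], "'")
  }
  coords_row <- as.character(raw[n_header, -1])
  if (!all(coords_row %in% c("x", "y", "likelihood")))
    stop("malformed header: coords row contains entries other than x/y/likelihood")
  has_conf <- "likelihood" %in% coords_row
  per_kp <- if (has_conf) 3L else 2L
  if (length(coords_row) %% per_kp != 0L ||
      !identical(unique(split(coords_row,
                              ceiling(seq_along(coords_row) / per_kp))[[1]]),
                 if (has_conf) c("x", "y", "likelihood") else c("x", "y")))
    stop("malformed header: coords row is not a repetition of ",
         if (has_conf) "x,y,likelihood" else "x,y")
  bp_row <- as.character(raw[n_header - 1L, -1])
  kp_first <- seq(1L, length(coords_row), by = per_kp)
  bodyparts_per_col <- bp_row[kp_first]
  if (dialect == "multi_nested") {
    ind_row <- as.character(raw[2, -1])
    individuals_per_col <- ind_row[kp_first]
    individuals <- unique(individuals_per_col)
    bodyparts <- unique(bodyparts_per_col[individuals_per_col == individuals[1]])
  } else {
    individuals_per_col <- rep(individual, length(kp_first))
    individuals <- individual
    bodyparts <- unique(bodyparts_per_col)
  }
  data <- raw[-seq_len(n_header), , drop = FALSE]
  nf <- nrow(data)
  ni <- length(individuals); nb <- length(bodyparts)
  if (length(kp_first) != ni * nb)
    stop("malformed header: ", length(kp_first), " keypoint columns do not ",
         "tile ", ni, " individuals x ", nb, " bodyparts")
  vals <- as.matrix(data[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  blank <- trimws(as.matrix(data[, -1, drop = FALSE])) == ""
  if (any(is.na(vals) & !blank))
    stop("parse error: non-numeric coordinate cell at data row ",
         which(rowSums(is.na(vals) & !blank) > 0)[1])
  co <- array(NA_real_, dim = c(nf, ni, nb, 2))
  conf <- if (has_conf) array(NA_real_, dim = c(nf, ni, nb)) else NULL
  for (k in seq_along(kp_first)) {
    i <- match(individuals_per_col[k], individuals)
    b <- match(bodyparts_per_col[k], bodyparts)
    col <- kp_first[k]
    co[, i, b, 1] <- vals[, col]
    co[, i, b, 2] <- vals[, col + 1L]
    if (has_conf) conf[, i, b] <- vals[, col + 2L]
  }
  half <- xor(is.na(co[, , , 1, drop = FALSE]), is.na(co[, , , 2, drop = FALSE]))
  if (any(half)) {
    warning("half-missing coordinate cells set to missing (",
            sum(half), " cells)")
    co[, , , 1][half] <- NA_real_
    co[, , , 2][half] <- NA_real_
  }
  tr <- pose_track(co, individuals, bodyparts, confidence = conf,
                   frame_rate = frame_rate)
  if (!is.null(confidence_min)) {
    if (is.null(tr$confidence))
      stop("confidence_min given but the table has no likelihood columns")
    drop <- !is.na(tr$confidence) & tr$confidence < confidence_min
    for (d in 1:2) tr$coords[, , , d][drop] <- NA_real_
    tr$confidence[drop] <- NA_real_
  }
  tr
}

#' Write a pose coordinate table
#'
#' Writes a [pose_track()] to CSV in either stacked-header dialect so that
#' [read_pose_table()] recovers a value-identical track. Missing keypoints
#' are written as empty cells.
#'
#' @param track A [pose_track()]. For `single_flat` the track must have
#'   exactly one individual (flatten first with [reshape_multi_to_flat()]).
#' @param path Output file path.
#' @param dialect One of `"multi_nested"`, `"single_flat"`.
#' @param scorer Scorer string written into the header (opaque).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path,
                             dialect = c("multi_nested", "single_flat"),
                             scorer = "vmtrack") {
  dialect <- match.arg(dialect)
  stopifnot(is_pose_track(track))
  if (dialect == "single_flat" && length(track$individuals) != 1L)
    stop("single_flat dialect requires a single-individual track; ",
         "use reshape_multi_to_flat() first")
  nf <- n_frames(track)
  ni <- length(track$individuals); nb <- length(track$bodyparts)
  has_conf <- !is.null(track$confidence)
  per_kp <- if (has_conf) 3L else 2L
  n_col <- ni * nb * per_kp
  header <- list()
  header$scorer <- c("scorer", rep(scorer, n_col))
  if (dialect == "multi_nested")
    header$individuals <- c("individuals",
                            rep(track$individuals, each = nb * per_kp))
  header$bodyparts <- c("bodyparts",
                        rep(rep(track$bodyparts, each = per_kp), times = ni))
  header$coords <- c("coords",
                     rep(if (has_conf) c("x", "y", "likelihood") else c("x", "y"),
                         times = ni * nb))
  body <- matrix("", nrow = nf, ncol = n_col)
  k <- 0L
  for (i in seq_len(ni)) for (b in seq_len(nb)) {
    x <- track$coords[, i, b, 1]; y <- track$coords[, i, b, 2]
    body[, k + 1L] <- ifelse(is.na(x), "", format_num(x))
    body[, k + 2L] <- ifelse(is.na(y), "", format_num(y))
    if (has_conf) {
      cf <- track$confidence[, i, b]
      body[, k + 3L] <- ifelse(is.na(cf), "", format_num(cf))
    }
    k <- k + per_kp
  }
  lines <- c(
    vapply(header, paste, character(1), collapse = ","),
    paste(seq_len(nf) - 1L, apply(body, 1, paste, collapse = ","), sep = ",")
  )
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e)))
  invisible(path)
}

# full-precision decimal formatting so that write -> read is bit-faithful
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Reshape a flat single-animal track into a multi-animal track
#'
#' Single-animal projects used for virtual-marker tracking encode several
#' animals implicitly: the flat body-part list is the concatenation, in
#' individual-major order, of each animal's body parts (for example 18
#' flat keypoints = 3 animals x 6 body parts). This operation splits such
#' a track into an explicit multi-individual track; [reshape_multi_to_flat()]
#' is its inverse.
#'
#' @param track A single-individual [pose_track()].
#' @param n_individuals Number of animals encoded in the flat list.
#' @param parts_per_individual Body parts per animal. Either a count, or
#'   `NULL` to derive it from the body-part count.
#' @param individuals Labels for the new individuals (default
#'   `individual1..individualN`).
#' @param bodyparts Labels for the per-animal body parts; default: the
#'   first animal's flat labels.
#' @return A multi-individual [pose_track()].
#' @export
reshape_flat_to_multi <- function(track, n_individuals,
                                  parts_per_individual = NULL,
                                  individuals = NULL, bodyparts = NULL) {
  stopifnot(is_pose_track(track))
  if (length(track$individuals) != 1L)
    stop("expected a single-individual (flat) track")
  nb_flat <- length(track$bodyparts)
  if (is.null(parts_per_individual)) {
    if (nb_flat %% n_individuals != 0L)
      stop("shape error: ", nb_flat, " flat bodyparts do not divide into ",
           n_individuals, " individuals")
    parts_per_individual <- nb_flat %/% n_individuals
  }
  if (nb_flat != n_individuals * parts_per_individual)
    stop("shape error: expected ", n_individuals * parts_per_individual,
         " flat bodyparts (", n_individuals, " x ", parts_per_individual,
         "), found ", nb_flat)
  if (is.null(individuals))
    individuals <- paste0("individual", seq_len(n_individuals))
  if (is.null(bodyparts))
    bodyparts <- track$bodyparts[seq_len(parts_per_individual)]
  nf <- n_frames(track)
  co <- array(NA_real_, dim = c(nf, n_individuals, parts_per_individual, 2))
  conf <- if (!is.null(track$confidence))
    array(NA_real_, dim = c(nf, n_individuals, parts_per_individual)) else NULL
  for (i in seq_len(n_individuals)) {
    cols <- (i - 1L) * parts_per_individual + seq_len(parts_per_individual)
    co[, i, , ] <- track$coords[, 1, cols, , drop = FALSE]
    if (!is.null(conf)) conf[, i, ] <- track$confidence[, 1, cols]
  }
  pose_track(co, individuals, bodyparts, confidence = conf,
             frame_rate = track$frame_rate)
}

#' @rdname reshape_flat_to_multi
#' @param sep Separator used when building flat body-part names as
#'   `<individual><sep><bodypart>`.
#' @export
reshape_multi_to_flat <- function(track, individual = "individual1",
                                  sep = "_") {
  stopifnot(is_pose_track(track))
  ni <- length(track$individuals); nb <- length(track$bodyparts)
  nf <- n_frames(track)
  flat_bp <- as.vector(t(outer(track$individuals, track$bodyparts, paste,
                               sep = sep)))
  co <- array(NA_real_, dim = c(nf, 1, ni * nb, 2))
  conf <- if (!is.null(track$confidence))
    array(NA_real_, dim = c(nf, 1, ni * nb)) else NULL
  for (i in seq_len(ni)) {
    cols <- (i - 1L) * nb + seq_len(nb)
    co[, 1, cols, ] <- track$coords[, i, , , drop = FALSE]
    if (!is.null(conf)) conf[, 1, cols] <- track$confidence[, i, ]
  }
  pose_track(co, individual, flat_bp, confidence = conf,
             frame_rate = track$frame_rate)
}
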