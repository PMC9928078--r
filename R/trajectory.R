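#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of 2D positions recorded at a uniform
#' time lapse. Positions are in micrometres, `dt` in seconds. Trajectories are
#' the atomic unit of every analysis in this package: they are featurized
#' either by classical descriptors ([classical_features()]) or by the graph
#' neural encoder ([fit_encoder()], [encode()]).
#'
#' @param positions numeric matrix with N rows and 2 columns (x, y in um),
#'   N >= 2, all finite.
#' @param dt time lapse between consecutive points, in seconds (> 0).
#' @param track_id identifier (coerced to character).
#' @param meta optional named list of labels (condition, region, and for
#'   simulated data the ground-truth model, alpha, D, noise sd).
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(positions, dt, track_id = "1", meta = list()) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 2L)
    stop("`positions` must be a numeric N x 2 matrix")
  if (nrow(positions) < 2L)
    stop("a trajectory needs at least 2 points")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (seconds)")
  dimnames(positions) <- list(NULL, c("x", "y"))
  structure(
    list(positions = positions, dt = dt, track_id = as.character(track_id),
         meta = meta),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d points, dt = %g s\n",
              x$track_id, nrow(x$positions), x$dt))
  invisible(x)
}

#' @export
length.trajectory <- function(x) nrow(x$positions)

## single-lapse displacement matrix, (N-1) x 2
displacements <- function(t) {
  diff(t$positions)
}

#' Construct a group of trajectories
#'
#' A trajectory group is a non-empty set of trajectories sharing the same time
#' lapse, carrying a label (condition, synapse id, field of view...). Groups
#' are the unit compared by [mmd_test()] and embedded by
#' [pairwise_group_mmd()].
#'
#' @param trajectories list of [trajectory()] objects, all with the same `dt`.
#' @param label group identifier.
#' @return an object of class `"trajectory_group"`.
#' @export
trajectory_group <- function(trajectories, label = "group") {
  if (!length(trajectories)) stop("a trajectory group must be non-empty")
  if (!all(vapply(trajectories, inherits, logical(1), "trajectory")))
    stop("all elements must be trajectory objects")
  dts <- vapply(trajectories, function(t) t$dt, numeric(1))
  if (diff(range(dts)) > 1e-9)
    stop("all trajectories in a group must share dt")
  structure(list(trajectories = trajectories, label = as.character(label)),
            class = "trajectory_group")
}

#' @export
print.trajectory_group <- function(x, ...) {
  ns <- vapply(x$trajectories, length, integer(1))
  cat(sprintf("<trajectory_group '%s'> %d trajectories, lengths %d-%d, dt = %g s\n",
              x$label, length(x$trajectories), min(ns), max(ns),
              x$trajectories[[1]]$dt))
  invisible(x)
}

#' @export
length.trajectory_group <- function(x) length(x$trajectories)

#' Read trajectories from a delimited table
#'
#' Parses a delimited text file (or data frame) with one localisation per row
#' into trajectory groups. Rows are grouped by track id and sorted by time;
#' the time lapse is inferred as the modal inter-frame interval. Tracks with a
#' single localisation are dropped with a warning. Positions are expected in
#' micrometres, times in seconds (or integer frames together with `dt`).
#'
#' @param path file path of a delimited table, or a data.frame.
#' @param column_map named list mapping the roles `track_id`, `t` (or `frame`),
#'   `x`, `y`, and optionally `group`, to column names in the table.
#' @param sep field separator when reading from file.
#' @param dt time lapse in seconds; required when only a `frame` column is
#'   given, otherwise inferred from the time column.
#' @param dt_tol tolerance on uniformity of the time lapse (seconds).
#' @return a list of [trajectory_group()] objects (one per value of the
#'   `group` column; a single unnamed group when absent).
#' @export
read_trajectories <- function(path,
                              column_map = list(track_id = "track_id", t = "t",
                                                x = "x", y = "y"),
                              sep = ",", dt = NULL, dt_tol = 1e-6) {
  df <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("track_id", "x", "y")
  for (role in need) {
    col <- column_map[[role]]
    if (is.null(col) || !col %in% names(df))
      stop(sprintf("missing mandatory column for role '%s'", role))
  }
  tcol <- column_map[["t"]]
  fcol <- column_map[["frame"]]
  if ((is.null(tcol) || !tcol %in% names(df)) &&
      (is.null(fcol) || !fcol %in% names(df)))
    stop("missing mandatory column for role 't' (or 'frame')")
  use_frame <- is.null(tcol) || !tcol %in% names(df)
  if (use_frame && is.null(dt))
    stop("`dt` must be given when only a frame column is present")

  gcol <- column_map[["group"]]
  gvals <- if (!is.null(gcol) && gcol %in% names(df)) as.character(df[[gcol]])
           else rep("group", nrow(df))
  metacols <- setdiff(names(df), unlist(column_map))

  out <- list()
  n_dropped <- 0L
  for (g in unique(gvals)) {
    sub <- df[gvals == g, , drop = FALSE]
    trajs <- list()
    for (id in unique(as.character(sub[[column_map$track_id]]))) {
      rows <- sub[as.character(sub[[column_map$track_id]]) == id, , drop = FALSE]
      tv <- if (use_frame) as.numeric(rows[[fcol]]) * dt else as.numeric(rows[[tcol]])
      o <- order(tv)
      rows <- rows[o, , drop = FALSE]; tv <- tv[o]
      if (nrow(rows) < 2L) { n_dropped <- n_dropped + 1L; next }
      steps <- diff(tv)
      dt_i <- if (use_frame) dt else modal_interval(steps)
      if (any(abs(steps - dt_i) > dt_tol))
        stop(sprintf("track '%s': non-uniform time lapse beyond tolerance", id))
      meta <- as.list(rows[1L, metacols, drop = FALSE])
      trajs[[length(trajs) + 1L]] <- trajectory(
        cbind(as.numeric(rows[[column_map$x]]), as.numeric(rows[[column_map$y]])),
        dt = dt_i, track_id = id, meta = meta)
    }
    if (length(trajs)) out[[g]] <- trajectory_group(trajs, label = g)
  }
  if (n_dropped > 0L)
    warning(sprintf("dropped %d track(s) with fewer than 2 localisations", n_dropped))
  out
}

modal_interval <- function(steps) {
  r <- round(steps, 9)
  as.numeric(names(sort(table(r), decreasing = TRUE))[1L])
}

#' Write trajectory groups to a delimited table
#'
#' Inverse of [read_trajectories()]: one row per localisation with columns
#' `track_id, frame, t, x, y, group` plus any scalar metadata fields.
#'
#' @param groups a [trajectory_group()] or list of them.
#' @param path output file path; when `NULL` the assembled data.frame is
#'   returned instead.
#' @param sep field separator.
#' @export
write_trajectories <- function(groups, path = NULL, sep = ",") {
  if (inherits(groups, "trajectory_group")) groups <- list(groups)
  rows <- list()
  for (g in groups) {
    for (t in g$trajectories) {
      n <- nrow(t$positions)
      base <- data.frame(track_id = t$track_id, frame = seq_len(n) - 1L,
                         t = (seq_len(n) - 1L) * t$dt,
                         x = t$positions[, 1L], y = t$positions[, 2L],
                         group = g$label, stringsAsFactors = FALSE)
      sc <- t$meta[vapply(t$meta, function(v) is.atomic(v) && length(v) == 1L,
                          logical(1))]
      for (nm in names(sc)) base[[nm]] <- sc[[nm]]
      rows[[length(rows) + 1L]] <- base
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
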