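#' @name track-metrics
#' @title Per-track migration metrics
#' @description
#' A track is a data frame with columns `t_min` (strictly increasing),
#' `x_um`, `y_um`, and usually `track_id` and `group`.  [path_length()],
#' [velocity()], [persistence()] and [deviation_angles()] operate on a
#' single track; [track_metrics()] maps them over a track table.
NULL

check_track <- function(track, min_points = 2L) {
  need <- c("t_min", "x_um", "y_um")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    input_error("a track needs columns t_min, x_um, y_um")
  }
  if (nrow(track) < min_points) {
    input_error(sprintf("track has %d point(s); need at least %d",
                        nrow(track), min_points))
  }
  if (!all(is.finite(track$t_min)) || !all(is.finite(track$x_um)) ||
      !all(is.finite(track$y_um))) {
    input_error("track contains non-finite coordinates or times")
  }
  if (any(diff(track$t_min) <= 0)) {
    input_error("track times must be strictly increasing")
  }
  invisible(track)
}

split_tracks <- function(tracks) {
  if (!"track_id" %in% names(tracks)) input_error("track table needs a track_id column")
  split(tracks, factor(tracks$track_id, levels = unique(tracks$track_id)))
}

#' Total migratory path length of a track
#'
#' Sum of the Euclidean lengths of the segments between consecutive
#' positions, in micrometres.
#'
#' @param track A single-track data frame (see [track-metrics]).
#' @return Path length in um.
#' @export
path_length <- function(track) {
  check_track(track)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Cell velocity: total distance traveled divided by elapsed time
#'
#' @inheritParams path_length
#' @return Velocity in um/min.
#' @export
velocity <- function(track) {
  check_track(track)
  elapsed <- track$t_min[nrow(track)] - track$t_min[1]
  if (elapsed <= 0) input_error("track has zero elapsed time")
  path_length(track) / elapsed
}

#' Directional persistence of a track
#'
#' Ratio of the straight-line distance from the first to the last position
#' to the total path length; 1 for a perfectly straight path, near 0 for a
#' path that returns to its origin.  A stationary cell (zero path length)
#' has undefined persistence and returns `NA`; group summaries exclude and
#' count such cells.
#'
#' @inheritParams path_length
#' @return Persistence in `[0, 1]`, or `NA` for a stationary cell.
#' @examples
#' tr <- data.frame(t_min = c(0, 10, 20), x_um = c(0, 3, 3), y_um = c(0, 0, 4))
#' persistence(tr) # 5 / 7
#' @export
persistence <- function(track) {
  check_track(track)
  total <- path_length(track)
  if (total == 0) return(NA_real_)
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  min(net / total, 1)
}

#' Deviation angles along a track
#'
#' For each consecutive triple of positions, the signed angle (degrees, in
#' `(-180, 180]`, counter-clockwise positive) from the displacement vector
#' p_i -> p_{i+1} to the displacement p_{i+1} -> p_{i+2}: the line between
#' the first and second position is compared with the line between the
#' second and third, then the process moves one point forward.  0 means the
#' cell kept its direction, 180 a full reversal.  Triples containing a
#' zero-length displacement carry no direction and are skipped; the number
#' skipped is attached as attribute `n_skipped`.
#'
#' @inheritParams path_length
#' @return Numeric vector of signed angles in degrees (empty for tracks
#'   with fewer than 3 points), with attribute `n_skipped`.
#' @export
deviation_angles <- function(track) {
  check_track(track)
  if (nrow(track) < 3L) {
    return(structure(numeric(0), n_skipped = 0L))
  }
  dx <- diff(track$x_um)
  dy <- diff(track$y_um)
  len <- sqrt(dx^2 + dy^2)
  i <- seq_len(length(dx) - 1L)
  ok <- len[i] > 0 & len[i + 1L] > 0
  cross <- dx[i] * dy[i + 1L] - dy[i] * dx[i + 1L]
  dot <- dx[i] * dx[i + 1L] + dy[i] * dy[i + 1L]
  ang <- atan2(cross, dot) * 180 / pi
  ang[ang <= -180] <- 180  # single convention: reversals are +180
  structure(ang[ok], n_skipped = sum(!ok))
}

#' Keep only tracks that span the analysis window
#'
#' Retains exactly those tracks that have a point at or before
#' `window_start_min` and at or after `window_end_min` — cells that could
#' be reliably followed through the whole window — and whose sampling
#' inside the window has no gap larger than `max_gap_factor` times the
#' nominal interval.  Retained tracks are cropped to the window.
#'
#' @param tracks Track table (multiple tracks).
#' @param window_start_min,window_end_min Analysis window in minutes;
#'   default 0-360, the 6 h filter applied to the recordings.
#' @param max_gap_factor Largest tolerated sampling gap, as a multiple of
#'   `nominal_dt_min`.
#' @param nominal_dt_min Nominal sampling interval; when `NULL` it is
#'   inferred as the median of all within-track time differences.
#' @return The filtered, cropped track table.  Attribute `n_dropped` holds
#'   the number of tracks removed.
#' @export
filter_complete_tracks <- function(tracks, window_start_min = 0,
                                   window_end_min = 360,
                                   max_gap_factor = 1.5,
                                   nominal_dt_min = NULL) {
  if (window_end_min <= window_start_min) {
    input_error("window_end_min must be greater than window_start_min")
  }
  if (nrow(tracks) == 0L) {
    return(structure(tracks, n_dropped = 0L))
  }
  by_track <- split_tracks(tracks)
  if (is.null(nominal_dt_min)) {
    nominal_dt_min <- stats::median(unlist(lapply(by_track, function(tr) diff(tr$t_min))))
  }
  kept <- lapply(by_track, function(tr) {
    if (min(tr$t_min) > window_start_min || max(tr$t_min) < window_end_min) {
      return(NULL)
    }
    cropped <- tr[tr$t_min >= window_start_min & tr$t_min <= window_end_min, ,
                  drop = FALSE]
    if (nrow(cropped) < 2L ||
        any(diff(cropped$t_min) > max_gap_factor * nominal_dt_min)) {
      return(NULL)
    }
    cropped
  })
  n_dropped <- sum(vapply(kept, is.null, logical(1)))
  out <- do.call(rbind, kept[!vapply(kept, is.null, logical(1))])
  if (is.null(out)) out <- tracks[0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = n_dropped)
}

#' Compute the full metric set for every track in a table
#'
#' @param tracks Track table with `track_id` (and optionally `group`).
#' @return A data frame with one row per track: `track_id`, `group`,
#'   `velocity_um_per_min`, `persistence`, `n_valid_steps` (number of
#'   deviation angles), `n_skipped_steps`, and a list column
#'   `deviation_angles_deg`.
#' @export
track_metrics <- function(tracks) {
  by_track <- split_tracks(tracks)
  rows <- lapply(by_track, function(tr) {
    ang <- deviation_angles(tr)
    data.frame(
      track_id = tr$track_id[1],
      group = if ("group" %in% names(tr)) tr$group[1] else NA_character_,
      velocity_um_per_min = velocity(tr),
      persistence = persistence(tr),
      n_valid_steps = length(ang),
      n_skipped_steps = attr(ang, "n_skipped"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$deviation_angles_deg <- I(lapply(by_track, function(tr) {
    as.numeric(deviation_angles(tr))
  }))
  rownames(out) <- NULL
  out
}

#' Pool deviation angles across the cells of each group
#'
#' @param tracks Track table.
#' @return Long data frame `track_id`, `group`, `angle_deg`, one row per
#'   valid deviation angle.
#' @export
deviation_angle_table <- function(tracks) {
  by_track <- split_tracks(tracks)
  rows <- lapply(by_track, function(tr) {
    ang <- as.numeric(deviation_angles(tr))
    if (!length(ang)) return(NULL)
    data.frame(track_id = tr$track_id[1],
               group = if ("group" %in% names(tr)) tr$group[1] else NA_character_,
               angle_deg = ang, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(track_id = character(0), group = character(0),
                      angle_deg = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Bin deviation angles into an angular histogram
#'
#' Counts angles over `n_bins` equal-width bins partitioning
#' `(-180, 180]`, half-open `(lo, hi]` so a boundary value belongs to the
#' bin it closes.  Rose-plot style summaries of how cells turn relative to
#' their last direction of movement.
#'
#' @param angles Numeric vector of signed angles in `(-180, 180]` degrees.
#' @param n_bins Number of bins; >= 2 and must divide 360 (default 8, i.e.
#'   45-degree bins).
#' @param group Optional group label carried on the histogram.
#' @param absolute When `TRUE`, bin `|angle|` over `(0, 180]` instead
#'   (left/right turns folded together); `n_bins` then partitions 180.
#' @return An object of class `angle_histogram`: list with `bin_edges_deg`,
#'   `counts` (integer, sums to `length(angles)`), `group`.
#' @export
bin_angles <- function(angles, n_bins = 8L, group = NA_character_,
                       absolute = FALSE) {
  check_scalar_number(n_bins, "n_bins", lower = 2)
  if (n_bins != round(n_bins) || 360 %% n_bins != 0) {
    config_error("n_bins", "must be an integer divisor of 360")
  }
  if (any(!is.finite(angles)) || any(angles <= -180) || any(angles > 180)) {
    input_error("angles must lie in (-180, 180] degrees; normalize upstream")
  }
  if (absolute) {
    angles <- abs(angles)
    edges <- seq(0, 180, length.out = n_bins + 1L)
    # |0| sits on the lowest edge of (0, 180]; keep it in the first bin
    counts <- tabulate(pmax(findInterval(angles, edges, left.open = TRUE), 1L),
                       nbins = n_bins)
  } else {
    edges <- seq(-180, 180, length.out = n_bins + 1L)
    counts <- tabulate(findInterval(angles, edges, left.open = TRUE),
                       nbins = n_bins)
  }
  structure(list(bin_edges_deg = edges, counts = as.integer(counts),
                 group = group),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  n <- length(x$counts)
  lab <- sprintf("(%g, %g]", x$bin_edges_deg[-(n + 1L)], x$bin_edges_deg[-1L])
  cat(sprintf("Angle histogram%s: %d angles in %d bins\n",
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              sum(x$counts), n))
  print(stats::setNames(x$counts, lab))
  invisible(x)
}

#' Group means and standard errors of velocity and persistence
#'
#' Summarizes a [track_metrics()] table per group.  Tracks with undefined
#' (stationary-cell) persistence are excluded from the persistence summary
#' and counted in the attribute `n_persistence_excluded`.  Groups with a
#' single track get an `NA` s.e.m. and a note.
#'
#' @param metrics Output of [track_metrics()].
#' @return Data frame `group`, `metric`, `n`, `mean`, `sem`, `note`.
#' @export
summarize_group_metrics <- function(metrics) {
  stopifnot(all(c("group", "velocity_um_per_min", "persistence") %in% names(metrics)))
  n_excl <- 0L
  rows <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g, ]
    for (m in c("velocity_um_per_min", "persistence")) {
      v <- sub[[m]]
      if (m == "persistence") {
        n_excl <- n_excl + sum(is.na(v))
        v <- v[!is.na(v)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g,
        metric = if (m == "persistence") "persistence" else "velocity",
        n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sem = if (length(v) >= 2L) sem(v) else NA_real_,
        note = if (length(v) >= 2L) "" else "n < 2: s.e.m. undefined",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_persistence_excluded = n_excl)
}
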