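# Track linking and kinematics.
#
# Linking follows the published acceptance rules exactly: nearest-neighbor
# association with a maximum frame-to-frame distance of 3 pixels (~192 nm at
# 64 nm pixels), no frame gaps, a 3-frame minimum track length, and
# whole-track rejection when any inter-segment angle exceeds 75 degrees.

#' Link localizations into motor tracks
#'
#' Frame-by-frame greedy nearest-neighbor assignment: all pairs
#' (active track end, next-frame detection) within `max_disp` are sorted by
#' distance and matched in ascending order, each endpoint and detection used
#' at most once. Unmatched detections seed new tracks; unmatched track ends
#' terminate (no frame gaps are permitted). Tracks shorter than `min_len`
#' frames are discarded and counted. Detections within a frame are put in a
#' canonical (y, x) order first, so linking is invariant to input row order.
#'
#' @param locs a `localization_table` (sorted by frame).
#' @param max_disp maximum frame-to-frame displacement in nm (default 192,
#'   i.e. 3 pixels at 64 nm).
#' @param min_len minimum track length in frames (default 3).
#' @param max_gap permitted frame gap; only 0 is supported (no gaps).
#' @return a `track_table`: list with `tracks` (per-localization data.frame:
#'   track_id, frame, x_nm, y_nm, precision_nm), `summary` (per-track
#'   kinematics), `rejected` counts and `params`.
#' @export
link_tracks <- function(locs, max_disp = 192, min_len = 3, max_gap = 0) {
  if (max_gap != 0) stop("only max_gap = 0 is supported (no frame gaps)")
  check_positive(max_disp, "max_disp")
  stopifnot(min_len >= 1)
  frame_interval <- attr(locs, "frame_interval_s")
  if (is.null(frame_interval)) frame_interval <- 0.1
  df <- as.data.frame(locs)
  if (!"precision_nm" %in% names(df)) df$precision_nm <- NA_real_
  df <- df[order(df$frame, df$y_nm, df$x_nm), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  track_of <- rep(NA_integer_, n)
  if (n > 0) {
    frames <- sort(unique(df$frame))
    idx_by_frame <- split(seq_len(n), df$frame)
    next_track <- 1L
    # active track ends: row index of last localization per open track
    first <- idx_by_frame[[as.character(frames[1])]]
    track_of[first] <- seq_len(length(first))
    next_track <- length(first) + 1L
    active <- first
    if (length(frames) > 1) for (fi in 2:length(frames)) {
      f <- frames[fi]
      det <- idx_by_frame[[as.character(f)]]
      if (f != frames[fi - 1] + 1L) active <- integer(0)  # gap: all terminate
      matched_det <- rep(FALSE, length(det))
      matched_act <- rep(FALSE, length(active))
      if (length(active) > 0 && length(det) > 0) {
        dx <- outer(df$x_nm[active], df$x_nm[det], "-")
        dy <- outer(df$y_nm[active], df$y_nm[det], "-")
        d <- sqrt(dx^2 + dy^2)
        ok <- which(d <= max_disp, arr.ind = TRUE)
        if (nrow(ok) > 0) {
          ord <- order(d[ok], ok[, 2], ok[, 1])  # distance, then det, then track
          for (r in ord) {
            a <- ok[r, 1]; dd <- ok[r, 2]
            if (matched_act[a] || matched_det[dd]) next
            matched_act[a] <- TRUE
            matched_det[dd] <- TRUE
            track_of[det[dd]] <- track_of[active[a]]
          }
        }
      }
      if (any(!matched_det)) {
        new_ids <- next_track + seq_len(sum(!matched_det)) - 1L
        track_of[det[!matched_det]] <- new_ids
        next_track <- next_track + length(new_ids)
      }
      active <- det
    }
  }
  df$track_id <- track_of
  lens <- table(df$track_id)
  keep_ids <- as.integer(names(lens)[lens >= min_len])
  n_short <- sum(lens < min_len)
  tracks <- df[df$track_id %in% keep_ids,
               c("track_id", "frame", "x_nm", "y_nm", "precision_nm")]
  # renumber consecutively in order of first appearance
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  tracks$track_id <- match(tracks$track_id, unique(tracks$track_id))
  rownames(tracks) <- NULL
  tt <- structure(list(tracks = tracks,
                       summary = NULL,
                       rejected = c(too_short = as.integer(n_short),
                                    angle = 0L),
                       params = list(max_disp = max_disp, min_len = min_len,
                                     max_gap = 0L,
                                     frame_interval_s = frame_interval)),
                  class = "track_table",
                  interpolated = FALSE)
  tt$summary <- summarize_tracks(tt)
  tt
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d tracks, %d localizations (rejected: %s)\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              paste(names(x$rejected), x$rejected, sep = "=", collapse = ", ")))
  invisible(x)
}

# per-track angles between consecutive displacement vectors (degrees);
# zero-length steps contribute 0 by convention
step_angles <- function(xy) {
  if (nrow(xy) < 3) return(numeric(0))
  v <- diff(xy)
  n <- sqrt(rowSums(v^2))
  a <- numeric(nrow(v) - 1)
  for (i in seq_along(a)) {
    if (n[i] == 0 || n[i + 1] == 0) { a[i] <- 0; next }
    cosang <- sum(v[i, ] * v[i + 1, ]) / (n[i] * n[i + 1])
    a[i] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  a
}

summarize_tracks <- function(tt) {
  dtf <- tt$params$frame_interval_s
  ids <- unique(tt$tracks$track_id)
  if (length(ids) == 0) {
    return(data.frame(track_id = integer(0), n_frames = integer(0),
                      speed_nm_s = numeric(0), mean_step_nm = numeric(0),
                      net_dx_nm = numeric(0), net_dy_nm = numeric(0),
                      max_angle_deg = numeric(0)))
  }
  do.call(rbind, lapply(ids, function(id) {
    sub <- tt$tracks[tt$tracks$track_id == id, ]
    xy <- cbind(sub$x_nm, sub$y_nm)
    k <- track_kinematics(xy, dtf)
    ang <- step_angles(xy)
    data.frame(track_id = id, n_frames = nrow(sub),
               speed_nm_s = k$speed_nm_s, mean_step_nm = k$mean_step_nm,
               net_dx_nm = xy[nrow(xy), 1] - xy[1, 1],
               net_dy_nm = xy[nrow(xy), 2] - xy[1, 2],
               max_angle_deg = if (length(ang)) max(ang) else 0)
  }))
}

#' Track kinematics from coordinates
#'
#' Speed is total path length divided by track duration; mean step is the
#' mean frame-to-frame displacement.
#'
#' @param xy n x 2 matrix of positions (nm), one row per frame.
#' @param frame_interval seconds per frame.
#' @return list with `speed_nm_s` and `mean_step_nm`.
#' @export
track_kinematics <- function(xy, frame_interval) {
  check_positive(frame_interval, "frame_interval")
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) stop("track must have at least 2 points")
  steps <- sqrt(rowSums(diff(xy)^2))
  list(speed_nm_s = sum(steps) / ((nrow(xy) - 1) * frame_interval),
       mean_step_nm = mean(steps))
}

#' Discard tracks with sharp turns
#'
#' A track is removed when any angle between consecutive displacement
#' vectors strictly exceeds `max_angle` degrees (whole-track rejection).
#'
#' @param tt a `track_table`.
#' @param max_angle threshold in degrees (default 75).
#' @return filtered `track_table` with updated rejection counts.
#' @export
filter_by_angle <- function(tt, max_angle = 75) {
  stopifnot(inherits(tt, "track_table"))
  keep_ids <- tt$summary$track_id[tt$summary$max_angle_deg <= max_angle]
  n_rej <- nrow(tt$summary) - length(keep_ids)
  tt$tracks <- tt$tracks[tt$tracks$track_id %in% keep_ids, ]
  rownames(tt$tracks) <- NULL
  tt$summary <- tt$summary[tt$summary$track_id %in% keep_ids, ]
  rownames(tt$summary) <- NULL
  tt$rejected["angle"] <- tt$rejected["angle"] + n_rej
  tt$params$max_angle <- max_angle
  tt
}

#' Write track tables as CSV
#'
#' `write_tracks_csv` writes per-localization rows (track_id, frame, x_nm,
#' y_nm, precision_nm, plus orientation if assigned);
#' `write_track_summary_csv` writes per-track kinematics.
#' @param tt a `track_table`.
#' @param path file path.
#' @export
write_tracks_csv <- function(tt, path) {
  utils::write.csv(tt$tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
write_track_summary_csv <- function(tt, path) {
  utils::write.csv(tt$summary, path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV back into a `track_table`
#' @param path file path.
#' @param frame_interval_s seconds per frame.
#' @export
read_tracks_csv <- function(path, frame_interval_s = 0.1) {
  df <- utils::read.csv(path)
  tt <- structure(list(tracks = df, summary = NULL,
                       rejected = c(too_short = NA_integer_, angle = NA_integer_),
                       params = list(frame_interval_s = frame_interval_s)),
                  class = "track_table", interpolated = FALSE)
  tt$summary <- summarize_tracks(tt)
  if ("orientation" %in% names(df)) {
    ori <- vapply(split(df$orientation, df$track_id)[
      as.character(tt$summary$track_id)], function(v) as.character(v[1]),
      character(1))
    tt$summary$orientation <- ori
  }
  tt
}
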