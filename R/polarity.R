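# Orientation classification of tracks and track densification.
#
# Because the motors are strictly plus-end-directed, a track's direction of
# motion reports the polarity of the microtubule underneath: an
# inward-moving motor (toward the soma) walked on a minus-end-OUT
# microtubule.

#' Neurite axis polyline
#'
#' Ordered polyline from the proximal end (soma) to the distal tip, used to
#' classify track direction as outward/inward by projected arclength.
#'
#' @param vertices matrix (>= 2 rows) with columns x_nm, y_nm, proximal
#'   first.
#' @return object of class `neurite_axis` with cumulative arclength.
#' @export
neurite_axis <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2, all(is.finite(vertices)))
  cs <- polyline_arclength(vertices)
  if (any(diff(cs) <= 0)) stop("axis arclength must be strictly increasing")
  colnames(vertices) <- c("x_nm", "y_nm")
  structure(list(vertices = vertices, arclength = cs), class = "neurite_axis")
}

#' Read / write an axis polyline CSV (vertex_index, x_nm, y_nm, proximal first)
#' @param path file path.
#' @export
read_axis_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$vertex_index), ]
  neurite_axis(cbind(df$x_nm, df$y_nm))
}

#' @rdname read_axis_csv
#' @param axis a `neurite_axis`.
#' @export
write_axis_csv <- function(axis, path) {
  utils::write.csv(data.frame(vertex_index = seq_len(nrow(axis$vertices)) - 1L,
                              x_nm = axis$vertices[, 1],
                              y_nm = axis$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Classify tracks into displacement quadrants
#'
#' The class is set by the signs of the track's total displacement
#' (`net_dx`, `net_dy`): Q++ (dx>0, dy>0), Q+- (dx>0, dy<0), Q-+ (dx<0,
#' dy>0), Q-- (dx<0, dy<0). An exactly zero component counts as positive
#' (the count of such ties is recorded in the table's provenance).
#'
#' @param tt a `track_table`.
#' @return the `track_table` with an `orientation` column in `summary` and
#'   `tracks`, scheme "quadrant".
#' @export
allocate_quadrant <- function(tt) {
  stopifnot(inherits(tt, "track_table"))
  sx <- tt$summary$net_dx_nm >= 0
  sy <- tt$summary$net_dy_nm >= 0
  lab <- paste0("Q", ifelse(sx, "+", "-"), ifelse(sy, "+", "-"))
  tt$summary$orientation <- lab
  tt$tracks$orientation <- lab[match(tt$tracks$track_id, tt$summary$track_id)]
  tt$params$orientation_scheme <- "quadrant"
  tt$params$zero_component_ties <-
    sum(tt$summary$net_dx_nm == 0 | tt$summary$net_dy_nm == 0)
  tt
}

#' Classify tracks as outward or inward along a neurite axis
#'
#' The first and last track points are projected onto the axis arclength;
#' the track is `outward` when the arclength increases (motor moving toward
#' the distal tip, so its microtubule is plus-end-out) and `inward`
#' otherwise (reporting a minus-end-out microtubule). Tracks whose endpoints
#' lie farther than `capture_nm` from the axis are left unclassified and
#' counted.
#'
#' @param tt a `track_table`.
#' @param axis a `neurite_axis`.
#' @param capture_nm maximum endpoint distance from the axis (default 2 um).
#' @return the `track_table` with an `orientation` column (outward/inward/
#'   NA), scheme "axis".
#' @export
allocate_axis <- function(tt, axis, capture_nm = 2000) {
  stopifnot(inherits(tt, "track_table"), inherits(axis, "neurite_axis"))
  ids <- tt$summary$track_id
  lab <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    sub <- tt$tracks[tt$tracks$track_id == ids[i], ]
    ends <- rbind(c(sub$x_nm[1], sub$y_nm[1]),
                  c(sub$x_nm[nrow(sub)], sub$y_nm[nrow(sub)]))
    pr <- polyline_project(axis$vertices, ends)
    if (max(pr$distance) > capture_nm) next
    lab[i] <- if (pr$arclength[2] > pr$arclength[1]) "outward" else "inward"
  }
  tt$summary$orientation <- lab
  tt$tracks$orientation <- lab[match(tt$tracks$track_id, tt$summary$track_id)]
  tt$params$orientation_scheme <- "axis"
  tt$params$capture_nm <- capture_nm
  tt$rejected["beyond_capture"] <- sum(is.na(lab))
  tt
}

#' Densify tracks by inserting localizations along each step
#'
#' Between each consecutive localization pair, points are inserted along the
#' straight segment at (at most) `spacing` nm: a step of length d is split
#' into `ceiling(d / spacing)` equal intervals, which gives exact 15-nm
#' spacing whenever d is a multiple of 15. Inserted points carry the average
#' precision of the two endpoints. The output is flagged `interpolated`, and
#' quantification functions refuse it: interpolation exists for rendering
#' only.
#'
#' @param tt a `track_table`.
#' @param spacing insertion spacing in nm (default 15).
#' @return a `track_table` with densified `tracks`, flagged interpolated.
#' @export
interpolate_track <- function(tt, spacing = 15) {
  stopifnot(inherits(tt, "track_table"))
  check_positive(spacing, "spacing")
  out <- vector("list", 0)
  has_ori <- "orientation" %in% names(tt$tracks)
  for (id in unique(tt$tracks$track_id)) {
    sub <- tt$tracks[tt$tracks$track_id == id, ]
    rows <- list(sub[1, , drop = FALSE])
    if (nrow(sub) > 1) for (i in 1:(nrow(sub) - 1)) {
      p0 <- c(sub$x_nm[i], sub$y_nm[i]); p1 <- c(sub$x_nm[i + 1], sub$y_nm[i + 1])
      d <- sqrt(sum((p1 - p0)^2))
      n_int <- if (d > spacing) ceiling(d / spacing) - 1L else 0L
      if (n_int > 0) {
        f <- seq_len(n_int) / (n_int + 1L)
        ins <- sub[rep(i, n_int), , drop = FALSE]
        ins$x_nm <- p0[1] + f * (p1[1] - p0[1])
        ins$y_nm <- p0[2] + f * (p1[2] - p0[2])
        ins$precision_nm <- mean(c(sub$precision_nm[i], sub$precision_nm[i + 1]))
        rows <- c(rows, list(ins))
      }
      rows <- c(rows, list(sub[i + 1, , drop = FALSE]))
    }
    out <- c(out, rows)
  }
  tt$tracks <- if (length(out)) do.call(rbind, out) else tt$tracks
  rownames(tt$tracks) <- NULL
  attr(tt, "interpolated") <- TRUE
  tt$params$interpolation_spacing_nm <- spacing
  tt
}

# guard used by all quantification entry points
assert_not_interpolated <- function(x, what = "this quantification") {
  if (isTRUE(attr(x, "interpolated")))
    stop(what, " must be computed on non-interpolated data", call. = FALSE)
  invisible(x)
}
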