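# Quantitative polarity readouts: the overlap correlation C between
# orientation channels across rendering pixel sizes, and minus-end-out
# fractions in axis segments. All quantifications refuse interpolated
# inputs.

#' Overlap correlation between two images
#'
#' `C = sum(a*b) / sqrt(sum(a^2) * sum(b^2))` — the normalized inner product
#' with no mean subtraction, so C lies in \[0, 1\] for nonnegative images:
#' 1 for identical (or proportional) images, 0 for disjoint support.
#'
#' @param img_a,img_b numeric matrices of equal shape (or `sr_image`s).
#' @return C in \[0, 1\]; NA (with a warning) when either image is all zero.
#' @export
overlap_correlation <- function(img_a, img_b) {
  a <- if (inherits(img_a, "sr_image")) img_a$intensity else img_a
  b <- if (inherits(img_b, "sr_image")) img_b$intensity else img_b
  if (!all(dim(a) == dim(b))) stop("images must have equal shapes")
  if (any(a < 0) || any(b < 0)) stop("intensities must be nonnegative")
  na <- sum(a^2); nb <- sum(b^2)
  if (na == 0 || nb == 0) {
    warning("overlap correlation undefined: an image is all zero")
    return(NA_real_)
  }
  sum(a * b) / sqrt(na * nb)
}

# common render extent for a set of localization tables
common_extent <- function(dfs, pad) {
  xs <- unlist(lapply(dfs, function(d) d$x_nm))
  ys <- unlist(lapply(dfs, function(d) d$y_nm))
  list(x = c(min(xs) - pad, max(xs) + pad), y = c(min(ys) - pad, max(ys) + pad))
}

#' Overlap correlation versus rendering pixel size
#'
#' For each pixel size both localization sets are histogram-rendered on a
#' common grid and the overlap correlation `C_in_out` is computed. The
#' control curve `C_odd_even` splits the pooled localizations by the parity
#' of their within-track index (odd vs even) and correlates those two
#' images: it measures the correlation floor set by sampling alone, since
#' both halves sample the same structures. Histogram rendering (not
#' Gaussian) is used so the sweep probes spatial structure, not kernel
#' width. Inputs must be non-interpolated and carry a `track_id` column.
#'
#' @param locs_a,locs_b data.frames of localizations of the two orientation
#'   channels (columns x_nm, y_nm, track_id) or `track_table`s (their
#'   `tracks` are used, split is the caller's job for channels).
#' @param pixel_sizes numeric vector of rendering pixel sizes (nm).
#' @return data.frame with pixel_size_nm, C_in_out, C_odd_even.
#' @export
correlation_vs_pixel_size <- function(locs_a, locs_b,
                                      pixel_sizes = c(50, 100, 200, 400, 800)) {
  assert_not_interpolated(locs_a, "correlation analysis")
  assert_not_interpolated(locs_b, "correlation analysis")
  a <- if (inherits(locs_a, "track_table")) locs_a$tracks else as.data.frame(locs_a)
  b <- if (inherits(locs_b, "track_table")) locs_b$tracks else as.data.frame(locs_b)
  if (!"track_id" %in% names(a) || !"track_id" %in% names(b))
    stop("localizations must carry a track_id column")
  pooled <- rbind(a[, c("x_nm", "y_nm", "track_id")],
                  b[, c("x_nm", "y_nm", "track_id")])
  # within-track localization index parity (tracks of a and b are disjoint sets
  # of rows here; parity is per original track)
  grp <- c(paste0("a", a$track_id), paste0("b", b$track_id))
  idx <- stats::ave(seq_len(nrow(pooled)), grp, FUN = seq_along)
  odd <- pooled[idx %% 2 == 1L, ]
  even <- pooled[idx %% 2 == 0L, ]
  ext <- common_extent(list(pooled), pad = max(pixel_sizes))
  out <- lapply(pixel_sizes, function(px) {
    ia <- reconstruct(a, px, mode = "histogram", extent = ext)
    ib <- reconstruct(b, px, mode = "histogram", extent = ext)
    io <- reconstruct(odd, px, mode = "histogram", extent = ext)
    ie <- reconstruct(even, px, mode = "histogram", extent = ext)
    data.frame(pixel_size_nm = px,
               C_in_out = overlap_correlation(ia, ib),
               C_odd_even = overlap_correlation(io, ie))
  })
  do.call(rbind, out)
}

#' Minus-end-out fraction in an axis segment
#'
#' Each localization of an orientation-classified track counts with unit
#' weight; localizations whose axis projection falls in
#' `[segment_start, segment_start + segment_len)` are summed per class. The
#' minus-end-out fraction is `inward / (inward + outward)`: motors moving
#' inward are plus-end-directed, so they report minus-end-out microtubules.
#' A per-position profile binned at `profile_bin_um` is also returned.
#'
#' @param tt a `track_table` with an axis `orientation` column
#'   (outward/inward), non-interpolated.
#' @param axis a `neurite_axis`.
#' @param segment_start segment start along the axis (um).
#' @param segment_len segment length (um, default 5).
#' @param profile_bin_um profile bin width (um, default 0.5).
#' @return object of class `segment_quant`: list with `sum_inward`,
#'   `sum_outward`, `frac_minus_out`, `profile`, and the segment definition;
#'   `frac_minus_out` is NA (flagged) for an empty segment.
#' @export
segment_fraction <- function(tt, axis, segment_start, segment_len = 5,
                             profile_bin_um = 0.5) {
  assert_not_interpolated(tt, "ratio analysis")
  stopifnot(inherits(tt, "track_table"), inherits(axis, "neurite_axis"))
  if (!"orientation" %in% names(tt$tracks))
    stop("tracks must carry axis orientation classes; run allocate_axis() first")
  df <- tt$tracks[!is.na(tt$tracks$orientation), ]
  s_um <- polyline_project(axis$vertices,
                           cbind(df$x_nm, df$y_nm))$arclength / 1000
  in_seg <- s_um >= segment_start & s_um < segment_start + segment_len
  seg <- df[in_seg, ]
  s_seg <- s_um[in_seg]
  sum_in <- sum(seg$orientation == "inward")
  sum_out <- sum(seg$orientation == "outward")
  frac <- if (sum_in + sum_out > 0) sum_in / (sum_in + sum_out) else NA_real_
  brk <- seq(segment_start, segment_start + segment_len, by = profile_bin_um)
  prof <- data.frame(
    pos_um = utils::head(brk, -1) + profile_bin_um / 2,
    inward = as.numeric(table(cut(s_seg[seg$orientation == "inward"], brk,
                                  right = FALSE))),
    outward = as.numeric(table(cut(s_seg[seg$orientation == "outward"], brk,
                                   right = FALSE))))
  structure(list(segment_start_um = segment_start,
                 segment_len_um = segment_len,
                 sum_inward = sum_in, sum_outward = sum_out,
                 frac_minus_out = frac, empty = sum_in + sum_out == 0,
                 profile = prof),
            class = "segment_quant")
}

#' @export
print.segment_quant <- function(x, ...) {
  cat(sprintf(
    "<segment_quant> [%.1f, %.1f) um: inward %d, outward %d, minus-end-out %.3f\n",
    x$segment_start_um, x$segment_start_um + x$segment_len_um,
    x$sum_inward, x$sum_outward, x$frac_minus_out))
  invisible(x)
}

#' Write a correlation curve / segment quantification CSV
#' @param curve data.frame from [correlation_vs_pixel_size()].
#' @param path file path.
#' @export
write_correlation_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @param sq a `segment_quant`.
#' @export
write_segment_csv <- function(sq, path) {
  utils::write.csv(data.frame(start_um = sq$segment_start_um,
                              len_um = sq$segment_len_um,
                              sum_in = sq$sum_inward, sum_out = sq$sum_outward,
                              frac_minus_out = sq$frac_minus_out),
                   path, row.names = FALSE)
  invisible(path)
}
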