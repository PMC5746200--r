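# Shared fixtures, all generated in code.

# hand-constructed ground truth from a positions data.frame
make_truth <- function(positions, n_frames, frame_interval_s = 0.1,
                       photons_per_frame = 500) {
  positions$t_s <- positions$frame * frame_interval_s
  if (is.null(positions$filament_id))
    positions$filament_id <- rep(1L, nrow(positions))
  if (is.null(positions$direction))
    positions$direction <- rep("outward", nrow(positions))
  structure(list(positions = positions,
                 motors = data.frame(motor_id = unique(positions$motor_id)),
                 network = NULL),
            class = "motor_truth", frame_interval_s = frame_interval_s,
            duration_s = n_frames * frame_interval_s, n_frames = n_frames,
            seed = NA_integer_, photons_per_frame = photons_per_frame)
}

# ideal localization table from ground truth: every position detected, with
# isotropic Gaussian localization error of SD `sigma` per coordinate
truth_locs <- function(truth, sigma = 10, seed = 1) {
  pos <- truth$positions
  withr::with_seed(seed, {
    as_localization_table(data.frame(
      frame = pos$frame,
      x_nm = pos$x_nm + rnorm(nrow(pos), 0, sigma),
      y_nm = pos$y_nm + rnorm(nrow(pos), 0, sigma),
      photons = 500, sigma_nm = 77, offset = 10,
      precision_nm = max(sigma, 1), fit_ok = TRUE),
      n_frames = attr(truth, "n_frames"))
  })
}

# per-motor ground-truth tracks (>= 3 frames) as a plain tracks data.frame
truth_tracks <- function(truth, min_len = 3) {
  pos <- truth$positions
  keep <- names(which(table(pos$motor_id) >= min_len))
  df <- pos[pos$motor_id %in% as.integer(keep), ]
  data.frame(track_id = df$motor_id, frame = df$frame, x_nm = df$x_nm,
             y_nm = df$y_nm, precision_nm = 10, orientation = df$direction)
}

# strictly alternating-polarity parallel filaments (interdigitated null)
alternating_network <- function(n_filaments = 16, spacing_nm = 50,
                                length_nm = 5000, origin = c(600, 600)) {
  fil <- lapply(seq_len(n_filaments), function(i) {
    y <- origin[2] + (i - 1) * spacing_nm
    x0 <- origin[1]; x1 <- origin[1] + length_nm
    if (i %% 2 == 0) rbind(c(x1, y), c(x0, y)) else rbind(c(x0, y), c(x1, y))
  })
  mt_network(fil)
}

# match each recovered track to the ground-truth motor owning most of its
# localizations; returns data.frame(track_id, motor_id, purity)
match_tracks <- function(tt, truth, radius_nm = 150) {
  pos <- truth$positions
  ids <- unique(tt$tracks$track_id)
  out <- lapply(ids, function(id) {
    sub <- tt$tracks[tt$tracks$track_id == id, ]
    mids <- vapply(seq_len(nrow(sub)), function(r) {
      tr <- pos[pos$frame == sub$frame[r], ]
      if (nrow(tr) == 0) return(NA_integer_)
      d <- sqrt((tr$x_nm - sub$x_nm[r])^2 + (tr$y_nm - sub$y_nm[r])^2)
      if (min(d) < radius_nm) tr$motor_id[which.min(d)] else NA_integer_
    }, integer(1))
    mt <- table(mids)
    if (length(mt) == 0)
      return(data.frame(track_id = id, motor_id = NA_integer_, purity = 0))
    data.frame(track_id = id, motor_id = as.integer(names(which.max(mt))),
               purity = max(mt) / nrow(sub))
  })
  do.call(rbind, out)
}

# a straight-line track table at given step length, pointing along +x
straight_track_locs <- function(n = 5, step = 75, start = c(1000, 1000),
                                frame0 = 0) {
  data.frame(frame = frame0 + seq_len(n) - 1L,
             x_nm = start[1] + (seq_len(n) - 1) * step,
             y_nm = start[2],
             photons = 500, sigma_nm = 77, offset = 10, precision_nm = 10,
             fit_ok = TRUE)
}

# build a track_table directly from a tracks data.frame
as_track_table <- function(tracks, frame_interval_s = 0.1) {
  tt <- structure(list(tracks = tracks, summary = NULL,
                       rejected = c(too_short = 0L, angle = 0L),
                       params = list(frame_interval_s = frame_interval_s)),
                  class = "track_table", interpolated = FALSE)
  tt$summary <- motorpaint:::summarize_tracks(tt)
  if ("orientation" %in% names(tracks)) {
    ori <- vapply(split(tracks$orientation, tracks$track_id)[
      as.character(tt$summary$track_id)], function(v) as.character(v[1]),
      character(1))
    tt$summary$orientation <- ori
  }
  tt
}

# minus-end-out fraction recovered from ground-truth tracks of a simulation
fraction_from_truth <- function(net, axis, seed, duration = 60,
                                kin = motor_kinetics(landing_rate = 0.1)) {
  truth <- simulate_motors(net, kin, duration, seed = seed)
  tt <- as_track_table(truth_tracks(truth))
  tt <- allocate_axis(tt, axis, capture_nm = Inf)
  seg_len <- (max(axis$arclength) / 1000)
  segment_fraction(tt, axis, segment_start = 0, segment_len = seg_len)$frac_minus_out
}

# render a single integrated-Gaussian spot (no noise) into a matrix
render_spot <- function(nr, nc, x_px, y_px, sigma_px = 75 / 64,
                        photons = 1000, offset = 0) {
  cols <- 0:(nc - 1); rows <- 0:(nr - 1)
  mx <- pnorm(cols + 1 - x_px, sd = sigma_px) - pnorm(cols - x_px, sd = sigma_px)
  my <- pnorm(rows + 1 - y_px, sd = sigma_px) - pnorm(rows - y_px, sd = sigma_px)
  offset + photons * outer(my, mx)
}
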