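# Single-molecule localization: Mexican-hat (LoG) spot detection, 2D
# Gaussian fitting by Levenberg-Marquardt least squares, Thompson-style
# precision, and drift correction from cross-correlated intermediate
# reconstructions.

# normalized Mexican-hat kernel (negated, zero-mean Laplacian of Gaussian)
# with scale sigma_px; spots produce positive responses
log_kernel <- function(sigma_px) {
  h <- max(2L, ceiling(4 * sigma_px))
  g <- -h:h
  xx <- matrix(g, 2 * h + 1, 2 * h + 1)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^4 * exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k)           # zero response to constant images
  k / sqrt(sum(k^2))         # unit energy
}

#' Detect candidate single-molecule spots in one frame
#'
#' The frame is convolved with a Mexican-hat (negated Laplacian-of-Gaussian)
#' kernel whose scale matches the PSF; candidates are 8-neighborhood local
#' maxima of the filtered image exceeding `threshold_k` times a robust (MAD)
#' estimate of the filtered noise SD. Candidates closer than `2 * psf_sigma`
#' are merged to the brighter one.
#'
#' @param frame_image 2D numeric matrix (photons).
#' @param psf_sigma PSF sigma in nm.
#' @param pixel_size pixel size in nm.
#' @param threshold_k detection threshold in robust noise SDs.
#' @return data.frame with columns `x_px`, `y_px` (continuous pixel
#'   coordinates, origin at the outer image corner) and `response`.
#' @export
detect_spots <- function(frame_image, psf_sigma = 75, pixel_size = 64,
                         threshold_k = 5) {
  if (!is.matrix(frame_image) || !is.numeric(frame_image))
    stop("frame_image must be a 2D numeric matrix")
  check_positive(threshold_k, "threshold_k")
  sigma_px <- psf_sigma / pixel_size
  kern <- log_kernel(sigma_px)
  filt <- EBImage::filter2(frame_image, kern, boundary = "replicate")
  noise <- stats::mad(filt)
  if (noise <= 0) noise <- stats::sd(filt)
  # numeric floor against round-off on constant/noiseless input
  noise <- max(noise, 1e-9 * max(abs(frame_image)), .Machine$double.eps)
  if (!is.finite(noise) || noise <= 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      response = numeric(0)))
  }
  thr <- threshold_k * noise
  nr <- nrow(filt); nc <- ncol(filt)
  is_max <- filt > thr
  # strict local maximum over 8-neighborhood (ties suppressed on one side)
  shift_ge <- function(dr, dc) {
    m <- matrix(-Inf, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    m[r_src + dr, c_src + dc] <- filt[r_src, c_src]
    m
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_ge(dr, dc)
    cmp <- if (dr < 0 || (dr == 0 && dc < 0)) filt >= nb else filt > nb
    is_max <- is_max & cmp
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      response = numeric(0)))
  cand <- data.frame(x_px = idx[, 2] - 0.5, y_px = idx[, 1] - 0.5,
                     response = filt[idx])
  cand <- cand[order(-cand$response), ]
  # merge candidates closer than 2 * psf_sigma: keep the brighter one
  min_d2 <- (2 * sigma_px)^2
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x_px[j] - cand$x_px[i])^2 + (cand$y_px[j] - cand$y_px[i])^2
      keep[j[d2 < min_d2]] <- FALSE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Fit a 2D Gaussian to a candidate ROI by Levenberg-Marquardt least squares
#'
#' Unweighted nonlinear least squares of
#' `offset + A * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))` sampled at pixel
#' centers. The fit is flagged not-ok (never an error) if it diverges, the
#' fitted sigma leaves `[0.5, 3] * psf_sigma`, or the center leaves the ROI.
#'
#' @param roi square numeric matrix, the window around the candidate.
#' @param init list/vector with elements `x_px`, `y_px`: initial center in
#'   ROI pixel coordinates (origin at the ROI's outer corner).
#' @param psf_sigma_px expected PSF sigma in pixels (initializer and bound
#'   reference).
#' @return list with `x_px`, `y_px`, `sigma_px`, `amplitude`, `offset`,
#'   `photons` (2 pi A sigma^2) and `fit_ok`.
#' @export
fit_gaussian_2d <- function(roi, init, psf_sigma_px = 1.2) {
  if (!is.matrix(roi) || !is.numeric(roi)) stop("roi must be a numeric matrix")
  nr <- nrow(roi); nc <- ncol(roi)
  bad <- list(x_px = NA_real_, y_px = NA_real_, sigma_px = NA_real_,
              amplitude = NA_real_, offset = NA_real_, photons = NA_real_,
              fit_ok = FALSE)
  rng <- range(roi)
  if (!all(is.finite(roi)) || diff(rng) <= 0) return(bad)
  xs <- rep(seq_len(nc) - 0.5, each = nr)   # pixel-center coordinates
  ys <- rep(seq_len(nr) - 0.5, times = nc)
  z <- as.numeric(roi)
  start <- c(A = diff(rng), x0 = as.numeric(init$x_px),
             y0 = as.numeric(init$y_px), sigma = psf_sigma_px, off = rng[1])
  resid_fn <- function(p) {
    p["off"] + p["A"] * exp(-((xs - p["x0"])^2 + (ys - p["y0"])^2) /
                              (2 * p["sigma"]^2)) - z
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- fit$par
  sigma <- abs(p[["sigma"]])
  converged <- is.numeric(fit$info) && fit$info %in% 1:4
  ok <- converged &&
    is.finite(p[["x0"]]) && is.finite(p[["y0"]]) && is.finite(sigma) &&
    p[["A"]] > 0 &&
    sigma >= 0.5 * psf_sigma_px && sigma <= 3 * psf_sigma_px &&
    p[["x0"]] >= 0 && p[["x0"]] <= nc && p[["y0"]] >= 0 && p[["y0"]] <= nr
  list(x_px = p[["x0"]], y_px = p[["y0"]], sigma_px = sigma,
       amplitude = p[["A"]], offset = p[["off"]],
       photons = 2 * pi * p[["A"]] * sigma^2, fit_ok = isTRUE(ok))
}

# Thompson-style localization precision (nm): pixelation + background terms
thompson_precision <- function(sigma_nm, pixel_nm, photons, bg_var) {
  if (!is.finite(photons) || photons <= 0) return(NA_real_)
  v <- (sigma_nm^2 + pixel_nm^2 / 12) / photons +
    8 * pi * sigma_nm^4 * bg_var / (pixel_nm^2 * photons^2)
  sqrt(v)
}

#' Localize an entire movie
#'
#' Per frame: Mexican-hat detection, then an LM 2D-Gaussian fit in a square
#' ROI of half-width `ceiling(3 * psf_sigma)` pixels around each candidate.
#' Precision is estimated with a Thompson-style formula from the fitted
#' sigma, photon count, pixel size and local background variance. Drift is
#' then estimated from intermediate reconstructions and subtracted.
#'
#' @param movie a `motor_movie`.
#' @param psf_sigma PSF sigma (nm); defaults to the movie's optics.
#' @param threshold_k detection threshold (robust SDs).
#' @param correct_drift logical; estimate and subtract drift.
#' @param drift_bins,drift_render_px drift-estimation parameters, see
#'   [estimate_drift()].
#' @param keep_failed keep rows with `fit_ok = FALSE` (default drops them).
#' @return a `localization_table`: data.frame with columns frame, x_nm,
#'   y_nm, photons, sigma_nm, offset, precision_nm, fit_ok; attributes
#'   `pixel_size_nm`, `frame_interval_s`, `interpolated = FALSE`, and
#'   `drift` (the subtracted `drift_series`, if any).
#' @export
localize_movie <- function(movie, psf_sigma = NULL, threshold_k = 5,
                           correct_drift = TRUE, drift_bins = 10,
                           drift_render_px = 32, keep_failed = FALSE) {
  stopifnot(inherits(movie, "motor_movie"))
  optics <- movie$optics
  if (is.null(psf_sigma)) psf_sigma <- optics$psf_sigma
  s <- optics$pixel_size
  sigma_px <- psf_sigma / s
  w <- max(3L, ceiling(3 * sigma_px))
  n_frames <- dim(movie$frames)[3]
  nr <- dim(movie$frames)[1]; nc <- dim(movie$frames)[2]
  rows <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    img <- movie$frames[, , k]
    cand <- detect_spots(img, psf_sigma, s, threshold_k)
    if (nrow(cand) == 0L) next
    out <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      cr <- floor(cand$y_px[i]) + 1L  # row index of candidate pixel
      cc <- floor(cand$x_px[i]) + 1L
      r0 <- cr - w; r1 <- cr + w; c0 <- cc - w; c1 <- cc + w
      if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc) next  # edge ROI skipped
      roi <- img[r0:r1, c0:c1]
      fit <- fit_gaussian_2d(roi,
                             init = list(x_px = cand$x_px[i] - (c0 - 1),
                                         y_px = cand$y_px[i] - (r0 - 1)),
                             psf_sigma_px = sigma_px)
      if (!fit$fit_ok && !keep_failed) next
      x_nm <- (fit$x_px + (c0 - 1)) * s
      y_nm <- (fit$y_px + (r0 - 1)) * s
      sigma_nm <- fit$sigma_px * s
      bg_var <- max(fit$offset, 0)   # Poisson background: variance ~ mean
      out[[i]] <- data.frame(
        frame = k - 1L, x_nm = x_nm, y_nm = y_nm, photons = fit$photons,
        sigma_nm = sigma_nm, offset = fit$offset,
        precision_nm = thompson_precision(sigma_nm, s, fit$photons, bg_var),
        fit_ok = fit$fit_ok)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) rows[[k]] <- do.call(rbind, out)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  locs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0),
               photons = numeric(0), sigma_nm = numeric(0),
               offset = numeric(0), precision_nm = numeric(0),
               fit_ok = logical(0))
  rownames(locs) <- NULL
  locs <- as_localization_table(locs, pixel_size_nm = s,
                                frame_interval_s = optics$frame_interval,
                                n_frames = n_frames)
  if (correct_drift && nrow(locs) > 0 && n_frames >= drift_bins * 2) {
    dr <- tryCatch(estimate_drift(locs, n_bins = drift_bins,
                                  render_px = drift_render_px),
                   error = function(e) NULL)
    if (!is.null(dr)) {
      locs <- apply_drift(locs, dr)
      attr(locs, "drift") <- dr
    }
  }
  locs
}

#' Construct a localization table
#' @param df data.frame with at least frame, x_nm, y_nm.
#' @param pixel_size_nm,frame_interval_s acquisition metadata.
#' @param n_frames movie frame count (for drift interpolation).
#' @param interpolated logical flag; quantification functions refuse
#'   interpolated tables.
#' @export
as_localization_table <- function(df, pixel_size_nm = 64,
                                  frame_interval_s = 0.1, n_frames = NULL,
                                  interpolated = FALSE) {
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("localization_table", "data.frame"),
            pixel_size_nm = pixel_size_nm,
            frame_interval_s = frame_interval_s,
            n_frames = if (is.null(n_frames)) max(df$frame, -1L) + 1L else n_frames,
            interpolated = interpolated)
}

#' Estimate stage drift from intermediate reconstructions
#'
#' Localizations are split into `n_bins` equal temporal bins; each bin is
#' rendered as a 2D histogram at `render_px` and the shift of each bin
#' against bin 0 is read from the cross-correlation peak, localized to
#' subpixel precision by a 2D Gaussian fit on its 5x5 neighborhood. The
#' per-frame drift interpolates linearly between bin centers (anchors), with
#' linear extrapolation beyond the first/last anchor; bin 0 is the zero
#' reference.
#'
#' @param locs a `localization_table`.
#' @param n_bins number of temporal bins (>= 2).
#' @param render_px rendering pixel size (nm).
#' @param max_shift_nm peak-search window per axis: bin-to-bin drift is
#'   assumed smaller than this (default 600 nm), which keeps the estimator
#'   from locking onto spurious self-similarity of sparse reconstructions.
#' @return a `drift_series`: data.frame with frame, dx_nm, dy_nm.
#' @export
estimate_drift <- function(locs, n_bins = 10, render_px = 32,
                           max_shift_nm = 600) {
  stopifnot(n_bins >= 2)
  n_frames <- attr(locs, "n_frames")
  if (is.null(n_frames) || n_frames < n_bins) n_frames <- max(locs$frame) + 1L
  edges <- seq(0, n_frames, length.out = n_bins + 1)
  bin <- findInterval(locs$frame, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  if (min(table(factor(bin, levels = seq_len(n_bins)))) < 100)
    warning("fewer than 100 localizations in some drift bins; estimate may be noisy")
  # common render grid
  pad <- 4 * render_px
  x0 <- min(locs$x_nm) - pad; x1 <- max(locs$x_nm) + pad
  y0 <- min(locs$y_nm) - pad; y1 <- max(locs$y_nm) + pad
  nc <- max(8L, ceiling((x1 - x0) / render_px))
  nr <- max(8L, ceiling((y1 - y0) / render_px))
  hist_bin <- function(sel) {
    img <- matrix(0, nr, nc)
    if (!any(sel)) return(img)
    cx <- pmin(pmax(floor((locs$x_nm[sel] - x0) / render_px), 0), nc - 1) + 1L
    cy <- pmin(pmax(floor((locs$y_nm[sel] - y0) / render_px), 0), nr - 1) + 1L
    tab <- table(cy, cx)
    img[cbind(as.integer(rownames(tab))[row(tab)],
              as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
    img
  }
  ref <- hist_bin(bin == 1L)
  anchors <- matrix(NA_real_, n_bins, 2)
  anchors[1, ] <- c(0, 0)
  for (b in 2:n_bins) {
    img <- hist_bin(bin == b)
    if (sum(img) == 0) { warning("empty drift bin ", b); next }
    sh <- xcorr_shift(ref, img, max_shift_px = max_shift_nm / render_px)
    if (any(!is.finite(sh))) next
    anchors[b, ] <- sh * render_px
  }
  # interpolate missing anchors from neighbors
  for (j in 1:2) {
    v <- anchors[, j]
    if (anyNA(v)) {
      ok <- which(!is.na(v))
      anchors[, j] <- stats::approx(ok, v[ok], xout = seq_len(n_bins),
                                    rule = 2)$y
    }
  }
  centers <- (edges[-length(edges)] + edges[-1]) / 2 - 0.5  # frame index of bin center
  frames <- seq_len(n_frames) - 1L
  interp_extrap <- function(v) {
    out <- stats::approx(centers, v, xout = frames, rule = 2)$y
    # linear extrapolation using the first/last segments
    if (n_bins >= 2) {
      s1 <- (v[2] - v[1]) / (centers[2] - centers[1])
      s2 <- (v[n_bins] - v[n_bins - 1]) / (centers[n_bins] - centers[n_bins - 1])
      lo <- frames < centers[1]; hi <- frames > centers[n_bins]
      out[lo] <- v[1] + s1 * (frames[lo] - centers[1])
      out[hi] <- v[n_bins] + s2 * (frames[hi] - centers[n_bins])
    }
    out
  }
  structure(data.frame(frame = frames,
                       dx_nm = interp_extrap(anchors[, 1]),
                       dy_nm = interp_extrap(anchors[, 2])),
            class = c("drift_series", "data.frame"), render_px = render_px,
            anchors = anchors, anchor_frames = centers)
}

# shift (dx_px, dy_px) of image b relative to image a from the circular
# cross-correlation peak, subpixel via a 2D Gaussian fit on its 5x5 patch;
# the peak search is restricted to |shift| <= max_shift_px per axis (drift
# between temporal bins is small compared to the imaged structure, and an
# unrestricted search can lock onto spurious self-similarity of sparse
# reconstructions)
xcorr_shift <- function(a, b, max_shift_px = Inf) {
  nr <- nrow(a); nc <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  cc_search <- cc
  if (is.finite(max_shift_px)) {
    sr <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr, seq_len(nr) - 1)
    sc <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc, seq_len(nc) - 1)
    mask <- outer(abs(sr) <= max_shift_px, abs(sc) <= max_shift_px)
    cc_search[!mask] <- -Inf
  }
  peak <- which(cc_search == max(cc_search), arr.ind = TRUE)[1, ]
  # wrap indices to signed shifts (a shifted by +d matches b at index 1+d)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  pr <- peak[1]; pc <- peak[2]
  patch_idx_r <- ((pr - 3):(pr + 1)) %% nr + 1L
  patch_idx_c <- ((pc - 3):(pc + 1)) %% nc + 1L
  patch <- cc[patch_idx_r, patch_idx_c]
  patch <- patch - min(patch)
  fit <- fit_gaussian_2d(patch, init = list(x_px = 2.5, y_px = 2.5),
                         psf_sigma_px = 1.2)
  sub_r <- if (fit$fit_ok) fit$y_px - 2.5 else 0
  sub_c <- if (fit$fit_ok) fit$x_px - 2.5 else 0
  dy <- wrap(pr, nr) + sub_r
  dx <- wrap(pc, nc) + sub_c
  # b appears shifted by (-dx, -dy) relative to a in this convention
  c(-dx, -dy)
}

#' Subtract a drift series from a localization table
#' @param locs a `localization_table`.
#' @param drift a `drift_series` (frame, dx_nm, dy_nm).
#' @export
apply_drift <- function(locs, drift) {
  i <- match(locs$frame, drift$frame)
  locs$x_nm <- locs$x_nm - drift$dx_nm[i]
  locs$y_nm <- locs$y_nm - drift$dy_nm[i]
  locs
}

#' Write / read a localization table CSV
#' Columns: frame, x_nm, y_nm, photons, sigma_nm, offset, precision_nm, fit_ok.
#' @param locs a `localization_table`.
#' @param path file path.
#' @export
write_locs_csv <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locs_csv
#' @param pixel_size_nm,frame_interval_s metadata to attach.
#' @export
read_locs_csv <- function(path, pixel_size_nm = 64, frame_interval_s = 0.1) {
  as_localization_table(utils::read.csv(path), pixel_size_nm,
                        frame_interval_s)
}
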