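# Camera forward model: render ground-truth motor positions into a noisy
# multi-frame movie.
#
# Coordinate convention: continuous nm coordinates with the origin at the
# outer corner of pixel (0,0); pixel (r,c) covers the half-open square
# [c*s, (c+1)*s) x [r*s, (r+1)*s); the row index r increases downward with y.

#' Render a ground-truth simulation into a camera movie
#'
#' Each visible motor contributes an integrated 2D Gaussian of width
#' `psf_sigma` centered at its true position (plus any per-frame drift);
#' pixel values are Poisson(signal + background) plus Gaussian read noise.
#' Rendering is deterministic for a fixed seed.
#'
#' @param truth a `motor_truth` from [simulate_motors()].
#' @param optics an `optics_camera`.
#' @param seed integer seed for shot/read noise.
#' @return object of class `motor_movie`: list with `frames` (rows x cols x
#'   n_frames array, photon units), `optics`, and `n_clipped` (count of
#'   motor-frames outside the field of view, silently clipped).
#' @export
render_movie <- function(truth, optics, seed = 1L) {
  stopifnot(inherits(truth, "motor_truth"), inherits(optics, "optics_camera"))
  n_frames <- attr(truth, "n_frames")
  nr <- optics$image_shape[1]; nc <- optics$image_shape[2]
  s <- optics$pixel_size; sig <- optics$psf_sigma
  drift <- optics$drift
  if (!is.null(drift) && nrow(drift) < n_frames)
    stop("drift series shorter than movie (", nrow(drift), " < ", n_frames, ")")
  pos <- truth$positions
  ppf <- truth_photons(truth)
  frames <- array(0, dim = c(nr, nc, n_frames))
  n_clipped <- 0L
  w <- ceiling(4 * sig / s)  # render window half-width, px

  for (k in seq_len(n_frames)) {
    img <- matrix(0, nr, nc)
    rows <- which(pos$frame == k - 1L)
    if (length(rows) > 0L) {
      dx <- if (is.null(drift)) 0 else drift[k, 1]
      dy <- if (is.null(drift)) 0 else drift[k, 2]
      for (i in rows) {
        x <- pos$x_nm[i] + dx
        y <- pos$y_nm[i] + dy
        cx <- x / s; cy <- y / s  # continuous px
        if (cx < 0 || cx >= nc || cy < 0 || cy >= nr) {
          n_clipped <- n_clipped + 1L
          next
        }
        c0 <- max(0L, floor(cx) - w); c1 <- min(nc - 1L, floor(cx) + w)
        r0 <- max(0L, floor(cy) - w); r1 <- min(nr - 1L, floor(cy) + w)
        cols_px <- c0:c1; rows_px <- r0:r1
        mx <- pnorm(((cols_px + 1) * s - x) / sig) - pnorm((cols_px * s - x) / sig)
        my <- pnorm(((rows_px + 1) * s - y) / sig) - pnorm((rows_px * s - y) / sig)
        img[rows_px + 1L, cols_px + 1L] <-
          img[rows_px + 1L, cols_px + 1L] + ppf[i] * outer(my, mx)
      }
    }
    frames[, , k] <- img
  }

  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      lam <- frames[, , k] + optics$background
      noisy <- rpois(nr * nc, lam)
      if (optics$read_noise_sd > 0)
        noisy <- noisy + rnorm(nr * nc, 0, optics$read_noise_sd)
      frames[, , k] <- matrix(pmax(noisy, 0), nr, nc)
    }
    structure(list(frames = frames, optics = optics, n_clipped = n_clipped),
              class = "motor_movie", seed = seed)
  })
}

# expected photons per motor-frame; constant unless photons_per_frame is 0
truth_photons <- function(truth) {
  k <- attr(truth, "photons_per_frame")
  rep(if (is.null(k)) 500 else k, nrow(truth$positions))
}

#' Attach a photon budget to a ground truth (photons per motor per frame)
#' @param truth a `motor_truth`.
#' @param photons_per_frame expected photons.
#' @export
set_photons <- function(truth, photons_per_frame) {
  check_positive(photons_per_frame, "photons_per_frame", strict = FALSE)
  attr(truth, "photons_per_frame") <- photons_per_frame
  truth
}

#' @export
print.motor_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<motor_movie> %d x %d px, %d frames, %d clipped motor-frames\n",
              d[1], d[2], d[3], x$n_clipped))
  invisible(x)
}

#' Write / read a movie as a multi-page 16-bit TIFF
#'
#' Photon values are rounded and clipped to \[0, 65535\] ADU.
#' @param movie a `motor_movie` (or plain 3D array for writing).
#' @param path file path.
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- if (inherits(movie, "motor_movie")) movie$frames else movie
  pages <- lapply(seq_len(dim(frames)[3]), function(k) {
    m <- round(frames[, , k])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535  # tiff package stores [0,1] scaled to bit depth
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param optics optional `optics_camera` to attach on read.
#' @export
read_movie_tiff <- function(path, optics = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * 65535
  structure(list(frames = frames,
                 optics = if (is.null(optics)) optics_camera(
                   image_shape = dim(frames)[1:2]) else optics,
                 n_clipped = NA_integer_),
            class = "motor_movie")
}
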