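# Super-resolved reconstruction and cross-section measurement.

#' Render localizations into a super-resolved image
#'
#' In `gaussian` mode each localization is rendered as a unit-integral 2D
#' Gaussian whose sigma is its localization precision (floored at half the
#' rendering pixel to avoid aliasing); in `histogram` mode localization
#' centers are binned into half-open pixels. With `unit_normalized = TRUE`
#' every localization contributes total mass exactly 1, so the image sum
#' equals the number of contributing localizations.
#'
#' @param locs a data.frame with x_nm, y_nm (and precision_nm for gaussian
#'   mode), e.g. a `localization_table` or the `tracks` component of a
#'   `track_table`.
#' @param pixel_size rendering pixel size (nm).
#' @param mode "gaussian" or "histogram".
#' @param unit_normalized logical; guarantee per-localization mass 1.
#' @param extent list(x = c(min, max), y = c(min, max)) in nm; computed from
#'   the data (with padding) when NULL. Supplying a common extent makes
#'   channels comparable.
#' @param channel label stored with the image.
#' @return object of class `sr_image`: list with `intensity` (rows = y,
#'   cols = x), `pixel_size`, `extent`, `mode`, `channel`.
#' @export
reconstruct <- function(locs, pixel_size = 16, mode = c("gaussian", "histogram"),
                        unit_normalized = TRUE, extent = NULL, channel = "all") {
  mode <- match.arg(mode)
  check_positive(pixel_size, "pixel_size")
  df <- as.data.frame(locs)
  if (is.null(extent)) {
    if (nrow(df) == 0) extent <- list(x = c(0, pixel_size * 8),
                                      y = c(0, pixel_size * 8))
    else {
      # pad by the largest kernel reach so no rendering mass is clipped
      sig_max <- if (mode == "gaussian" && "precision_nm" %in% names(df))
        max(pmax(df$precision_nm[is.finite(df$precision_nm)], pixel_size / 2),
            pixel_size) else pixel_size
      pad <- 4 * sig_max
      extent <- list(x = c(min(df$x_nm) - pad, max(df$x_nm) + pad),
                     y = c(min(df$y_nm) - pad, max(df$y_nm) + pad))
    }
  }
  nc <- max(1L, ceiling((extent$x[2] - extent$x[1]) / pixel_size))
  nr <- max(1L, ceiling((extent$y[2] - extent$y[1]) / pixel_size))
  img <- matrix(0, nr, nc)
  if (nrow(df) > 0) {
    if (mode == "histogram") {
      cx <- floor((df$x_nm - extent$x[1]) / pixel_size)
      cy <- floor((df$y_nm - extent$y[1]) / pixel_size)
      ok <- cx >= 0 & cx < nc & cy >= 0 & cy < nr
      for (i in which(ok)) img[cy[i] + 1L, cx[i] + 1L] <-
          img[cy[i] + 1L, cx[i] + 1L] + 1
    } else {
      prec <- if ("precision_nm" %in% names(df)) df$precision_nm else
        rep(pixel_size, nrow(df))
      prec[!is.finite(prec)] <- pixel_size
      sig <- pmax(prec, pixel_size / 2)
      for (i in seq_len(nrow(df))) {
        x <- df$x_nm[i] - extent$x[1]; y <- df$y_nm[i] - extent$y[1]
        w <- ceiling(4 * sig[i] / pixel_size)
        c0 <- max(0L, floor(x / pixel_size) - w)
        c1 <- min(nc - 1L, floor(x / pixel_size) + w)
        r0 <- max(0L, floor(y / pixel_size) - w)
        r1 <- min(nr - 1L, floor(y / pixel_size) + w)
        if (c1 < c0 || r1 < r0) next
        cols <- c0:c1; rows <- r0:r1
        mx <- pnorm(((cols + 1) * pixel_size - x) / sig[i]) -
          pnorm((cols * pixel_size - x) / sig[i])
        my <- pnorm(((rows + 1) * pixel_size - y) / sig[i]) -
          pnorm((rows * pixel_size - y) / sig[i])
        kern <- outer(my, mx)
        if (unit_normalized) {
          tot <- sum(kern)
          if (tot > 0) kern <- kern / tot
        }
        img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + kern
      }
    }
  }
  structure(list(intensity = img, pixel_size = pixel_size, extent = extent,
                 mode = mode, channel = channel,
                 unit_normalized = unit_normalized),
            class = "sr_image")
}

#' @export
print.sr_image <- function(x, ...) {
  cat(sprintf("<sr_image> %d x %d px @ %.1f nm (%s, channel %s), sum %.2f\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$mode,
              x$channel, sum(x$intensity)))
  invisible(x)
}

#' Write a reconstruction as 32-bit float TIFF
#' @param recon an `sr_image`.
#' @param path file path.
#' @export
write_recon_tiff <- function(recon, path) {
  m <- recon$intensity
  mx <- max(m)
  tiff::writeTIFF(if (mx > 0) m / mx else m, path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

# bilinear sampling of an sr_image at nm coordinates
sample_image <- function(recon, x_nm, y_nm) {
  px <- recon$pixel_size
  cx <- (x_nm - recon$extent$x[1]) / px - 0.5  # continuous col index (0-based)
  cy <- (y_nm - recon$extent$y[1]) / px - 0.5
  nr <- nrow(recon$intensity); nc <- ncol(recon$intensity)
  c0 <- floor(cx); r0 <- floor(cy)
  fc <- cx - c0; fr <- cy - r0
  val <- function(r, c) {
    out <- numeric(length(r))
    ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
    out[ok] <- recon$intensity[cbind(r[ok] + 1, c[ok] + 1)]
    out  # outside the rendered extent the image is zero
  }
  (1 - fr) * ((1 - fc) * val(r0, c0) + fc * val(r0, c0 + 1)) +
    fr * ((1 - fc) * val(r0 + 1, c0) + fc * val(r0 + 1, c0 + 1))
}

#' Measure the FWHM of a structure cross-section
#'
#' Intensity is sampled on a grid along the profile line (which should cross
#' the structure roughly perpendicularly) and averaged across `width_nm`
#' along the structure; a 1D Gaussian is fitted to the averaged profile by
#' Levenberg-Marquardt and FWHM = 2.3548 * sigma is returned.
#'
#' @param recon an `sr_image`.
#' @param p0,p1 numeric c(x_nm, y_nm): ends of the profile line.
#' @param width_nm averaging extent perpendicular to the profile line.
#' @param step_nm sampling step along the profile (default pixel/2).
#' @return list with `fwhm_nm`, `sigma_nm`, `center_nm` (along-profile
#'   offset), `profile` (data.frame) and `ok`; `ok = FALSE` with
#'   `fwhm_nm = NA` for a flat profile.
#' @export
line_profile_fwhm <- function(recon, p0, p1, width_nm = 200, step_nm = NULL) {
  if (is.null(step_nm)) step_nm <- recon$pixel_size / 2
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  u <- p1 - p0
  len <- sqrt(sum(u^2))
  check_positive(len, "profile length")
  u <- u / len
  v <- c(-u[2], u[1])  # perpendicular: averaging direction
  t_s <- seq(0, len, by = step_nm)
  w_s <- seq(-width_nm / 2, width_nm / 2, by = step_nm)
  prof <- vapply(t_s, function(t) {
    pts_x <- p0[1] + t * u[1] + w_s * v[1]
    pts_y <- p0[2] + t * u[2] + w_s * v[2]
    mean(sample_image(recon, pts_x, pts_y))
  }, numeric(1))
  bad <- list(fwhm_nm = NA_real_, sigma_nm = NA_real_, center_nm = NA_real_,
              profile = data.frame(t_nm = t_s, intensity = prof), ok = FALSE)
  if (max(prof) - min(prof) <= 0) return(bad)
  start <- c(A = max(prof) - min(prof), mu = t_s[which.max(prof)],
             sigma = len / 8, off = min(prof))
  fit <- tryCatch(minpack.lm::nls.lm(
    par = start,
    fn = function(p) p["off"] + p["A"] *
      exp(-(t_s - p["mu"])^2 / (2 * p["sigma"]^2)) - prof,
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$par[["sigma"]])) return(bad)
  sigma <- abs(fit$par[["sigma"]])
  if (sigma <= 0 || sigma > len) return(bad)
  list(fwhm_nm = 2 * sqrt(2 * log(2)) * sigma, sigma_nm = sigma,
       center_nm = fit$par[["mu"]],
       profile = data.frame(t_nm = t_s, intensity = prof), ok = TRUE)
}
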