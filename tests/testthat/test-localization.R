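test_that("a constant image yields no candidates and non-2D input errors", {
  expect_equal(nrow(detect_spots(matrix(7, 32, 32))), 0)
  expect_error(detect_spots(array(0, c(4, 4, 4))), "2D")
})

test_that("single and double spots are detected at SNR 10", {
  withr::with_seed(11, {
    img <- render_spot(40, 40, x_px = 20.0, y_px = 30.0, photons = 3000,
                       offset = 10)
    img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
    cand <- detect_spots(img)
    expect_equal(nrow(cand), 1)
    expect_lt(abs(cand$x_px - 20.0), 1)
    expect_lt(abs(cand$y_px - 30.0), 1)
    img2 <- render_spot(40, 40, 15, 20, photons = 3000, offset = 0) +
      render_spot(40, 40, 25, 20, photons = 3000, offset = 10)
    img2 <- matrix(rpois(length(img2), img2), 40, 40)
    expect_equal(nrow(detect_spots(img2)), 2)
  })
})

test_that("the Gaussian fit recovers a noiseless center to 1e-3 px", {
  nr <- 11; nc <- 11
  xs <- rep(seq_len(nc) - 0.5, each = nr)
  ys <- rep(seq_len(nr) - 0.5, times = nc)
  roi <- matrix(5 + 20 * exp(-((xs - 5.75)^2 + (ys - 3.40)^2) / (2 * 1.3^2)),
                nr, nc)
  fit <- fit_gaussian_2d(roi, list(x_px = 5.5, y_px = 3.5), 1.3)
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$x_px - 5.75), 1e-3)
  expect_lt(abs(fit$y_px - 3.40), 1e-3)
  expect_lt(abs(fit$sigma_px - 1.3), 1e-3)
})

test_that("flat or degenerate ROIs return fit_ok = FALSE, never an error", {
  expect_false(fit_gaussian_2d(matrix(3, 9, 9),
                               list(x_px = 4.5, y_px = 4.5))$fit_ok)
  expect_false(fit_gaussian_2d(matrix(NA_real_, 9, 9),
                               list(x_px = 4.5, y_px = 4.5))$fit_ok)
})

test_that("localization RMSE scales as 1/sqrt(photons)", {
  levels <- c(250, 1000, 4000)
  rmse <- vapply(levels, function(N) {
    errs <- vapply(1:40, function(s) {
      withr::with_seed(1000 * N + s, {
        x0 <- 6 + runif(1) - 0.5; y0 <- 6 + runif(1) - 0.5
        img <- render_spot(13, 13, x0, y0, photons = N, offset = 10)
        img <- matrix(rpois(length(img), img), 13, 13)
        fit <- fit_gaussian_2d(img, list(x_px = 6, y_px = 6), 75 / 64)
        if (!fit$fit_ok) return(NA_real_)
        sqrt((fit$x_px - x0)^2 + (fit$y_px - y0)^2)
      })
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }, numeric(1))
  slope <- coef(lm(log(rmse) ~ log(levels)))[[2]]
  expect_lt(abs(slope - (-0.5)), 0.1)
})

test_that("localization is equivariant to integer-pixel image shifts", {
  withr::with_seed(5, {
    img <- render_spot(40, 40, 14.3, 17.8, photons = 3000, offset = 10)
    img <- matrix(rpois(length(img), img), 40, 40)
  })
  shifted <- matrix(10, 40, 40)  # background level where unset
  shifted[(1:34) + 6, (1:36) + 4] <- img[1:34, 1:36]
  c1 <- detect_spots(img)
  c2 <- detect_spots(shifted)
  expect_equal(nrow(c1), 1); expect_equal(nrow(c2), 1)
  expect_equal(c2$x_px - c1$x_px, 4)
  expect_equal(c2$y_px - c1$y_px, 6)
  roi1 <- img[12:24, 9:21]
  roi2 <- shifted[(12:24) + 6, (9:21) + 4]
  f1 <- fit_gaussian_2d(roi1, list(x_px = 6.5, y_px = 6.5), 75 / 64)
  f2 <- fit_gaussian_2d(roi2, list(x_px = 6.5, y_px = 6.5), 75 / 64)
  expect_equal(f1$x_px, f2$x_px, tolerance = 1e-6)
  expect_equal(f1$y_px, f2$y_px, tolerance = 1e-6)
})

test_that("localize_movie handles a blank movie and is deterministic", {
  truth <- make_truth(data.frame(frame = integer(0), motor_id = integer(0),
                                 x_nm = numeric(0), y_nm = numeric(0)),
                      n_frames = 4)
  opt <- optics_camera(image_shape = c(24L, 24L), background = 0,
                       read_noise_sd = 0)
  mov <- render_movie(truth, opt, seed = 1)
  locs <- localize_movie(mov, correct_drift = FALSE)
  expect_equal(nrow(locs), 0)

  net <- make_network("parallel_bundles", list(n_filaments = 4), seed = 1)
  tr <- simulate_motors(net, motor_kinetics(), 5, seed = 2)
  mv <- render_movie(tr, optics_camera(image_shape = c(48L, 64L)), seed = 3)
  l1 <- localize_movie(mv, correct_drift = FALSE)
  l2 <- localize_movie(mv, correct_drift = FALSE)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("sparse movies are localized with high recall and precision", {
  net <- make_network("parallel_bundles",
                      list(n_filaments = 6, spacing_nm = 600,
                           filament_length_nm = 5000), seed = 1)
  kin <- motor_kinetics(landing_rate = 0.02)
  truth <- simulate_motors(net, kin, 30, seed = 2)
  opt <- optics_camera(image_shape = c(72L, 104L))
  mov <- render_movie(truth, opt, seed = 3)
  locs <- localize_movie(mov, correct_drift = FALSE)
  pos <- truth$positions
  in_fov <- pos$x_nm >= 300 & pos$x_nm <= 6300 & pos$y_nm >= 300 &
    pos$y_nm <= 4300
  tp <- 0; fp <- 0
  for (k in unique(locs$frame)) {
    lk <- locs[locs$frame == k, ]
    tr <- pos[pos$frame == k, ]
    for (i in seq_len(nrow(lk))) {
      d <- if (nrow(tr)) sqrt((tr$x_nm - lk$x_nm[i])^2 +
                                (tr$y_nm - lk$y_nm[i])^2) else Inf
      if (min(d) < 150) tp <- tp + 1 else fp <- fp + 1
    }
  }
  precision <- tp / (tp + fp)
  recall <- tp / sum(in_fov)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
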