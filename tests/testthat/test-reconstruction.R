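test_that("unit-normalized rendering conserves localization mass", {
  one <- data.frame(x_nm = 500, y_nm = 500, precision_nm = 20)
  r1 <- reconstruct(one, pixel_size = 10, mode = "gaussian")
  expect_equal(sum(r1$intensity), 1, tolerance = 1e-6)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      precision_nm = numeric(0))
  r0 <- reconstruct(empty, pixel_size = 10)
  expect_true(all(r0$intensity == 0))
  withr::with_seed(2, {
    many <- data.frame(x_nm = runif(200, 0, 2000), y_nm = runif(200, 0, 2000),
                       precision_nm = runif(200, 5, 30))
  })
  rn <- reconstruct(many, pixel_size = 16, mode = "gaussian")
  expect_equal(sum(rn$intensity), 200, tolerance = 1e-6 * 200)
  rh <- reconstruct(many, pixel_size = 16, mode = "histogram")
  expect_equal(sum(rh$intensity), 200)
})

test_that("rendering is linear: image of a union is the sum of images", {
  withr::with_seed(3, {
    a <- data.frame(x_nm = runif(50, 0, 1000), y_nm = runif(50, 0, 1000),
                    precision_nm = 15)
    b <- data.frame(x_nm = runif(70, 0, 1000), y_nm = runif(70, 0, 1000),
                    precision_nm = 15)
  })
  ext <- list(x = c(-100, 1100), y = c(-100, 1100))
  for (m in c("gaussian", "histogram")) {
    ra <- reconstruct(a, 20, mode = m, extent = ext)
    rb <- reconstruct(b, 20, mode = m, extent = ext)
    rab <- reconstruct(rbind(a, b), 20, mode = m, extent = ext)
    expect_lt(max(abs(rab$intensity - (ra$intensity + rb$intensity))), 1e-9)
  }
})

test_that("histogram pixels count localizations in half-open squares exactly", {
  pts <- data.frame(x_nm = c(0, 15.999, 16, 31.999, 5, 5),
                    y_nm = c(0, 0, 0, 0, 16, 16))
  r <- reconstruct(pts, 16, mode = "histogram",
                   extent = list(x = c(0, 48), y = c(0, 48)))
  expect_equal(r$intensity[1, 1], 2)  # x in [0,16), y in [0,16)
  expect_equal(r$intensity[1, 2], 2)  # x in [16,32)
  expect_equal(r$intensity[2, 1], 2)  # y in [16,32)
  expect_equal(sum(r$intensity), 6)
})

test_that("a 20 nm precision microtubule renders at FWHM 2.355 x 20", {
  withr::with_seed(4, {
    line <- data.frame(x_nm = runif(4000, 500, 4500), y_nm = 1000,
                       precision_nm = 20)
  })
  rec <- reconstruct(line, pixel_size = 8, mode = "gaussian")
  prof <- line_profile_fwhm(rec, c(2500, 700), c(2500, 1300), width_nm = 3000)
  expect_true(prof$ok)
  expect_equal(prof$fwhm_nm, 2.355 * 20, tolerance = 0.15)
  # doubling the precision doubles the FWHM
  line2 <- line; line2$precision_nm <- 40
  rec2 <- reconstruct(line2, pixel_size = 8, mode = "gaussian")
  prof2 <- line_profile_fwhm(rec2, c(2500, 700), c(2500, 1300), width_nm = 3000)
  expect_equal(prof2$fwhm_nm / prof$fwhm_nm, 2, tolerance = 0.05)
})

test_that("two filaments 300 nm apart resolve as two ~47 nm peaks", {
  withr::with_seed(5, {
    two <- data.frame(x_nm = runif(8000, 500, 4500),
                      y_nm = rep(c(1000, 1300), each = 4000),
                      precision_nm = 20)
  })
  rec <- reconstruct(two, pixel_size = 8, mode = "gaussian")
  full <- line_profile_fwhm(rec, c(2500, 700), c(2500, 1600), width_nm = 3000)
  prof <- full$profile
  # two local maxima near 300 and 600 nm along the profile
  v <- prof$intensity
  is_pk <- c(FALSE, v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
               v[2:(length(v) - 1)] >= v[3:length(v)], FALSE)
  pk <- prof$t_nm[is_pk][order(-v[is_pk])][1:2]
  expect_equal(sort(pk), c(300, 600), tolerance = 0.1)
  trough <- min(prof$intensity[prof$t_nm > 350 & prof$t_nm < 550])
  expect_lt(trough, 0.5 * max(prof$intensity))
  for (yc in c(1000, 1300)) {
    p <- line_profile_fwhm(rec, c(2500, yc - 110), c(2500, yc + 110),
                           width_nm = 3000)
    expect_equal(p$fwhm_nm, 47, tolerance = 0.15)
  }
})

test_that("histogram rendering of scattered localizations reports the scatter", {
  # scatter SD = claimed precision: profile FWHM/2.355 must match it
  withr::with_seed(6, {
    line <- data.frame(x_nm = runif(6000, 500, 4500),
                       y_nm = 1000 + rnorm(6000, 0, 20), precision_nm = 20)
  })
  rec <- reconstruct(line, pixel_size = 5, mode = "histogram")
  prof <- line_profile_fwhm(rec, c(2500, 800), c(2500, 1200), width_nm = 3000)
  expect_true(prof$ok)
  expect_equal(prof$fwhm_nm / 2.355, 20, tolerance = 0.15)
})

test_that("flat profiles flag an error instead of returning a number", {
  rec <- structure(list(intensity = matrix(1, 32, 32), pixel_size = 10,
                        extent = list(x = c(0, 320), y = c(0, 320)),
                        mode = "histogram", channel = "all",
                        unit_normalized = FALSE), class = "sr_image")
  out <- line_profile_fwhm(rec, c(50, 160), c(270, 160), width_nm = 100)
  expect_false(out$ok)
  expect_true(is.na(out$fwhm_nm))
})
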