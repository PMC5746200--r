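test_that("quadrant allocation follows the sign of the total displacement", {
  tr <- rbind(
    data.frame(track_id = 1, frame = 0:2, x_nm = c(0, 250, 500),
               y_nm = c(0, 10, 20)),
    data.frame(track_id = 2, frame = 0:2, x_nm = c(0, -250, -500),
               y_nm = c(0, -10, -20)),
    data.frame(track_id = 3, frame = 0:2, x_nm = c(0, 250, 500),
               y_nm = c(0, -10, -20)),
    data.frame(track_id = 4, frame = 0:2, x_nm = c(0, -250, -500),
               y_nm = c(0, 10, 20)))
  tr$precision_nm <- 10
  tt <- allocate_quadrant(as_track_table(tr))
  expect_equal(tt$summary$orientation, c("Q++", "Q--", "Q+-", "Q-+"))
  # mirroring x swaps Q++ <-> Q-+ and Q+- <-> Q--
  trm <- tr; trm$x_nm <- -trm$x_nm
  ttm <- allocate_quadrant(as_track_table(trm))
  swap <- c("Q++" = "Q-+", "Q-+" = "Q++", "Q+-" = "Q--", "Q--" = "Q+-")
  expect_equal(ttm$summary$orientation, unname(swap[tt$summary$orientation]))
})

test_that("exactly zero displacement components count as positive and are flagged", {
  tr <- data.frame(track_id = 1, frame = 0:2, x_nm = c(0, 100, 200),
                   y_nm = 0, precision_nm = 10)
  tt <- allocate_quadrant(as_track_table(tr))
  expect_equal(tt$summary$orientation, "Q++")
  expect_equal(tt$params$zero_component_ties, 1)
})

test_that("axis allocation reads direction from projected arclength", {
  axis <- neurite_axis(rbind(c(0, 0), c(10000, 0)))
  tr <- data.frame(track_id = 1, frame = 0:2, x_nm = c(1000, 1300, 1600),
                   y_nm = 500, precision_nm = 10)
  tt <- allocate_axis(as_track_table(tr), axis)
  expect_equal(tt$summary$orientation, "outward")
  # reversing the axis direction flips the class
  axis_rev <- neurite_axis(rbind(c(10000, 0), c(0, 0)))
  tt_rev <- allocate_axis(as_track_table(tr), axis_rev)
  expect_equal(tt_rev$summary$orientation, "inward")
})

test_that("tracks beyond the capture distance stay unclassified and are counted", {
  axis <- neurite_axis(rbind(c(0, 0), c(10000, 0)))
  tr <- data.frame(track_id = 1, frame = 0:2, x_nm = c(1000, 1300, 1600),
                   y_nm = 5000, precision_nm = 10)
  tt <- allocate_axis(as_track_table(tr), axis, capture_nm = 2000)
  expect_true(is.na(tt$summary$orientation))
  expect_equal(unname(tt$rejected["beyond_capture"]), 1L)
})

test_that("axis allocation is invariant to rigid rotation of track plus axis", {
  rot <- function(xy, th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    t(R %*% t(as.matrix(xy)))
  }
  axis_xy <- rbind(c(0, 0), c(4000, 2000), c(9000, 3000))
  tr <- data.frame(track_id = 1, frame = 0:3,
                   x_nm = c(2000, 2300, 2600, 2900),
                   y_nm = c(1100, 1250, 1400, 1500), precision_nm = 10)
  base <- allocate_axis(as_track_table(tr), neurite_axis(axis_xy))
  for (th in c(0.7, 2.1, -1.2)) {
    tr2 <- tr
    tr2[, c("x_nm", "y_nm")] <- rot(tr[, c("x_nm", "y_nm")], th)
    got <- allocate_axis(as_track_table(tr2), neurite_axis(rot(axis_xy, th)))
    expect_equal(got$summary$orientation, base$summary$orientation)
  }
})

test_that("a uniform plus-end-out dendrite yields 100% outward tracks", {
  net <- make_network("dendrite", list(minus_end_out_fraction = 0), seed = 3)
  truth <- simulate_motors(net, motor_kinetics(), 20, seed = 4)
  tt <- as_track_table(truth_tracks(truth)[, c("track_id", "frame", "x_nm",
                                               "y_nm", "precision_nm")])
  tt <- allocate_axis(tt, motorpaint:::default_axis(net))
  cls <- tt$summary$orientation[!is.na(tt$summary$orientation)]
  expect_gt(length(cls), 10)
  expect_true(all(cls == "outward"))
})

test_that("track interpolation inserts points at 15 nm spacing", {
  tr <- data.frame(track_id = 1, frame = 0:1, x_nm = c(0, 75), y_nm = 0,
                   precision_nm = c(20, 30))
  out <- interpolate_track(as_track_table(tr))
  expect_equal(nrow(out$tracks), 2 + 4)      # 4 interior points, 5 intervals
  ins <- out$tracks[!(out$tracks$x_nm %in% c(0, 75)), ]
  expect_equal(sort(ins$x_nm), c(15, 30, 45, 60))
  expect_true(all(ins$precision_nm == 25))
  expect_true(attr(out, "interpolated"))
})

test_that("interpolation with spacing larger than the step inserts nothing", {
  tr <- data.frame(track_id = 1, frame = 0:1, x_nm = c(0, 10), y_nm = 0,
                   precision_nm = 10)
  out <- interpolate_track(as_track_table(tr), spacing = 15)
  expect_equal(nrow(out$tracks), 2)
})

test_that("quantification refuses interpolated inputs", {
  tr <- data.frame(track_id = 1, frame = 0:2, x_nm = c(0, 75, 150), y_nm = 0,
                   precision_nm = 10, orientation = "outward")
  tt <- interpolate_track(as_track_table(tr))
  axis <- neurite_axis(rbind(c(0, 0), c(1000, 0)))
  expect_error(segment_fraction(tt, axis, 0), "non-interpolated")
  expect_error(correlation_vs_pixel_size(tt, tt), "non-interpolated")
})
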