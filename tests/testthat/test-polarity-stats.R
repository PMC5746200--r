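test_that("overlap correlation reproduces its defining identities", {
  withr::with_seed(1, a <- matrix(runif(64), 8, 8))
  expect_equal(overlap_correlation(a, a), 1)
  expect_equal(overlap_correlation(a, 3.7 * a), 1)       # scale invariance
  b <- matrix(0, 8, 8); b[1:4, ] <- a[1:4, ]
  d <- matrix(0, 8, 8); d[5:8, ] <- a[5:8, ]
  expect_equal(overlap_correlation(b, d), 0)             # disjoint support
  expect_equal(overlap_correlation(matrix(c(1, 0, 0, 0), 2),
                                   matrix(c(1, 0, 1, 0), 2)),
               1 / sqrt(2), tolerance = 1e-12)
  withr::with_seed(2, e <- matrix(runif(64), 8, 8))
  expect_equal(overlap_correlation(a, e), overlap_correlation(e, a))
  expect_gte(overlap_correlation(a, e), 0)
  expect_lte(overlap_correlation(a, e), 1)
})

test_that("degenerate correlation inputs are rejected or flagged", {
  a <- matrix(1, 4, 4)
  expect_error(overlap_correlation(a, matrix(1, 5, 5)), "equal shapes")
  expect_error(overlap_correlation(a, matrix(-1, 4, 4)), "nonnegative")
  expect_warning(z <- overlap_correlation(a, matrix(0, 4, 4)), "all zero")
  expect_true(is.na(z))
})

test_that("identical localization sets give C = 1 at every pixel size", {
  withr::with_seed(3, {
    df <- data.frame(x_nm = runif(500, 0, 4000), y_nm = runif(500, 0, 2000),
                     track_id = rep(1:50, each = 10))
  })
  cv <- correlation_vs_pixel_size(df, df, c(50, 100, 200))
  expect_equal(cv$C_in_out, rep(1, 3), tolerance = 1e-12)
})

test_that("polarity-segregated bundles decorrelate the orientation channels", {
  net <- make_network("dendrite",
                      list(minus_end_out_fraction = 0.5,
                           bundle_enrichment = 1, n_bundles = 8), seed = 2)
  truth <- simulate_motors(net, motor_kinetics(landing_rate = 0.15), 60,
                           seed = 3)
  tr <- truth_tracks(truth)
  a <- tr[tr$orientation == "inward", ]
  b <- tr[tr$orientation == "outward", ]
  cv <- correlation_vs_pixel_size(a, b, c(50, 100, 200, 400))
  expect_true(all(cv$C_in_out < cv$C_odd_even))
  # the odd/even control stays high: both halves sample the same structures
  expect_true(all(cv$C_odd_even > 0.7))
})

test_that("interdigitated equal-polarity filaments are a correlation null", {
  net <- alternating_network(n_filaments = 16, spacing_nm = 50)
  kin <- motor_kinetics(landing_rate = 2, run_length_mean = 400,
                        bleach_rate = 0)
  truth <- simulate_motors(net, kin, 200, seed = 5)
  tr <- truth_tracks(truth)
  tr <- tr[tr$x_nm >= 1600 & tr$x_nm <= 4600, ]  # interior, away from ends
  a <- tr[tr$orientation == "inward", ]
  b <- tr[tr$orientation == "outward", ]
  cv <- correlation_vs_pixel_size(a, b, c(200, 400))
  expect_true(all(cv$C_odd_even - cv$C_in_out < 0.05))
})

test_that("segment fractions are localization-count ratios", {
  axis <- neurite_axis(rbind(c(0, 0), c(10000, 0)))
  mk <- function(n_in, n_out) {
    tr <- rbind(
      if (n_in > 0) data.frame(track_id = 1, frame = seq_len(n_in) - 1,
                               x_nm = seq(2000, 2500, length.out = n_in),
                               y_nm = 100, precision_nm = 10,
                               orientation = "inward"),
      if (n_out > 0) data.frame(track_id = 2, frame = seq_len(n_out) - 1,
                                x_nm = seq(2000, 2500, length.out = n_out),
                                y_nm = 200, precision_nm = 10,
                                orientation = "outward"))
    as_track_table(tr)
  }
  sq <- segment_fraction(mk(200, 100), axis, segment_start = 0)
  expect_equal(sq$frac_minus_out, 200 / 300, tolerance = 1e-12)
  expect_equal(sq$sum_inward, 200)
  expect_equal(segment_fraction(mk(150, 150), axis, 0)$frac_minus_out, 0.5)
  # complement identity: swapping the class labels mirrors the fraction
  tt <- mk(170, 60)
  sw <- tt
  sw$tracks$orientation <- ifelse(sw$tracks$orientation == "inward",
                                  "outward", "inward")
  sw$summary$orientation <- ifelse(sw$summary$orientation == "inward",
                                   "outward", "inward")
  f1 <- segment_fraction(tt, axis, 0)$frac_minus_out
  f2 <- segment_fraction(sw, axis, 0)$frac_minus_out
  expect_equal(f1 + f2, 1, tolerance = 1e-12)
})

test_that("an empty segment flags an undefined fraction", {
  axis <- neurite_axis(rbind(c(0, 0), c(100000, 0)))
  tr <- data.frame(track_id = 1, frame = 0:2, x_nm = c(0, 75, 150), y_nm = 0,
                   precision_nm = 10, orientation = "outward")
  sq <- segment_fraction(as_track_table(tr), axis, segment_start = 50)
  expect_true(sq$empty)
  expect_true(is.na(sq$frac_minus_out))
})

test_that("segment membership uses half-open projected arclength intervals", {
  axis <- neurite_axis(rbind(c(0, 0), c(10000, 0)))
  tr <- data.frame(track_id = 1, frame = 0:2,
                   x_nm = c(4999.9, 5000, 5000.1), y_nm = 0,
                   precision_nm = 10, orientation = "inward")
  sq <- segment_fraction(as_track_table(tr), axis, segment_start = 0,
                         segment_len = 5)
  expect_equal(sq$sum_inward, 1)  # only the point strictly below 5 um
})

test_that("removing the dynamic subset shifts polarity toward the stable one", {
  shifts <- vapply(1:5, function(s) {
    net <- make_network("dendrite",
                        list(minus_end_out_fraction = 0.5, n_bundles = 10),
                        seed = s)
    stable <- drop_subset(net, "dynamic")
    ax <- motorpaint:::default_axis(net)
    f_all <- fraction_from_truth(net, ax, seed = s + 10)
    f_stable <- fraction_from_truth(stable, ax, seed = s + 20)
    f_stable - f_all
  }, numeric(1))
  # the stable subset is minus-end-out enriched by construction: the
  # recovered fraction must rise in every replicate (sign test)
  expect_true(all(shifts > 0))
})
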