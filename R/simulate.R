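# Motor kinetics, optics, and ground-truth motor simulation.

#' Motor kinetics parameter set
#'
#' Defaults follow the motility observed in the fixed-cytoskeleton kinesin
#' assay: per-motor speeds of 750 +/- 300 nm/s (population mean +/- SD across
#' motors), sampled at 10 Hz. The photon budget, landing rate and run length
#' are not measured quantities; defaults are chosen so that localization
#' precision lands in the regime implied by the ~50 nm microtubule FWHM.
#'
#' @param landing_rate events per um of filament per second.
#' @param speed_mean,speed_sd population mean and SD of per-motor speed
#'   (nm/s); speeds are truncated at zero. Each motor moves at its own
#'   constant speed; within-track spread comes from localization error only.
#' @param run_length_mean mean distance before detachment (nm, exponential).
#' @param bleach_rate photobleaching rate (1/s, single-step).
#' @param photons_per_frame expected photons collected per motor per frame.
#' @return object of class `motor_kinetics`.
#' @export
motor_kinetics <- function(landing_rate = 0.05, speed_mean = 750,
                           speed_sd = 300, run_length_mean = 1500,
                           bleach_rate = 0.2, photons_per_frame = 500) {
  check_positive(landing_rate, "landing_rate", strict = FALSE)
  check_positive(speed_mean, "speed_mean")
  check_positive(speed_sd, "speed_sd", strict = FALSE)
  check_positive(run_length_mean, "run_length_mean")
  check_positive(bleach_rate, "bleach_rate", strict = FALSE)
  check_positive(photons_per_frame, "photons_per_frame", strict = FALSE)
  structure(list(landing_rate = landing_rate, speed_mean = speed_mean,
                 speed_sd = speed_sd, run_length_mean = run_length_mean,
                 bleach_rate = bleach_rate,
                 photons_per_frame = photons_per_frame),
            class = "motor_kinetics")
}

#' Optics and camera parameter set
#'
#' @param psf_sigma Gaussian PSF standard deviation (nm).
#' @param pixel_size camera pixel size in sample space (nm).
#' @param frame_interval seconds per frame (0.1 s = 10 Hz stream).
#' @param background mean background (photons/pixel/frame).
#' @param read_noise_sd Gaussian read noise SD (photon-equivalents).
#' @param image_shape integer c(rows, cols).
#' @param drift optional per-frame (dx_nm, dy_nm) matrix added to true
#'   positions at render time; default zero.
#' @return object of class `optics_camera`.
#' @export
optics_camera <- function(psf_sigma = 75, pixel_size = 64,
                          frame_interval = 0.1, background = 10,
                          read_noise_sd = 1.6,
                          image_shape = c(96L, 96L), drift = NULL) {
  check_positive(psf_sigma, "psf_sigma")
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  check_positive(background, "background", strict = FALSE)
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    stopifnot(ncol(drift) == 2, all(is.finite(drift)))
  }
  structure(list(psf_sigma = psf_sigma, pixel_size = pixel_size,
                 frame_interval = frame_interval, background = background,
                 read_noise_sd = read_noise_sd,
                 image_shape = as.integer(image_shape), drift = drift),
            class = "optics_camera")
}

#' Linear drift series helper
#' @param n_frames number of frames.
#' @param total_nm length-2 c(dx, dy): drift accumulated from first to last
#'   frame (linear ramp starting at zero).
#' @export
linear_drift <- function(n_frames, total_nm) {
  f <- if (n_frames > 1) (seq_len(n_frames) - 1) / (n_frames - 1) else 0
  cbind(dx_nm = f * total_nm[1], dy_nm = f * total_nm[2])
}

#' Simulate plus-end-directed motors on a fixed microtubule network
#'
#' Landing events form a Poisson process with mean
#' `landing_rate x total filament length x duration`; each motor lands
#' uniformly along the network, walks toward its filament's plus end at a
#' per-motor constant speed drawn from a truncated normal, and disappears at
#' detachment (exponential run length), photobleaching, or the plus end.
#' Motors never reverse. Positions are sampled at frame times
#' `k * frame_interval_s`.
#'
#' @param network an `mt_network`.
#' @param kinetics a `motor_kinetics`.
#' @param duration total simulated time (s).
#' @param seed integer seed.
#' @param frame_interval_s sampling interval (s).
#' @param axis optional `neurite_axis` used to assign each filament an
#'   outward/inward direction class (outward = plus end distal); defaults to
#'   a +x axis through the network.
#' @return object of class `motor_truth`: list with `positions` (data.frame
#'   frame, t_s, motor_id, x_nm, y_nm, filament_id, direction), `motors`
#'   (per-motor truth incl. speed), `network`, and metadata attributes.
#' @export
simulate_motors <- function(network, kinetics, duration, seed = 1L,
                            frame_interval_s = 0.1, axis = NULL) {
  check_positive(duration, "duration")
  stopifnot(inherits(network, "mt_network"), inherits(kinetics, "motor_kinetics"))
  n_frames <- as.integer(ceiling(duration / frame_interval_s))
  empty <- function() {
    structure(list(
      positions = data.frame(frame = integer(0), t_s = numeric(0),
                             motor_id = integer(0), x_nm = numeric(0),
                             y_nm = numeric(0), filament_id = integer(0),
                             direction = character(0)),
      motors = data.frame(motor_id = integer(0), filament_id = integer(0),
                          speed_nm_s = numeric(0), t_land_s = numeric(0),
                          s0_nm = numeric(0), t_end_s = numeric(0),
                          end_reason = character(0)),
      network = network),
      class = "motor_truth", frame_interval_s = frame_interval_s,
      duration_s = duration, n_frames = n_frames, seed = seed,
      photons_per_frame = kinetics$photons_per_frame)
  }
  if (length(network$filaments) == 0L) return(empty())
  lens <- vapply(network$filaments, polyline_length, numeric(1))
  total_um <- sum(lens) / 1000
  if (is.null(axis)) axis <- default_axis(network)
  plus_out <- vapply(network$filaments, function(f) {
    s <- polyline_project(axis$vertices, rbind(f[1, ], f[nrow(f), ]))$arclength
    s[2] > s[1]  # plus end distal -> motor moves outward
  }, logical(1))

  with_seed(seed, {
    n_events <- rpois(1, kinetics$landing_rate * total_um * duration)
    if (n_events == 0L) return(empty())
    fil <- sample.int(length(lens), n_events, replace = TRUE, prob = lens)
    s0 <- runif(n_events) * lens[fil]
    t0 <- runif(n_events, 0, duration)
    v <- rtnorm_pos(n_events, kinetics$speed_mean, kinetics$speed_sd)
    run_len <- rexp(n_events, 1 / kinetics$run_length_mean)
    t_bleach <- if (kinetics$bleach_rate > 0)
      rexp(n_events, kinetics$bleach_rate) else rep(Inf, n_events)

    t_detach <- run_len / v
    t_plus_end <- (lens[fil] - s0) / v
    dt_end <- pmin(t_detach, t_bleach, t_plus_end)
    reason <- c("detach", "bleach", "plus_end")[
      max.col(-cbind(t_detach, t_bleach, t_plus_end), ties.method = "first")]
    t_end <- pmin(t0 + dt_end, duration)

    motors <- data.frame(motor_id = seq_len(n_events), filament_id = fil,
                         speed_nm_s = v, t_land_s = t0, s0_nm = s0,
                         t_end_s = t_end, end_reason = reason)

    # sample each motor at frame times within [t0, t_end]
    k0 <- pmax(0L, as.integer(ceiling(t0 / frame_interval_s)))
    k1 <- pmin(n_frames - 1L, as.integer(floor(t_end / frame_interval_s)))
    keep <- which(k1 >= k0)
    pos_list <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      ks <- k0[i]:k1[i]
      ts <- ks * frame_interval_s
      s <- s0[i] + v[i] * (ts - t0[i])
      pp <- polyline_point(network$filaments[[fil[i]]], s)
      pos_list[[j]] <- data.frame(
        frame = ks, t_s = ts, motor_id = i,
        x_nm = pp$xy[, 1], y_nm = pp$xy[, 2], filament_id = fil[i],
        direction = if (plus_out[fil[i]]) "outward" else "inward")
    }
    positions <- if (length(pos_list)) do.call(rbind, pos_list) else
      empty()$positions
    positions <- positions[order(positions$frame, positions$motor_id), ]
    rownames(positions) <- NULL
    structure(list(positions = positions, motors = motors, network = network),
              class = "motor_truth", frame_interval_s = frame_interval_s,
              duration_s = duration, n_frames = n_frames, seed = seed,
              photons_per_frame = kinetics$photons_per_frame)
  })
}

#' @export
print.motor_truth <- function(x, ...) {
  cat(sprintf("<motor_truth> %d motors, %d frame-positions, %d frames\n",
              nrow(x$motors), nrow(x$positions), attr(x, "n_frames")))
  invisible(x)
}

#' Write ground-truth motor positions as CSV
#' Columns: frame, motor_id, x_nm, y_nm, filament_id, direction.
#' @param truth a `motor_truth`.
#' @param path file path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth$positions[, c("frame", "motor_id", "x_nm", "y_nm",
                                       "filament_id", "direction")],
                   path, row.names = FALSE)
  invisible(path)
}
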