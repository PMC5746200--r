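# Microtubule network generation.
#
# A network is a list of 2D polylines in nm. Polarity is encoded purely by
# vertex order: the first vertex is the minus end, the last the plus end.
# Plus-end-directed motors therefore walk from the first vertex toward the
# last.

#' Construct a microtubule network object
#'
#' @param filaments list of numeric matrices (>= 2 rows, columns x_nm, y_nm);
#'   vertex order encodes polarity (first vertex = minus end).
#' @param bundle_id integer vector, one entry per filament.
#' @param subset_label character vector per filament (e.g. "stable",
#'   "dynamic"); used only to parameterize bundle composition.
#' @param geometry character tag recording the generator used.
#' @return an object of class `mt_network`.
#' @export
mt_network <- function(filaments, bundle_id = seq_along(filaments),
                       subset_label = rep("stable", length(filaments)),
                       geometry = "custom") {
  stopifnot(is.list(filaments),
            length(bundle_id) == length(filaments),
            length(subset_label) == length(filaments))
  for (i in seq_along(filaments)) {
    f <- filaments[[i]]
    if (!is.matrix(f) || ncol(f) != 2 || nrow(f) < 2 || !all(is.finite(f)))
      stop("filament ", i, " must be a finite numeric matrix with 2 columns and >= 2 vertices")
    if (polyline_length(f) <= 0)
      stop("filament ", i, " has zero total length")
    colnames(f) <- c("x_nm", "y_nm")
    filaments[[i]] <- f
  }
  structure(list(filaments = filaments,
                 bundle_id = as.integer(bundle_id),
                 subset_label = as.character(subset_label),
                 geometry = geometry),
            class = "mt_network")
}

#' @export
print.mt_network <- function(x, ...) {
  cat(sprintf("<mt_network> %d filaments (%s), total length %.1f um\n",
              length(x$filaments), x$geometry, network_length(x) / 1000))
  invisible(x)
}

#' Total filament length of a network (nm)
#' @param network an `mt_network`.
#' @export
network_length <- function(network) {
  if (length(network$filaments) == 0L) return(0)
  sum(vapply(network$filaments, polyline_length, numeric(1)))
}

#' Length-weighted minus-end-out fraction of a network
#'
#' A filament is minus-end-out when its minus end (first vertex) lies
#' farther along the reference axis than its plus end, i.e. a plus-end
#' directed motor on it moves inward (toward the proximal end of the axis).
#'
#' @param network an `mt_network`.
#' @param axis a `neurite_axis`; defaults to the +x axis spanning the network.
#' @export
minus_end_out_fraction <- function(network, axis = NULL) {
  if (length(network$filaments) == 0L) return(NA_real_)
  if (is.null(axis)) axis <- default_axis(network)
  lens <- vapply(network$filaments, polyline_length, numeric(1))
  minus_out <- vapply(network$filaments, function(f) {
    ends <- rbind(f[1, ], f[nrow(f), ])
    s <- polyline_project(axis$vertices, ends)$arclength
    s[1] > s[2]  # minus end distal of plus end
  }, logical(1))
  sum(lens[minus_out]) / sum(lens)
}

# straight +x axis covering the network extent (proximal = min x)
default_axis <- function(network) {
  allv <- do.call(rbind, network$filaments)
  xr <- range(allv[, 1])
  ymid <- mean(range(allv[, 2]))
  neurite_axis(cbind(x_nm = c(xr[1] - 1, xr[2] + 1), y_nm = c(ymid, ymid)))
}

#' Generate a ground-truthed microtubule network
#'
#' Three geometries emulate the experimental scenarios: `radial`, a
#' centrosome-like aster with every minus end at the origin (the
#' nocodazole-washout validation geometry); `dendrite`, parallel filaments
#' grouped into laterally offset bundles of preferred polarity along a
#' proximal-to-distal +x axis; `parallel_bundles`, a simpler flat set of
#' parallel filaments with a prescribed polarity mix.
#'
#' Polarity composition is assigned by exact counts (`round(fraction * n)`),
#' so the realized length-weighted minus-end-out fraction equals the request
#' up to rounding; randomness enters through geometry only.
#'
#' @param geometry one of "radial", "dendrite", "parallel_bundles".
#' @param params named list of geometry parameters; see Details. Unknown
#'   entries are rejected.
#' @param seed integer seed; generation is deterministic for a fixed seed.
#'
#' @details Parameters (defaults in parentheses):
#' * radial: `n_filaments` (141), `length_mean_nm` (4000), `length_sd_nm`
#'   (600), `center` (c(0,0)).
#' * dendrite: `n_bundles` (8), `filaments_per_bundle` (3),
#'   `filament_length_nm` (5000), `bundle_spacing_nm` (400),
#'   `offset_range_nm` (c(50, 100)), `minus_end_out_fraction` (0.5),
#'   `bundle_enrichment` (0.85) — the fraction of a bundle's filaments
#'   sharing the bundle's dominant orientation, `p_stable_minus_out` (0.8)
#'   and `p_stable_plus_out` (0.3) — probability of the "stable" label given
#'   orientation, `x_jitter_nm` (400), `origin_nm` (c(600, 600)) — offset of
#'   the first bundle's proximal corner, keeping the network inside a camera
#'   field of view.
#' * parallel_bundles: `n_filaments` (12), `filament_length_nm` (5000),
#'   `spacing_nm` (400), `minus_end_out_fraction` (0.5), `origin_nm`
#'   (c(600, 600)).
#' @return an `mt_network`.
#' @export
make_network <- function(geometry = c("radial", "dendrite", "parallel_bundles"),
                         params = list(), seed = 1L) {
  geometry <- match.arg(geometry)
  with_seed(seed, switch(geometry,
    radial = make_network_radial(params),
    dendrite = make_network_dendrite(params),
    parallel_bundles = make_network_parallel(params)))
}

merge_params <- function(defaults, params) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop("unknown network parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

make_network_radial <- function(params) {
  p <- merge_params(list(n_filaments = 141, length_mean_nm = 4000,
                         length_sd_nm = 600, center = c(0, 0)), params)
  check_positive(p$n_filaments, "n_filaments", strict = FALSE)
  if (p$n_filaments == 0) return(mt_network(list(), geometry = "radial"))
  check_positive(p$length_mean_nm, "length_mean_nm")
  check_positive(p$length_sd_nm, "length_sd_nm", strict = FALSE)
  if (!is.numeric(p$center) || length(p$center) != 2 || any(!is.finite(p$center)))
    stop("'center' must be a finite length-2 numeric")
  n <- as.integer(p$n_filaments)
  theta <- runif(n, 0, 2 * pi)
  len <- rtnorm_pos(n, p$length_mean_nm, p$length_sd_nm)
  fil <- lapply(seq_len(n), function(i) {
    # minus end at the center: first vertex = center
    rbind(c(p$center[1], p$center[2]),
          c(p$center[1] + len[i] * cos(theta[i]),
            p$center[2] + len[i] * sin(theta[i])))
  })
  mt_network(fil, bundle_id = seq_len(n), geometry = "radial")
}

make_network_dendrite <- function(params) {
  p <- merge_params(list(n_bundles = 8, filaments_per_bundle = 3,
                         filament_length_nm = 5000, bundle_spacing_nm = 400,
                         offset_range_nm = c(50, 100),
                         minus_end_out_fraction = 0.5,
                         bundle_enrichment = 0.85,
                         p_stable_minus_out = 0.8, p_stable_plus_out = 0.3,
                         x_jitter_nm = 400, origin_nm = c(600, 600)), params)
  check_positive(p$n_bundles, "n_bundles", strict = FALSE)
  if (p$n_bundles == 0) return(mt_network(list(), geometry = "dendrite"))
  check_positive(p$filaments_per_bundle, "filaments_per_bundle")
  check_positive(p$filament_length_nm, "filament_length_nm")
  check_positive(p$bundle_spacing_nm, "bundle_spacing_nm")
  check_positive(p$offset_range_nm, "offset_range_nm")
  check_fraction(p$minus_end_out_fraction, "minus_end_out_fraction")
  check_fraction(p$bundle_enrichment, "bundle_enrichment")
  check_positive(p$x_jitter_nm, "x_jitter_nm", strict = FALSE)

  nb <- as.integer(p$n_bundles)
  npb <- as.integer(p$filaments_per_bundle)
  e <- p$bundle_enrichment
  # exact global composition, segregated into bundles: the total minus-end-out
  # filament count is fixed by the requested fraction; bundles (in random
  # order) are filled with minus-out filaments up to their enrichment cap
  # first, so polarity segregates by bundle while the network-wide fraction
  # is exact up to rounding
  n_fil <- nb * npb
  n_minus_total <- round(p$minus_end_out_fraction * n_fil)
  cap <- max(round(e * npb), ceiling(npb / 2))
  bundle_order <- sample.int(nb)
  n_minus_bundle <- integer(nb)
  remaining <- n_minus_total
  for (b in bundle_order) {           # dominant fill up to cap
    take <- min(cap, remaining)
    n_minus_bundle[b] <- take
    remaining <- remaining - take
    if (remaining == 0L) break
  }
  if (remaining > 0L) for (b in bundle_order) {  # overflow beyond caps
    take <- min(npb - n_minus_bundle[b], remaining)
    n_minus_bundle[b] <- n_minus_bundle[b] + take
    remaining <- remaining - take
    if (remaining == 0L) break
  }
  if (!is.numeric(p$origin_nm) || length(p$origin_nm) != 2 ||
      any(!is.finite(p$origin_nm)))
    stop("'origin_nm' must be a finite length-2 numeric")
  filaments <- list(); bundle_id <- integer(0); minus_out <- logical(0)
  for (b in seq_len(nb)) {
    y0 <- p$origin_nm[2] + (b - 1) * p$bundle_spacing_nm
    off <- cumsum(runif(npb, p$offset_range_nm[1], p$offset_range_nm[2]))
    off <- off - mean(off)
    fil_minus_out <- sample(c(rep(TRUE, n_minus_bundle[b]),
                              rep(FALSE, npb - n_minus_bundle[b])))
    for (j in seq_len(npb)) {
      x0 <- p$origin_nm[1] + runif(1, 0, p$x_jitter_nm)
      x1 <- x0 + p$filament_length_nm
      y <- y0 + off[j]
      v <- if (fil_minus_out[j]) {
        rbind(c(x1, y), c(x0, y))  # minus end distal: vertices run distal->proximal
      } else {
        rbind(c(x0, y), c(x1, y))  # plus end distal
      }
      filaments <- c(filaments, list(v))
      bundle_id <- c(bundle_id, b)
      minus_out <- c(minus_out, fil_minus_out[j])
    }
  }
  p_stable <- ifelse(minus_out, p$p_stable_minus_out, p$p_stable_plus_out)
  label <- ifelse(runif(length(minus_out)) < p_stable, "stable", "dynamic")
  mt_network(filaments, bundle_id = bundle_id, subset_label = label,
             geometry = "dendrite")
}

make_network_parallel <- function(params) {
  p <- merge_params(list(n_filaments = 12, filament_length_nm = 5000,
                         spacing_nm = 400, minus_end_out_fraction = 0.5,
                         origin_nm = c(600, 600)), params)
  check_positive(p$n_filaments, "n_filaments", strict = FALSE)
  if (p$n_filaments == 0) return(mt_network(list(), geometry = "parallel_bundles"))
  check_positive(p$filament_length_nm, "filament_length_nm")
  check_positive(p$spacing_nm, "spacing_nm")
  check_fraction(p$minus_end_out_fraction, "minus_end_out_fraction")
  n <- as.integer(p$n_filaments)
  n_minus <- round(n * p$minus_end_out_fraction)
  minus_out <- sample(c(rep(TRUE, n_minus), rep(FALSE, n - n_minus)))
  fil <- lapply(seq_len(n), function(i) {
    y <- p$origin_nm[2] + (i - 1) * p$spacing_nm
    x0 <- p$origin_nm[1]; x1 <- p$origin_nm[1] + p$filament_length_nm
    if (minus_out[i]) rbind(c(x1, y), c(x0, y))
    else rbind(c(x0, y), c(x1, y))
  })
  mt_network(fil, bundle_id = seq_len(n), geometry = "parallel_bundles")
}

#' Drop a labelled filament subset from a network
#'
#' Emulates a nocodazole-style perturbation: filaments carrying
#' `label` (typically "dynamic") are removed and the remaining network is
#' returned for re-simulation.
#'
#' @param network an `mt_network`.
#' @param label subset label to remove.
#' @export
drop_subset <- function(network, label = "dynamic") {
  keep <- network$subset_label != label
  mt_network(network$filaments[keep], network$bundle_id[keep],
             network$subset_label[keep], geometry = network$geometry)
}

#' Write / read a network as a plain CSV of vertices
#'
#' Columns: filament_id, vertex_index, x_nm, y_nm, bundle_id, subset_label.
#' Vertex order encodes polarity (first vertex = minus end).
#' @param network an `mt_network`.
#' @param path file path.
#' @export
write_network_csv <- function(network, path) {
  rows <- lapply(seq_along(network$filaments), function(i) {
    f <- network$filaments[[i]]
    data.frame(filament_id = i, vertex_index = seq_len(nrow(f)) - 1L,
               x_nm = f[, 1], y_nm = f[, 2],
               bundle_id = network$bundle_id[i],
               subset_label = network$subset_label[i])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filament_id = integer(0), vertex_index = integer(0),
               x_nm = numeric(0), y_nm = numeric(0), bundle_id = integer(0),
               subset_label = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$filament_id)
  fil <- list(); bid <- integer(0); lab <- character(0)
  for (i in ids) {
    sub <- df[df$filament_id == i, ]
    sub <- sub[order(sub$vertex_index), ]
    fil <- c(fil, list(cbind(x_nm = sub$x_nm, y_nm = sub$y_nm)))
    bid <- c(bid, sub$bundle_id[1])
    lab <- c(lab, as.character(sub$subset_label[1]))
  }
  mt_network(fil, bundle_id = bid, subset_label = lab, geometry = "custom")
}
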