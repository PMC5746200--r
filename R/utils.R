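#' @keywords internal
#' @importFrom stats pnorm rnorm runif rpois rexp sd mad approx na.omit ave
#'   coef lm setNames
"_PACKAGE"

# ---- seeds ----------------------------------------------------------------

#' Derive a reproducible child seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds by a fixed affine map
#' modulo a Mersenne prime, so each stage is independently reproducible.
#'
#' @param seed integer global seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271 + (k + 1) * 7919) %% (m - 1)) + 1)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# ---- numeric checks -------------------------------------------------------

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0))) {
    stop(sprintf("'%s' must be %s finite numeric, got: %s", name,
                 if (strict) "strictly positive" else "non-negative",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1], got: %s", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# truncated-at-zero normal draws (rejection; fine for cv <= ~0.5)
rtnorm_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd <= 0) return(rep(max(mean, 0), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

# ---- polyline geometry ----------------------------------------------------

# vertices: matrix with columns x, y (nm); returns cumulative arclength from
# the first vertex (the minus end)
polyline_arclength <- function(vertices) {
  d <- sqrt(rowSums(diff(vertices)^2))
  c(0, cumsum(d))
}

polyline_length <- function(vertices) {
  sum(sqrt(rowSums(diff(vertices)^2)))
}

# position (and unit tangent) at arclength s along the polyline
polyline_point <- function(vertices, s) {
  cs <- polyline_arclength(vertices)
  total <- cs[length(cs)]
  s <- pmin(pmax(s, 0), total)
  seg <- findInterval(s, cs, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(vertices) - 1L)
  p0 <- vertices[seg, , drop = FALSE]
  p1 <- vertices[seg + 1L, , drop = FALSE]
  len <- cs[seg + 1L] - cs[seg]
  f <- ifelse(len > 0, (s - cs[seg]) / len, 0)
  pos <- p0 + (p1 - p0) * f
  tans <- (p1 - p0) / ifelse(len > 0, len, 1)
  list(xy = pos, tangent = tans)
}

# project points (n x 2) onto a polyline; returns arclength of the nearest
# point and the perpendicular distance
polyline_project <- function(vertices, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  cs <- polyline_arclength(vertices)
  n_seg <- nrow(vertices) - 1L
  best_d2 <- rep(Inf, nrow(points))
  best_s <- rep(NA_real_, nrow(points))
  for (k in seq_len(n_seg)) {
    a <- vertices[k, ]
    b <- vertices[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]
    py <- a[2] + t * ab[2]
    d2 <- (points[, 1] - px)^2 + (points[, 2] - py)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cs[k] + t[upd] * sqrt(len2)
  }
  list(arclength = best_s, distance = sqrt(best_d2))
}
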