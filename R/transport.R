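# Closed-form model of plus-end-directed cargo transport on a
# mixed-polarity microtubule bundle, plus a Monte-Carlo twin.
#
# A cargo performs successive runs along the bundle axis: each run is
# directed outward (toward the distal end, x = L) with probability p_plus
# and inward with probability p_minus, with exponential run length of mean
# l before switching microtubules. With reflecting ends the steady-state
# cargo density is c(x) = c0 * exp(alpha x), alpha = (p_plus - p_minus)/l.

#' Construct a transport model
#'
#' @param p_plus probability a run is directed outward (toward the distal
#'   end).
#' @param p_minus probability a run is directed inward; must satisfy
#'   `p_plus + p_minus = 1`.
#' @param l mean run length before switching microtubules (um).
#' @param L bundle (dendrite) length (um).
#' @return object of class `transport_model` with derived
#'   `alpha = (p_plus - p_minus) / l` (1/um).
#' @export
transport_model <- function(p_plus = 2/3, p_minus = 1 - p_plus, l = 2.05,
                            L = 20) {
  check_fraction(p_plus, "p_plus")
  check_fraction(p_minus, "p_minus")
  if (abs(p_plus + p_minus - 1) > 1e-12)
    stop("p_plus + p_minus must equal 1")
  check_positive(l, "l")
  check_positive(L, "L")
  structure(list(p_plus = p_plus, p_minus = p_minus, l = l, L = L,
                 alpha = (p_plus - p_minus) / l),
            class = "transport_model")
}

#' @export
print.transport_model <- function(x, ...) {
  cat(sprintf(
    "<transport_model> p+ = %.3f, p- = %.3f, l = %.2f um, L = %.1f um, alpha = %.4f /um\n",
    x$p_plus, x$p_minus, x$l, x$L, x$alpha))
  invisible(x)
}

#' Steady-state cargo density (relative to the proximal end)
#'
#' `c(x)/c0 = exp(alpha x)` with `alpha = (p_plus - p_minus) / l`.
#'
#' @param model a `transport_model`.
#' @param x position(s) along the bundle (um), in \[0, L\].
#' @return density ratio `c(x)/c0`.
#' @export
steady_state_density <- function(model, x) {
  stopifnot(inherits(model, "transport_model"))
  if (any(x < 0 | x > model$L))
    stop("x must lie within [0, L] = [0, ", model$L, "]")
  exp(model$alpha * x)
}

#' Cumulative cargo count up to a position
#'
#' `n(x) = (1/alpha) (exp(alpha x) - 1)` (with c0 = 1); for
#' `|alpha| < 1e-9` the series limit `x + alpha x^2 / 2` is used so the
#' count is continuous at alpha -> 0.
#'
#' @param model a `transport_model`.
#' @param x_n position(s) along the bundle (um), in \[0, L\].
#' @export
cumulative_count <- function(model, x_n) {
  stopifnot(inherits(model, "transport_model"))
  if (any(x_n < 0 | x_n > model$L))
    stop("x_n must lie within [0, L] = [0, ", model$L, "]")
  a <- model$alpha
  if (abs(a) < 1e-9) x_n + a * x_n^2 / 2 else (exp(a * x_n) - 1) / a
}

#' Fraction of bundle length distal to the median cargo position
#'
#' The median position `L50` solves `n(L50) = n(L)/2`, giving
#' `L50/L = ln(exp(alpha L)/2 + 1/2) / (alpha L)`; the returned fraction is
#' `1 - L50/L`. The symmetric case `p_plus = p_minus` returns 0.5 exactly
#' (series limit), and the fraction decreases strictly with `alpha * L`.
#'
#' @param model a `transport_model`.
#' @return fraction in (0, 1).
#' @export
l50_fraction <- function(model) {
  stopifnot(inherits(model, "transport_model"))
  aL <- model$alpha * model$L
  if (abs(aL) < 1e-9) {
    # L50/L = ln((e^aL + 1)/2)/aL = 1/2 + aL/8 + O(aL^2)
    return(0.5 - aL / 8)
  }
  1 - log(0.5 * exp(aL) + 0.5) / aL
}

#' Monte-Carlo twin of the transport model
#'
#' `n_motors` cargoes start uniformly on \[0, L\] and perform `n_steps`
#' successive runs; each run is outward with probability `p_plus`, has
#' exponential length (mean `l`), and reflects at both bundle ends.
#' Positions after the first half of the steps (equilibration) are
#' recorded. Deterministic for a fixed seed.
#'
#' @param model a `transport_model`.
#' @param n_motors number of cargoes.
#' @param n_steps number of runs per cargo.
#' @param seed integer seed.
#' @return numeric vector of recorded positions (um).
#' @export
simulate_cargo <- function(model, n_motors = 1e5, n_steps = 100, seed = 1L) {
  stopifnot(inherits(model, "transport_model"), n_motors > 0, n_steps > 0)
  n_motors <- as.integer(n_motors); n_steps <- as.integer(n_steps)
  L <- model$L
  with_seed(seed, {
    pos <- runif(n_motors, 0, L)
    burn <- n_steps %/% 2L
    rec <- vector("list", n_steps - burn)
    for (k in seq_len(n_steps)) {
      dir <- ifelse(runif(n_motors) < model$p_plus, 1, -1)
      step <- dir * rexp(n_motors, 1 / model$l)
      pos <- pos + step
      # reflect into [0, L] (repeat for long runs)
      while (any(pos < 0 | pos > L)) {
        pos <- ifelse(pos < 0, -pos, pos)
        pos <- ifelse(pos > L, 2 * L - pos, pos)
      }
      if (k > burn) rec[[k - burn]] <- pos
    }
    unlist(rec)
  })
}

#' Log-density slope of simulated cargo positions
#'
#' Histogram the positions into `n_bins` over \[0, L\], take the log of the
#' counts and fit a line over the central region (boundary bins within
#' `trim * L` of either end are excluded, since reflecting boundaries
#' perturb the density within about one run length of the ends). The slope
#' estimates alpha.
#'
#' @param positions vector of positions from [simulate_cargo()].
#' @param L bundle length (um).
#' @param n_bins histogram bins (default 50).
#' @param trim fraction of \[0, L\] excluded at each end (default 0.05).
#' @return slope (1/um).
#' @export
mc_density_slope <- function(positions, L, n_bins = 50, trim = 0.05) {
  h <- graphics::hist(positions, breaks = seq(0, L, length.out = n_bins + 1),
                      plot = FALSE)
  mid <- h$mids
  keep <- mid > trim * L & mid < (1 - trim) * L & h$counts > 0
  stats::coef(stats::lm(log(h$counts[keep]) ~ mid[keep]))[[2]]
}
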