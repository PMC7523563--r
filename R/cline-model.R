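#' Sigmoid geographic cline with optional exponential tails
#'
#' The cline core is the standard tension-zone sigmoid
#' `y(x) = 1 / (1 + exp(-4 (x - center) / width))`, so `width` is the inverse
#' of the maximum slope and `y(center) = 0.5`. Exponential introgression
#' tails may replace the sigmoid beyond a distance `delta` from the center:
#' on the left (low-`x`) side, for `x < center - delta_l`,
#' `y(x) = y_l * exp(4 * tau_l * (x - center + delta_l) /
#' (width * (1 + exp(-4 * delta_l / width))))` with
#' `y_l = 1 / (1 + exp(4 * delta_l / width))`; the right tail is the mirror
#' image. `tau` in `[0, 1]` controls how fast the tail decays relative to the
#' sigmoid slope at the join (the tail is tangent-continuous at `tau = 1`).
#' Finally the curve is scaled to `[p_min, p_max]`.
#'
#' Tail configurations and their free parameter counts: `none` (2: center,
#' width), `left`/`right` (4), `mirror` (4; one shared `delta`/`tau` pair
#' applied to both sides), `both` (6).
#'
#' @param center Cline center in km (frequency 0.5).
#' @param width Cline width in km (1 / maximum slope); must be positive.
#' @param tails One of `"none"`, `"left"`, `"right"`, `"mirror"`, `"both"`.
#' @param delta_l,delta_r Tail lengths in km (>= 0).
#' @param tau_l,tau_r Tail slopes in `[0, 1]`.
#' @param p_min,p_max Frequency asymptotes (defaults 0 and 1, appropriate for
#'   markers fixed between the transect-edge reference populations).
#' @return A list of class `cline_model`.
#' @export
cline_model <- function(center, width, tails = c("none", "left", "right", "mirror", "both"),
                        delta_l = 0, tau_l = 0, delta_r = 0, tau_r = 0,
                        p_min = 0, p_max = 1) {
  tails <- match.arg(tails)
  if (width <= 0) abort("width must be positive")
  if (p_min >= p_max) abort("p_min must be < p_max")
  if (any(c(delta_l, delta_r) < 0)) abort("tail lengths must be >= 0")
  if (any(c(tau_l, tau_r) < 0 | c(tau_l, tau_r) > 1)) abort("tau must be in [0, 1]")
  if (tails == "mirror") {
    delta_r <- delta_l
    tau_r <- tau_l
  }
  structure(
    list(center = center, width = width, tails = tails,
         delta_l = delta_l, tau_l = tau_l, delta_r = delta_r, tau_r = tau_r,
         p_min = p_min, p_max = p_max),
    class = "cline_model"
  )
}

#' @export
print.cline_model <- function(x, ...) {
  cat(sprintf("<cline_model> center = %.3g km, width = %.3g km, tails = %s\n",
              x$center, x$width, x$tails))
  if (x$tails != "none") {
    cat(sprintf("  left:  delta = %.3g, tau = %.3g\n  right: delta = %.3g, tau = %.3g\n",
                x$delta_l, x$tau_l, x$delta_r, x$tau_r))
  }
  invisible(x)
}

#' Number of free parameters of a tail configuration
#' @param tails Tail configuration string.
#' @return Integer parameter count (2, 4 or 6).
#' @export
cline_n_par <- function(tails) {
  switch(tails, none = 2L, left = 4L, right = 4L, mirror = 4L, both = 6L,
         abort("unknown tail configuration"))
}

#' Evaluate a cline at transect positions
#'
#' @param x Numeric vector of positions (km).
#' @param model A [cline_model()].
#' @return Frequencies in `[p_min, p_max]`, same length as `x`.
#' @export
cline_value <- function(x, model) {
  m <- model
  if (m$width <= 0) abort("width must be positive")
  y <- 1 / (1 + exp(-4 * (x - m$center) / m$width))
  if (m$tails %in% c("left", "mirror", "both")) {
    lo <- x < m$center - m$delta_l
    if (any(lo)) {
      e <- exp(-4 * m$delta_l / m$width)
      y_l <- 1 / (1 + exp(4 * m$delta_l / m$width))
      y[lo] <- y_l * exp(4 * m$tau_l * (x[lo] - m$center + m$delta_l) /
                           (m$width * (1 + e)))
    }
  }
  if (m$tails %in% c("right", "mirror", "both")) {
    hi <- x > m$center + m$delta_r
    if (any(hi)) {
      e <- exp(-4 * m$delta_r / m$width)
      y_r <- 1 / (1 + exp(4 * m$delta_r / m$width))
      y[hi] <- 1 - y_r * exp(-4 * m$tau_r * (x[hi] - m$center - m$delta_r) /
                               (m$width * (1 + e)))
    }
  }
  m$p_min + (m$p_max - m$p_min) * y
}

#' Binomial log-likelihood of a cline for population frequencies
#'
#' `sum_i [ k_i log y(x_i) + (n_i - k_i) log(1 - y(x_i)) ]` with the fitted
#' frequencies clamped to `[1e-9, 1 - 1e-9]`.
#'
#' @param model A [cline_model()].
#' @param freqs A population frequency table (columns `distance_km`,
#'   `n_alleles`, `focal_allele_count`).
#' @return The log-likelihood (a scalar).
#' @export
cline_loglik <- function(model, freqs) {
  if (nrow(freqs) == 0) abort("frequency table is empty")
  y <- cline_value(freqs$distance_km, model)
  y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
  sum(freqs$focal_allele_count * log(y) +
        (freqs$n_alleles - freqs$focal_allele_count) * log1p(-y))
}
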