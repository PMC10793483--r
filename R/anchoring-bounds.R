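#' Precision bounds for anchored (non-scaling) positioning mechanisms
#'
#' If a positional marker sits at a fixed absolute distance from the anterior
#' pole, its scaled position `f_p = x_p / L` fluctuates purely because embryo
#' lengths vary. To leading order in the length variability `cv = sigma_L/<L>`
#' the standard deviation of the scaled position is `f_p * cv` (anterior
#' anchoring) or `(1 - f_p) * cv` (posterior anchoring); combining both signals
#' optimally gives the inverse-variance combination of the two. These curves
#' are the null against which measured scaled-position SDs are compared: a
#' marker more precise than the combined bound cannot be explained by any
#' mechanism without explicit sensitivity to embryo length.
#'
#' `exact = TRUE` evaluates the full moment expression
#' `sigma^2 = x_p^2 (<1/L^2> - <1/L>^2)` with `x_p = f_p <L>`, using the
#' stated length distribution (closed form for lognormal, numerical
#' integration for the 4-sd-truncated Gaussian). The leading-order forms are
#' the default because published bound curves use them; the exact variant
#' differs at relative order `cv^2`.
#'
#' @param fp mean scaled position(s) in `[0, 1]` (vectorized).
#' @param cv relative length variability `sigma_L / <L>`, >= 0.
#' @param exact if `TRUE`, evaluate the exact moment expression under `model`.
#' @param model a [length_model()] supplying the distribution for the exact
#'   variant; its `cv` is overridden by `cv`.
#' @return standard deviation(s) of scaled position (dimensionless).
#' @export
anchor_sd_anterior <- function(fp, cv, exact = FALSE, model = length_model()) {
  stopifnot(all(fp >= 0 & fp <= 1), cv >= 0)
  if (!exact) return(fp * cv)
  m <- inverse_length_moments(length_model(model$mean_length, cv, model$distribution))
  fp * model$mean_length * sqrt(pmax(m$m2 - m$m1^2, 0))
}

#' @rdname anchor_sd_anterior
#' @export
anchor_sd_posterior <- function(fp, cv, exact = FALSE, model = length_model()) {
  anchor_sd_anterior(1 - fp, cv, exact = exact, model = model)
}

#' @rdname anchor_sd_anterior
#' @export
anchor_sd_combined <- function(fp, cv, exact = FALSE, model = length_model()) {
  a <- anchor_sd_anterior(fp, cv, exact = exact, model = model)
  p <- anchor_sd_posterior(fp, cv, exact = exact, model = model)
  out <- sqrt(1 / (1 / a^2 + 1 / p^2))
  # at the poles one bound vanishes and the combination has limit 0
  out[a == 0 | p == 0] <- 0
  out
}

# First two inverse moments <1/L>, <1/L^2> of a length distribution.
inverse_length_moments <- function(model) {
  m <- model$mean_length; cv <- model$cv
  if (cv == 0) return(list(m1 = 1 / m, m2 = 1 / m^2))
  if (model$distribution == "lognormal") {
    s2 <- log(1 + cv^2)
    mu <- log(m) - s2 / 2
    list(m1 = exp(-mu + s2 / 2), m2 = exp(-2 * mu + 2 * s2))
  } else {
    sdl <- cv * m
    lo <- max(m - 4 * sdl, .Machine$double.eps); hi <- m + 4 * sdl
    z <- integrate(function(L) dnorm(L, m, sdl), lo, hi)$value
    m1 <- integrate(function(L) dnorm(L, m, sdl) / L, lo, hi)$value / z
    m2 <- integrate(function(L) dnorm(L, m, sdl) / L^2, lo, hi)$value / z
    list(m1 = m1, m2 = m2)
  }
}

#' Anchoring bound curves along the axis
#'
#' Tabulates the anterior, posterior and combined anchoring bounds on a grid
#' of mean scaled positions, for overlaying on measured scaled-position SD
#' profiles.
#'
#' @param cv relative length variability.
#' @param grid_step spacing of the `fp` grid; default 0.01.
#' @param exact,model passed to [anchor_sd_anterior()].
#' @return a `data.frame` with columns `fp`, `sd_anterior`, `sd_posterior`,
#'   `sd_combined`, and attribute `cv`.
#' @export
bound_curve <- function(cv, grid_step = 0.01, exact = FALSE, model = length_model()) {
  fp <- seq(grid_step, 1 - grid_step, by = grid_step)
  out <- data.frame(
    fp = fp,
    sd_anterior = anchor_sd_anterior(fp, cv, exact, model),
    sd_posterior = anchor_sd_posterior(fp, cv, exact, model),
    sd_combined = anchor_sd_combined(fp, cv, exact, model)
  )
  attr(out, "cv") <- cv
  out
}
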