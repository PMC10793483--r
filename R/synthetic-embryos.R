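#' Length distribution model
#'
#' Describes the distribution of embryo lengths: mean `<L>` and coefficient of
#' variation `cv = sigma_L / <L>`. Laboratory fly embryos vary in length by
#' about 4 percent (cv ~ 0.037-0.04 depending on fixation), which is the
#' regime all defaults in this package target.
#'
#' @param mean_length mean length in micron; default 490 (live embryos).
#' @param cv coefficient of variation of length, >= 0; default 0.037.
#' @param distribution `"gaussian"` (truncated at +/- 4 sd, so draws are always
#'   positive for any cv < 0.25) or `"lognormal"`. The lognormal option matters
#'   when the exact anchoring bound, which involves `<1/L^2>`, is evaluated.
#' @return an object of class `length_model`.
#' @export
length_model <- function(mean_length = 490, cv = 0.037,
                         distribution = c("gaussian", "lognormal")) {
  distribution <- match.arg(distribution)
  if (mean_length <= 0) stop("mean_length must be positive")
  if (cv < 0) stop("cv must be non-negative")
  structure(list(mean_length = mean_length, cv = cv, distribution = distribution),
            class = "length_model")
}

#' Draw embryo lengths
#'
#' Samples `n` positive lengths from a [length_model()]. Gaussian draws are
#' truncated at four standard deviations (resampled if outside), which keeps
#' every draw positive at realistic cv and leaves the first two moments
#' essentially unchanged.
#'
#' @param n number of embryos, >= 1.
#' @param model a [length_model()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of `n` lengths (micron).
#' @export
draw_lengths <- function(n, model = length_model(), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(inherits(model, "length_model"))
  if (model$cv == 0) return(rep(model$mean_length, n))
  with_seed(seed, {
    if (model$distribution == "gaussian") {
      sdl <- model$cv * model$mean_length
      out <- rnorm(n, model$mean_length, sdl)
      bad <- abs(out - model$mean_length) > 4 * sdl | out <= 0
      while (any(bad)) {
        out[bad] <- rnorm(sum(bad), model$mean_length, sdl)
        bad <- abs(out - model$mean_length) > 4 * sdl | out <= 0
      }
      out
    } else {
      sdlog <- sqrt(log(1 + model$cv^2))
      meanlog <- log(model$mean_length) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    }
  })
}

# --- mean-shape primitives (functions of scaled position) -------------------

logistic_rise <- function(x0, w = 0.015) function(xs) 1 / (1 + exp(-(xs - x0) / w))
logistic_fall <- function(x0, w = 0.015) function(xs) 1 / (1 + exp((xs - x0) / w))

# Plateau between a rising and a falling boundary; half-max crossings sit at
# the two midpoints when the boundaries are separated by >> w.
expression_domain <- function(rise, fall, w = 0.015) {
  fr <- logistic_rise(rise, w); ff <- logistic_fall(fall, w)
  function(xs) fr(xs) * ff(xs)
}

gaussian_bump <- function(center, width) {
  function(xs) exp(-(xs - center)^2 / (2 * width^2))
}

#' Profile family: mean shapes, noise model and scaling mode
#'
#' A `profile_family` bundles, for each gene, a mean-shape function
#' `Phi_i(xs, t)` on scaled position (unit-maximum normalized at the reference
#' time), a noise model, and the `scaling_mode` that controls how
#' [generate_ensemble()] maps the shape into embryos of different lengths:
#'
#' * `"scaled"`: expression depends on `xs = x/L` only (exact scale
#'   invariance).
#' * `"anchored_anterior"`: expression is a fixed function of absolute
#'   distance `x` from the anterior pole; the shape is interpreted in absolute
#'   coordinates via `x / ref_length`.
#' * `"anchored_posterior"`: same, measured from the posterior pole.
#' * `"exponential"`: `g(x) = exp(-x / lambda)` with a decay length `lambda`
#'   (micron) independent of `L` — the non-scaling maternal-input case.
#'
#' @param genes character gene names.
#' @param shapes list of functions `f(xs, t)` (one per gene) returning mean
#'   expression; must accept arguments outside `[0, 1]` (anchored modes
#'   evaluate the shape at `xs * L / ref_length`).
#' @param mode scaling mode, see above.
#' @param noise_sd expression noise SD: a constant or a function of `xs`;
#'   default 0.05 of unit maximum.
#' @param lambda decay length (micron) for `mode = "exponential"`.
#' @param ref_length reference length (micron) used by the anchored modes to
#'   interpret the shape in absolute coordinates; default 490.
#' @param t0 reference time (minutes) at which shapes are unit-max normalized.
#' @return an object of class `profile_family`.
#' @export
profile_family <- function(genes, shapes,
                           mode = c("scaled", "anchored_anterior",
                                    "anchored_posterior", "exponential"),
                           noise_sd = 0.05, lambda = NULL, ref_length = 490,
                           t0 = 45) {
  mode <- match.arg(mode)
  if (length(genes) != length(shapes)) stop("one shape per gene required")
  if (mode == "exponential" && (is.null(lambda) || lambda <= 0))
    stop("exponential mode requires a positive decay length lambda (micron)")
  # normalize each shape to unit maximum at the reference time
  xs_fine <- seq(1e-4, 1 - 1e-4, length.out = 4096)
  shapes <- lapply(shapes, function(f) {
    f2 <- if (length(formals(f)) == 1L) function(xs, t) f(xs) else f
    m <- max(f2(xs_fine, t0))
    if (m <= 0) stop("shape has non-positive maximum")
    function(xs, t = t0) f2(xs, t) / m
  })
  structure(list(genes = genes, shapes = shapes, mode = mode,
                 noise_sd = noise_sd, lambda = lambda,
                 ref_length = ref_length, t0 = t0),
            class = "profile_family")
}

#' Gap-gene-like profile family
#'
#' Builds a family of graded profiles shaped like the trunk gap genes: broad
#' expression domains bounded by logistic transitions, each gene crossing its
#' half-maximum level 2-4 times within `xs` in `[0.1, 0.9]`. The default
#' 4-gene family mimics the Hb / Kr / Kni / Gt domain layout and has 13
#' half-maximum boundaries in total.
#'
#' @param n_genes number of genes; the curated layout is used for
#'   `n_genes = 4`, a single falling boundary for `n_genes = 1`, and evenly
#'   spread two-boundary domains otherwise.
#' @param mode scaling mode passed to [profile_family()].
#' @param noise_sd expression noise SD; default 0.05.
#' @param seed seed for the small positional jitter applied in the generic
#'   (`n_genes` not 1 or 4) layout.
#' @return a `profile_family`.
#' @export
make_gap_like_family <- function(n_genes = 4, mode = "scaled", noise_sd = 0.05,
                                 seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  add <- function(...) { fs <- list(...); function(xs) Reduce(`+`, lapply(fs, function(f) f(xs))) }
  scaled_domain <- function(rise, fall, a = 1) { d <- expression_domain(rise, fall); function(xs) a * d(xs) }
  if (n_genes == 4) {
    shapes <- list(
      hb  = add(logistic_fall(0.45), scaled_domain(0.78, 0.89, 0.85)),
      kr  = expression_domain(0.40, 0.63),
      kni = add(scaled_domain(0.18, 0.28, 0.60), scaled_domain(0.60, 0.75)),
      gt  = add(scaled_domain(0.13, 0.35), scaled_domain(0.70, 0.88))
    )
    genes <- names(shapes)
  } else if (n_genes == 1) {
    shapes <- list(g1 = logistic_fall(0.47))
    genes <- "g1"
  } else {
    edges <- seq(0.1, 0.9, length.out = 2 * n_genes + 1)
    jit <- with_seed(seed, runif(2 * n_genes, -0.2, 0.2)) * diff(edges)[1]
    genes <- paste0("g", seq_len(n_genes))
    shapes <- lapply(seq_len(n_genes), function(i) {
      expression_domain(edges[2 * i - 1] + jit[2 * i - 1],
                        edges[2 * i + 1] + jit[2 * i])
    })
    names(shapes) <- genes
  }
  profile_family(genes, shapes, mode = mode, noise_sd = noise_sd)
}

#' Pair-rule-like striped profile family
#'
#' Periodic stripes modeled as Gaussian bumps whose scaled positions drift
#' linearly in time: stripe `i` peaks at `f_i + s_i * (t - t0)`. The default
#' is a 7-stripe (Eve-like) layout spanning `xs` 0.30-0.79, with drift rates
#' of order 1e-3 per minute, larger for posterior stripes.
#'
#' @param n_stripes number of stripes, >= 1.
#' @param positions scaled stripe positions at `t0`; default evenly spaced on
#'   `[0.30, 0.79]`.
#' @param drift_slopes per-stripe drift rate in scaled units per minute;
#'   default ramps from -5e-4 (anterior) to -2e-3 (posterior).
#' @param width Gaussian stripe width (scaled units); default 0.015.
#' @param t0 reference time (min); default 45.
#' @param mode,noise_sd passed to [profile_family()].
#' @param seed unused in the default layout (kept for interface symmetry).
#' @return a `profile_family` with a single gene whose shape is the stripe sum.
#' @export
make_pair_rule_family <- function(n_stripes = 7, positions = NULL,
                                  drift_slopes = NULL, width = 0.015, t0 = 45,
                                  mode = "scaled", noise_sd = 0.05, seed = NULL) {
  if (n_stripes < 1) stop("n_stripes must be >= 1")
  if (is.null(positions)) positions <- seq(0.30, 0.79, length.out = n_stripes)
  if (length(positions) != n_stripes) stop("need one position per stripe")
  if (is.unsorted(positions, strictly = TRUE)) stop("stripe positions must be increasing")
  if (n_stripes > 1 && min(diff(positions)) < 2 * width)
    stop("stripes overlap at the reference time")
  if (is.null(drift_slopes)) {
    r <- if (n_stripes > 1) (positions - positions[1]) / diff(range(positions)) else 0
    drift_slopes <- -5e-4 - 1.5e-3 * r
  }
  if (length(drift_slopes) == 1L) drift_slopes <- rep(drift_slopes, n_stripes)
  # warn (but still generate) if drift can bring stripes into overlap over the
  # usual 30-60 min window
  for (dt in c(-15, 15)) {
    p <- positions + drift_slopes * dt
    if (n_stripes > 1 && min(diff(p)) < 2 * width) {
      warning("stripes overlap after drift"); break
    }
  }
  shape <- function(xs, t = t0) {
    p <- positions + drift_slopes * (t - t0)
    out <- 0
    for (i in seq_len(n_stripes)) out <- out + exp(-(xs - p[i])^2 / (2 * width^2))
    out
  }
  fam <- profile_family("stripes", list(stripes = shape), mode = mode,
                        noise_sd = noise_sd, t0 = t0)
  fam$stripe_positions <- positions
  fam$drift_slopes <- drift_slopes
  fam$stripe_width <- width
  fam
}

#' Exponential (maternal-input-like) non-scaling family
#'
#' A single profile `g(x) = exp(-x / lambda)` with a decay length fixed in
#' absolute units, emulating the anterior maternal morphogen: profiles of
#' embryos with different lengths coincide when plotted against absolute
#' position but separate when plotted against scaled position.
#'
#' @param lambda decay length in micron; default 100 (about 0.2 of the mean
#'   embryo length).
#' @param gene gene name; default `"bcd"`.
#' @param noise_sd expression noise SD; default 0.05.
#' @return a `profile_family` with `mode = "exponential"`.
#' @export
make_exponential_family <- function(lambda = 100, gene = "bcd", noise_sd = 0.05) {
  fam <- profile_family(gene, stats::setNames(list(function(xs) exp(-xs)), gene),
                        mode = "exponential", noise_sd = noise_sd, lambda = lambda)
  fam
}

#' Generate a synthetic embryo ensemble
#'
#' Evaluates the family's mean shapes for each embryo according to the
#' family's scaling mode (see [profile_family()]), then adds independent
#' Gaussian noise at every grid point and clips at zero.
#'
#' @param family a [profile_family()].
#' @param lengths embryo lengths (micron), e.g. from [draw_lengths()].
#' @param times developmental times (minutes); `NULL` draws them uniformly on
#'   `[30, 60]` (the usual measurement window).
#' @param noise_sd overrides the family's noise SD (constant or function of
#'   `xs`); `NULL` keeps the family default.
#' @param n_grid number of (cell-centered) grid points; default 1000.
#' @param seed integer seed.
#' @return an [embryo_ensemble()].
#' @export
generate_ensemble <- function(family, lengths, times = NULL, noise_sd = NULL,
                              n_grid = 1000, seed = NULL) {
  stopifnot(inherits(family, "profile_family"))
  n <- length(lengths)
  if (n < 1) stop("lengths must be non-empty")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (is.null(noise_sd)) noise_sd <- family$noise_sd
  xs <- (seq_len(n_grid) - 0.5) / n_grid
  sd_vec <- if (is.function(noise_sd)) noise_sd(xs) else rep(noise_sd, n_grid)
  if (any(sd_vec < 0)) stop("noise_sd must be non-negative")
  G <- length(family$genes)
  with_seed(seed, {
    if (is.null(times)) times <- runif(n, 30, 60)
    if (length(times) != n) stop("lengths and times must have the same count")
    profiles <- array(0, dim = c(n, n_grid, G))
    for (a in seq_len(n)) {
      arg <- switch(family$mode,
        scaled = xs,
        anchored_anterior = xs * lengths[a] / family$ref_length,
        anchored_posterior = 1 - (1 - xs) * lengths[a] / family$ref_length,
        exponential = xs * lengths[a]  # absolute position, handled below
      )
      for (g in seq_len(G)) {
        base <- if (family$mode == "exponential") {
          exp(-arg / family$lambda)
        } else {
          family$shapes[[g]](arg, times[a])
        }
        profiles[a, , g] <- base
      }
    }
    if (any(sd_vec > 0)) {
      noise <- array(rnorm(n * n_grid * G), dim = c(n, n_grid, G)) *
        rep(sd_vec, each = n)
      profiles <- pmax(profiles + noise, 0)
    }
    embryo_ensemble(xs, lengths, times, family$genes, profiles,
                    params = list(mode = family$mode, noise_sd = noise_sd,
                                  seed = seed, family = family))
  })
}

#' Gaussian calibration ensemble with known delta-I
#'
#' Builds a single-gene ensemble whose deviation from scaling is known in
#' closed form, for calibrating the delta-I estimator. Embryos are assigned to
#' `n_length_bins` equal-count length bins; within a bin the expression at
#' every scaled position is `m + c * z_b + noise`, where `z_b` is the
#' standardized bin score and `c = noise_sd * sqrt(2^(2 dI) - 1)`. Because the
#' length effect is constant within each equal-count bin, conditioning on the
#' bin removes it exactly and the true decomposition value is `dI` bits.
#'
#' The closed-form value refers to the variable the estimator actually sees:
#' the expression value per scaled-position bin. The default grid therefore
#' places exactly one sample per 0.01 analysis bin, so the per-bin noise SD is
#' `noise_sd` itself and `delta_I_bits` is exact (a finer grid would be
#' averaged down by the binning and inflate the realized value).
#'
#' @param delta_I_bits target deviation from scaling, in bits.
#' @param n_embryos ensemble size; default 301.
#' @param n_length_bins number of equal-count length bins the construction
#'   (and the matched estimator call) uses; default 5.
#' @param noise_sd per-bin expression SD; default 0.05.
#' @param length_dist a [length_model()].
#' @param n_grid grid size; default 100 (one sample per 0.01 bin).
#' @param seed integer seed.
#' @return an [embryo_ensemble()] with attribute `delta_I_true` (bits).
#' @export
gaussian_toy_ensemble <- function(delta_I_bits, n_embryos = 301,
                                  n_length_bins = 5, noise_sd = 0.05,
                                  length_dist = length_model(), n_grid = 100,
                                  seed = NULL) {
  if (delta_I_bits < 0) stop("delta_I_bits must be >= 0")
  seeds <- spawn_seeds(seed, 2L)
  lengths <- draw_lengths(n_embryos, length_dist, seed = seeds[1])
  bins <- adaptive_length_bins(lengths, n_length_bins)
  z <- bins$assignment
  z <- (z - mean(z)) / stats::sd(z)
  cc <- noise_sd * sqrt(2^(2 * delta_I_bits) - 1)
  xs <- (seq_len(n_grid) - 0.5) / n_grid
  ens <- with_seed(seeds[2], {
    times <- runif(n_embryos, 30, 60)
    profiles <- array(rnorm(n_embryos * n_grid, sd = noise_sd),
                      dim = c(n_embryos, n_grid, 1))
    profiles <- profiles + 0.5 + cc * z  # recycled over grid points, per embryo
    embryo_ensemble(xs, lengths, times, "g1", profiles,
                    params = list(mode = "gaussian_toy",
                                  delta_I_true = delta_I_bits, seed = seed))
  })
  attr(ens, "delta_I_true") <- delta_I_bits
  ens
}
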