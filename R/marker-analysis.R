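#' Detect stripe peaks in a single expression profile
#'
#' Finds local maxima of a concentration profile on the scaled-position grid,
#' keeps those whose topographic prominence exceeds `min_prominence` (as a
#' fraction of the profile maximum), and refines each position to sub-grid
#' accuracy by the vertex of the parabola through the maximum and its two
#' neighbours. Peaks are returned anterior to posterior.
#'
#' @param profile numeric concentration vector (>= 5 points).
#' @param xs scaled-position grid matching `profile`.
#' @param min_prominence prominence threshold in (0, 1), as a fraction of the
#'   profile maximum; default 0.1.
#' @return a `data.frame` with columns `xs_pos`, `height`, `prominence`
#'   (zero rows if no peak qualifies).
#' @export
detect_peaks <- function(profile, xs, min_prominence = 0.1) {
  stopifnot(length(profile) >= 5, length(profile) == length(xs),
            min_prominence > 0, min_prominence < 1)
  n <- length(profile)
  top <- max(profile)
  if (top <= 0 || diff(range(profile)) == 0)
    return(data.frame(xs_pos = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  # strict rise on the left, non-strict fall on the right, so the left point of
  # a flat-topped pair is the candidate; the parabola vertex then places the
  # refined position between them.
  cand <- which(profile[2:(n - 1)] > profile[1:(n - 2)] &
                  profile[2:(n - 1)] >= profile[3:n]) + 1L
  if (!length(cand))
    return(data.frame(xs_pos = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence(profile, i, cand), numeric(1))
  keep <- prom >= min_prominence * top
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand))
    return(data.frame(xs_pos = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  pos <- vapply(cand, function(i) {
    y <- profile[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    delta <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    xs[i] + delta * (xs[min(i + 1, n)] - xs[i])
  }, numeric(1))
  ord <- order(pos)
  data.frame(xs_pos = pos[ord], height = profile[cand][ord],
             prominence = prom[ord])
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles, where each saddle is the minimum between the
# peak and the nearest strictly higher terrain (or the profile end).
peak_prominence <- function(profile, i, cand) {
  h <- profile[i]
  left <- profile[seq_len(i - 1)]
  higher <- which(left > h)
  sl <- min(left[seq(from = if (length(higher)) max(higher) else 1L,
                     to = i - 1L)])
  right <- profile[seq(i + 1L, length(profile))]
  higher <- which(right > h)
  sr <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
  h - max(sl, sr)
}

#' Detect half-maximum expression boundaries across an ensemble
#'
#' The boundary threshold is half the maximum of the ensemble-mean profile of
#' the gene. Reference boundaries are the threshold crossings of the mean
#' profile (localized by linear interpolation and labelled rising/falling by
#' the local slope). Each embryo's own crossings are then matched to the
#' nearest reference boundary within `match_window` in scaled position;
#' embryos with no crossing near a reference boundary contribute a missing
#' value for it.
#'
#' Profiles are first averaged with a centered moving window of width
#' `smooth_window` (in scaled units, default 0.01 — the scale at which
#' intensities are measured), which suppresses the spurious threshold
#' re-crossings that raw per-point noise produces; among the remaining
#' same-direction crossings inside `match_window`, the median position is
#' taken, which is unbiased with respect to the reference position (picking
#' the *nearest* crossing would shrink per-embryo positions toward the
#' ensemble mean and bias position-versus-length slopes).
#'
#' @param ensemble an [embryo_ensemble()] (>= 2 embryos).
#' @param gene gene name.
#' @param match_window maximum scaled distance between an embryo crossing and
#'   the reference boundary it is assigned to; default 0.05.
#' @param smooth_window width (scaled units) of the moving-average pre-filter
#'   applied to each profile before localization; default 0.01.
#' @return a `data.frame` of markers with columns `marker_id`, `embryo_id`,
#'   `gene`, `kind` (`"boundary_rising"`/`"boundary_falling"`), `f` (scaled
#'   position, `NA` if missing), `x_um` (absolute position), `L_um`, `t_min`,
#'   `time_corrected` (logical).
#' @export
detect_half_max_boundaries <- function(ensemble, gene, match_window = 0.05,
                                       smooth_window = 0.01) {
  stopifnot(inherits(ensemble, "embryo_ensemble"), n_embryos(ensemble) >= 2)
  g <- match(gene, ensemble$genes)
  if (is.na(g)) stop("unknown gene: ", gene)
  xs <- ensemble$xs
  k <- smooth_points(smooth_window, xs)
  prof <- ensemble$profiles[, , g, drop = TRUE]
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  prof <- t(apply(prof, 1, smooth_profile, k = k))
  mean_prof <- colMeans(prof)
  thr <- 0.5 * max(mean_prof)
  ref <- threshold_crossings(mean_prof, xs, thr)
  if (!nrow(ref)) stop("mean profile never crosses its half-maximum")
  out <- vector("list", n_embryos(ensemble))
  for (a in seq_len(n_embryos(ensemble))) {
    cr <- threshold_crossings(prof[a, ], xs, thr)
    f <- rep(NA_real_, nrow(ref))
    for (b in seq_len(nrow(ref))) {
      same <- cr[cr$kind == ref$kind[b], , drop = FALSE]
      if (nrow(same)) {
        d <- abs(same$xs_pos - ref$xs_pos[b])
        if (min(d) <= match_window)
          f[b] <- stats::median(same$xs_pos[d <= match_window])
      }
    }
    out[[a]] <- data.frame(
      marker_id = paste0(gene, "_", ref$kind, "_", seq_len(nrow(ref))),
      embryo_id = a, gene = gene, kind = paste0("boundary_", ref$kind),
      f = f, x_um = f * ensemble$lengths[a],
      L_um = ensemble$lengths[a], t_min = ensemble$times[a],
      time_corrected = FALSE
    )
  }
  do.call(rbind, out)
}

# Centered moving average with edge replication; k = 1 is a no-op.
smooth_profile <- function(y, k) {
  if (k <= 1) return(y)
  n <- length(y)
  half <- (k - 1L) %/% 2L
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, rep(1 / k, k), sides = 2))[(half + 1):(half + n)]
}

smooth_points <- function(smooth_window, xs) {
  dx <- xs[2] - xs[1]
  k <- max(1L, round(smooth_window / dx))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

# Linear-interpolation crossings of `profile` through `thr`, labelled by slope.
threshold_crossings <- function(profile, xs, thr) {
  s <- profile - thr
  idx <- which(s[-length(s)] * s[-1] < 0 | (s[-length(s)] == 0 & s[-1] != 0))
  if (!length(idx))
    return(data.frame(xs_pos = numeric(0), kind = character(0)))
  pos <- xs[idx] + (xs[idx + 1] - xs[idx]) * s[idx] / (s[idx] - s[idx + 1])
  kind <- ifelse(s[idx + 1] > s[idx], "rising", "falling")
  data.frame(xs_pos = pos, kind = kind)
}

#' Extract stripe-peak markers for every embryo
#'
#' Runs [detect_peaks()] on each embryo's profile of `gene` and matches peaks
#' to the reference peaks of the ensemble-mean profile (nearest within
#' `match_window`), so that the same physical stripe carries the same
#' `marker_id` across embryos.
#'
#' Profiles are pre-filtered with the same moving average as
#' [detect_half_max_boundaries()] so that per-point noise does not create
#' spurious local maxima inside a stripe.
#'
#' @inheritParams detect_half_max_boundaries
#' @param min_prominence passed to [detect_peaks()].
#' @return a marker `data.frame` in the same layout as
#'   [detect_half_max_boundaries()], `kind = "peak"`.
#' @export
detect_peak_markers <- function(ensemble, gene, min_prominence = 0.1,
                                match_window = 0.05, smooth_window = 0.01) {
  stopifnot(inherits(ensemble, "embryo_ensemble"))
  g <- match(gene, ensemble$genes)
  if (is.na(g)) stop("unknown gene: ", gene)
  xs <- ensemble$xs
  k <- smooth_points(smooth_window, xs)
  prof <- ensemble$profiles[, , g, drop = TRUE]
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  prof <- t(apply(prof, 1, smooth_profile, k = k))
  ref <- detect_peaks(colMeans(prof), xs, min_prominence)
  if (!nrow(ref)) stop("mean profile has no qualifying peak")
  out <- vector("list", n_embryos(ensemble))
  for (a in seq_len(n_embryos(ensemble))) {
    pk <- detect_peaks(prof[a, ], xs, min_prominence)
    f <- rep(NA_real_, nrow(ref))
    for (b in seq_len(nrow(ref))) {
      if (nrow(pk)) {
        d <- abs(pk$xs_pos - ref$xs_pos[b])
        if (min(d) <= match_window) f[b] <- pk$xs_pos[which.min(d)]
      }
    }
    out[[a]] <- data.frame(
      marker_id = paste0(gene, "_peak_", seq_len(nrow(ref))),
      embryo_id = a, gene = gene, kind = "peak",
      f = f, x_um = f * ensemble$lengths[a],
      L_um = ensemble$lengths[a], t_min = ensemble$times[a],
      time_corrected = FALSE
    )
  }
  do.call(rbind, out)
}

#' Fit linear temporal drift of marker positions
#'
#' Scaled marker positions drift slowly during the measurement window and are
#' well described by `f_i(t) = f_i(t0) + s_i (t - t0)`. This fits one ordinary
#' least squares line per `marker_id`, pooling embryos.
#'
#' @param markers a marker `data.frame` (see [detect_half_max_boundaries()]).
#' @param t0 reference time in minutes; default 45.
#' @return a `data.frame` with one row per marker: `marker_id`, `slope`
#'   (scaled units per minute), `slope_se`, `f_t0` (intercept at `t0`),
#'   `f_t0_se`, `n`.
#' @export
fit_drift <- function(markers, t0 = 45) {
  split_m <- split(markers, markers$marker_id)
  rows <- lapply(split_m, function(m) {
    m <- m[!is.na(m$f), ]
    if (length(unique(m$t_min)) < 3)
      stop("fit_drift needs >= 3 distinct times per marker (",
           m$marker_id[1], ")")
    fit <- lm(f ~ I(t_min - t0), data = m)
    cf <- summary(fit)$coefficients
    data.frame(marker_id = m$marker_id[1], slope = cf[2, 1],
               slope_se = cf[2, 2], f_t0 = cf[1, 1], f_t0_se = cf[1, 2],
               n = nrow(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "t0") <- t0
  out
}

#' Shift marker positions to a common reference time
#'
#' Applies `f -> f - s_i (t - t0)` using the per-marker drift slopes, records
#' that positions are now referenced to `t0` (so the correction is idempotent
#' at the same `t0`), and updates absolute positions accordingly.
#'
#' @param markers a marker `data.frame`.
#' @param drift the [fit_drift()] table.
#' @param t0 reference time in minutes; default 45.
#' @return the marker table with corrected `f`, `x_um`, `t_min = t0` and
#'   `time_corrected = TRUE`; the slope used is attached as column `slope`.
#' @export
time_correct <- function(markers, drift, t0 = 45) {
  s <- drift$slope[match(markers$marker_id, drift$marker_id)]
  if (anyNA(s)) stop("missing drift slope for some markers")
  markers$f <- markers$f - s * (markers$t_min - t0)
  markers$x_um <- markers$f * markers$L_um
  markers$t_min <- t0
  markers$time_corrected <- TRUE
  markers$slope <- s
  markers
}

#' Position-versus-length scaling fit for one marker
#'
#' Regresses absolute marker position (micron) on embryo length. Under exact
#' scaling the slope equals the mean scaled position and the intercept is
#' zero; under pole anchoring the slope is zero and the intercept is the fixed
#' absolute position. Bootstrap (resampling embryos) supplies standard errors
#' for slope, intercept, and the scaled-position SD `sigma_f`.
#'
#' @param markers rows of a marker `data.frame` for a single `marker_id`
#'   (>= 10 embryos with non-missing positions).
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed integer seed for the bootstrap.
#' @return a one-row `data.frame`: `marker_id`, `slope`, `slope_sd`,
#'   `intercept_um`, `intercept_sd`, `f_mean`, `sigma_f`, `sigma_f_sd`, `n`.
#' @export
fit_position_vs_length <- function(markers, n_boot = 1000, seed = NULL) {
  if (length(unique(markers$marker_id)) != 1)
    stop("fit_position_vs_length expects markers for a single marker_id")
  m <- markers[!is.na(markers$f), ]
  n <- nrow(m)
  if (n < 10) stop("need >= 10 embryos with a measured position")
  if (sd(m$L_um) == 0) stop("zero length variance: slope undefined")
  base <- fit_xl(m$x_um, m$L_um)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      c(fit_xl(m$x_um[i], m$L_um[i]), sigma_f = sd(m$f[i]))
    })
  })
  data.frame(
    marker_id = m$marker_id[1],
    slope = base[["slope"]], slope_sd = sd(boot["slope", ]),
    intercept_um = base[["intercept"]], intercept_sd = sd(boot["intercept", ]),
    f_mean = mean(m$f), sigma_f = sd(m$f), sigma_f_sd = sd(boot["sigma_f", ]),
    n = n
  )
}

fit_xl <- function(x, L) {
  cf <- coef(lm(x ~ L))
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Scaling fits for every marker in a table
#'
#' Convenience wrapper applying [fit_position_vs_length()] per `marker_id`.
#'
#' @inheritParams fit_position_vs_length
#' @return a `data.frame` with one row per marker.
#' @export
fit_all_markers <- function(markers, n_boot = 1000, seed = NULL) {
  seeds <- spawn_seeds(seed, length(unique(markers$marker_id)))
  groups <- split(markers, markers$marker_id)
  out <- Map(function(m, s) fit_position_vs_length(m, n_boot = n_boot, seed = s),
             groups, as.list(seeds))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scaled-position SD as a function of mean position
#'
#' Collects `(mean scaled position, sigma_f, bootstrap SD of sigma_f)` from a
#' set of scaling fits, sorted along the axis — the measured curve to compare
#' against the anchoring [bound_curve()].
#'
#' @param fits a `data.frame` of scaling fits (rows from
#'   [fit_position_vs_length()] / [fit_all_markers()]).
#' @return a `data.frame` with columns `marker_id`, `f_mean`, `sigma_f`,
#'   `sigma_f_sd`, `n`, sorted by `f_mean`.
#' @export
scaled_position_sd_profile <- function(fits) {
  out <- fits[order(fits$f_mean),
              c("marker_id", "f_mean", "sigma_f", "sigma_f_sd", "n")]
  rownames(out) <- NULL
  out
}
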