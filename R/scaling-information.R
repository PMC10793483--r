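#' Bin expression profiles along scaled position
#'
#' Averages each embryo's profile over half-open scaled-position bins
#' `[k*dxs, (k+1)*dxs)`, keeping bins that lie inside `xs_range`. With the
#' default 1000-point cell-centered grid and `dxs = 0.01`, every bin averages
#' exactly 10 grid samples. Pole regions are excluded by default because in
#' real data they are dominated by imaging artifacts (the generator mirrors
#' that convention).
#'
#' @param ensemble an [embryo_ensemble()].
#' @param dxs scaled-position bin width; must be at least the grid spacing.
#' @param xs_range axis range to retain; default `c(0.1, 0.9)`.
#' @return an object of class `binned_ensemble`: list with `values`
#'   (`n_embryos x n_bins x n_genes` array of bin means), `centers`, `lengths`,
#'   `times`, `genes`, `dxs`, `xs_range`.
#' @export
bin_positions <- function(ensemble, dxs = 0.01, xs_range = c(0.1, 0.9)) {
  stopifnot(inherits(ensemble, "embryo_ensemble"))
  xs <- ensemble$xs
  if (dxs < max(diff(xs)) - 1e-12)
    stop("dxs is finer than the profile grid; bins would be empty")
  k <- floor(xs / dxs + 1e-9)
  keep_bins <- sort(unique(k))
  lo <- keep_bins * dxs; hi <- (keep_bins + 1) * dxs
  keep_bins <- keep_bins[lo >= xs_range[1] - 1e-9 & hi <= xs_range[2] + 1e-9]
  if (!length(keep_bins)) stop("no bins inside xs_range")
  counts <- tabulate(match(k, keep_bins), nbins = length(keep_bins))
  if (any(counts == 0)) stop("empty scaled-position bin; refine the grid")
  # grid-to-bin averaging matrix
  M <- matrix(0, length(xs), length(keep_bins))
  sel <- !is.na(match(k, keep_bins))
  M[cbind(which(sel), match(k[sel], keep_bins))] <- 1
  M <- sweep(M, 2, colSums(M), "/")
  n <- n_embryos(ensemble); G <- length(ensemble$genes)
  values <- array(0, dim = c(n, length(keep_bins), G))
  for (g in seq_len(G)) values[, , g] <- ensemble$profiles[, , g] %*% M
  structure(list(values = values,
                 centers = (keep_bins + 0.5) * dxs,
                 lengths = ensemble$lengths, times = ensemble$times,
                 genes = ensemble$genes, dxs = dxs, xs_range = xs_range),
            class = "binned_ensemble")
}

#' Equal-count (adaptive) length bins
#'
#' Assigns embryos to `n_bins` bins of length with populations differing by at
#' most one, by rank. The returned edges reproduce the assignment under
#' `cut()` when lengths are distinct.
#'
#' @param lengths embryo lengths.
#' @param n_bins number of bins, >= 2.
#' @return a list with `assignment` (integer bin per embryo, 1 = shortest),
#'   `edges` (numeric, length `n_bins + 1`), `counts`.
#' @export
adaptive_length_bins <- function(lengths, n_bins) {
  n <- length(lengths)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (n_bins > n) stop("more bins than embryos")
  if (diff(range(lengths)) == 0) stop("all lengths identical: degenerate bins")
  r <- rank(lengths, ties.method = "first")
  assignment <- as.integer(floor((r - 1) * n_bins / n) + 1)
  srt <- sort(lengths)
  cuts <- which(diff(assignment[order(lengths)]) > 0)
  edges <- c(min(lengths), (srt[cuts] + srt[cuts + 1]) / 2, max(lengths))
  list(assignment = assignment, edges = edges,
       counts = tabulate(assignment, n_bins))
}

#' Conditional first and second moments per scaled-position bin
#'
#' For each scaled-position bin, computes the mean vector and covariance
#' matrix of expression across all embryos (pooled), and across embryos within
#' each equal-count length bin (conditional). Sample moments use the `n - 1`
#' denominator. Length bins whose population falls below `min_count` are
#' flagged and excluded from conditional averages (their weight is
#' renormalized over the retained cells).
#'
#' @param binned a [bin_positions()] result (or an `embryo_ensemble`, binned
#'   with defaults).
#' @param n_length_bins number of equal-count length bins; default 5.
#' @param genes gene subset; default all.
#' @param min_count minimum embryos per (xs, L) cell; default
#'   `max(3, n_genes + 2)`.
#' @return an object of class `conditional_moments`.
#' @export
conditional_moments <- function(binned, n_length_bins = 5, genes = NULL,
                                min_count = NULL) {
  if (inherits(binned, "embryo_ensemble")) binned <- bin_positions(binned)
  stopifnot(inherits(binned, "binned_ensemble"))
  gi <- if (is.null(genes)) seq_along(binned$genes) else match(genes, binned$genes)
  if (anyNA(gi)) stop("unknown gene(s)")
  V <- binned$values[, , gi, drop = FALSE]
  G <- length(gi); n <- dim(V)[1]; B <- dim(V)[2]
  if (is.null(min_count)) min_count <- max(3, G + 2)
  lb <- adaptive_length_bins(binned$lengths, n_length_bins)
  distinct <- vapply(seq_len(n_length_bins),
                     function(l) length(unique(binned$lengths[lb$assignment == l])),
                     numeric(1))
  retained <- lb$counts >= min_count & distinct >= min_count
  if (!any(retained)) stop("no length bin reaches the cell-count floor")
  pooled_mean <- array(0, c(B, G)); pooled_cov <- array(0, c(B, G, G))
  cond_cov <- array(NA_real_, c(B, n_length_bins, G, G))
  fill <- function(rows) {
    m <- length(rows)
    mu <- colMeans(V[rows, , , drop = FALSE], dims = 1)   # B x G
    Vc <- V[rows, , , drop = FALSE] - rep(mu, each = m)
    cv <- array(0, c(B, G, G))
    for (g in seq_len(G)) for (h in g:G) {
      s <- colSums(Vc[, , g, drop = FALSE] * Vc[, , h, drop = FALSE]) / (m - 1)
      cv[, g, h] <- s; cv[, h, g] <- s
    }
    list(mu = mu, cov = cv)
  }
  p <- fill(seq_len(n))
  pooled_mean <- p$mu; pooled_cov <- p$cov
  for (l in which(lb$counts >= 2)) {
    cl <- fill(which(lb$assignment == l))
    cond_cov[, l, , ] <- cl$cov
  }
  structure(list(pooled_mean = pooled_mean, pooled_cov = pooled_cov,
                 cond_cov = cond_cov, counts = lb$counts, retained = retained,
                 n = n, centers = binned$centers,
                 genes = binned$genes[gi], min_count = min_count,
                 n_length_bins = n_length_bins),
            class = "conditional_moments")
}

log2det <- function(S) {
  if (length(S) == 1) {
    if (S <= 0) return(NA_real_)
    return(log2(S))
  }
  d <- determinant(S, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus) / log(2)
}

#' Plug-in deviation from scaling, single gene
#'
#' The Gaussian-approximation plug-in estimate of the extra information that
#' expression carries about absolute position and length beyond scaled
#' position: the bin-averaged `1/2 log2` pooled variance minus the
#' cell-averaged `1/2 log2` length-conditional variance, in bits.
#'
#' @param moments a [conditional_moments()] object.
#' @param gene gene name (required if the moments hold several genes).
#' @param weight_cells `"count"` (default) weights (xs, L) cells by embryo
#'   count; `"equal"` weights retained length bins equally.
#' @return delta-I in bits (plug-in, biased upward at finite sample size).
#' @export
delta_I_single <- function(moments, gene = NULL,
                           weight_cells = c("count", "equal")) {
  weight_cells <- match.arg(weight_cells)
  g <- if (is.null(gene)) {
    if (length(moments$genes) != 1)
      stop("moments hold several genes; name one or use delta_I_multi")
    1L
  } else match(gene, moments$genes)
  if (is.na(g)) stop("unknown gene")
  pooled <- moments$pooled_cov[, g, g]
  cond <- moments$cond_cov[, , g, g, drop = FALSE]
  dim(cond) <- dim(moments$cond_cov)[1:2]
  delta_I_from_terms(pooled, cond, moments, weight_cells, single = TRUE)
}

#' Plug-in deviation from scaling, multiple genes jointly
#'
#' As [delta_I_single()] but with log-determinants of the gene-expression
#' covariance matrices, capturing deviations from scaling visible only in the
#' joint code.
#'
#' @inheritParams delta_I_single
#' @return delta-I in bits.
#' @export
delta_I_multi <- function(moments, weight_cells = c("count", "equal")) {
  weight_cells <- match.arg(weight_cells)
  B <- dim(moments$pooled_cov)[1]
  pooled <- vapply(seq_len(B), function(b) log2det(moments$pooled_cov[b, , ]),
                   numeric(1))
  cond <- matrix(NA_real_, B, moments$n_length_bins)
  for (l in which(moments$retained))
    cond[, l] <- vapply(seq_len(B),
                        function(b) log2det(moments$cond_cov[b, l, , ]),
                        numeric(1))
  delta_I_from_logdets(pooled, cond, moments, weight_cells)
}

delta_I_from_terms <- function(pooled_var, cond_var, moments, weight_cells,
                               single = TRUE) {
  if (any(pooled_var <= 0))
    stop("zero pooled variance in a retained bin; add a noise floor")
  lp <- log2(pooled_var)
  lc <- log2(cond_var)
  if (any(!is.finite(lc[, moments$retained])))
    stop("zero conditional variance in a retained cell; add a noise floor")
  delta_I_from_logdets(lp, lc, moments, weight_cells)
}

delta_I_from_logdets <- function(lp, lc, moments, weight_cells) {
  w <- if (weight_cells == "count") moments$counts else as.numeric(moments$retained)
  w[!moments$retained] <- 0
  w <- w / sum(w)
  cond_term <- as.vector(lc[, moments$retained, drop = FALSE] %*%
                           w[moments$retained])
  mean(lp) / 2 - mean(cond_term) / 2
}

# ---- fast plug-in path -------------------------------------------------------
# Recomputes the plug-in estimate for an embryo subset directly from the
# binned value array; algebraically identical to conditional_moments +
# delta_I_single/multi (asserted in the test suite) but avoids building the
# moment arrays, which matters inside subsample/bootstrap loops.
plugin_delta_I <- function(values, lengths, idx, n_length_bins, min_count,
                           weight_cells = "count") {
  V <- values[idx, , , drop = FALSE]
  n <- length(idx); B <- dim(V)[2]; G <- dim(V)[3]
  lsub <- lengths[idx]
  lb <- adaptive_length_bins(lsub, n_length_bins)
  # the cell-count floor applies to *distinct* embryos: bootstrap resamples
  # carry duplicated rows that add no covariance rank (continuous lengths
  # identify embryos)
  distinct <- vapply(seq_len(n_length_bins),
                     function(l) length(unique(lsub[lb$assignment == l])),
                     numeric(1))
  retained <- lb$counts >= min_count & distinct >= min_count
  if (!any(retained)) stop("no length bin reaches the cell-count floor")
  lp <- logdet_bins(V, seq_len(n))
  lc <- matrix(NA_real_, B, n_length_bins)
  for (l in which(retained)) lc[, l] <- logdet_bins(V, which(lb$assignment == l))
  if (any(!is.finite(lp)) || any(!is.finite(lc[, retained])))
    stop("singular covariance in a retained cell; raise the cell-count floor")
  w <- if (weight_cells == "count") lb$counts else as.numeric(retained)
  w[!retained] <- 0
  w <- w / sum(w)
  mean(lp) / 2 - mean(as.vector(lc[, retained, drop = FALSE] %*% w[retained])) / 2
}

# log2 determinant of the per-bin covariance of V[rows, , ]; B-vector.
logdet_bins <- function(V, rows) {
  m <- length(rows); B <- dim(V)[2]; G <- dim(V)[3]
  Vs <- V[rows, , , drop = FALSE]
  mu <- colMeans(Vs, dims = 1)
  Vc <- Vs - rep(mu, each = m)
  if (G == 1) {
    s <- colSums(Vc[, , 1, drop = FALSE]^2) / (m - 1)
    out <- ifelse(s > 0, log2(s), NA_real_)
    return(as.vector(out))
  }
  S <- array(0, c(B, G, G))
  for (g in seq_len(G)) for (h in g:G) {
    s <- colSums(Vc[, , g, drop = FALSE] * Vc[, , h, drop = FALSE]) / (m - 1)
    S[, g, h] <- s; S[, h, g] <- s
  }
  vapply(seq_len(B), function(b) log2det(S[b, , ]), numeric(1))
}

as_binned <- function(x, dxs = 0.01, xs_range = c(0.1, 0.9)) {
  if (inherits(x, "binned_ensemble")) x else bin_positions(x, dxs, xs_range)
}

#' Plug-in estimates over random embryo subsamples
#'
#' Draws `reps` random subsets (without replacement) at each size in
#' `n_values` and records the plug-in estimate, exposing its `1/N`
#' finite-sample bias for extrapolation.
#'
#' @param x an [embryo_ensemble()] or [bin_positions()] result.
#' @param genes gene subset (default all; a single gene uses the variance
#'   form, several the covariance-determinant form).
#' @param n_values subsample sizes; default `n * c(1, 3/4, 1/2, 1/3, 1/4)`
#'   rounded. Sizes below the cell-count floor are skipped with a warning.
#' @param reps random subsets per size; default 30 (a full-ensemble size is
#'   recorded once, as every draw is identical).
#' @param n_length_bins equal-count length bins; default 5.
#' @param weight_cells see [delta_I_single()].
#' @param min_count cell-count floor; default `max(3, n_genes + 2)`.
#' @param seed integer seed.
#' @return a `data.frame` with columns `n_em`, `rep`, `delta_I`.
#' @export
subsample_curve <- function(x, genes = NULL, n_values = NULL, reps = 30,
                            n_length_bins = 5, weight_cells = "count",
                            min_count = NULL, seed = NULL) {
  binned <- as_binned(x)
  gi <- if (is.null(genes)) seq_along(binned$genes) else match(genes, binned$genes)
  if (anyNA(gi)) stop("unknown gene(s)")
  V <- binned$values[, , gi, drop = FALSE]
  n <- dim(V)[1]; G <- length(gi)
  if (is.null(min_count)) min_count <- max(3, G + 2)
  if (is.null(n_values)) n_values <- unique(round(n * c(1, 3/4, 1/2, 1/3, 1/4)))
  if (max(n_values) > n) stop("subsample size exceeds the ensemble")
  if (reps < 1) stop("reps must be >= 1")
  floor_n <- n_length_bins * min_count
  ok <- n_values >= floor_n
  if (!all(ok)) {
    warning("skipping subsample sizes below the cell-count floor: ",
            paste(n_values[!ok], collapse = ", "))
    n_values <- n_values[ok]
  }
  rows <- list()
  with_seed(seed, {
    for (nv in sort(n_values, decreasing = TRUE)) {
      r_here <- if (nv == n) 1L else reps
      for (r in seq_len(r_here)) {
        idx <- if (nv == n) seq_len(n) else sample.int(n, nv)
        di <- plugin_delta_I(V, binned$lengths, idx, n_length_bins, min_count,
                             weight_cells)
        rows[[length(rows) + 1L]] <- data.frame(n_em = nv, rep = r, delta_I = di)
      }
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- n
  out
}

#' Extrapolate the plug-in estimate to infinite sample size
#'
#' Fits a straight line (weighted least squares) of the mean plug-in estimate
#' against `1/N`, with weights given by the inverse variance of the per-size
#' mean across replicates; the intercept is the bias-corrected estimate.
#' Sizes with zero across-replicate variance (the full-ensemble point, whose
#' single draw is exact) receive the largest finite weight.
#'
#' @param curve a [subsample_curve()] table (>= 3 distinct sizes).
#' @return a list: `delta_I` (intercept, bits), `se_fit` (WLS standard error
#'   of the intercept), `slope`, `means` (per-size summary), `fit` (the `lm`).
#' @export
extrapolate_infinite_N <- function(curve) {
  agg <- do.call(rbind, lapply(split(curve, curve$n_em), function(d) {
    data.frame(n_em = d$n_em[1], mean = mean(d$delta_I),
               var = if (nrow(d) > 1) var(d$delta_I) else NA_real_,
               reps = nrow(d))
  }))
  if (nrow(agg) < 3) stop("need >= 3 distinct subsample sizes to extrapolate")
  w <- agg$reps / agg$var
  if (all(!is.finite(w))) w <- rep(1, nrow(agg))
  w[!is.finite(w) | w <= 0] <- max(w[is.finite(w) & w > 0])
  agg$inv_n <- 1 / agg$n_em
  fit <- lm(mean ~ inv_n, data = agg, weights = w)
  cf <- summary(fit)$coefficients
  list(delta_I = cf[1, 1], se_fit = cf[1, 2], slope = cf[2, 1],
       means = agg[order(agg$n_em), ], fit = fit)
}

#' Shuffle control: permute embryo lengths
#'
#' Randomly permutes the length labels across embryos, leaving the profiles
#' (as functions of scaled position) untouched. By construction expression is
#' then independent of length given scaled position, so the true deviation
#' from scaling is exactly zero — the calibration null for the estimator.
#'
#' @param x an [embryo_ensemble()] or `binned_ensemble`.
#' @param seed integer seed.
#' @return an object of the same class with permuted lengths.
#' @export
shuffle_control <- function(x, seed = NULL) {
  perm <- with_seed(seed, sample.int(length(x$lengths)))
  x$lengths <- x$lengths[perm]
  x
}

#' Full deviation-from-scaling estimate with extrapolation and bootstrap error
#'
#' The complete estimator: bin the profiles, compute the subsample curve,
#' extrapolate `1/N -> 0`, and (optionally) obtain the error bar as the SD of
#' the extrapolated value over bootstrap resamplings of embryos.
#'
#' @inheritParams subsample_curve
#' @param x an [embryo_ensemble()] or `binned_ensemble`.
#' @param dxs,xs_range binning, used when `x` is an unbinned ensemble.
#' @param subsample_fracs fractions of the ensemble used as subsample sizes.
#' @param n_boot bootstrap resamplings for the error bar (default 200);
#'   `0` falls back to the WLS fit SE.
#' @return an object of class `delta_I_estimate`: list with `delta_I` (bits),
#'   `error` (bits), `plugin` (full-sample plug-in), `curve`, `means`,
#'   `boot` (bootstrap intercepts), and the settings used.
#' @export
estimate_delta_I <- function(x, genes = NULL, dxs = 0.01,
                             xs_range = c(0.1, 0.9), n_length_bins = 5,
                             subsample_fracs = c(1, 3/4, 1/2, 1/3, 1/4),
                             reps = 30, n_boot = 200, weight_cells = "count",
                             min_count = NULL, seed = NULL) {
  binned <- as_binned(x, dxs, xs_range)
  gi <- if (is.null(genes)) seq_along(binned$genes) else match(genes, binned$genes)
  if (anyNA(gi)) stop("unknown gene(s)")
  genes <- binned$genes[gi]
  n <- length(binned$lengths)
  G <- length(gi)
  if (is.null(min_count)) min_count <- max(3, G + 2)
  n_values <- unique(round(n * subsample_fracs))
  seeds <- spawn_seeds(seed, 1L + n_boot)
  curve <- subsample_curve(binned, genes = genes, n_values = n_values,
                           reps = reps, n_length_bins = n_length_bins,
                           weight_cells = weight_cells, min_count = min_count,
                           seed = seeds[1])
  ext <- extrapolate_infinite_N(curve)
  V <- binned$values[, , gi, drop = FALSE]
  plugin <- plugin_delta_I(V, binned$lengths, seq_len(n), n_length_bins,
                           min_count, weight_cells)
  boot <- NULL
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(r) {
      bseeds <- spawn_seeds(seeds[1L + r], 2L)
      idx <- with_seed(bseeds[1], sample.int(n, n, replace = TRUE))
      bb <- binned
      bb$values <- binned$values[idx, , , drop = FALSE]
      bb$lengths <- binned$lengths[idx]
      bb$times <- binned$times[idx]
      cv <- subsample_curve(bb, genes = genes, n_values = n_values,
                            reps = reps, n_length_bins = n_length_bins,
                            weight_cells = weight_cells, min_count = min_count,
                            seed = bseeds[2])
      extrapolate_infinite_N(cv)$delta_I
    }, numeric(1))
  }
  structure(list(delta_I = ext$delta_I,
                 error = if (n_boot > 0) sd(boot) else ext$se_fit,
                 se_fit = ext$se_fit, plugin = plugin, slope = ext$slope,
                 curve = curve, means = ext$means, boot = boot,
                 settings = list(genes = genes, dxs = binned$dxs,
                                 xs_range = binned$xs_range,
                                 n_length_bins = n_length_bins,
                                 reps = reps, n_boot = n_boot,
                                 min_count = min_count,
                                 weight_cells = weight_cells, n = n,
                                 seed = seed)),
            class = "delta_I_estimate")
}

#' @export
print.delta_I_estimate <- function(x, ...) {
  cat(sprintf("deviation from scaling (delta-I): %.4f +/- %.4f bits\n",
              x$delta_I, x$error))
  cat(sprintf("  plug-in at n = %d: %.4f bits; genes: %s; %d length bins\n",
              x$settings$n, x$plugin, paste(x$settings$genes, collapse = ", "),
              x$settings$n_length_bins))
  invisible(x)
}

#' Shuffle-null distribution of the extrapolated estimator
#'
#' Runs the subsample + extrapolation estimator on repeated length shuffles of
#' the same ensemble. The true value is zero for every shuffle, so the spread
#' of the returned values calibrates the estimator's error bar and their mean
#' checks it for bias.
#'
#' @inheritParams estimate_delta_I
#' @param n_shuffles number of independent length permutations; default 20.
#' @return numeric vector of extrapolated values (bits), one per shuffle.
#' @export
delta_I_shuffle_null <- function(x, genes = NULL, n_shuffles = 20, dxs = 0.01,
                                 xs_range = c(0.1, 0.9), n_length_bins = 5,
                                 subsample_fracs = c(1, 3/4, 1/2, 1/3, 1/4),
                                 reps = 30, weight_cells = "count",
                                 min_count = NULL, seed = NULL) {
  binned <- as_binned(x, dxs, xs_range)
  seeds <- spawn_seeds(seed, 2L * n_shuffles)
  vapply(seq_len(n_shuffles), function(s) {
    sh <- shuffle_control(binned, seed = seeds[2 * s - 1])
    est <- estimate_delta_I(sh, genes = genes, n_length_bins = n_length_bins,
                            subsample_fracs = subsample_fracs, reps = reps,
                            n_boot = 0, weight_cells = weight_cells,
                            min_count = min_count, seed = seeds[2 * s])
    est$delta_I
  }, numeric(1))
}

#' Positional information carried about scaled position
#'
#' Gaussian-approximation mutual information between the (multi-gene)
#' expression vector and the scaled-position bin: the entropy of the marginal
#' expression distribution (an equal-weight mixture of the per-bin Gaussians,
#' integrated by Monte Carlo) minus the average Gaussian conditional entropy.
#' This is the denominator for expressing the deviation from scaling as a
#' fraction of the total information.
#'
#' @inheritParams estimate_delta_I
#' @param n_mc Monte Carlo samples for the mixture entropy; default 20000.
#' @return a list: `I` (bits), `se` (Monte Carlo standard error, bits),
#'   `H_marginal`, `H_conditional`.
#' @export
positional_information <- function(x, genes = NULL, dxs = 0.01,
                                   xs_range = c(0.1, 0.9), n_mc = 20000,
                                   seed = NULL) {
  binned <- as_binned(x, dxs, xs_range)
  gi <- if (is.null(genes)) seq_along(binned$genes) else match(genes, binned$genes)
  if (anyNA(gi)) stop("unknown gene(s)")
  V <- binned$values[, , gi, drop = FALSE]
  n <- dim(V)[1]; B <- dim(V)[2]; G <- dim(V)[3]
  mu <- colMeans(V, dims = 1)                     # B x G
  chols <- vector("list", B)
  h_cond <- numeric(B)
  for (b in seq_len(B)) {
    S <- cov(matrix(V[, b, ], n, G))
    R <- tryCatch(chol(S), error = function(e)
      stop("singular covariance in bin ", b, "; add a noise floor"))
    chols[[b]] <- R
    h_cond[b] <- (G * log2(2 * pi * exp(1)) + 2 * sum(log2(diag(R)))) / 2
  }
  with_seed(seed, {
    comp <- sample.int(B, n_mc, replace = TRUE)
    Z <- matrix(rnorm(n_mc * G), n_mc, G)
    X <- matrix(0, n_mc, G)
    for (b in seq_len(B)) {
      rows <- which(comp == b)
      if (length(rows))
        X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[b]] +
          rep(mu[b, ], each = length(rows))
    }
    # mixture log-density at the samples
    logp <- matrix(0, n_mc, B)
    for (b in seq_len(B)) {
      R <- chols[[b]]
      D <- sweep(X, 2, mu[b, ])
      Zb <- D %*% backsolve(R, diag(G))
      logp[, b] <- -0.5 * rowSums(Zb^2) - sum(log(diag(R))) -
        G / 2 * log(2 * pi)
    }
    mx <- apply(logp, 1, max)
    lp <- (mx + log(rowMeans(exp(logp - mx)))) / log(2)
    H_marg <- -mean(lp)
    se <- sd(lp) / sqrt(n_mc)
    list(I = H_marg - mean(h_cond), se = se,
         H_marginal = H_marg, H_conditional = mean(h_cond))
  })
}
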