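test_that("position binning has exact arithmetic on the default grid", {
  fam <- make_gap_like_family(1)
  ens <- generate_ensemble(fam, c(490, 500), times = c(45, 45), noise_sd = 0,
                           seed = 1)
  b <- bin_positions(ens, dxs = 0.01, xs_range = c(0, 1))
  expect_equal(length(b$centers), 100)

  # constant profile: every bin equals the constant
  cens <- embryo_ensemble(ens$xs, c(490, 500), c(45, 45), "g",
                          array(0.37, c(2, 1000, 1)))
  cb <- bin_positions(cens, xs_range = c(0, 1))
  expect_true(all(abs(cb$values - 0.37) < 1e-12))

  # linear profile: bin value equals bin midpoint within half a grid step
  lens <- embryo_ensemble(ens$xs, c(490, 500), c(45, 45), "g",
                          array(rep(ens$xs, each = 2), c(2, 1000, 1)))
  lb <- bin_positions(lens, xs_range = c(0, 1))
  expect_true(all(abs(lb$values[1, , 1] - lb$centers) < 0.5 / 1000))

  # grid coarser than the bin width is rejected
  coarse <- embryo_ensemble((1:20 - 0.5) / 20, c(490, 500), c(45, 45), "g",
                            array(0.5, c(2, 20, 1)))
  expect_error(bin_positions(coarse, dxs = 0.01), "grid")
})

test_that("adaptive length bins are equal-count", {
  L <- draw_lengths(301, length_model(), seed = 2)
  lb <- adaptive_length_bins(L, 5)
  expect_equal(sort(lb$counts, decreasing = TRUE), c(61, 60, 60, 60, 60))
  expect_equal(length(lb$edges), 6)
  # bins respect length order
  expect_true(all(diff(tapply(L, lb$assignment, mean)) > 0))

  lb2 <- adaptive_length_bins(draw_lengths(20, seed = 3), 4)
  expect_equal(lb2$counts, rep(5, 4))

  expect_error(adaptive_length_bins(rep(490, 10), 5), "identical")
})

test_that("conditional moments match generator ground truth and total variance", {
  b <- gap_binned()
  mom <- conditional_moments(b, n_length_bins = 5)
  # homoskedastic grid noise 0.05 averaged 10x per bin -> cell variances ~ 2.5e-4
  cellvar <- mom$cond_cov[, , 1, 1]
  expect_equal(median(cellvar, na.rm = TRUE), 0.05^2 / 10, tolerance = 0.15)

  # law of total variance, per gene and bin: pooled >= count-weighted conditional
  w <- mom$counts / sum(mom$counts)
  for (g in 1:4) {
    pooled <- mom$pooled_cov[, g, g]
    condm <- mom$cond_cov[, , g, g] %*% w
    expect_true(all(pooled >= condm * (1 - 0.05)))
  }

  # noiseless non-scaling profiles: conditional variance collapses, pooled does not
  fam <- make_exponential_family(lambda = 100, noise_sd = 1e-4)
  ens <- generate_ensemble(fam, draw_lengths(300, length_model(490, 0.04),
                                             seed = 4), seed = 5)
  momx <- conditional_moments(bin_positions(ens), n_length_bins = 5)
  mid <- which.min(abs(momx$centers - 0.25))
  pooled_mid <- momx$pooled_cov[mid, 1, 1]
  cond_mid <- mean(momx$cond_cov[mid, , 1, 1], na.rm = TRUE)
  expect_gt(pooled_mid / cond_mid, 10)
})

test_that("fast plug-in path agrees exactly with the moment-object path", {
  b <- gap_binned()
  mom <- conditional_moments(b, n_length_bins = 5)
  slow_multi <- delta_I_multi(mom)
  slow_single <- delta_I_single(mom, gene = "hb")
  fast_multi <- embryoscale:::plugin_delta_I(b$values, b$lengths,
                                             seq_along(b$lengths), 5, 6)
  Vh <- b$values[, , 1, drop = FALSE]
  fast_single <- embryoscale:::plugin_delta_I(Vh, b$lengths,
                                              seq_along(b$lengths), 5, 3)
  expect_equal(fast_multi, slow_multi, tolerance = 1e-12)
  expect_equal(fast_single, slow_single, tolerance = 1e-12)
  # plug-in is non-negative (Jensen / law of total variance)
  expect_gte(fast_multi, 0)
  expect_gte(fast_single, 0)
})

test_that("multi-gene delta-I factorizes over independent genes and is invariant", {
  # hand-built diagonal moments: determinant factorizes exactly
  B <- 10; G <- 3; nl <- 4
  mom <- structure(list(
    pooled_cov = array(0, c(B, G, G)),
    cond_cov = array(0, c(B, nl, G, G)),
    counts = rep(25, nl), retained = rep(TRUE, nl), n = 100,
    centers = seq(0.1, 0.9, length.out = B), genes = c("a", "b", "c"),
    min_count = 5, n_length_bins = nl), class = "conditional_moments")
  set.seed(6)
  for (g in 1:G) {
    mom$pooled_cov[, g, g] <- runif(B, 0.01, 0.02)
    for (l in 1:nl) mom$cond_cov[, l, g, g] <- runif(B, 0.002, 0.01)
  }
  total <- delta_I_multi(mom)
  per_gene <- sapply(c("a", "b", "c"), function(g) delta_I_single(mom, gene = g))
  expect_equal(total, sum(per_gene), tolerance = 1e-12)

  # a single gene: multi and single estimators coincide exactly
  b <- gap_binned()
  mh <- conditional_moments(b, genes = "hb", n_length_bins = 5)
  expect_equal(delta_I_multi(mh), delta_I_single(mh), tolerance = 1e-12)

  # affine per-gene rescaling and invertible mixing leave delta-I unchanged
  base <- embryoscale:::plugin_delta_I(b$values, b$lengths,
                                       seq_along(b$lengths), 5, 6)
  aff <- b
  scale <- c(2, 0.5, 3, 1.5); shift <- c(0.1, -0.2, 0, 5)
  for (g in 1:4) aff$values[, , g] <- scale[g] * b$values[, , g] + shift[g]
  expect_equal(embryoscale:::plugin_delta_I(aff$values, b$lengths,
                                            seq_along(b$lengths), 5, 6),
               base, tolerance = 1e-9)
  set.seed(7)
  M <- matrix(rnorm(16), 4, 4)
  mixed <- b
  n <- dim(b$values)[1]; nb <- dim(b$values)[2]
  flat <- matrix(b$values, n * nb, 4) %*% t(M)
  mixed$values <- array(flat, c(n, nb, 4))
  expect_equal(embryoscale:::plugin_delta_I(mixed$values, b$lengths,
                                            seq_along(b$lengths), 5, 6),
               base, tolerance = 1e-8)
})

test_that("subsample curve exposes the 1/N bias and extrapolation removes it", {
  b <- gap_binned()
  sh <- shuffle_control(b, seed = 8)
  curve <- subsample_curve(sh, genes = "hb", reps = 20, seed = 9)
  agg <- aggregate(delta_I ~ n_em, curve, mean)
  # plug-in bias increases monotonically in 1/N on shuffled data
  expect_true(all(diff(agg$delta_I[order(1 / agg$n_em)]) > 0))
  # and is linear in 1/N: R^2 > 0.9
  fit <- lm(delta_I ~ I(1 / n_em), data = agg)
  expect_gt(summary(fit)$r.squared, 0.9)

  # full-size draw reproduces the plug-in exactly
  full <- subsample_curve(b, genes = "hb", n_values = c(301, 225, 150),
                          reps = 3, seed = 10)
  plug <- embryoscale:::plugin_delta_I(b$values[, , 1, drop = FALSE],
                                       b$lengths, 1:301, 5, 3)
  expect_equal(unique(full$delta_I[full$n_em == 301]), plug, tolerance = 1e-12)

  # an exactly linear curve extrapolates to its intercept at machine precision
  toy <- expand.grid(n_em = c(100, 200, 300), rep = 1:3)
  toy$delta_I <- 0.123 + 4.5 / toy$n_em
  ext <- suppressWarnings(extrapolate_infinite_N(toy))  # exact fit by design
  expect_equal(ext$delta_I, 0.123, tolerance = 1e-10)
  expect_error(extrapolate_infinite_N(toy[toy$n_em < 150, ]), ">= 3")
})

test_that("shuffling permutes lengths only and delta-I machinery sees a null", {
  ens <- gap_ensemble()
  sh <- shuffle_control(ens, seed = 11)
  expect_identical(sh$profiles, ens$profiles)
  expect_identical(sort(sh$lengths), sort(ens$lengths))
  expect_false(identical(sh$lengths, ens$lengths))
  expect_identical(shuffle_control(ens, seed = 11)$lengths, sh$lengths)
})

test_that("identical profiles across lengths give a null deviation from scaling", {
  # scaled ensemble with pure noise: the estimator extrapolates to ~ 0
  b <- gap_binned()
  est <- estimate_delta_I(b, genes = "hb", n_boot = 50, seed = 12)
  expect_lt(abs(est$delta_I), 2.5 * est$error)
  # the plug-in itself is positive (finite-sample bias)
  expect_gt(est$plugin, 0)
})

test_that("deviation estimates agree across length-bin counts (single gene)", {
  b <- gap_binned()
  # the subsample schedule keeps >= 9 embryos per (xs, L) cell even at 20
  # length bins; deeper subsampling would push high-bin-count variants into
  # the regime where the plug-in bias is no longer linear in 1/N
  ests <- lapply(c(5, 10, 15, 20), function(nb)
    estimate_delta_I(b, genes = "hb", n_length_bins = nb, n_boot = 40,
                     subsample_fracs = c(1, 0.9, 0.8, 0.7, 0.6), seed = 13))
  for (i in 1:3) for (j in (i + 1):4) {
    d <- abs(ests[[i]]$delta_I - ests[[j]]$delta_I)
    expect_lt(d, 2 * sqrt(ests[[i]]$error^2 + ests[[j]]$error^2))
  }
})

test_that("positional information matches a quadrature oracle and saturates", {
  # two bins, equal variance, mean separation: 1-D quadrature oracle
  n <- 4000; sigma <- 0.05; delta <- 0.12
  xs <- (1:2 - 0.5) / 2
  vals <- array(0, c(n, 2, 1))
  set.seed(14)
  vals[, 1, 1] <- rnorm(n, 0.4, sigma)
  vals[, 2, 1] <- rnorm(n, 0.4 + delta, sigma)
  b <- structure(list(values = vals, centers = c(0.25, 0.75),
                      lengths = rep(490, n), times = rep(45, n), genes = "g",
                      dxs = 0.5, xs_range = c(0, 1)), class = "binned_ensemble")
  est <- positional_information(b, n_mc = 40000, seed = 15)
  # oracle: I = H[mixture] - H[gaussian], mixture entropy by quadrature
  mix <- function(x) 0.5 * dnorm(x, 0.4, sigma) + 0.5 * dnorm(x, 0.4 + delta, sigma)
  Hm <- integrate(function(x) {
    d <- mix(x); ifelse(d > 0, -d * log2(d), 0)
  }, 0.4 - 8 * sigma, 0.4 + delta + 8 * sigma)$value
  I_true <- Hm - 0.5 * log2(2 * pi * exp(1) * sigma^2)
  expect_lt(abs(est$I - I_true), 4 * est$se + 0.01)

  # far-separated bins: information saturates at log2(number of bins)
  vals2 <- vals
  vals2[, 2, 1] <- rnorm(n, 5, sigma)
  b2 <- b; b2$values <- vals2
  est2 <- positional_information(b2, n_mc = 20000, seed = 16)
  expect_equal(est2$I, 1, tolerance = 0.01)

  # the scaled 4-gene ensemble carries a few bits about scaled position and
  # the deviation from scaling is a tiny fraction of it
  pi4 <- positional_information(gap_binned(), n_mc = 20000, seed = 17)
  expect_gt(pi4$I, 3)
  est4 <- estimate_delta_I(gap_binned(), n_boot = 0, seed = 18)
  expect_lt(abs(est4$delta_I) / pi4$I, 0.02)
})
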