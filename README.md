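# embryoscale

Tools for testing whether one-dimensional morphogen expression patterns are
*scale invariant* — whether expression depends on position only through the
fraction `xs = x/L` of embryo length. The question matters because embryos of
one species vary in length by several percent while pattern elements sit at
fractional positions reproducible to ~1%; deciding between "patterns scale"
and "patterns are anchored in absolute coordinates" requires both precise
statistics and the right null models.

The package is aimed at quantitative developmental biologists and biophysicists
analyzing ensembles of expression profiles (one concentration vector per gene
per embryo, plus the embryo's length and age). It provides four connected
analyses:

* **Discrete positional markers** — stripe-peak and half-maximum-boundary
  extraction with sub-grid refinement, linear time-drift correction to a
  reference age `t0`, and position-versus-length regression with bootstrap
  errors. Scale invariance predicts `x_i = f_i * L` (slope = mean fractional
  position, zero intercept); pole anchoring predicts the reverse.
* **Anchoring precision bounds** — the closed-form null for mechanisms without
  length sensitivity: a marker anchored to the anterior pole has scaled-position
  SD `f * cv` (with `cv = sigma_L / <L>`), a posterior-anchored one
  `(1 - f) * cv`, and the optimal combination
  `1/sigma^2 = 1/sigma_A^2 + 1/sigma_P^2`, which peaks at `cv / (2 sqrt 2)`
  (~1.4% for `cv = 0.04`). Measured markers *below* this curve rule out
  anchoring.
* **Information decomposition** — the package's central statistic. The
  positional information splits as `I(g; {x, L}) = I(g; x/L) + delta_I`, and
  `delta_I = 0` exactly under scaling. In the Gaussian approximation,

  `delta_I = < ½ log2 sigma²(g|xs) >  −  < ½ log2 sigma²(g|xs, L) >`

  (covariance determinants in the joint multi-gene version), estimated with
  0.01-wide position bins, equal-count length bins, subsampling plus linear
  `1/N` extrapolation of the finite-sample bias, bootstrap error bars, and a
  length-shuffle null in which the true value is zero by construction.
* **Zero-mode analysis** — if a reaction-diffusion gene network
  `dg_i/dt = lambda_i² g_i'' + F_i(g) − g_i` has exactly scaling steady states,
  the profile `psi_i = −xs Phi_i'(xs)` must be a zero eigenmode of the
  linearized dynamics (a line attractor indexed by length). The module builds
  the discretized linear operator, computes its spectrum, flags zero modes,
  and verifies their signatures (conserved amplitude, `1/lambda` fluctuation
  scaling, linear-in-time variance growth along the flat direction).

A synthetic-embryo generator supplies ensembles with controlled ground truth
(exactly scaled, pole-anchored, or exponential with a fixed micron decay
length — the maternal-input case), so the entire pipeline is testable without
any external data.

## Worked example

```r
library(embryoscale)

fam <- make_gap_like_family(4)                        # Hb/Kr/Kni/Gt-like shapes
lengths <- draw_lengths(301, length_model(490, 0.037), seed = 11)
ens <- generate_ensemble(fam, lengths, noise_sd = 0.05, seed = 12)

## markers: do boundary positions scale with L?
mk <- detect_half_max_boundaries(ens, "hb")
fit_all_markers(mk, seed = 1)
#>      marker_id  slope slope_sd intercept_um intercept_sd f_mean   sigma_f ...
#> 1 hb_falling_1 0.4506 0.001522      -0.3299       0.7446 0.4500 0.0009417
#> 2 hb_falling_3 0.8855 0.001782      -0.4475       0.8696 0.8845 0.0011200
#> 3  hb_rising_2 0.7848 0.001496       0.2985       0.7358 0.7854 0.0010750
# slopes equal the mean fractional positions and intercepts are zero within
# ~2 bootstrap SDs: the scaled-mode ground truth is recovered, and every
# sigma_f is far below the 1.4% anchoring ceiling.

## information: how many bits about absolute position beyond scaled position?
est <- estimate_delta_I(ens, genes = "hb", seed = 2)
est
#> deviation from scaling (delta-I): -0.0012 +/- 0.0028 bits
#>   plug-in at n = 301: 0.0097 bits; genes: hb; 5 length bins
# consistent with zero: the plug-in 0.01 bits is pure finite-sample bias,
# removed by the 1/N extrapolation.

## null calibration: shuffling lengths forces the true value to zero
nulls <- delta_I_shuffle_null(ens, genes = "hb", seed = 3)
round(c(mean = mean(nulls), sd = sd(nulls)), 4)
#>    mean      sd
#> -0.0011  0.0013

## the anchoring null these precisions must beat
max(bound_curve(cv = 0.04)$sd_combined)
#> [1] 0.01414214

## zero mode: spectrum of the diffusion-decay operator
md <- eigenmodes(dd_operator(lambda = 40, L = 500, n_grid = 500))
round(head(md$values, 3), 4)
#> [1] 1.0000 1.0632 1.2527   # 1 + lambda^2 (mu pi / L)^2
```

A non-scaling input is detected the same way: an exponential profile with a
fixed 100-um decay length over the same length distribution gives
`delta_I = 0.18 ± 0.01` bits — tens of error bars from zero — while its
profiles overlay perfectly in absolute coordinates.

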