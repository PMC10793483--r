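---
title: "Testing scale invariance of morphogen patterns: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing scale invariance of morphogen patterns: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoscale)
```

## The scientific question

In early fly embryos, the concentration profiles of a handful of morphogens —
maternal inputs, the gap genes, the pair-rule genes — determine cell fates
along the anterior-posterior axis. Embryos from a single laboratory stock vary
in length `L` by about 4% (SD), yet pattern elements (stripe peaks, expression
boundaries) sit at reproducible *fractional* positions. *Scale invariance* is
the strong statement that expression depends only on scaled position
`xs = x/L`:

```
g_i(x; L) = Phi_i(x / L)
```

This package implements three complementary ways to test that statement and
one consequence of it:

1. **Discrete markers.** Peaks and half-maximum boundaries are extracted per
   embryo; absolute position is regressed on length. Scaling predicts slope =
   mean fractional position and intercept = 0.
2. **Anchoring bounds.** Closed-form null curves for how precise a
   non-scaling, pole-anchored mechanism can be: `sigma_f = f * cv` (anterior),
   `(1 - f) * cv` (posterior), and their inverse-variance combination, which
   peaks at `cv / (2 * sqrt(2))` — about 1.4% at `cv = 0.04`. Markers more
   precise than the combined curve cannot be explained without explicit
   length sensitivity.
3. **Information decomposition.** The mutual information between expression
   and `(x, L)` splits as `I(g; {x, L}) = I(g; x/L) + delta_I`. Under perfect
   scaling `delta_I = 0`; `delta_I > 0` measures information about absolute
   position/length. In the Gaussian approximation, `delta_I` reduces to
   averaged log-ratios of pooled to length-conditional variances (single
   gene) or covariance determinants (multi-gene).
4. **Zero mode.** If the steady-state pattern of a reaction-diffusion gene
   network scales exactly, then the profile `psi_i(xs) = -xs * Phi_i'(xs)`
   must be annihilated by the linearized dynamics operator — the network must
   have a *zero mode*, i.e. a line attractor of patterns indexed by length.

No real embryo data ship with the package; a synthetic-embryo generator
provides ensembles with controlled ground truth (exactly scaled, pole-anchored,
or exponential with a fixed decay length) so every stage is testable.

## The synthetic-embryo generator

`generate_ensemble()` evaluates a `profile_family()` on a fixed grid of 1000
cell-centered scaled positions `xs_j = (j - 1/2)/1000` and adds independent
Gaussian noise per grid point, clipped at zero. The cell-centered grid is
chosen so that the information pipeline's 0.01-wide position bins contain
exactly 10 grid samples each; clipping is a mild non-Gaussianity that only
matters where the mean is within ~2 SD of zero.

Default study conditions mirror the measured regime for this system:

| parameter | default | meaning |
|---|---|---|
| `mean_length` | 490 um | mean embryo length (live) |
| `cv` | 0.037 | relative length SD (0.038 fixed, 0.037 live) |
| `n_embryos` | 301 | joint 4-gene ensemble size |
| `noise_sd` | 0.05 | expression noise, units of unit maximum |
| times | uniform on [30, 60] min | measurement window |
| `t0` | 45 min | reference time for drift correction |
| `lambda` | 100 um | decay length of the exponential (maternal-like) mode |

The expression-noise magnitude and its spatial correlation are *not*
published quantities; 0.05 of unit maximum with independent noise per grid
point is this package's convention (the order of magnitude of the shaded
SD bands in published profile figures). Because noise is independent across
grid points, averaging into 0.01 bins reduces its variance tenfold; real
imaging noise is correlated on the nuclear scale and averages down less. This
is the main respect in which passing tests here do not certify behavior on
real data: synthetic ensembles are *cleaner* than real ones at the same
nominal noise level.

The four-gene default family reproduces the canonical trunk layout (an
anterior domain with a posterior boundary near 0.45 plus a small posterior
domain; a central domain; a two-domain gene; an abdominal domain with a small
anterior element), giving 13 half-maximum boundaries in total — matching the
number of gap-gene boundaries tracked in the motivating measurements. The
pair-rule-like family has 7 Gaussian stripes between `xs` 0.30 and 0.79 whose
positions drift linearly in time at rates of order 10^-3 per minute (faster
posteriorly), the regime reported for stripe dynamics.

Anchored modes evaluate the same shapes as fixed functions of absolute
distance from one pole (interpreted via a 490-um reference length); the
exponential mode is `g(x) = exp(-x / lambda)` with `lambda` fixed in microns.

## Marker conventions

* Peaks: local maxima with topographic prominence at least 0.1 of the profile
  maximum, refined by the vertex of a parabola through the peak sample and
  its neighbours (which also breaks flat-top ties at the midpoint).
* Boundaries: threshold = half the maximum of the *ensemble-mean* profile;
  per-embryo crossings are localized by linear interpolation and matched to
  the mean profile's crossings within 0.05 in `xs`; unmatched boundaries are
  recorded as missing for that embryo. The matching window is this package's
  convention — noisy profiles can create extra crossings and the source
  measurements do not state how they were resolved.
* Drift correction: per-marker pooled OLS of scaled position on `t - t0`,
  then `f -> f - s_i (t - t0)`; corrected tables carry `t_min = t0`, making
  the correction idempotent.
* Scaling fits: OLS of absolute position on length; errors for slope,
  intercept and `sigma_f` from bootstrap over embryos (default 1000
  replicates).

## The delta-I estimator

The pipeline is: bin positions (`dxs = 0.01`, default range `xs` in
[0.1, 0.9] because pole regions are unreliable in real data), form
equal-count length bins (default 5), compute pooled and length-conditional
sample moments with `n - 1` denominators, and take

```
delta_I = < 1/2 log2 var(g | xs) >_xs  -  < 1/2 log2 var(g | xs, L) >_xs,L
```

with log-determinants of 4x4 covariance matrices in the joint-gene version.
Cells are weighted by embryo count (an equal-weight option exists; the
source does not state which was used). Cells with fewer embryos than
`max(3, n_genes + 2)` are dropped and the remaining weights renormalized —
sample covariances need more observations than dimensions.

The plug-in estimate is biased upward at finite `N` (log of a noisy variance),
with a leading `1/N` term. The estimator therefore records plug-in values on
random subsamples (default sizes `N * {1, 3/4, 1/2, 1/3, 1/4}`, 30 draws
without replacement each) and extrapolates the per-size means linearly in
`1/N` by weighted least squares, weights = inverse variance of each mean. The
full-ensemble point has zero across-draw variance (every draw is identical)
and receives the largest finite weight. The quoted error is the SD of the
extrapolated value over 200 bootstrap resamplings of embryos (`n_boot = 0`
falls back to the WLS intercept SE).

### Calibration and its limits

Shuffling length labels makes expression independent of length given `xs`,
so the true `delta_I` is exactly zero. On the default scaled-mode ensemble
(n = 301), the single-gene estimator's shuffle null is clean: mean within
about 0.001 bits of zero, well inside the quoted per-run error. Two caveats
discovered while validating, both documented rather than hidden:

* **Multi-gene second-order bias.** For the 4-gene determinant version the
  plug-in bias has a noticeable `1/N^2` component (second-order terms of the
  log-determinant of a Wishart matrix; conditional cells hold only N/5
  embryos). A straight line in `1/N` fitted down to quarter-size subsamples
  then undershoots the intercept by about 0.02 bits at these problem sizes.
  This is visible as a small negative offset in the multi-gene extrapolation,
  inside its ~0.015-bit bootstrap error bar but systematic across shuffles.
  The linear-only extrapolation is retained deliberately: it matches the
  stated leading-order theory, and the headline single-gene analysis is
  unaffected.
* **Cell occupancy governs validity.** The linear-in-`1/N` bias model holds
  while every (position, length) cell keeps roughly ten or more embryos.
  Results are stable across 5-20 length bins provided the subsample schedule
  respects that occupancy (e.g. sizes down to 0.6 N at 20 bins); subsampling
  a 20-bin analysis down to N/4 leaves fewer than 4 embryos per cell and the
  extrapolation drifts. Bootstrap resamples apply the cell-count floor to
  *distinct* embryos, since duplicated rows add no covariance rank.
* **Shuffle spread vs bootstrap error.** Permutations of one dataset share
  all its expression noise, so the SD across shuffles is smaller than the
  bootstrap error bar, which emulates dataset-level resampling. The quoted
  bar is therefore conservative with respect to the permutation null on
  synthetic data.

The `gaussian_toy_ensemble()` calibration construction makes the target value
exact: embryos get an expression offset that is a *step function of their
equal-count length-bin index*, so conditioning on the bin removes it exactly
and `delta_I* = 1/2 log2(1 + c^2 / sigma0^2)` in closed form. The toy is
generated with one grid sample per analysis bin so that `sigma0` refers to
the variable the estimator actually sees (a finer grid would be averaged down
by the binning and inflate the realized value). The estimator recovers
`delta_I*` in {0, 0.05, 0.1, 0.3} bits within its errors.

`positional_information()` supplies the denominator for expressing the
deviation as a fraction of the total: conditional entropies are Gaussian,
and the marginal entropy of the equal-weight mixture of bin Gaussians is
integrated by Monte Carlo (default 20,000 samples, with the MC standard
error reported).

## Zero-mode analysis

The dynamics module works in normalized units (lifetimes `tau = 1`, maximum
steady-state concentration 1), so the only per-gene parameter with units is
the length scale `lambda_i = sqrt(D_i tau)` in microns. Discretization is a
uniform node-at-boundary grid with second-order central differences; no-flux
boundaries are closed with mirror ghost nodes (which conserves the trapezoid
mass integral exactly for pure diffusion), and a constant anterior influx `T`
enters the boundary node as a source `2T/h`. Steady states are found by
relaxation followed by Newton polishing to residual 1e-8; the linearized
operator is the dense `n_genes * n_grid` matrix with the regulation Jacobian
evaluated pointwise at the steady profiles.

Eigenvalues are reported as relaxation rates (`A phi = -lambda_mu phi`);
`|lambda_mu| < 1e-6` flags a zero mode (the spectrum is O(1) in these units;
the tolerance is configurable). The module does not search for a biologically
realistic regulation function that scales — it verifies the mathematical
chain on constructed instances: the scaling profile `psi = -xs Phi'(xs)` is
annihilated by operators built to have that zero mode, is *not* annihilated
for a fixed-length-scale (anchored exponential) pattern, a flagged zero mode
keeps constant amplitude under the linear dynamics, and mode fluctuations
under white noise follow the Ornstein-Uhlenbeck `1/lambda_mu` law, crossing
over to linear-in-time growth along a flat direction. The claim that
*nonlinear* relaxation along a zero mode is a power law involves saturation
terms outside the linear analysis and is deliberately untested.

## Numerical choices and degenerate inputs

* Lengths: Gaussian truncated at 4 SD (always positive at realistic `cv`);
  lognormal offered because the exact anchoring bound involves `<1/L^2>`.
  `cv = 0` returns the mean exactly.
* Zero noise is allowed in the generator but rejected by the information
  estimator (zero variances make the log-ratios undefined); the error message
  advises a noise floor.
* All randomized routines accept one integer seed and derive independent
  sub-streams deterministically (`subsampling`, bootstrap, shuffles), so any
  single stage can be reproduced in isolation; the caller's RNG state is
  restored afterwards.
* Equal-count length bins are assigned by rank, so populations differ by at
  most one even with tied lengths; all-identical lengths are an error.
* Problem sizes used in the packaged tests (n = 301-582 embryos, 1000-point
  profiles, 100-500 grid-point operators, 200 bootstrap replicates) were
  chosen so the full suite exercises study-scale ensembles while each stage
  stays at seconds-to-minutes on a single core.

## Worked example

```{r example, eval = FALSE}
fam <- make_gap_like_family(4)
lengths <- draw_lengths(301, length_model(490, 0.037), seed = 11)
ens <- generate_ensemble(fam, lengths, noise_sd = 0.05, seed = 12)

# marker route
mk <- detect_half_max_boundaries(ens, "hb")
fit_all_markers(mk, seed = 1)

# information route
est <- estimate_delta_I(ens, seed = 2)
est
nulls <- delta_I_shuffle_null(ens, genes = "hb", seed = 3)
mean(nulls); sd(nulls)

# zero-mode route
md <- eigenmodes(dd_operator(lambda = 40, L = 500, n_grid = 500))
head(md$values)
```
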