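#' Reaction-diffusion gene-network model
#'
#' Dynamics of `G` interacting genes on the interval `[0, L]`:
#' `dg_i/dt = lambda_i^2 d2g_i/dx2 + F_i(g) - g_i`, in units where every
#' protein lifetime is 1 and the maximum steady-state concentration is 1.
#' `lambda_i = sqrt(D_i * tau)` is the length scale of species `i` in micron.
#' Boundary conditions are no-flux at both poles, except that a gene may carry
#' a constant anterior influx (the maternal-input case): `-lambda_i^2 dg/dx =
#' T_i` at `x = 0`.
#'
#' @param lambda numeric vector of per-gene length scales (micron), >= 0.
#' @param F regulation function: takes an `n_grid x G` matrix of
#'   concentrations, returns the same shape; `NULL` means no regulation
#'   (`F = 0`).
#' @param jacobian derivative of `F`: takes the `n_grid x G` matrix and
#'   returns an `n_grid x G x G` array with `[k, i, j] = dF_i/dg_j` at node
#'   `k`; `NULL` uses central finite differences of `F`.
#' @param anterior_flux numeric vector of per-gene anterior influx rates
#'   (0 = plain no-flux); default all zero.
#' @param genes gene names; default `g1, g2, ...`.
#' @param check if `TRUE` (default) and both `F` and `jacobian` are supplied,
#'   the Jacobian is verified against finite differences at random states.
#' @return an object of class `network_model`.
#' @export
network_model <- function(lambda, F = NULL, jacobian = NULL,
                          anterior_flux = NULL, genes = NULL, check = TRUE) {
  G <- length(lambda)
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (is.null(anterior_flux)) anterior_flux <- rep(0, G)
  if (length(anterior_flux) != G) stop("one anterior_flux per gene")
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  if (is.null(F)) F <- function(g) 0 * g
  if (is.null(jacobian)) jacobian <- fd_jacobian(F, G)
  model <- structure(list(lambda = lambda, F = F, jacobian = jacobian,
                          anterior_flux = anterior_flux, genes = genes),
                     class = "network_model")
  if (check) check_jacobian(model)
  model
}

fd_jacobian <- function(F, G, eps = 1e-6) {
  function(g) {
    n <- nrow(g)
    J <- array(0, c(n, G, G))
    for (j in seq_len(G)) {
      up <- g; up[, j] <- up[, j] + eps
      dn <- g; dn[, j] <- dn[, j] - eps
      J[, , j] <- (F(up) - F(dn)) / (2 * eps)
    }
    J
  }
}

check_jacobian <- function(model, n_points = 5, tol = 1e-4) {
  G <- length(model$lambda)
  g <- matrix(seq(0.05, 0.95, length.out = n_points * G), n_points, G)
  J <- model$jacobian(g)
  Jfd <- fd_jacobian(model$F, G)(g)
  if (max(abs(J - Jfd)) > tol)
    stop("supplied jacobian disagrees with finite differences of F")
  invisible(TRUE)
}

#' Linear regulation helper
#'
#' `F(g) = g %*% t(W) + b`: gene `i` receives `sum_j W[i, j] g_j + b_i`.
#'
#' @param W `G x G` interaction matrix.
#' @param b per-gene constant production; default 0.
#' @return a list with elements `F` and `jacobian` to pass to
#'   [network_model()].
#' @export
reg_linear <- function(W, b = 0) {
  W <- as.matrix(W); G <- nrow(W)
  if (length(b) == 1) b <- rep(b, G)
  list(
    F = function(g) sweep(g %*% t(W), 2, b, "+"),
    jacobian = function(g) {
      J <- array(0, c(nrow(g), G, G))
      for (i in seq_len(G)) for (j in seq_len(G)) J[, i, j] <- W[i, j]
      J
    }
  )
}

# Tridiagonal second-difference matrix with mirror-ghost (no-flux) closure on
# a node-at-boundary grid of spacing h.
second_difference <- function(n, h) {
  D <- matrix(0, n, n)
  for (k in 2:(n - 1)) D[k, (k - 1):(k + 1)] <- c(1, -2, 1)
  D[1, 1:2] <- c(-2, 2)
  D[n, (n - 1):n] <- c(2, -2)
  D / h^2
}

# Right-hand side of the method-of-lines system; y is the flattened state
# (gene-major), returns the flattened time derivative.
network_rhs <- function(y, model, n, h) {
  G <- length(model$lambda)
  g <- matrix(y, n, G)
  lap <- matrix(0, n, G)
  for (i in seq_len(G)) {
    gi <- g[, i]
    lap[2:(n - 1), i] <- (gi[1:(n - 2)] - 2 * gi[2:(n - 1)] + gi[3:n]) / h^2
    lap[1, i] <- 2 * (gi[2] - gi[1]) / h^2
    lap[n, i] <- 2 * (gi[n - 1] - gi[n]) / h^2
  }
  dg <- sweep(lap, 2, model$lambda^2, "*") + model$F(g) - g
  # constant anterior influx enters the boundary node as a source 2*T/h
  flux <- model$anterior_flux
  if (any(flux != 0)) dg[1, ] <- dg[1, ] + 2 * flux / h
  as.vector(dg)
}

#' Simulate the network dynamics
#'
#' Method-of-lines integration of the reaction-diffusion system on a uniform
#' grid with nodes at both poles; no-flux boundaries are closed with mirror
#' ghost nodes and an anterior influx appears as a source at the boundary
#' node.
#'
#' @param model a [network_model()].
#' @param init initial condition: an `n_grid x G` matrix, a single value, or
#'   a function of the absolute positions returning the matrix.
#' @param L embryo length (micron).
#' @param duration integration time (lifetimes, since `tau = 1`).
#' @param n_grid grid points, >= 50.
#' @param n_save number of saved time points; default 51.
#' @param rtol,atol integrator tolerances.
#' @return a list of class `network_trajectory`: `times`, `x` (grid),
#'   `states` (`n_save x n_grid x G` array), `model`, `L`.
#' @export
simulate_network <- function(model, init, L, duration, n_grid = 200,
                             n_save = 51, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "network_model"), n_grid >= 50, duration > 0)
  G <- length(model$lambda)
  x <- seq(0, L, length.out = n_grid)
  h <- x[2] - x[1]
  g0 <- resolve_init(init, x, G)
  times <- seq(0, duration, length.out = n_save)
  sol <- deSolve::ode(y = as.vector(g0), times = times,
                      func = function(t, y, p) list(network_rhs(y, model, n_grid, h)),
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("integrator failed; see deSolve diagnostics")
  states <- array(sol[, -1], dim = c(nrow(sol), n_grid, G))
  structure(list(times = sol[, 1], x = x, states = states, model = model, L = L),
            class = "network_trajectory")
}

resolve_init <- function(init, x, G) {
  n <- length(x)
  if (is.function(init)) init <- init(x)
  if (length(init) == 1) init <- matrix(init, n, G)
  init <- as.matrix(init)
  if (!all(dim(init) == c(n, G))) stop("init must be n_grid x n_genes")
  init
}

#' Steady-state pattern of the network
#'
#' Relaxes the dynamics for `t_relax` lifetimes and then polishes with Newton
#' iterations using the linearized operator, until the residual of the
#' steady-state equation falls below `tol`.
#'
#' @inheritParams simulate_network
#' @param t_relax relaxation time before Newton; default 30 lifetimes.
#' @param tol residual tolerance (max norm); default 1e-8.
#' @param max_newton maximum Newton steps; default 25.
#' @return a list of class `steady_state`: `L`, `x`, `Phi` (`n_grid x G`),
#'   `residual` (max-norm), `model`.
#' @export
find_steady_state <- function(model, L, n_grid = 200, init = 0, t_relax = 30,
                              tol = 1e-8, max_newton = 25) {
  G <- length(model$lambda)
  x <- seq(0, L, length.out = n_grid)
  h <- x[2] - x[1]
  traj <- simulate_network(model, init, L, t_relax, n_grid, n_save = 2)
  g <- matrix(traj$states[dim(traj$states)[1], , ], n_grid, G)
  res <- function(gm) max(abs(network_rhs(as.vector(gm), model, n_grid, h)))
  hist <- res(g)
  steady <- structure(list(L = L, x = x, Phi = g, residual = hist[1],
                           model = model), class = "steady_state")
  it <- 0
  while (tail(hist, 1) > tol && it < max_newton) {
    A <- linearized_operator(model, steady, .check_residual = FALSE)
    r <- network_rhs(as.vector(g), model, n_grid, h)
    step <- tryCatch(solve(A, -r), error = function(e) NULL)
    if (is.null(step)) break
    g <- g + matrix(step, n_grid, G)
    steady$Phi <- g
    hist <- c(hist, res(g))
    it <- it + 1
  }
  steady$residual <- tail(hist, 1)
  steady$residual_history <- hist
  if (steady$residual > tol)
    stop(sprintf("steady state did not converge: residual %.3g (history: %s)",
                 steady$residual, paste(signif(hist, 3), collapse = " -> ")))
  steady
}

#' Linearized network operator at a steady state
#'
#' The matrix of the operator governing small deviations from the steady
#' pattern: diffusion and decay on the diagonal blocks (second-order central
#' differences with mirror-ghost no-flux closure) plus the regulation Jacobian
#' evaluated pointwise at the steady profiles. The state ordering is
#' gene-major (`(i - 1) * n_grid + k` for gene `i`, node `k`).
#'
#' @param model a [network_model()].
#' @param steady a [find_steady_state()] result (or a list with `x` and `Phi`).
#' @param .check_residual internal; skip the residual assertion.
#' @return a dense square matrix of size `n_grid * G`, with attributes `x`,
#'   `n_grid`, `n_genes`.
#' @export
linearized_operator <- function(model, steady, .check_residual = TRUE) {
  if (.check_residual && !is.null(steady$residual) && steady$residual > 1e-4)
    warning("steady-state residual is large; the linearization may be off")
  x <- steady$x; n <- length(x); h <- x[2] - x[1]
  G <- length(model$lambda)
  if (any(model$lambda > 0 & model$lambda < 2 * h))
    warning("grid too coarse: lambda below 2 grid steps")
  D <- second_difference(n, h)
  A <- matrix(0, n * G, n * G)
  for (i in seq_len(G)) {
    ii <- ((i - 1) * n + 1):(i * n)
    A[ii, ii] <- model$lambda[i]^2 * D - diag(n)
  }
  J <- model$jacobian(steady$Phi)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    ii <- (i - 1) * n + seq_len(n)
    jj <- (j - 1) * n + seq_len(n)
    A[cbind(ii, jj)] <- A[cbind(ii, jj)] + J[, i, j]
  }
  attr(A, "x") <- x; attr(A, "n_grid") <- n; attr(A, "n_genes") <- G
  A
}

#' Diffusion-decay operator (no regulation)
#'
#' Convenience constructor for the single-gene linear operator
#' `lambda^2 d2/dx2 - 1` with no-flux boundaries; its relaxation spectrum is
#' `lambda_mu = 1 + lambda^2 (mu * pi / L)^2`, `mu = 0, 1, 2, ...` in the
#' continuum limit.
#'
#' @param lambda length scale (micron).
#' @param L domain length (micron).
#' @param n_grid grid points.
#' @return operator matrix as in [linearized_operator()].
#' @export
dd_operator <- function(lambda, L, n_grid) {
  x <- seq(0, L, length.out = n_grid)
  h <- x[2] - x[1]
  A <- lambda^2 * second_difference(n_grid, h) - diag(n_grid)
  attr(A, "x") <- x; attr(A, "n_grid") <- n_grid; attr(A, "n_genes") <- 1L
  A
}

#' Operator with a constructed zero mode
#'
#' Adds a space-dependent diagonal regulation term `j(x)` to the
#' diffusion-decay operator, chosen so that a given positive profile `v`
#' satisfies `A v = 0` exactly — a minimal instance of the zero mode implied
#' by exact scale invariance, useful for validating the mode diagnostics.
#'
#' @param v positive numeric vector: the desired zero mode on the grid.
#' @param lambda,L as in [dd_operator()]; `n_grid = length(v)`.
#' @return operator matrix with `A %*% v = 0`.
#' @export
make_zero_mode_operator <- function(v, lambda, L) {
  if (any(v <= 0)) stop("v must be strictly positive")
  n <- length(v)
  A0 <- dd_operator(lambda, L, n)
  j <- -as.vector(A0 %*% v) / v
  A <- A0 + diag(j)
  attr(A, "x") <- attr(A0, "x")
  attr(A, "n_grid") <- attr(A0, "n_grid")
  attr(A, "n_genes") <- attr(A0, "n_genes")
  A
}

#' Eigenmode decomposition of the linearized operator
#'
#' Solves the eigenproblem `A phi = -lambda_mu phi`, so `lambda_mu >= 0` means
#' the steady state is stable and `lambda_mu = 0` is a zero mode (flat
#' direction). Modes are unit-normalized and sorted by increasing relaxation
#' rate.
#'
#' @param A operator matrix from [linearized_operator()] or [dd_operator()].
#' @param zero_tol relaxation rates with `|lambda_mu| < zero_tol` are flagged
#'   as zero modes; default 1e-6 (normalized units; the spectrum is O(1)).
#' @return a list of class `mode_decomposition`: `values` (relaxation rates
#'   `lambda_mu`, ascending), `vectors` (columns, unit norm), `zero_modes`
#'   (indices), `n_grid`, `n_genes`, `x`.
#' @export
eigenmodes <- function(A, zero_tol = 1e-6) {
  e <- eigen(unclass(A))
  if (max(abs(Im(e$values))) > 1e-8 * max(abs(e$values)))
    warning("complex eigenvalues; reporting real parts")
  vals <- -Re(e$values)
  vecs <- Re(e$vectors)
  ord <- order(vals)
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  structure(list(values = vals, vectors = vecs,
                 zero_modes = which(abs(vals) < zero_tol),
                 n_grid = attr(A, "n_grid"), n_genes = attr(A, "n_genes"),
                 x = attr(A, "x")),
            class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf("mode_decomposition: %d modes (%d genes x %d nodes)\n",
              length(x$values), x$n_genes, x$n_grid))
  cat("  slowest relaxation rates:",
      paste(signif(head(x$values, 5), 4), collapse = ", "), "\n")
  if (length(x$zero_modes))
    cat("  zero modes:", paste(x$zero_modes, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the linearized dynamics
#'
#' Integrates `d(dg)/dt = A dg` from an initial deviation; used to verify
#' that mode amplitudes decay at their eigen rates (and that a zero-mode
#' amplitude is conserved).
#'
#' @param A operator matrix.
#' @param init initial deviation (vector of length `ncol(A)`).
#' @param times output times.
#' @param rtol,atol integrator tolerances.
#' @return matrix `length(times) x ncol(A)` of deviations.
#' @export
simulate_linear <- function(A, init, times, rtol = 1e-10, atol = 1e-12) {
  A <- unclass(A)
  sol <- deSolve::ode(y = as.numeric(init), times = times,
                      func = function(t, y, p) list(as.vector(A %*% y)),
                      parms = NULL, rtol = rtol, atol = atol)
  unname(sol[, -1, drop = FALSE])
}

#' Scaling mode of a steady-state family
#'
#' Under exact scale invariance a small relative change in embryo length
#' shifts the pattern along `psi_i(xs) = -xs * Phi_i'(xs)`, and this profile
#' must be annihilated by the linearized operator (the zero-mode condition).
#' Computes `psi` by centered finite differences and, when an operator is
#' supplied, the relative residual `||A psi|| / ||psi||`.
#'
#' @param steady a [find_steady_state()] result, or a list with `x` and `Phi`.
#' @param A optional operator matrix for the residual.
#' @return a list of class `scaling_mode_check`: `psi` (`n_grid x G`),
#'   `residual_rel` (`NA` without an operator), `x`.
#' @export
scaling_mode <- function(steady, A = NULL) {
  x <- steady$x
  Phi <- as.matrix(steady$Phi)
  n <- nrow(Phi); G <- ncol(Phi)
  psi <- matrix(0, n, G)
  for (i in seq_len(G)) {
    d <- numeric(n)
    d[2:(n - 1)] <- (Phi[3:n, i] - Phi[1:(n - 2), i]) / (x[3:n] - x[1:(n - 2)])
    d[1] <- (Phi[2, i] - Phi[1, i]) / (x[2] - x[1])
    d[n] <- (Phi[n, i] - Phi[n - 1, i]) / (x[n] - x[n - 1])
    # xs * dPhi/dxs = x * dPhi/dx, so psi can be evaluated in absolute x
    psi[, i] <- -x * d
  }
  res <- NA_real_
  if (!is.null(A)) {
    nv <- sqrt(sum(psi^2))
    res <- if (nv == 0) 0 else sqrt(sum((unclass(A) %*% as.vector(psi))^2)) / nv
  }
  structure(list(psi = psi, residual_rel = res, x = x),
            class = "scaling_mode_check")
}

#' Stationary fluctuations along eigenmodes under white noise
#'
#' Adds independent Gaussian white noise of amplitude `noise_sd` to every grid
#' node of the linearized dynamics and measures the variance of each mode
#' amplitude. For a stable mode the amplitude is an Ornstein-Uhlenbeck process
#' with stationary variance proportional to `1 / lambda_mu`; along a zero mode
#' the variance grows linearly in time (reported as non-stationary, with the
#' growth slope).
#'
#' Mode amplitudes are obtained with the left eigenvectors (`a = V^-1 dg`),
#' and the per-mode noise power `noise_sd^2 * ||row_mu(V^-1)||^2` enters the
#' theoretical variance, so non-orthogonal mode bases are handled exactly.
#' The simulation uses the exact one-step OU update in mode coordinates with
#' the full cross-mode noise covariance.
#'
#' @param A operator matrix.
#' @param noise_sd white-noise amplitude per node (per sqrt time).
#' @param t_end simulated time (lifetimes); default 50.
#' @param dt time step; default 0.05.
#' @param n_traj independent trajectories; default 200.
#' @param burn_in fraction of each trajectory discarded before measuring
#'   stationary variances; default 0.5.
#' @param zero_tol threshold on `lambda_mu` for the non-stationary flag.
#' @param seed integer seed.
#' @return a `data.frame` with one row per mode: `lambda`, `var_empirical`,
#'   `var_theory`, `nonstationary`.
#' @export
fluctuation_spectrum <- function(A, noise_sd, t_end = 50, dt = 0.05,
                                 n_traj = 200, burn_in = 0.5, zero_tol = 1e-6,
                                 seed = NULL) {
  A <- unclass(A)
  e <- eigen(A)
  vals <- -Re(e$values); V <- Re(e$vectors)
  ord <- order(vals); vals <- vals[ord]; V <- V[, ord, drop = FALSE]
  Vinv <- solve(V)
  m <- length(vals)
  if (noise_sd == 0) {
    return(data.frame(lambda = vals, var_empirical = 0,
                      var_theory = ifelse(vals > zero_tol, 0, 0),
                      nonstationary = vals < zero_tol))
  }
  # one-step covariance of the mode-coordinate noise over dt:
  # Q[mu,nu] = noise_sd^2 (Vinv Vinv^T)[mu,nu] * (1 - e^{-(l_mu+l_nu) dt}) / (l_mu+l_nu)
  P <- noise_sd^2 * tcrossprod(Vinv)
  S <- outer(vals, vals, "+")
  fac <- ifelse(abs(S) < 1e-12, dt, (1 - exp(-S * dt)) / S)
  Q <- P * fac
  Rq <- chol(Q + diag(1e-14 * max(diag(Q)), m))
  decay <- exp(-vals * dt)
  n_steps <- ceiling(t_end / dt)
  keep_from <- ceiling(burn_in * n_steps)
  nonstat <- vals < zero_tol
  with_seed(seed, {
    a <- matrix(0, m, n_traj)
    ssum <- numeric(m); ssq <- numeric(m); cnt <- 0L
    for (s in seq_len(n_steps)) {
      xi <- t(Rq) %*% matrix(rnorm(m * n_traj), m, n_traj)
      a <- a * decay + xi
      if (s > keep_from) {
        ssum <- ssum + rowSums(a)
        ssq <- ssq + rowSums(a^2)
        cnt <- cnt + n_traj
      }
    }
    var_stat <- ssq / cnt - (ssum / cnt)^2
    var_final <- apply(a, 1, var)
    power <- noise_sd^2 * rowSums(Vinv^2)
    data.frame(
      lambda = vals,
      var_empirical = ifelse(nonstat, var_final, var_stat),
      var_theory = ifelse(nonstat, power * n_steps * dt, power / (2 * vals)),
      nonstationary = nonstat
    )
  })
}
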