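#' Coupled overdamped-oscillator model of two dihedral degrees of freedom
#'
#' Minimal analytic model for a pair of interacting dihedrals: two linearly
#' coupled, drag-dominated harmonic degrees of freedom \eqn{\theta_i, \theta_j}
#' obeying, in the long-time (inertia-free) limit,
#' \deqn{\gamma_i \dot\theta_i = -\omega_i^2 \theta_i + \alpha' \theta_j + noise}
#' \deqn{\gamma_j \dot\theta_j = -\omega_j^2 \theta_j + \beta'  \theta_i + noise}
#' with characteristic frequencies \eqn{\omega}, drags \eqn{\gamma > 0} and
#' asymmetric coupling strengths \eqn{\alpha'} (action of j on i) and
#' \eqn{\beta'} (action of i on j). Every lagged correlation of this system is
#' available in closed form, so it serves both as the oracle for the TDCF
#' estimator and as the synthetic-data engine.
#'
#' @param omega_i,omega_j Characteristic frequencies (stiffness parameters);
#'   \eqn{\omega^2/\gamma} is the relaxation rate in 1/ns.
#' @param gamma_i,gamma_j Drag coefficients, must be positive.
#' @param alpha Coupling strength of j acting on i (\eqn{\alpha'}).
#' @param beta Coupling strength of i acting on j (\eqn{\beta'}).
#' @param noise Length-2 vector of diffusion coefficients (deg^2/ns); the
#'   stochastic variant integrates \eqn{d\theta = A\theta\,dt + \sqrt{D}\,dW}
#'   with \eqn{D = diag(noise)}.
#' @param sigma0 Optional 2x2 symmetric PSD initial-condition covariance for
#'   the deterministic-relaxation variant; defaults to the stationary
#'   covariance of the stochastic variant.
#' @return An object of class `oscillator_system`.
#' @seealso [relaxation_matrix()], [analytic_tdcf()], [simulate_oscillators()]
#' @export
oscillator_system <- function(omega_i, omega_j, gamma_i = 1, gamma_j = 1,
                              alpha = 0, beta = 0, noise = c(1, 1),
                              sigma0 = NULL) {
  stopifnot(gamma_i > 0, gamma_j > 0, length(noise) == 2L, all(noise >= 0))
  sys <- structure(
    list(omega_i = omega_i, omega_j = omega_j,
         gamma_i = gamma_i, gamma_j = gamma_j,
         alpha = alpha, beta = beta,
         noise = as.numeric(noise), sigma0 = sigma0),
    class = "oscillator_system")
  relaxation_matrix(sys)  # validates stability at construction
  sys
}

#' Convenience constructor from relaxation times
#'
#' Builds an [oscillator_system()] with unit drags from the two marginal
#' relaxation times (ns), the coupling rates (1/ns), and target stationary
#' standard deviations (degrees) of the uncoupled variables.
#'
#' @param tau_i,tau_j Marginal relaxation times in ns.
#' @param alpha,beta Coupling rates (1/ns), j-on-i and i-on-j.
#' @param sd_i,sd_j Stationary standard deviations (degrees) the uncoupled
#'   variables would have; sets the noise amplitudes.
#' @return An `oscillator_system`.
#' @export
oscillator_from_times <- function(tau_i, tau_j, alpha = 0, beta = 0,
                                  sd_i = 25, sd_j = 25) {
  stopifnot(tau_i > 0, tau_j > 0)
  oscillator_system(omega_i = 1 / sqrt(tau_i), omega_j = 1 / sqrt(tau_j),
                    gamma_i = 1, gamma_j = 1, alpha = alpha, beta = beta,
                    noise = c(2 * sd_i^2 / tau_i, 2 * sd_j^2 / tau_j))
}

#' Relaxation matrix of an oscillator system
#'
#' The drift matrix of the overdamped equations of motion,
#' \deqn{A = \begin{pmatrix} -\omega_i^2/\gamma_i & \alpha'/\gamma_i \\
#'                            \beta'/\gamma_j & -\omega_j^2/\gamma_j \end{pmatrix}.}
#' Stability (all eigenvalues with negative real part) is checked; an unstable
#' parameter set, e.g. \eqn{\alpha'\beta' > \omega_i^2\omega_j^2}, is an error.
#'
#' @param sys An `oscillator_system`.
#' @return 2x2 numeric matrix.
#' @export
relaxation_matrix <- function(sys) {
  A <- matrix(c(-sys$omega_i^2 / sys$gamma_i, sys$alpha / sys$gamma_i,
                sys$beta / sys$gamma_j, -sys$omega_j^2 / sys$gamma_j),
              nrow = 2, byrow = TRUE)
  check_stable(A)
  A
}

check_stable <- function(A) {
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) {
    stop_tdcf("relaxation matrix is unstable; eigenvalues: %s",
              paste(format(ev, digits = 4), collapse = ", "),
              class = "tdcf_unstable")
  }
  invisible(ev)
}

#' Stationary covariance of a linear stochastic system
#'
#' Solves the continuous Lyapunov equation \eqn{A\Sigma + \Sigma A^T + D = 0}
#' for the stationary covariance of \eqn{d x = A x\,dt + \sqrt{D}\,dW}, via the
#' Kronecker vectorization identity. For a decoupled variable with relaxation
#' rate \eqn{\omega^2/\gamma} and diffusion \eqn{D_{kk}} this reduces to the
#' scalar Ornstein-Uhlenbeck variance \eqn{D_{kk}\gamma/(2\omega^2)}.
#'
#' @param A Stable drift matrix (all eigenvalues with negative real part).
#' @param D Symmetric positive semi-definite diffusion matrix.
#' @return Symmetric covariance matrix with attribute `residual`, the max-norm
#'   of \eqn{A\Sigma + \Sigma A^T + D}.
#' @export
stationary_covariance <- function(A, D) {
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(D) == n))
  if (max(abs(D - t(D))) > 1e-10) stop("D must be symmetric")
  check_stable(A)
  I <- diag(n)
  M <- kronecker(I, A) + kronecker(A, I)
  sig <- matrix(solve(M, -as.vector(D)), n, n)
  sig <- (sig + t(sig)) / 2
  res <- max(abs(A %*% sig + sig %*% t(A) + D))
  if (res > 1e-8 * max(1, max(abs(D))))
    warning("Lyapunov residual larger than expected: ", format(res))
  attr(sig, "residual") <- res
  sig
}

# Σ for a system: stochastic stationary law unless a sigma0 was supplied
system_covariance <- function(sys) {
  if (!is.null(sys$sigma0)) {
    s0 <- sys$sigma0
    stopifnot(all(dim(s0) == 2L), max(abs(s0 - t(s0))) < 1e-10)
    if (any(eigen(s0, only.values = TRUE)$values < -1e-12))
      stop("sigma0 must be positive semi-definite")
    return(s0)
  }
  stationary_covariance(relaxation_matrix(sys), diag(sys$noise))
}

# entry [b, a] of exp(A dt) %*% Sigma for a vector of dt, by eigendecomposition
# (the lagged covariance <x_b(t + dt) x_a(t)> of the stationary process)
lag_cov_entry <- function(A, Sigma, dt, b, a) {
  es <- eigen(A)
  V <- es$vectors
  if (rcond(V) > 1e-10) {
    w <- V[b, ] * solve(V, Sigma)[, a]
    return(Re(as.vector(exp(outer(dt, es$values)) %*% w)))
  }
  # near-defective A: fall back to a dense matrix exponential per lag
  vapply(dt, function(h) {
    E <- as.matrix(Matrix::expm(A * h))
    (E %*% Sigma)[b, a]
  }, numeric(1))
}

#' Analytic lagged cross-correlation of the oscillator model
#'
#' Closed-form normalized cross-correlation
#' \eqn{C_{ij}(\Delta t) = [e^{A\Delta t}\Sigma]_{ji} / \sqrt{\Sigma_{ii}\Sigma_{jj}}}
#' (forward direction: variable i taken at the earlier time; the reverse curve
#' uses the transposed entry). At \eqn{\Delta t = 0} this is the Pearson
#' coefficient; it decays to 0 as \eqn{\Delta t \to \infty} for any stable
#' system.
#'
#' @param sys An `oscillator_system`.
#' @param dt_ns Vector of non-negative lags in ns.
#' @param direction `"forward"` (i at the earlier time) or `"reverse"`.
#' @param Sigma Optional covariance to use instead of the system's own
#'   (stationary or `sigma0`) covariance.
#' @return Numeric vector of correlation values, one per lag.
#' @export
analytic_tdcf <- function(sys, dt_ns, direction = c("forward", "reverse"),
                          Sigma = NULL) {
  direction <- match.arg(direction)
  stopifnot(all(dt_ns >= 0))
  A <- relaxation_matrix(sys)
  Sigma <- Sigma %||% system_covariance(sys)
  norm <- sqrt(Sigma[1, 1] * Sigma[2, 2])
  if (norm <= 0) stop_tdcf("zero marginal variance in Sigma",
                           class = "tdcf_zero_variance")
  if (direction == "forward") lag_cov_entry(A, Sigma, dt_ns, 2, 1) / norm
  else                        lag_cov_entry(A, Sigma, dt_ns, 1, 2) / norm
}

#' Analytic Laplace-domain cross-correlation (resolvent form)
#'
#' The Laplace transform of [analytic_tdcf()] in closed form,
#' \eqn{F_{ij}(s) = [(sI - A)^{-1}\Sigma]_{ji} / \sqrt{\Sigma_{ii}\Sigma_{jj}}}.
#' Its \eqn{s \to 0} value has the sign of the Pearson coefficient (a maximum
#' in s for correlated pairs, a minimum for anti-correlated ones), the forward
#' and reverse curves differ whenever \eqn{\alpha' \neq \beta'}, and for large
#' s it decays algebraically with leading term \eqn{\Sigma_{ji}/s} (exponent 1
#' when the equal-time cross-covariance is nonzero, else
#' \eqn{[A\Sigma]_{ji}/s^2}, exponent 2).
#'
#' @inheritParams analytic_tdcf
#' @param s Vector of positive Laplace frequencies (1/ns).
#' @return Numeric vector F(s) (units ns), one value per frequency.
#' @export
analytic_laplace <- function(sys, s, direction = c("forward", "reverse"),
                             Sigma = NULL) {
  direction <- match.arg(direction)
  if (any(s <= 0)) stop_tdcf("Laplace frequencies must be positive",
                             class = "tdcf_domain")
  A <- relaxation_matrix(sys)
  Sigma <- Sigma %||% system_covariance(sys)
  norm <- sqrt(Sigma[1, 1] * Sigma[2, 2])
  idx <- if (direction == "forward") c(2, 1) else c(1, 2)
  vapply(s, function(si) {
    (solve(diag(2) * si - A, Sigma))[idx[1], idx[2]] / norm
  }, numeric(1))
}

#' Pearson coefficient of the oscillator model
#'
#' Equal-time correlation \eqn{\Sigma_{ij}/\sqrt{\Sigma_{ii}\Sigma_{jj}}} of
#' the model's (stationary or initial-condition) covariance.
#'
#' @inheritParams analytic_tdcf
#' @return Scalar in \[-1, 1\].
#' @export
analytic_pearson <- function(sys, Sigma = NULL) {
  Sigma <- Sigma %||% system_covariance(sys)
  Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
}

# shared Euler-Maruyama engine: d x = A x dt + sqrt(D) dW.
# Returns the post-burn-in sample matrix (n_steps x d).
sim_ou <- function(A, D, n_steps, dt_ns, seed = NULL, burnin_steps = NULL,
                   x0 = NULL) {
  d <- nrow(A)
  ev <- check_stable(A)
  rates <- -Re(ev)
  r_fast <- max(rates); r_slow <- min(rates)
  if (dt_ns > 0.5 / r_fast) {
    stop_tdcf(
      "dt = %g ns does not resolve the fastest relaxation (%.3g ns); use dt <= %g",
      dt_ns, 1 / r_fast, signif(0.1 / r_fast, 2), class = "tdcf_dt")
  }
  if (dt_ns > 0.1 / r_fast)
    warning(sprintf("dt = %g ns is coarse for the fastest mode (%.3g ns)",
                    dt_ns, 1 / r_fast))
  if (is.null(burnin_steps))
    burnin_steps <- ceiling(10 / (r_slow * dt_ns))
  if (!is.null(seed)) set.seed(seed)
  Sigma <- stationary_covariance(A, D)
  x <- if (is.null(x0)) {
    es <- eigen(Sigma); es$values[es$values < 0] <- 0
    as.vector(es$vectors %*% (sqrt(es$values) * stats::rnorm(d)))
  } else as.numeric(x0)
  n_tot <- n_steps + burnin_steps
  sqD <- if (max(abs(D - diag(diag(D)))) < 1e-14) diag(sqrt(diag(D)), d)
         else {
           es <- eigen(D); es$values[es$values < 0] <- 0
           es$vectors %*% (sqrt(es$values) * t(es$vectors))
         }
  noise <- matrix(stats::rnorm(n_tot * d), n_tot, d) %*% (sqrt(dt_ns) * t(sqD))
  M <- diag(d) + A * dt_ns
  out <- matrix(0, n_tot, d)
  for (t in seq_len(n_tot)) {
    x <- M %*% x + noise[t, ]
    out[t, ] <- x
  }
  out[(burnin_steps + 1):n_tot, , drop = FALSE]
}

#' Simulate angular time series from the oscillator model
#'
#' Euler-Maruyama integration of the stochastic variant
#' \eqn{d\theta = A\theta\,dt + \sqrt{D}\,dW}, initialized from the stationary
#' law and discarding a burn-in of ten slowest relaxation times. Amplitudes
#' are meant to stay well below 180 degrees (small-angle regime) so that
#' circular wrapping downstream is inert; the mean offsets shift the series
#' away from zero without affecting correlations.
#'
#' @param sys An `oscillator_system`.
#' @param n_steps Number of post-burn-in samples.
#' @param dt_ns Integration and sampling step (ns); must resolve the fastest
#'   relaxation mode (error above half of it, warning above a tenth).
#' @param seed Optional integer seed; a fixed seed gives bit-identical series.
#' @param mean_deg Length-2 vector of mean angles added to the two series.
#' @param dof Length-2 character vector of dof labels for the output series.
#' @return List of two [angle_series] objects (residues 1 and 2).
#' @export
simulate_oscillators <- function(sys, n_steps, dt_ns, seed = NULL,
                                 mean_deg = c(0, 0),
                                 dof = c("phi", "phi")) {
  A <- relaxation_matrix(sys)
  X <- sim_ou(A, diag(sys$noise), n_steps, dt_ns, seed = seed)
  times <- seq(0, by = dt_ns, length.out = n_steps)
  list(
    angle_series(1L, dof[1], times, wrap_angle(X[, 1] + mean_deg[1])),
    angle_series(2L, dof[2], times, wrap_angle(X[, 2] + mean_deg[2]))
  )
}

#' Stokes-Einstein rotational correlation time
#'
#' Rotational diffusion constant \eqn{D_r = k_B T / (8\pi\eta R^3)} of a
#' sphere of radius R, and the rank-l rotational correlation time
#' \eqn{\tau_l = 1/(l(l+1) D_r)}; rank 1 (dipolar, \eqn{\tau = 4\pi\eta R^3/k_BT})
#' and rank 2 (e.g. NMR relaxation, three times shorter) conventions are both
#' available since different experiments report different ranks.
#'
#' @param radius_nm Hydrodynamic radius in nm.
#' @param temperature_K Temperature in kelvin.
#' @param viscosity_mPas Solvent viscosity in mPa s (water at 310 K: ~0.69).
#' @param rank Spherical-harmonic rank l, 1 or 2.
#' @return Rotational correlation time in ns, with attribute `convention`.
#' @export
#' @examples
#' rotational_time(2.4, 310, 0.69, rank = 1)
rotational_time <- function(radius_nm, temperature_K = 310,
                            viscosity_mPas = 0.69, rank = 1) {
  stopifnot(radius_nm > 0, temperature_K > 0, viscosity_mPas > 0,
            rank %in% c(1, 2))
  kB <- 1.380649e-23                       # J/K
  eta <- viscosity_mPas * 1e-3             # Pa s
  R <- radius_nm * 1e-9                    # m
  Dr <- kB * temperature_K / (8 * pi * eta * R^3)   # 1/s
  tau_s <- 1 / (rank * (rank + 1) * Dr)
  structure(tau_s * 1e9,
            convention = sprintf("rank-%d spherical harmonic, tau = 1/(l(l+1) D_r)",
                                 rank))
}
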