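# Lagged cross-sums s_l = sum_t x[t] y[t + l], l = 0..L, via zero-padded FFT.
# Equivalent to the naive O(N L) double loop, checked against it in tests.
cross_sums <- function(x, y, L) {
  n <- length(x)
  stopifnot(length(y) == n, L < n)
  m <- stats::nextn(n + L, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  cc <- stats::fft(Conj(X) * Y, inverse = TRUE) / m
  Re(cc[seq_len(L + 1L)])
}

#' Time-dependent dihedral cross-correlation function (TDCF)
#'
#' Estimates the normalized lagged cross-correlation between the fluctuations
#' of two dihedrals sharing a time grid:
#' \deqn{C_{ij}(\theta\theta'; \Delta t_l) =
#'   \frac{1}{N_l}\sum_{t_1} \frac{\delta\theta_i(t_1)\,\delta\theta'_j(t_1+\Delta t_l)}
#'        {\sqrt{var(\theta_i)\,var(\theta'_j)}}}
#' where \eqn{N_l = N - l} is the number of observation pairs at lag l and the
#' variances are those of the full series of wrapped deviations. The curve is
#' the *forward* direction for the argument order given (`fi` evaluated at the
#' earlier time); the reverse curve is `tdcf_estimate(fj, fi, ...)`, and the
#' two generally differ (exchange asymmetry). \eqn{|C(0)| \le 1} exactly; at
#' positive lags small exceedances of 1 of order \eqn{1/N_l} can occur because
#' the normalization uses the full-series variance — they are reported as-is,
#' never clipped.
#'
#' @param fi,fj [fluctuations()] objects (or [angle_series], centered with the
#'   default policy) on the same time grid; `fi` is the earlier-time series.
#' @param max_lag_ns Largest lag; default one quarter of the series span
#'   (beyond that too few observation pairs remain per lag).
#' @param min_count Smallest \eqn{N_l} for which the curve is reported;
#'   shorter-count lags are set to `NA`.
#' @param normalization `"full"` (default; full-series variances, the printed
#'   definition) or `"per-window"` (each lag normalized by the variances of
#'   the overlapping windows).
#' @return Object of class `tdcf_curve`: fields `lag_ns`, `C`, `N_l`, the
#'   pair/direction identity and the variances used.
#' @export
tdcf_estimate <- function(fi, fj, max_lag_ns = NULL, min_count = 10L,
                          normalization = c("full", "per-window")) {
  normalization <- match.arg(normalization)
  fi <- as_fluct(fi); fj <- as_fluct(fj)
  n <- length(fi$dev_deg)
  if (length(fj$dev_deg) != n ||
      max(abs(fi$times_ns - fj$times_ns)) > 1e-9 * max(fi$dt_ns, 1))
    stop_tdcf("series are not on the same time grid", class = "tdcf_alignment")
  dt <- fi$dt_ns
  span <- (n - 1) * dt
  max_lag_ns <- max_lag_ns %||% (0.25 * span)
  if (max_lag_ns >= span)
    stop_tdcf("max_lag (%g ns) must be below the series span (%g ns)",
              max_lag_ns, span, class = "tdcf_alignment")
  L <- floor(max_lag_ns / dt + 1e-9)
  N_l <- n - 0:L
  s <- cross_sums(fi$dev_deg, fj$dev_deg, L)
  if (normalization == "full") {
    C <- s / (N_l * sqrt(fi$var_deg2 * fj$var_deg2))
  } else {
    cx <- cumsum(fi$dev_deg^2); cy <- cumsum(fj$dev_deg^2)
    vx <- cx[n - 0:L] / N_l                      # var of x over [1, n-l]
    vy <- (cy[n] - c(0, cy[seq_len(L)])) / N_l   # var of y over [l+1, n]
    C <- s / (N_l * sqrt(vx * vy))
  }
  C[N_l < min_count] <- NA_real_
  structure(
    list(lag_ns = 0:L * dt, C = C, N_l = N_l,
         i = fi$res_index, dof_i = fi$dof,
         j = fj$res_index, dof_j = fj$dof,
         direction = "forward", dt_ns = dt,
         var_i = fi$var_deg2, var_j = fj$var_deg2,
         normalization = normalization),
    class = "tdcf_curve")
}

#' @export
print.tdcf_curve <- function(x, ...) {
  cat(sprintf("tdcf_curve: (%d,%s) -> (%d,%s), %d lags to %g ns, C(0) = %.3f\n",
              x$i, x$dof_i, x$j, x$dof_j, length(x$lag_ns),
              max(x$lag_ns), x$C[1]))
  invisible(x)
}

#' Pearson correlation of two dihedral fluctuation series
#'
#' The equal-time statistical correlation, identical by construction to the
#' TDCF at zero lag.
#'
#' @inheritParams tdcf_estimate
#' @return Scalar in \[-1, 1\].
#' @export
tdcf_pearson <- function(fi, fj) {
  fi <- as_fluct(fi); fj <- as_fluct(fj)
  n <- length(fi$dev_deg)
  if (length(fj$dev_deg) != n)
    stop_tdcf("series are not on the same time grid", class = "tdcf_alignment")
  sum(fi$dev_deg * fj$dev_deg) / (n * sqrt(fi$var_deg2 * fj$var_deg2))
}

#' TDCF convergence across trajectory prefixes
#'
#' Recomputes the TDCF on leading fractions of the trajectory and reports the
#' pairwise sup-norm differences between the curves, so saturation of the
#' estimate with trajectory length can be asserted (curves from long-enough
#' prefixes should be close, while short prefixes differ).
#'
#' @inheritParams tdcf_estimate
#' @param fractions Vector of prefix fractions in (0, 1].
#' @return List with `curves` (one `tdcf_curve` per usable fraction) and
#'   `sup_diff`, the matrix of max absolute differences over the common lags.
#' @export
convergence_check <- function(fi, fj, fractions = c(0.5, 0.75, 1),
                              max_lag_ns = NULL, min_count = 10L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  fi <- as_fluct(fi); fj <- as_fluct(fj)
  n <- length(fi$dev_deg)
  span <- (n - 1) * fi$dt_ns
  max_lag_ns <- max_lag_ns %||% (0.25 * span)
  trunc_fl <- function(f, m) {
    idx <- seq_len(m)
    s <- structure(list(res_index = f$res_index, dof = f$dof,
                        times_ns = f$times_ns[idx], dt_ns = f$dt_ns,
                        dev_deg = f$dev_deg[idx] - mean(f$dev_deg[idx]),
                        var_deg2 = mean((f$dev_deg[idx] - mean(f$dev_deg[idx]))^2),
                        mean_deg = f$mean_deg, policy = f$policy),
                   class = "fluct_series")
    s
  }
  curves <- list()
  used <- numeric(0)
  for (f in sort(fractions)) {
    m <- floor(f * n)
    if ((m - 1) * fi$dt_ns <= max_lag_ns) {
      warning(sprintf("fraction %g too short to cover max_lag = %g ns; skipped",
                      f, max_lag_ns))
      next
    }
    curves[[length(curves) + 1L]] <-
      tdcf_estimate(trunc_fl(fi, m), trunc_fl(fj, m),
                    max_lag_ns = max_lag_ns, min_count = min_count)
    used <- c(used, f)
  }
  names(curves) <- make.unique(sprintf("%g", used))
  k <- length(curves)
  sup <- matrix(0, k, k, dimnames = list(names(curves), names(curves)))
  if (k >= 2L) {
    nl <- min(vapply(curves, function(cu) length(cu$C), 1L))
    for (a in seq_len(k)) for (b in seq_len(k))
      sup[a, b] <- max(abs(curves[[a]]$C[1:nl] - curves[[b]]$C[1:nl]), na.rm = TRUE)
  }
  list(curves = curves, sup_diff = sup, fractions = used)
}

#' Numerical Laplace transform of a TDCF curve
#'
#' \eqn{F(s) = \int_0^{\Delta t_{max}} C(\Delta t)\,e^{-s\Delta t}\,d\Delta t}
#' by composite trapezoid quadrature on the lag grid, evaluated on a log-spaced
#' frequency grid. The truncation-bias bound \eqn{|C(\Delta t_{max})|/s} is
#' attached per frequency; the returned F (units ns) tends to 0 as
#' \eqn{s \to \infty} and, at small s, to the trapezoid estimate of
#' \eqn{\int C\,d\Delta t}, so its low-frequency extremum carries the sign of
#' the net correlation.
#'
#' @param curve A `tdcf_curve` (or any list with `lag_ns` and `C`).
#' @param s_grid Positive frequencies (1/ns); default 200 log-spaced points
#'   spanning \eqn{[1/(2\Delta t_{max}),\ 10/dt]}, bracketing both the
#'   low-frequency extremum and the algebraic tail.
#' @param n_s Number of grid points when `s_grid` is defaulted.
#' @return Object of class `laplace_curve`: fields `s`, `F_s`, `trunc_bias`,
#'   grid metadata and the pair identity.
#' @export
laplace_transform <- function(curve, s_grid = NULL, n_s = 200L) {
  lag <- curve$lag_ns; C <- curve$C
  keep <- !is.na(C)
  if (!all(keep)) { last <- which(!keep)[1] - 1L; lag <- lag[1:last]; C <- C[1:last] }
  stopifnot(length(lag) >= 3L)
  dt <- lag[2] - lag[1]
  dt_max <- lag[length(lag)]
  if (is.null(s_grid)) s_grid <- logspace(1 / (2 * dt_max), 10 / dt, n_s)
  if (any(s_grid <= 0)) stop_tdcf("Laplace frequencies must be positive",
                                  class = "tdcf_domain")
  s_grid <- sort(s_grid)
  w <- rep(dt, length(lag)); w[c(1, length(lag))] <- dt / 2  # trapezoid weights
  wc <- w * C
  F_s <- vapply(s_grid, function(si) sum(wc * exp(-si * lag)), numeric(1))
  structure(
    list(s = s_grid, F_s = F_s,
         trunc_bias = abs(C[length(C)]) / s_grid,
         dt_ns = dt, dt_max_ns = dt_max,
         i = curve$i, dof_i = curve$dof_i, j = curve$j, dof_j = curve$dof_j,
         direction = curve$direction %||% "forward"),
    class = "laplace_curve")
}

#' @export
print.laplace_curve <- function(x, ...) {
  ex <- laplace_extremum(x)
  cat(sprintf("laplace_curve: (%s,%s)->(%s,%s), s in [%.3g, %.3g] 1/ns, F_ext = %.4g ns at s = %.3g (tau = %.3g ns%s)\n",
              x$i, x$dof_i, x$j, x$dof_j, min(x$s), max(x$s),
              ex$F_ext, ex$s_peak, ex$tau_ns,
              if (ex$boundary) ", boundary" else ""))
  invisible(x)
}

#' Extremum of a Laplace-domain correlation curve
#'
#' Locates the peak that measures correlation strength: an interior maximum of
#' F(s) when the pair is net-correlated (F at low s positive), an interior
#' minimum when anti-correlated. The inverse peak position is the
#' characteristic correlation timescale \eqn{\tau = 1/s_{peak}}. A monotone
#' curve yields a boundary extremum, flagged, with \eqn{\tau} then only a
#' bound; exact ties resolve to the smallest s (longest timescale) and are
#' flagged.
#'
#' @param lc A `laplace_curve` computed on at least 10 grid points.
#' @return List with `F_ext`, `s_peak`, `tau_ns`, `boundary`, `tie`.
#' @export
laplace_extremum <- function(lc) {
  s <- lc$s; F_s <- lc$F_s
  stopifnot(length(s) >= 10L)
  sgn <- sign(F_s[1])
  if (sgn == 0) sgn <- sign(F_s[which.max(abs(F_s))])
  v <- sgn * F_s
  idx <- which.max(v)                 # first index wins: smallest s on a tie
  tie <- sum(v == v[idx]) > 1L
  boundary <- idx == 1L || idx == length(s)
  list(F_ext = F_s[idx], s_peak = s[idx], tau_ns = 1 / s[idx],
       boundary = boundary, tie = tie)
}

#' Algebraic tail exponent of a Laplace-domain curve
#'
#' Fits \eqn{|F(s)| \sim s^{-\kappa}} at large s by least squares on
#' \eqn{\ln|F|} vs \eqn{\ln s}. The default window is the highest decade of
#' the grid on which (a) |F| exceeds 5x the truncation-bias bound
#' \eqn{|C(\Delta t_{max})|/s} and (b) \eqn{s \le 0.5/dt}, below which the
#' trapezoid quadrature still resolves the exponential kernel (its relative
#' error grows as \eqn{(s\,dt)^2/12} and the discrete transform flattens for
#' \eqn{s\,dt \gtrsim 1}). A sign change of F inside the window shrinks it to
#' the portion after the last change, with a warning.
#'
#' @param lc A `laplace_curve`.
#' @param window Optional length-2 vector of s bounds overriding the default.
#' @return List with `kappa`, `stderr`, `window`, `n_points`, `r_squared`.
#' @export
tail_exponent <- function(lc, window = NULL) {
  s <- lc$s; F_s <- lc$F_s
  if (is.null(window)) {
    ok <- abs(F_s) > 5 * lc$trunc_bias & s <= 0.5 / lc$dt_ns & F_s != 0
    if (!any(ok))
      stop_tdcf("no frequencies above the truncation-bias floor; extend the lag grid",
                class = "tdcf_tail")
    s_hi <- max(s[ok])
    window <- c(s_hi / 10, s_hi)
  }
  in_win <- s >= window[1] & s <= window[2] & F_s != 0
  sw <- s[in_win]; Fw <- F_s[in_win]
  if (length(unique(sign(Fw))) > 1L) {
    last_change <- max(which(diff(sign(Fw)) != 0))
    warning("F changes sign inside the tail window; window shrunk")
    sw <- sw[(last_change + 1):length(sw)]
    Fw <- Fw[(last_change + 1):length(Fw)]
  }
  if (length(sw) < 5L)
    stop_tdcf("tail window has fewer than 5 usable points", class = "tdcf_tail")
  fit <- stats::lm(log(abs(Fw)) ~ log(sw))
  sm <- summary(fit)
  list(kappa = -unname(stats::coef(fit)[2]),
       stderr = unname(sm$coefficients[2, 2]),
       window = c(min(sw), max(sw)), n_points = length(sw),
       r_squared = sm$r.squared)
}

#' Write TDCF and Laplace curves as TSV; summarize a pair as JSON
#'
#' @param curve A `tdcf_curve` or `laplace_curve`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tdcf_tsv <- function(curve, path) {
  utils::write.table(
    data.frame(dt_ns = curve$lag_ns, C = curve$C, N_l = curve$N_l),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tdcf_tsv
#' @export
write_laplace_tsv <- function(curve, path) {
  utils::write.table(
    data.frame(s_per_ns = curve$s, F_ns = curve$F_s,
               trunc_bias = curve$trunc_bias),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tdcf_tsv
#' @param lc A `laplace_curve` for the pair.
#' @param pearson Equal-time correlation of the pair.
#' @export
pair_summary <- function(lc, pearson = NA_real_) {
  ex <- laplace_extremum(lc)
  ta <- tryCatch(tail_exponent(lc), error = function(e) list(kappa = NA_real_))
  list(i = lc$i, dof_i = lc$dof_i, j = lc$j, dof_j = lc$dof_j,
       direction = lc$direction,
       F_ext = ex$F_ext, s_peak = ex$s_peak, tau_ns = ex$tau_ns,
       boundary = ex$boundary, kappa = ta$kappa, pearson = pearson)
}

#' @rdname write_tdcf_tsv
#' @export
write_pair_summary_json <- function(lc, path, pearson = NA_real_) {
  jsonlite::write_json(pair_summary(lc, pearson), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
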