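#' Dihedral angle time series
#'
#' One dihedral degree of freedom of one residue, sampled uniformly in time.
#' Angles live on the principal branch (-180, +180] degrees; times are in ns
#' with strictly positive, constant spacing.
#'
#' @param res_index 1-based residue index.
#' @param dof Dof label, one of `"phi"`, `"psi"`, `"chi1"`.
#' @param times_ns Numeric vector of sample times (ns), uniformly spaced.
#' @param angles_deg Numeric vector of angles in degrees; wrapped onto
#'   (-180, 180] at construction.
#' @return Object of class `angle_series`.
#' @export
angle_series <- function(res_index, dof, times_ns, angles_deg) {
  stopifnot(length(times_ns) == length(angles_deg), length(times_ns) >= 2L)
  dof <- match.arg(dof, c("phi", "psi", "chi1"))
  dt <- diff(times_ns)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
    stop("times must be uniformly increasing")
  if (any(!is.finite(angles_deg))) stop("non-finite angles")
  structure(
    list(res_index = as.integer(res_index), dof = dof,
         times_ns = as.numeric(times_ns),
         angles_deg = wrap_angle(as.numeric(angles_deg)),
         dt_ns = mean(dt)),
    class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("angle_series: residue %d %s, %d frames, dt = %g ns, span %g ns\n",
              x$res_index, x$dof, length(x$angles_deg), x$dt_ns,
              diff(range(x$times_ns))))
  invisible(x)
}

#' Centered dihedral fluctuations
#'
#' Removes the circular mean from an [angle_series] and wraps each deviation
#' back onto (-180, 180] (minimal-image deviations), the parameter-free
#' default for circular data. The variance used to normalize TDCFs is the
#' plain second moment of the wrapped deviations, which makes the zero-lag
#' autocorrelation exactly 1 (Cauchy-Schwarz). For series that hop branches
#' frequently, `policy = "unwrap"` first unwraps the trajectory (cumulative
#' minimal-image increments) and centers on the arithmetic mean instead.
#'
#' @param series An [angle_series].
#' @param policy `"wrap"` (default) or `"unwrap"`.
#' @return Object of class `fluct_series` with fields `dev_deg`, `var_deg2`,
#'   `mean_deg`, plus the parent identity.
#' @export
fluctuations <- function(series, policy = c("wrap", "unwrap")) {
  policy <- match.arg(policy)
  x <- series$angles_deg
  if (policy == "wrap") {
    mu <- circular_mean(x)
    dev <- wrap_angle(x - mu)
  } else {
    ux <- x[1] + c(0, cumsum(wrap_angle(diff(x))))
    mu <- mean(ux)
    dev <- ux - mu
  }
  v <- mean(dev^2)
  if (v < 1e-12)
    stop_tdcf("residue %d %s: constant series, variance is zero and the TDCF normalization is undefined",
              series$res_index, series$dof, class = "tdcf_zero_variance")
  structure(
    list(res_index = series$res_index, dof = series$dof,
         times_ns = series$times_ns, dt_ns = series$dt_ns,
         dev_deg = dev, var_deg2 = v, mean_deg = mu, policy = policy),
    class = "fluct_series")
}

as_fluct <- function(x, policy = "wrap") {
  if (inherits(x, "fluct_series")) x
  else if (inherits(x, "angle_series")) fluctuations(x, policy)
  else stop("expected an angle_series or fluct_series")
}

#' @export
print.fluct_series <- function(x, ...) {
  cat(sprintf("fluct_series: residue %d %s, %d frames, mean %.2f deg, var %.2f deg^2 (%s)\n",
              x$res_index, x$dof, length(x$dev_deg), x$mean_deg, x$var_deg2,
              x$policy))
  invisible(x)
}

#' Read and write angle series as delimited text
#'
#' The plain-text dialect used across the package: one tab-separated file per
#' residue/dof named `res<idx>_<dof>.tsv`, with columns `time_ns` and
#' `value_deg`. Pre-extracted series from any MD package can be dropped into a
#' directory in this form and analyzed without the trajectory.
#'
#' @param series An [angle_series] (for writing).
#' @param path File path.
#' @return `read_angle_series` returns an [angle_series];
#'   `write_angle_series` returns the path invisibly.
#' @export
write_angle_series <- function(series, path) {
  utils::write.table(
    data.frame(time_ns = series$times_ns, value_deg = series$angles_deg),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_angle_series
#' @param res_index,dof Identity of the series; if `NULL`, parsed from a
#'   `res<idx>_<dof>.tsv` file name.
#' @export
read_angle_series <- function(path, res_index = NULL, dof = NULL) {
  if (is.null(res_index) || is.null(dof)) {
    m <- regmatches(basename(path),
                    regexec("^res([0-9]+)_(phi|psi|chi1)\\.tsv$", basename(path)))[[1]]
    if (length(m) != 3L)
      stop("cannot parse residue/dof from file name '", basename(path),
           "'; pass res_index and dof explicitly")
    res_index <- as.integer(m[2]); dof <- m[3]
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_ns", "value_deg") %in% names(d)))
  angle_series(res_index, dof, d$time_ns, d$value_deg)
}

#' @rdname write_angle_series
#' @param series_list List of [angle_series].
#' @param dir Directory for the per-series files (created if needed).
#' @export
write_series_dir <- function(series_list, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in series_list)
    write_angle_series(s, file.path(dir, sprintf("res%d_%s.tsv", s$res_index, s$dof)))
  invisible(dir)
}

#' @rdname write_angle_series
#' @export
read_series_dir <- function(dir) {
  files <- list.files(dir, pattern = "^res[0-9]+_(phi|psi|chi1)\\.tsv$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no res<idx>_<dof>.tsv files in ", dir)
  out <- lapply(files, read_angle_series)
  names(out) <- vapply(out, function(s) sprintf("res%d_%s", s$res_index, s$dof), "")
  out
}

#' Tidy table of a set of angle series
#'
#' @param series_list List of [angle_series].
#' @return Long data frame with columns res_index, dof, time_ns, value_deg.
#' @export
series_table <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(res_index = s$res_index, dof = s$dof,
               time_ns = s$times_ns, value_deg = s$angles_deg)))
}
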