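#' Planted coupling topologies
#'
#' Helpers building edge tables for [make_system()]: a directed chain
#' `1 -> 2 -> ... -> k` and a star (one hub driving spokes). Strengths are
#' coupling rates in 1/ns; a directed (non-reciprocal) topology is always
#' stable because the assembled relaxation matrix stays triangular.
#'
#' @param residues Residue indices in chain order.
#' @param dof Dof label carrying the coupling.
#' @param strength Coupling rate (1/ns) per edge, recycled.
#' @return Data frame with columns from_res, from_dof, to_res, to_dof,
#'   strength.
#' @export
chain_edges <- function(residues, dof = "phi", strength = 0.6) {
  k <- length(residues)
  stopifnot(k >= 2L)
  data.frame(from_res = residues[-k], from_dof = dof,
             to_res = residues[-1], to_dof = dof,
             strength = rep_len(strength, k - 1L))
}

#' @rdname chain_edges
#' @param hub Driving residue.
#' @param spokes Driven residues.
#' @export
star_edges <- function(hub, spokes, dof = "phi", strength = 0.6) {
  data.frame(from_res = hub, from_dof = dof, to_res = spokes, to_dof = dof,
             strength = rep_len(strength, length(spokes)))
}

#' Assemble a synthetic protein with a planted coupling network
#'
#' Builds a whole synthetic "protein": `n_res` residues with coarse 3-D
#' backbone positions laid along a gentle chain-like curve (so the spatially
#' closest residue of any residue is its sequence neighbour), a dihedral dof
#' set per residue, and a multivariate stationary linear (Ornstein-Uhlenbeck)
#' dynamics block-assembled from single-dof relaxers on the diagonal plus the
#' planted directed couplings. The ground-truth edge list is retained in the
#' object. Stands in for an undeposited MD trajectory by emulating its
#' statistical structure: stationary nanosecond-scale correlated dihedral
#' series plus residue geometry with controllable positional jitter.
#'
#' @param n_res Number of residues.
#' @param edges Planted directed couplings (see [chain_edges()]); `NULL` for a
#'   fully independent system.
#' @param dofs Dof labels generated for every residue.
#' @param tau_ns Marginal relaxation times (ns) per variable, recycled; `NULL`
#'   draws them uniformly from 2-20 ns under `seed`.
#' @param sd_deg Stationary standard deviation (degrees) of each uncoupled
#'   dof; the default 25 degrees keeps the dynamics in the small-angle regime
#'   where circular wrapping is inert. `amplitude = "wrap-stress"` instead
#'   uses 80 degrees with means near the branch cut, to stress the circular
#'   statistics path.
#' @param jitter_nm Positional jitter amplitude (nm, per-frame Gaussian sd).
#'   With `jitter_mode = "by-coupling"`, residues touched by an edge get
#'   0.3x this and uncoupled residues 3x, so correlation amplitude clusters
#'   at low distance variance.
#' @param jitter_mode `"uniform"` or `"by-coupling"`.
#' @param amplitude `"small"` or `"wrap-stress"`.
#' @param seed Integer seed; the same seed reproduces the identical system.
#' @return Object of class `synth_system`.
#' @export
make_system <- function(n_res, edges = NULL, dofs = "phi", tau_ns = NULL,
                        sd_deg = NULL, jitter_nm = 0.02,
                        jitter_mode = c("uniform", "by-coupling"),
                        amplitude = c("small", "wrap-stress"), seed = 1L) {
  jitter_mode <- match.arg(jitter_mode)
  amplitude <- match.arg(amplitude)
  stopifnot(n_res >= 1L)
  dofs <- match.arg(dofs, c("phi", "psi", "chi1"), several.ok = TRUE)
  vars <- expand.grid(dof = dofs, res = seq_len(n_res),
                      stringsAsFactors = FALSE)[, 2:1]
  vars <- data.frame(res = vars$res, dof = vars$dof, idx = seq_len(nrow(vars)))
  n_var <- nrow(vars)
  set.seed(seed)
  if (is.null(sd_deg)) sd_deg <- if (amplitude == "wrap-stress") 80 else 25
  tau <- if (is.null(tau_ns)) stats::runif(n_var, 2, 20)
         else rep_len(tau_ns, n_var)
  sdv <- rep_len(sd_deg, n_var)
  A <- diag(-1 / tau, n_var)
  D <- diag(2 * sdv^2 / tau, n_var)
  if (!is.null(edges) && nrow(edges)) {
    vi <- function(r, d) {
      k <- vars$idx[vars$res == r & vars$dof == d]
      if (length(k) != 1L) stop("edge references unknown dof (res ", r, " ", d, ")")
      k
    }
    for (e in seq_len(nrow(edges)))
      A[vi(edges$to_res[e], edges$to_dof[e]),
        vi(edges$from_res[e], edges$from_dof[e])] <-
        A[vi(edges$to_res[e], edges$to_dof[e]),
          vi(edges$from_res[e], edges$from_dof[e])] + edges$strength[e]
    # reciprocal couplings can destabilize; rescale off-diagonals until stable
    tries <- 0L
    while (any(Re(eigen(A, only.values = TRUE)$values) >= 0)) {
      tries <- tries + 1L
      if (tries > 20L) stop("planted topology cannot be stabilized")
      off <- A - diag(diag(A))
      A <- diag(diag(A)) + 0.8 * off
    }
    if (tries > 0L)
      warning(sprintf("couplings rescaled by %.3g to restore stability", 0.8^tries))
    # couplings amplify downstream variances; rescale the variables
    # (similarity transform, Pearson correlations and timescales invariant)
    # so every stationary sd stays at sd_deg -- the small-angle regime
    S <- stationary_covariance(A, D)
    cs <- sdv / sqrt(diag(S))
    A <- diag(cs) %*% A %*% diag(1 / cs)
    D <- diag(cs) %*% D %*% diag(cs)
  }
  Sigma <- stationary_covariance(A, D)
  i_seq <- seq_len(n_res)
  positions <- cbind(0.38 * i_seq, 0.45 * sin(i_seq / 2), 0.30 * cos(i_seq / 3))
  cb_dir <- cbind(0, cos(i_seq), sin(i_seq))
  cb_offset <- 0.153 * cb_dir / sqrt(rowSums(cb_dir^2))
  coupled <- if (is.null(edges)) integer(0) else unique(c(edges$from_res, edges$to_res))
  jit <- rep_len(jitter_nm, n_res)
  if (jitter_mode == "by-coupling") {
    jit <- ifelse(i_seq %in% coupled, 0.3 * jitter_nm, 3 * jitter_nm)
  }
  mean_deg <- if (amplitude == "wrap-stress") {
    stats::runif(n_var, 150, 210)          # near the branch cut, wraps often
  } else {
    c(phi = -65, psi = -40, chi1 = 60)[vars$dof]
  }
  structure(
    list(n_res = n_res, vars = vars, A = A, D = D, Sigma = Sigma,
         tau_ns = tau, sd_deg = sdv, mean_deg = unname(mean_deg),
         positions = positions, cb_offset = cb_offset, jitter_nm = jit,
         edges = edges, dofs = dofs, amplitude = amplitude,
         jitter_mode = jitter_mode, seed = seed),
    class = "synth_system")
}

#' @export
print.synth_system <- function(x, ...) {
  cat(sprintf("synth_system: %d residues x {%s}, %d planted edges, seed %d\n",
              x$n_res, paste(x$dofs, collapse = ","),
              if (is.null(x$edges)) 0L else nrow(x$edges), x$seed))
  invisible(x)
}

#' Generate synthetic dihedral series and residue positions
#'
#' Integrates the system's multivariate dynamics by Euler-Maruyama (shared
#' engine with [simulate_oscillators()]; stationary initialization, ten
#' slowest relaxation times of burn-in discarded) and emits one
#' [angle_series] per residue/dof plus per-frame residue positions
#' (base + seeded isotropic Gaussian jitter), so distance statistics with
#' controlled variance are available alongside the angle series.
#'
#' @param sys A `synth_system`.
#' @param length_ns Trajectory length after burn-in.
#' @param dt_ns Sampling step; must resolve the fastest mode.
#' @param seed Integer seed.
#' @param positions Whether to generate per-frame positions (needed for
#'   distance statistics).
#' @return Object of class `synth_data`: `series` (named
#'   `res<idx>_<dof>` list), `sys`, `dt_ns`, and if requested `ca_pos` /
#'   `cb_pos` arrays (frames x residues x 3, nm).
#' @export
generate_synthetic <- function(sys, length_ns, dt_ns, seed = 1L,
                               positions = TRUE) {
  n_steps <- floor(length_ns / dt_ns)
  stopifnot(n_steps >= 10L)
  X <- sim_ou(sys$A, sys$D, n_steps, dt_ns, seed = seed)
  times <- seq(0, by = dt_ns, length.out = n_steps)
  series <- vector("list", nrow(sys$vars))
  names(series) <- sprintf("res%d_%s", sys$vars$res, sys$vars$dof)
  for (k in seq_len(nrow(sys$vars)))
    series[[k]] <- angle_series(sys$vars$res[k], sys$vars$dof[k], times,
                                wrap_angle(X[, k] + sys$mean_deg[k]))
  out <- list(series = series, sys = sys, dt_ns = dt_ns, n_frames = n_steps)
  if (positions) {
    ca <- array(0, c(n_steps, sys$n_res, 3))
    cb <- array(0, c(n_steps, sys$n_res, 3))
    for (r in seq_len(sys$n_res)) {
      jr <- matrix(stats::rnorm(n_steps * 3, sd = sys$jitter_nm[r]), n_steps, 3)
      ca[, r, ] <- rep(sys$positions[r, ], each = n_steps) + jr
      jb <- matrix(stats::rnorm(n_steps * 3, sd = sys$jitter_nm[r]), n_steps, 3)
      cb[, r, ] <- rep(sys$positions[r, ] + sys$cb_offset[r, ], each = n_steps) + jb
    }
    out$ca_pos <- ca; out$cb_pos <- cb
  }
  structure(out, class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("synth_data: %d series x %d frames (dt = %g ns)%s\n",
              length(x$series), x$n_frames, x$dt_ns,
              if (is.null(x$ca_pos)) "" else ", with positions"))
  invisible(x)
}

#' @export
distance_stats.synth_data <- function(x, i, j,
                                      kind = c("alpha-alpha", "alpha-beta", "beta-beta"),
                                      first_frame = 1L, ...) {
  kind <- match.arg(kind)
  if (is.null(x$ca_pos)) stop("synthetic data was generated without positions")
  pi_ <- switch(kind, "alpha-alpha" = x$ca_pos[, i, ],
                "alpha-beta" = x$ca_pos[, i, ], "beta-beta" = x$cb_pos[, i, ])
  pj <- switch(kind, "alpha-alpha" = x$ca_pos[, j, ],
               "alpha-beta" = x$cb_pos[, j, ], "beta-beta" = x$cb_pos[, j, ])
  keep <- seq(first_frame, x$n_frames)
  d <- sqrt(rowSums((pi_[keep, , drop = FALSE] - pj[keep, , drop = FALSE])^2))
  structure(list(i = i, j = j, kind = kind, mean_nm = mean(d),
                 var_nm2 = stats::var(d), n_frames = length(d)),
            class = "distance_stats")
}

#' Write the ground truth of a synthetic system as JSON
#'
#' Emits the planted edge list, per-variable relaxation times and the seed,
#' for use by external test harnesses alongside series written with
#' [write_series_dir()].
#'
#' @param sys A `synth_system`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(sys, path) {
  jsonlite::write_json(
    list(n_res = sys$n_res, dofs = sys$dofs, seed = sys$seed,
         tau_ns = sys$tau_ns, sd_deg = sys$sd_deg,
         jitter_nm = sys$jitter_nm,
         edges = sys$edges %||% data.frame()),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
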