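# shared fixtures: ideal-geometry peptides, rotations, closed-form curves

# Rodrigues rotation of point p about the axis through axis0 -> axis1, degrees
rotate_about <- function(p, axis0, axis1, ang_deg) {
  u <- axis1 - axis0
  u <- u / sqrt(sum(u^2))
  a <- ang_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  as.vector(R %*% (p - axis0)) + axis0
}

# small peptide with idealized coordinates (nm); residue types chosen to
# exercise the chi1 contract (LEU has CG, ALA/GLY do not)
peptide_atoms <- function(resids = c("ALA", "LEU", "GLY")) {
  rows <- list()
  add <- function(res, resid, elety, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      elety = elety, resid = resid, chain = "A", resno = res, res_index = res,
      x = xyz[1], y = xyz[2], z = xyz[3])
  }
  for (k in seq_along(resids)) {
    x0 <- 0.4 * (k - 1)
    add(k, resids[k], "N",  c(x0 + 0.00, 0.00, 0))
    add(k, resids[k], "CA", c(x0 + 0.15, 0.10, 0))
    add(k, resids[k], "C",  c(x0 + 0.30, 0.00, 0))
    add(k, resids[k], "O",  c(x0 + 0.30, -0.12, 0.05))
    if (resids[k] != "GLY") add(k, resids[k], "CB", c(x0 + 0.15, 0.20, 0.12))
    if (resids[k] == "LEU") add(k, resids[k], "CG", c(x0 + 0.25, 0.30, 0.20))
  }
  do.call(rbind, rows)
}

atom_xyz_of <- function(atoms, res, elety) {
  unlist(atoms[atoms$res_index == res & atoms$elety == elety,
               c("x", "y", "z")])
}

# trajectory that rotates all atoms of `move_res` about the axis
# axis_res:axis_from -> axis_res:axis_to by the given per-frame angles
rotating_trajectory <- function(atoms, move_res, axis_res, axis_from, axis_to,
                                angles_deg, dt_ns = 0.1, extra_move = NULL) {
  a0 <- atom_xyz_of(atoms, axis_res, axis_from)
  a1 <- atom_xyz_of(atoms, axis_res, axis_to)
  xyz <- matrix(0, length(angles_deg), 3L * nrow(atoms))
  for (f in seq_along(angles_deg)) {
    at <- atoms
    move <- at$res_index %in% move_res
    if (!is.null(extra_move)) move <- move | extra_move(at)
    for (i in which(move)) {
      p <- rotate_about(unlist(at[i, c("x", "y", "z")]), a0, a1, angles_deg[f])
      at$x[i] <- p[1]; at$y[i] <- p[2]; at$z[i] <- p[3]
    }
    xyz[f, ] <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  }
  trajectory(structure_from_atoms(atoms), xyz, dt_ns)
}

static_trajectory <- function(atoms, n_frames = 5L, dt_ns = 0.1) {
  xyz <- matrix(rep(as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                    each = n_frames), nrow = n_frames)
  trajectory(structure_from_atoms(atoms), xyz, dt_ns)
}

# wrap a sampled correlation function in the minimal tdcf_curve shape
fake_curve <- function(lag_ns, C) {
  structure(list(lag_ns = lag_ns, C = C, N_l = rev(seq_along(lag_ns)),
                 i = 1L, dof_i = "phi", j = 2L, dof_j = "phi",
                 direction = "forward", dt_ns = lag_ns[2] - lag_ns[1]),
            class = "tdcf_curve")
}

# angle_series from a plain numeric vector
series_of <- function(x, dt_ns = 0.1, res = 1L, dof = "phi") {
  angle_series(res, dof, seq(0, by = dt_ns, length.out = length(x)), x)
}

# random stable two-variable systems for property sweeps
random_stable_system <- function(seed) {
  set.seed(seed)
  tau <- stats::runif(2, 1, 50)
  repeat {
    alpha <- stats::runif(1, -0.8, 0.8) / tau[1]
    beta <- stats::runif(1, -0.8, 0.8) / tau[2]
    if (alpha * beta < 1 / (tau[1] * tau[2])) break
  }
  oscillator_from_times(tau[1], tau[2], alpha = alpha, beta = beta,
                        sd_i = stats::runif(1, 15, 35),
                        sd_j = stats::runif(1, 15, 35))
}
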