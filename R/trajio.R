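# chi1 terminal atom per residue type (IUPAC Cgamma-equivalent);
# Gly and Ala have no chi1.
CHI1_GAMMA <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", GLN = "CG", GLU = "CG", HIS = "CG",
  HSD = "CG", HSE = "CG", HSP = "CG", LEU = "CG", LYS = "CG", MET = "CG",
  PHE = "CG", PRO = "CG", TRP = "CG", TYR = "CG",
  ILE = "CG1", VAL = "CG1", SER = "OG", THR = "OG1", CYS = "SG")

#' Read a protein structure (PDB)
#'
#' Thin wrapper over [bio3d::read.pdb()] producing the package's structure
#' container: protein ATOM records with coordinates converted to nm and a
#' contiguous 1-based internal residue index alongside the author (PDB)
#' numbering.
#'
#' @param path Path to a PDB file.
#' @return Object of class `tdcf_structure`: `atoms` (data frame with `elety`,
#'   `resid`, `chain`, `resno`, `res_index`, `x`, `y`, `z` in nm), `n_res`,
#'   and `residues`, the residue index/numbering map.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  key <- paste(a$chain, a$resno, a$insert %||% "")
  res_index <- match(key, unique(key))
  atoms <- data.frame(
    elety = a$elety, resid = a$resid, chain = a$chain, resno = a$resno,
    res_index = res_index,
    x = a$x / 10, y = a$y / 10, z = a$z / 10)   # angstrom -> nm
  structure_from_atoms(atoms)
}

#' @rdname read_structure
#' @param atoms Data frame with columns `elety`, `resid`, `chain`, `resno`,
#'   `res_index`, `x`, `y`, `z` (nm); used to build structures in code
#'   (synthetic peptides, tests).
#' @export
structure_from_atoms <- function(atoms) {
  need <- c("elety", "resid", "chain", "resno", "res_index", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  residues <- unique(atoms[, c("res_index", "resno", "resid", "chain")])
  residues <- residues[order(residues$res_index), ]
  structure(list(atoms = atoms, n_res = nrow(residues), residues = residues),
            class = "tdcf_structure")
}

#' @export
print.tdcf_structure <- function(x, ...) {
  cat(sprintf("tdcf_structure: %d residues, %d atoms\n", x$n_res, nrow(x$atoms)))
  invisible(x)
}

#' Trajectory container
#'
#' A reference structure plus per-frame coordinates on a uniform time grid.
#' `read_trajectory` reads coordinates from a DCD file via
#' [bio3d::read.dcd()]; frame times are not stored in DCD, so the frame
#' spacing must be supplied. Pre-extracted angle series in delimited text
#' (see [read_series_dir()]) are the alternative input route.
#'
#' @param struct A `tdcf_structure`.
#' @param xyz Numeric matrix, frames x (3 * n_atoms), in nm, atom order as in
#'   `struct$atoms`.
#' @param dt_ns Frame spacing in ns (> 0).
#' @param t0_ns Time of the first frame.
#' @return Object of class `tdcf_trajectory`.
#' @export
trajectory <- function(struct, xyz, dt_ns, t0_ns = 0) {
  stopifnot(inherits(struct, "tdcf_structure"), dt_ns > 0,
            ncol(xyz) == 3L * nrow(struct$atoms), nrow(xyz) >= 2L)
  structure(
    list(structure = struct, xyz = xyz, dt_ns = dt_ns,
         times_ns = t0_ns + (seq_len(nrow(xyz)) - 1L) * dt_ns),
    class = "tdcf_trajectory")
}

#' @rdname trajectory
#' @param pdb_path Topology/reference PDB.
#' @param dcd_path DCD coordinate file (same atom order and count as the PDB's
#'   protein ATOM records).
#' @export
read_trajectory <- function(pdb_path, dcd_path, dt_ns, t0_ns = 0) {
  struct <- read_structure(pdb_path)
  xyz <- bio3d::read.dcd(dcd_path, verbose = FALSE)
  if (ncol(xyz) != 3L * nrow(struct$atoms))
    stop(sprintf("DCD has %d atoms but the PDB has %d protein atoms",
                 ncol(xyz) / 3, nrow(struct$atoms)))
  trajectory(struct, xyz / 10, dt_ns, t0_ns)   # angstrom -> nm
}

#' @export
print.tdcf_trajectory <- function(x, ...) {
  cat(sprintf("tdcf_trajectory: %d frames, dt = %g ns, %d residues\n",
              nrow(x$xyz), x$dt_ns, x$structure$n_res))
  invisible(x)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed torsion for stacked coordinates (n x 3 matrices), degrees in (-180, 180]
dihedral_xyz <- function(m1, m2, m3, m4, labels = c("p1", "p2", "p3", "p4")) {
  b1 <- m2 - m1; b2 <- m3 - m2; b3 <- m4 - m3
  eps <- 1e-10
  if (any(rowSums(b1^2) < eps^2) || any(rowSums(b2^2) < eps^2) ||
      any(rowSums(b3^2) < eps^2))
    stop_tdcf("degenerate geometry: coincident points among %s",
              paste(labels, collapse = "-"), class = "tdcf_degenerate")
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  if (any(rowSums(n1^2) < eps^2) || any(rowSums(n2^2) < eps^2))
    stop_tdcf("degenerate geometry: collinear triple among %s",
              paste(labels, collapse = "-"), class = "tdcf_degenerate")
  u2 <- b2 / sqrt(rowSums(b2^2))
  y <- rowSums(row_cross(n1, n2) * u2)
  x <- rowSums(n1 * n2)
  wrap_angle(unname(atan2(y, x)) * 180 / pi)
}

#' Signed dihedral angle of four points
#'
#' The torsion about the p2-p3 axis for four consecutive atoms, signed by the
#' standard IUPAC right-hand convention (viewed from p2 toward p3, clockwise
#' rotation of the far bond relative to the near bond is positive), in degrees
#' on (-180, +180]. Coplanar cis gives 0, coplanar trans gives 180. Coincident
#' points or a collinear triple raise a degenerate-geometry error naming the
#' atoms.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinates.
#' @param labels Atom names used in error messages.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4, labels = c("p1", "p2", "p3", "p4")) {
  dihedral_xyz(rbind(p1), rbind(p2), rbind(p3), rbind(p4), labels)
}

# atom quadruple (res_index, elety) defining a dof, with contract checks
dof_quadruple <- function(struct, residue, dof) {
  res <- struct$residues
  row <- res[res$res_index == residue, ]
  if (nrow(row) == 0L) stop("residue index ", residue, " not in structure")
  if (dof == "phi") {
    if (residue == min(res$res_index))
      stop_tdcf("phi undefined for the first residue (%d): no C of residue i-1",
                residue, class = "tdcf_undefined_dof")
    list(res = c(residue - 1L, residue, residue, residue),
         atom = c("C", "N", "CA", "C"))
  } else if (dof == "psi") {
    if (residue == max(res$res_index))
      stop_tdcf("psi undefined for the last residue (%d): no N of residue i+1",
                residue, class = "tdcf_undefined_dof")
    list(res = c(residue, residue, residue, residue + 1L),
         atom = c("N", "CA", "C", "N"))
  } else if (dof == "chi1") {
      gamma <- unname(CHI1_GAMMA[row$resid])
    if (is.na(gamma))
      stop_tdcf("chi1 undefined for residue %d (%s): no Cgamma-equivalent atom",
                residue, row$resid, class = "tdcf_undefined_dof")
    list(res = c(residue, residue, residue, residue),
         atom = c("N", "CA", "CB", gamma))
  } else stop("unknown dof '", dof, "'")
}

atom_row <- function(struct, residue, elety) {
  i <- which(struct$atoms$res_index == residue & struct$atoms$elety == elety)
  if (length(i) == 0L)
    stop_tdcf("residue %d has no atom %s", residue, elety,
              class = "tdcf_missing_atom")
  i[1]
}

# frames x 3 coordinate block of one atom
atom_frames <- function(traj, atom_idx) {
  traj$xyz[, (3L * (atom_idx - 1L) + 1L):(3L * atom_idx), drop = FALSE]
}

#' Extract a dihedral angle time series from a trajectory
#'
#' Computes one dihedral (phi: C(i-1)-N-CA-C, psi: N-CA-C-N(i+1), chi1:
#' N-CA-CB-Cgamma with the IUPAC gamma-equivalent per residue type) for every
#' frame at or after `first_frame`. Undefined dofs (phi of the first residue,
#' psi of the last, chi1 of Gly/Ala) raise an undefined-dof error rather than
#' being silently omitted.
#'
#' @param traj A `tdcf_trajectory`.
#' @param residue 1-based residue index.
#' @param dof `"phi"`, `"psi"` or `"chi1"`.
#' @param first_frame First frame to keep (burn-in handling; see
#'   [backbone_rmsd_burnin()]).
#' @return An [angle_series].
#' @export
extract_series <- function(traj, residue, dof = c("phi", "psi", "chi1"),
                           first_frame = 1L) {
  dof <- match.arg(dof)
  struct <- traj$structure
  q <- dof_quadruple(struct, residue, dof)
  idx <- mapply(atom_row, q$res, q$atom, MoreArgs = list(struct = struct))
  keep <- seq(first_frame, nrow(traj$xyz))
  labels <- sprintf("res%d:%s", q$res, q$atom)
  sub <- function(k) atom_frames(traj, idx[k])[keep, , drop = FALSE]
  ang <- dihedral_xyz(sub(1), sub(2), sub(3), sub(4), labels)
  angle_series(residue, dof, traj$times_ns[keep], ang)
}

#' @rdname extract_series
#' @param dofs Dof labels to attempt for every residue; undefined combinations
#'   are skipped (they are only an error when requested singly).
#' @export
extract_all_series <- function(traj, dofs = c("phi", "psi", "chi1"),
                               first_frame = 1L) {
  out <- list()
  for (r in traj$structure$residues$res_index) {
    for (dof in dofs) {
      s <- tryCatch(extract_series(traj, r, dof, first_frame),
                    tdcf_undefined_dof = function(e) NULL,
                    tdcf_missing_atom = function(e) NULL)
      if (!is.null(s)) out[[sprintf("res%d_%s", r, dof)]] <- s
    }
  }
  out
}

#' Equilibration detection from a backbone RMSD profile
#'
#' `detect_burnin` operates on any RMSD series: it computes the moving-window
#' mean and returns the smallest frame index after which the window mean never
#' again changes by `tol` or more per window (saturation). If the profile
#' never saturates, a no-equilibration warning is raised and the trajectory
#' start is returned with `equilibrated = FALSE`. `backbone_rmsd_burnin`
#' builds the profile from a trajectory: each frame's backbone (N, CA, C, O)
#' is superposed on the reference frame by optimal rigid-body fitting
#' ([bio3d::fit.xyz()]) before the deviation is measured.
#'
#' @param rmsd Numeric RMSD per frame (nm).
#' @param window Window length in frames.
#' @param tol Saturation tolerance (nm per window).
#' @return List with `index` (first equilibrated frame, 1-based),
#'   `equilibrated` flag and the `rmsd` profile.
#' @export
detect_burnin <- function(rmsd, window, tol) {
  n <- length(rmsd)
  stopifnot(window >= 1L, n >= 2L * window)
  wm <- stats::filter(rmsd, rep(1 / window, window), sides = 1)
  wm <- wm[!is.na(wm)]                     # window means ending at frames window..n
  k <- length(wm) - window
  if (k < 1L) return(list(index = 1L, equilibrated = TRUE, rmsd = rmsd))
  d <- abs(wm[(window + 1):(window + k)] - wm[1:k])  # change over one window
  ok <- rev(cumprod(rev(d < tol))) == 1    # TRUE where all later diffs small
  if (!any(ok)) {
    warning("backbone RMSD never saturates; using the trajectory start")
    return(list(index = 1L, equilibrated = FALSE, rmsd = rmsd))
  }
  list(index = which(ok)[1], equilibrated = TRUE, rmsd = rmsd)
}

#' @rdname detect_burnin
#' @param traj A `tdcf_trajectory`.
#' @export
backbone_rmsd_burnin <- function(traj, window, tol) {
  at <- traj$structure$atoms
  bb <- which(at$elety %in% c("N", "CA", "C", "O"))
  inds <- as.vector(t(outer(bb - 1L, 1:3, function(a, k) 3L * a + k)))
  ref <- traj$xyz[1, ]
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = traj$xyz,
                           fixed.inds = inds, mobile.inds = inds)
  r <- bio3d::rmsd(ref, fitted, a.inds = inds, b.inds = inds, fit = FALSE)
  detect_burnin(r, window, tol)
}

#' @rdname detect_burnin
#' @param fraction Leading fraction of frames to drop when RMSD-based
#'   detection is not requested (default 5%, mirroring dropping 50 ns of a
#'   1.05 us run).
#' @export
burnin_fraction <- function(traj, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 1)
  as.integer(floor(fraction * nrow(traj$xyz))) + 1L
}

#' Inter-residue distance statistics
#'
#' Mean and variance of the distance between two residues over the analyzed
#' frames: Ca-Ca (`"alpha-alpha"`, the backbone separation used for path
#' construction), Ca(i)-Cb(j) (`"alpha-beta"`) or Cb-Cb (`"beta-beta"`,
#' undefined for Gly which has no Cb). A generic: methods exist for
#' trajectories and for [generate_synthetic()] output.
#'
#' @param x A `tdcf_trajectory` or `synth_data` object.
#' @param i,j Residue indices.
#' @param kind Distance kind.
#' @param first_frame First frame included.
#' @param ... Passed to methods.
#' @return List (class `distance_stats`) with `i`, `j`, `kind`, `mean_nm`,
#'   `var_nm2`, `n_frames`.
#' @export
distance_stats <- function(x, i, j, kind = c("alpha-alpha", "alpha-beta", "beta-beta"),
                           first_frame = 1L, ...) {
  UseMethod("distance_stats")
}

#' @export
distance_stats.tdcf_trajectory <- function(x, i, j,
                                           kind = c("alpha-alpha", "alpha-beta", "beta-beta"),
                                           first_frame = 1L, ...) {
  kind <- match.arg(kind)
  at <- switch(kind, "alpha-alpha" = c("CA", "CA"),
               "alpha-beta" = c("CA", "CB"), "beta-beta" = c("CB", "CB"))
  ai <- tryCatch(atom_row(x$structure, i, at[1]), tdcf_missing_atom = function(e)
    stop_tdcf("distance kind %s undefined: residue %d has no %s", kind, i, at[1],
              class = "tdcf_undefined_kind"))
  aj <- tryCatch(atom_row(x$structure, j, at[2]), tdcf_missing_atom = function(e)
    stop_tdcf("distance kind %s undefined: residue %d has no %s", kind, j, at[2],
              class = "tdcf_undefined_kind"))
  keep <- seq(first_frame, nrow(x$xyz))
  d <- sqrt(rowSums((atom_frames(x, ai)[keep, , drop = FALSE] -
                     atom_frames(x, aj)[keep, , drop = FALSE])^2))
  structure(list(i = i, j = j, kind = kind, mean_nm = mean(d),
                 var_nm2 = stats::var(d), n_frames = length(d)),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("distance_stats: %d-%d %s, mean %.3f nm, var %.3g nm^2 (%d frames)\n",
              x$i, x$j, x$kind, x$mean_nm, x$var_nm2, x$n_frames))
  invisible(x)
}

#' Crystal-structure distance between two residues
#'
#' Single-conformation counterpart of [distance_stats()], evaluated on a
#' structure (e.g. the crystal reference).
#'
#' @inheritParams distance_stats
#' @param struct A `tdcf_structure`.
#' @return Distance in nm.
#' @export
crystal_distance <- function(struct, i, j,
                             kind = c("alpha-alpha", "alpha-beta", "beta-beta")) {
  kind <- match.arg(kind)
  at <- switch(kind, "alpha-alpha" = c("CA", "CA"),
               "alpha-beta" = c("CA", "CB"), "beta-beta" = c("CB", "CB"))
  pi_ <- unlist(struct$atoms[atom_row(struct, i, at[1]), c("x", "y", "z")])
  pj <- unlist(struct$atoms[atom_row(struct, j, at[2]), c("x", "y", "z")])
  sqrt(sum((pi_ - pj)^2))
}

#' Tidy distance table over residue pairs
#'
#' @param x Object with a [distance_stats()] method.
#' @param pairs Two-column matrix or data frame of residue index pairs.
#' @param kind Distance kind, recycled over pairs.
#' @param ... Passed to [distance_stats()].
#' @return Data frame with columns i, j, kind, mean_nm, var_nm2.
#' @export
distance_table <- function(x, pairs, kind = "alpha-alpha", ...) {
  pairs <- as.matrix(pairs)
  kind <- rep_len(kind, nrow(pairs))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    ds <- distance_stats(x, pairs[k, 1], pairs[k, 2], kind[k], ...)
    data.frame(i = ds$i, j = ds$j, kind = ds$kind,
               mean_nm = ds$mean_nm, var_nm2 = ds$var_nm2)
  }))
}
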