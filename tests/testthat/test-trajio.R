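test_that("dihedral_angle reproduces reference geometries and the bio3d convention", {
  # coplanar cis and trans
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1.5, 0)), 0)
  expect_equal(dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)), 180)
  # constructed 60-degree geometry: p4 rotated counterclockwise seen from p2
  # toward p3, which is negative under the IUPAC right-hand convention
  g <- 60 * pi / 180
  ang <- dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(cos(g), 1, sin(g)))
  expect_equal(ang, -60)
  expect_equal(bio3d::torsion.xyz(c(1, 0, 0, 0, 0, 0, 0, 1, 0, cos(g), 1, sin(g))),
               ang, ignore_attr = TRUE, tolerance = 1e-8)
  # agreement with bio3d on random quadruples
  set.seed(4)
  for (k in 1:20) {
    q <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                 bio3d::torsion.xyz(as.vector(t(q))),
                 ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("dihedral_angle is invariant under rigid motions, reversal-symmetric, and mirror-antisymmetric", {
  set.seed(11)
  for (k in 1:25) {
    q <- matrix(rnorm(12), 4, 3)
    a0 <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    # random rotation (QR of a random matrix) + translation
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tr <- rnorm(3)
    qm <- t(R %*% t(q)) + rep(tr, each = 4)
    expect_equal(dihedral_angle(qm[1, ], qm[2, ], qm[3, ], qm[4, ]), a0,
                 tolerance = 1e-9)
    # reversal symmetry
    expect_equal(dihedral_angle(q[4, ], q[3, ], q[2, ], q[1, ]), a0,
                 tolerance = 1e-9)
    # mirror antisymmetry (negate one axis)
    qn <- q; qn[, 3] <- -qn[, 3]
    expect_equal(dihedral_angle(qn[1, ], qn[2, ], qn[3, ], qn[4, ]), -a0,
                 tolerance = 1e-9)
  }
})

test_that("degenerate dihedral geometry raises a naming error", {
  p <- c(0, 0, 0)
  expect_error(dihedral_angle(p, p, c(0, 1, 0), c(1, 1, 0), labels = c("A", "B", "C", "D")),
               "A-B-C-D", class = "tdcf_degenerate")
  # collinear triple
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               class = "tdcf_degenerate")
})

test_that("extract_series reproduces planted rotation increments and enforces dof contracts", {
  atoms <- peptide_atoms()
  incs <- seq(0, 57, by = 3)
  # rotate residue 3 about the CA2-C2 axis: changes psi of residue 2 by the
  # same increments (modulo branch wrapping)
  tr <- rotating_trajectory(atoms, move_res = 3, axis_res = 2,
                            axis_from = "CA", axis_to = "C", angles_deg = incs)
  ps <- extract_series(tr, 2, "psi")
  expect_length(ps$angles_deg, length(incs))
  expect_equal(wrap_angle(diff(ps$angles_deg)), diff(incs), tolerance = 1e-8)
  expect_true(all(ps$angles_deg > -180 & ps$angles_deg <= 180))

  expect_error(extract_series(tr, 1, "phi"), class = "tdcf_undefined_dof")
  expect_error(extract_series(tr, 3, "psi"), class = "tdcf_undefined_dof")
  expect_error(extract_series(tr, 1, "chi1"), class = "tdcf_undefined_dof")  # ALA
  expect_error(extract_series(tr, 3, "chi1"), class = "tdcf_undefined_dof")  # GLY

  # static trajectory -> constant series; LEU chi1 defined
  st <- static_trajectory(atoms, n_frames = 6)
  chi <- extract_series(st, 2, "chi1")
  expect_equal(diff(range(chi$angles_deg)), 0)

  all_s <- extract_all_series(st)
  expect_setequal(names(all_s),
                  c("res1_psi", "res2_phi", "res2_psi", "res2_chi1", "res3_phi"))
})

test_that("burn-in detection finds RMSD saturation and flags drift", {
  # static trajectory: zero RMSD everywhere -> first frame
  st <- static_trajectory(peptide_atoms(), n_frames = 12)
  b <- backbone_rmsd_burnin(st, window = 3, tol = 1e-6)
  expect_equal(b$index, 1L)
  expect_true(b$equilibrated)
  expect_equal(max(abs(b$rmsd)), 0, tolerance = 1e-9)

  # synthetic profile: ramps for k frames then constant
  k <- 40
  prof <- c(seq(0, 0.3, length.out = k), rep(0.3, 60))
  d <- detect_burnin(prof, window = 5, tol = 1e-4)
  expect_true(d$equilibrated)
  expect_gte(d$index, k - 10L)
  expect_lte(d$index, k + 6L)

  # monotone growth never saturates
  expect_warning(d2 <- detect_burnin(seq(0, 1, length.out = 80), window = 5,
                                     tol = 1e-4),
                 "never saturates")
  expect_false(d2$equilibrated)
  expect_equal(d2$index, 1L)

  expect_equal(burnin_fraction(st, 0.05), 1L)
  expect_equal(burnin_fraction(st, 0.5), 7L)
})

test_that("distance statistics match the crystal value, a sinusoidal closed form, and brute force", {
  atoms <- peptide_atoms()
  st <- static_trajectory(atoms, n_frames = 5)
  ds <- distance_stats(st, 1, 2, "alpha-alpha")
  expect_equal(ds$var_nm2, 0, tolerance = 1e-12)
  expect_equal(ds$mean_nm, crystal_distance(st$structure, 1, 2, "alpha-alpha"))

  # residue 3 oscillating along the x axis: separation d0 + a sin, var -> a^2/2
  d0 <- atoms
  n <- 256L; amp <- 0.05
  ph <- 2 * pi * (0:(n - 1)) / n     # whole number of periods: exact moments
  xyz <- matrix(rep(as.vector(t(as.matrix(d0[, c("x", "y", "z")]))), each = n),
                nrow = n)
  ca3_col <- 3L * (which(d0$res_index == 3 & d0$elety == "CA") - 1L) + 1L
  xyz[, ca3_col] <- xyz[, ca3_col] + amp * sin(ph)
  tr <- trajectory(structure_from_atoms(d0), xyz, dt_ns = 0.1)
  ds2 <- distance_stats(tr, 1, 3, "alpha-alpha")
  base <- crystal_distance(tr$structure, 1, 3, "alpha-alpha")
  expect_equal(ds2$mean_nm, base, tolerance = 1e-2)
  expect_equal(ds2$var_nm2, amp^2 / 2, tolerance = 0.01)

  # brute-force recomputation over frames
  i1 <- which(d0$res_index == 1 & d0$elety == "CA")
  i3 <- which(d0$res_index == 3 & d0$elety == "CA")
  dd <- sapply(seq_len(n), function(f) {
    p1 <- xyz[f, (3 * (i1 - 1) + 1):(3 * i1)]
    p3 <- xyz[f, (3 * (i3 - 1) + 1):(3 * i3)]
    sqrt(sum((p1 - p3)^2))
  })
  expect_equal(ds2$mean_nm, mean(dd))
  expect_equal(ds2$var_nm2, var(dd))

  # beta-beta undefined for Gly
  expect_error(distance_stats(st, 1, 3, "beta-beta"), class = "tdcf_undefined_kind")
})

test_that("angle series survive a text round trip in the res<idx>_<dof>.tsv dialect", {
  dir <- withr::local_tempdir()
  s1 <- series_of(c(-170, 175, -165, 160, 150), res = 4L, dof = "chi1")
  s2 <- series_of(sin(1:40) * 30, res = 2L, dof = "phi")
  write_series_dir(list(s1, s2), dir)
  expect_setequal(list.files(dir), c("res4_chi1.tsv", "res2_phi.tsv"))
  back <- read_series_dir(dir)
  expect_equal(back$res4_chi1$angles_deg, s1$angles_deg)
  expect_equal(back$res2_phi$times_ns, s2$times_ns)
  expect_equal(back$res2_phi$dof, "phi")
  tb <- series_table(back)
  expect_equal(nrow(tb), 45L)
  expect_error(read_angle_series(file.path(dir, "nope.tsv")), "cannot parse")
})
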