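# Geometry optimization, internal coordinates, scans, constraints.

test_that("internal-coordinate measurements follow the stated conventions", {
  # right-angle triatomic with unit bonds (in Angstrom)
  A <- qed_constants$angstrom_per_bohr
  m <- molecule(c("O", "H", "H"),
                rbind(c(0, 0, 0), c(1 / A, 0, 0), c(0, 1 / A, 0)))
  ic <- measure_internals(m, list(bonds = list(c(1, 2), c(1, 3)),
                                  angles = list(c(2, 1, 3))))
  expect_equal(ic$bonds, c(1, 1), tolerance = 1e-10)
  expect_equal(ic$angles, 90, tolerance = 1e-8)

  # planar cis -> 0, trans -> 180
  frame <- function(last) molecule(c("C", "C", "C", "C"),
    rbind(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0), last))
  expect_equal(measure_internals(frame(c(2, 1, 0)),
    list(dihedrals = list(1:4)))$dihedrals, 0, tolerance = 1e-8)
  expect_equal(abs(measure_internals(frame(c(2, -1, 0)),
    list(dihedrals = list(1:4)))$dihedrals), 180, tolerance = 1e-8)

  # mirror reflection of the outer atom flips the sign
  twist <- molecule(c("C", "C", "C", "C"),
    rbind(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0), c(2, 0.3, 0.8)))
  mirr <- twist; mirr$xyz[4, 3] <- -mirr$xyz[4, 3]
  d1 <- measure_internals(twist, list(dihedrals = list(1:4)))$dihedrals
  d2 <- measure_internals(mirr, list(dihedrals = list(1:4)))$dihedrals
  expect_equal(d1, -d2, tolerance = 1e-10)
  expect_true(d1 > -180 && d1 <= 180)

  # collinear definitions are rejected
  lin <- molecule(c("C", "C", "C"), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(measure_internals(lin, list(angles = list(c(1, 1, 2)))),
               "coincident|undefined")
  lin4 <- molecule(c("C", "C", "C", "C"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(measure_internals(lin4, list(dihedrals = list(1:4))),
               "collinear")
})

test_that("field-free optimization converges below its thresholds", {
  res <- optimize_geometry(make_fixture("water"), minimal_basis())
  expect_true(res$converged)
  expect_lt(res$energy, res$trajectory[[1]]$energy)
  expect_lte(res$gradient$max_component, 4.5e-4 + 1e-12)
  # energy is monotonically non-increasing along accepted steps
  Es <- vapply(res$trajectory, `[[`, numeric(1), "energy")
  expect_true(all(diff(Es) <= 1e-12))
})

test_that("field-free optimized internals are invariant to initial orientation", {
  bas <- minimal_basis()
  defs <- list(bonds = list(c(1, 2)), angles = list(c(2, 1, 3)))
  r1 <- optimize_geometry(make_fixture("water"), bas)
  w2 <- qedhf:::rotate_molecule(make_fixture("water"), c(1, 0.5, -0.2), 53)
  w2 <- qedhf:::translate_molecule(w2, c(2, -1, 3))
  r2 <- optimize_geometry(w2, bas)
  i1 <- measure_internals(r1$molecule, defs)
  i2 <- measure_internals(r2$molecule, defs)
  expect_lt(abs(i1$bonds - i2$bonds), 1e-5)
  expect_lt(abs(i1$angles - i2$angles), 1e-3)
  expect_lt(abs(r1$energy - r2$energy), 1e-8)
})

test_that("rigid-rotation scans are flat without fields and periodic", {
  bas <- minimal_basis()
  w <- optimize_geometry(make_fixture("water"), bas)$molecule
  sc0 <- rigid_rotation_scan(w, bas, axis = "y", increment_deg = 60)
  expect_lt(diff(range(sc0$energy)), 1e-9)
  expect_lt(sc0$periodicity_error, 1e-9)
  expect_error(rigid_rotation_scan(w, bas, axis = c(0, 0, 0)), "zero-length")
})

test_that("H2 rotation scan in a cavity is 180-degree periodic", {
  bas <- minimal_basis()
  h2 <- make_fixture("h2")
  sc <- rigid_rotation_scan(h2, bas, axis = "x", increment_deg = 45,
                            fields = qed_mode_z(0.1))
  # centrosymmetric molecule: E(theta) = E(theta + 180)
  idx180 <- which(sc$grid == 180)
  shift <- sc$energy[idx180:(idx180 + 4)]
  expect_lt(max(abs(sc$energy[1:5] - shift)), 1e-9)
})

test_that("optimized orientation in a field matches the rigid-scan minimum", {
  bas <- minimal_basis()
  w <- optimize_geometry(make_fixture("water"), bas)$molecule
  fl <- field_config(E_ext = c(0, 0, 0.01))
  sc <- rigid_rotation_scan(w, bas, axis = "x", increment_deg = 15, fields = fl)
  best <- sc$grid[which.min(sc$energy)]
  # start from a clearly rotated geometry; optimization must rotate back
  w_rot <- qedhf:::rotate_molecule(w, c(1, 0, 0), 40,
                                   center = qedhf:::center_of_mass(w))
  res <- optimize_geometry(w_rot, bas, fl)
  mu <- res$state$energy_terms$dipole
  ang <- acos(sum(mu * c(0, 0, 1)) / sqrt(sum(mu^2))) * 180 / pi
  # scan minimum is at dipole parallel to +z (0 deg within one grid cell)
  expect_lte(min(abs(c(best, best - 360))), 15)
  expect_lte(ang, 15)
})

test_that("an inactive dihedral constraint reproduces the free optimum", {
  bas <- minimal_basis()
  free <- optimize_geometry(make_h2o2(), bas,
                            settings = opt_settings(grad_max = 2e-4,
                                                    grad_rms = 1.5e-4))
  expect_true(free$converged)
  dih <- measure_internals(free$molecule,
                           list(dihedrals = list(c(3, 1, 2, 4))))$dihedrals
  sc <- constrained_scan(free$molecule, bas, c(3, 1, 2, 4), dih,
                         settings = opt_settings(grad_max = 2e-4,
                                                 grad_rms = 1.5e-4))
  expect_lt(abs(sc$energy[1] - free$energy), 1e-8)
  # and the constraint is honoured to 0.01 deg
  dcheck <- measure_internals(sc$geometries[[1]],
                              list(dihedrals = list(c(3, 1, 2, 4))))$dihedrals
  expect_lt(abs(dcheck - dih), 0.01)
})

test_that("constrained scans hold the dihedral at each grid point", {
  bas <- minimal_basis()
  start <- make_h2o2()
  grid <- c(100, 115, 130)
  sc <- constrained_scan(start, bas, c(3, 1, 2, 4), grid,
                         settings = opt_settings(grad_max = 3e-4,
                                                 grad_rms = 2e-4))
  for (i in seq_along(grid)) {
    d <- measure_internals(sc$geometries[[i]],
                           list(dihedrals = list(c(3, 1, 2, 4))))$dihedrals
    expect_lt(abs(d - grid[i]), 0.01)
  }
  # adjacent energies differ by less than the scan's span (continuity)
  expect_true(all(abs(diff(sc$energy)) <= diff(range(sc$energy)) + 1e-15))
  expect_error(constrained_scan(start, bas, c(3, 1, 2, 4), c(1, 3, 2)),
               "monotone")
})

test_that("a single-point coupling sweep reduces to plain optimization", {
  bas <- minimal_basis()
  defs <- list(bonds = list(c(1, 2)), angles = list(c(2, 1, 3)))
  sw <- coupling_sweep(make_fixture("water"), bas, lambdas = 0,
                       definitions = defs)
  r <- optimize_geometry(make_fixture("water"), bas)
  expect_equal(sw$energy[1], r$energy, tolerance = 1e-8)
  expect_equal(unname(unlist(sw[1, c("delta_bonds", "delta_angles")])),
               c(0, 0))
})

test_that("frozen-coordinate constraints stay exactly frozen", {
  bas <- minimal_basis()
  amm <- make_fixture("ammonia")
  planar <- qedhf:::set_coords(amm, cbind(amm$xyz[, 1:2], 0))
  res <- optimize_geometry(planar, bas,
                           constraints = list(frozen = 3L * 1:4))
  expect_true(all(res$molecule$xyz[, 3] == 0))
})
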