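# QED-HF SCF: reduction to RHF, MO-basis oracles, self-energy properties,
# invariances.

test_that("a zero-coupling mode reproduces plain RHF bit for bit", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  s_plain <- scf_solve(mol, bas)
  s_zero <- scf_solve(mol, bas,
                      field_config(modes = list(cavity_mode(c(0, 0, 0), 0.5))))
  expect_identical(s_plain$E_total, s_zero$E_total)
  expect_identical(s_plain$D, s_zero$D)
  expect_identical(Re(s_plain$F), Re(s_zero$F))
  expect_length(s_zero$energy_terms$dipole_self_energy, 1L)
  expect_identical(s_zero$energy_terms$dipole_self_energy, 0)
})

test_that("converged states satisfy the density invariants", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  st <- scf_solve(mol, bas, qed_mode_z(0.08))
  S <- st$ints$S
  expect_equal(sum(st$D * t(S)), st$ints$nelec / 2, tolerance = 1e-10)
  expect_lt(max(abs(st$D %*% S %*% st$D - st$D)), 1e-7)    # DSD = D
  expect_lt(max(abs(st$F - t(st$F))), 1e-10)               # Hermitian
  expect_true(st$converged)
})

test_that("modified one-electron matrix matches the MO-basis expression", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  fl <- field_config(modes = list(cavity_mode(c(0.03, -0.02, 0.09), 0.7)))
  st <- scf_solve(mol, bas, fl)
  ints <- st$ints
  h_ao <- assemble_modified_oei(ints, st$D, fl)
  C <- st$C
  h_mo <- t(C) %*% h_ao %*% C
  # direct MO-basis evaluation of the same operator
  A_ao <- qedhf:::mode_matrices(ints, fl)[[1]]
  A_mo <- t(C) %*% A_ao %*% C
  avg <- 2 * sum(diag(A_mo[seq_len(st$nocc), seq_len(st$nocc), drop = FALSE]))
  he_mo <- t(C) %*% ints$h_e %*% C
  Ne <- ints$nelec
  h_ref <- he_mo + 0.5 * A_mo %*% A_mo - avg * A_mo +
    diag(avg^2 / (2 * Ne), nrow(h_mo))
  expect_lt(max(abs(h_mo - h_ref)), 1e-10)
})

test_that("all fields zero gives h = h_e exactly and doubling lambda quadruples the quadratic term", {
  mol <- make_fixture("water")
  ints <- integral_set(mol, minimal_basis())
  D <- diag(0, ints$n)
  expect_identical(assemble_modified_oei(ints, D, field_config()), ints$h_e)
  h1 <- assemble_modified_oei(ints, D, qed_mode_z(0.05)) - ints$h_e
  h2 <- assemble_modified_oei(ints, D, qed_mode_z(0.10)) - ints$h_e
  expect_lt(max(abs(h2 - 4 * h1)), 1e-12)   # with <A>=0 only the 1/2 A S^-1 A term
})

test_that("Fock matrix matches the brute-force double contraction of the modified integrals", {
  bas <- custom_basis(list(H = list(c(0, 1.3), c(0, 0.35), c(1, 0.8))))
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  fl <- field_config(modes = list(cavity_mode(c(0.04, 0, 0.07), 0.5)))
  ints <- integral_set(mol, bas)
  eri <- eri_screened(mol, bas, threshold = 0)
  st <- scf_solve(mol, bas, fl, ints = ints, eri = eri)
  D <- st$D
  h <- assemble_modified_oei(ints, D, fl)
  Fb <- fock_build(D, h, eri, ints, fl)
  # brute force: g_uvrs = g_e + A_uv A_rs contracted per the direct formula
  ge <- qedhf:::eri_dense(mol, bas)
  A <- qedhf:::mode_matrices(ints, fl)[[1]]
  n <- ints$n
  Fref <- h
  for (u in 1:n) for (v in 1:n) {
    acc <- 0
    for (r in 1:n) for (s in 1:n) {
      g_uvrs <- ge[u, v, r, s] + A[u, v] * A[r, s]
      g_usrv <- ge[u, s, r, v] + A[u, s] * A[r, v]
      acc <- acc + D[r, s] * (2 * g_uvrs - g_usrv)
    }
    Fref[u, v] <- Fref[u, v] + acc
  }
  expect_lt(max(abs(Fb - Fref)), 1e-10)
  # D = 0 gives F = h; lambda = 0 gives the standard closed-shell Fock
  expect_identical(fock_build(D * 0, h, eri, ints, fl), h)
})

test_that("dipole self-energy equals the explicit variance and is non-negative", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  lam <- c(0, 0, 0.05)
  st <- scf_solve(mol, bas, field_config(modes = list(cavity_mode(lam, 0.5))))
  ints <- st$ints
  A <- qedhf:::mode_matrices(ints, st$fields)[[1]]
  D <- st$D
  # variance oracle: 1/2 lam^2 (<d^2> - <d>^2) via explicit AO contraction
  var_o <- 2 * sum(diag(D %*% A %*% (ints$Sinv - D) %*% A))
  dse <- st$energy_terms$dipole_self_energy
  expect_equal(dse, var_o / 2, tolerance = 1e-10)
  expect_gte(dse, 0)
  # property: non-negative for any orbital-derived density (fixed seed)
  set.seed(11)
  n <- ints$n; nocc <- ints$nelec / 2
  for (rep in 1:5) {
    M <- matrix(rnorm(n * n), n)
    # orthonormalise against S to get a valid closed-shell density
    Co <- M %*% solve(chol(t(M) %*% ints$S %*% M))
    Dr <- tcrossprod(Co[, 1:nocc])
    val <- sum(diag(Dr %*% A %*% (ints$Sinv - Dr) %*% A))
    expect_gte(val, -1e-12)
  }
})

test_that("energy is independent of the mode frequency", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  e1 <- scf_solve(mol, bas, qed_mode_z(0.1, omega = 0.25))$E_total
  e2 <- scf_solve(mol, bas, qed_mode_z(0.1, omega = 3.0))$E_total
  expect_lt(abs(e1 - e2), 1e-9)
})

test_that("QED-HF energy is translation invariant, also for charged systems", {
  bas <- minimal_basis()
  fl <- field_config(modes = list(cavity_mode(c(0.05, 0, 0.08), 0.5)))
  mol <- make_fixture("water")
  e0 <- scf_solve(mol, bas, fl)$E_total
  eT <- scf_solve(qedhf:::translate_molecule(mol, c(5, 0, 0)), bas, fl)$E_total
  expect_lt(abs(e0 - eT), 1e-9)
  oh <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 1.8)), charge = -1L)
  ec0 <- suppressWarnings(scf_solve(oh, bas, fl)$E_total)
  ecT <- suppressWarnings(
    scf_solve(qedhf:::translate_molecule(oh, c(-3, 2, 4)), bas, fl)$E_total)
  expect_lt(abs(ec0 - ecT), 1e-9)
})

test_that("cavity coupling raises the energy above plain HF", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  e_hf <- scf_solve(mol, bas)$E_total
  e_qed <- scf_solve(mol, bas, qed_mode_z(0.1))$E_total
  expect_gt(e_qed, e_hf)
})

test_that("energy breakdown terms sum to the total", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  fl <- field_config(modes = list(cavity_mode(c(0, 0.02, 0.08), 0.5),
                                  cavity_mode(c(0.05, 0, 0), 1.2)),
                     E_ext = c(0, 0, 0.005))
  st <- scf_solve(mol, bas, fl)
  expect_lt(abs(st$E_total - st$E_terms_sum), 1e-12)
  expect_length(st$energy_terms$dipole_self_energy, 2L)
})

test_that("non-convergence raises a diagnostic error carrying the trace", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  err <- tryCatch(
    scf_solve(mol, bas, settings = scf_settings(max_iter = 2L,
                                                tol_residual = 1e-12)),
    qedhf_scf_error = function(e) e)
  expect_s3_class(err, "qedhf_scf_error")
  expect_s3_class(err$trace, "data.frame")
  expect_equal(nrow(err$trace), 2L)
})

test_that("serialised states can be restored for restart", {
  mol <- make_fixture("h2")
  bas <- minimal_basis()
  st <- scf_solve(mol, bas)
  f <- tempfile(fileext = ".rds")
  saveRDS(list(E = st$E_total, C = st$C, D = st$D,
               settings = st$settings), f)
  back <- readRDS(f)
  st2 <- scf_solve(mol, bas, D0 = back$D)
  expect_equal(st2$E_total, back$E, tolerance = 1e-10)
  expect_lte(st2$iterations, st$iterations)
})
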