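# Analytical gradient vs finite-difference oracles, breakdown consistency,
# sum rules.

test_that("plain-HF gradient path equals the lambda=0 cavity path", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  g_hf <- qed_hf_gradient(scf_solve(mol, bas))
  g_l0 <- qed_hf_gradient(scf_solve(mol, bas,
    field_config(modes = list(cavity_mode(c(0, 0, 0), 0.5)))))
  expect_identical(g_hf$gradient, g_l0$gradient)
  # dipole-specific breakdown terms are exactly zero at lambda = 0
  expect_identical(max(abs(g_l0$term_breakdown$dipole_terms)), 0)
})

test_that("term breakdown sums to the total gradient", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  fl <- field_config(modes = list(cavity_mode(c(0, 0.03, 0.08), 0.5)),
                     E_ext = c(0.002, 0, 0.01))
  g <- qed_hf_gradient(scf_solve(mol, bas, fl))
  tot <- Reduce(`+`, g$term_breakdown)
  expect_lt(max(abs(tot - g$gradient)), 1e-12)
})

test_that("unconverged or magnetic states are refused with guidance", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  st <- scf_solve(mol, bas)
  st$converged <- FALSE
  expect_error(qed_hf_gradient(st), "not converged")
  stb <- scf_solve(mol, bas, field_config(B_ext = c(0, 0, 0.05)))
  expect_error(qed_hf_gradient(stb), "finite_difference_gradient")
})

test_that("finite differences on a known polynomial recover exact derivatives", {
  mol <- make_fixture("h2")
  w <- matrix(seq(0.1, 0.6, length.out = 6), 2, 3)
  quad <- function(m) sum(w * m$xyz^2)
  g <- finite_difference_gradient(mol, minimal_basis(), step = 1e-3,
                                  energy_fn = quad)
  expect_lt(max(abs(g$gradient - 2 * w * mol$xyz)), 1e-9)
})

test_that("finite-difference steps are Richardson consistent", {
  mol <- make_fixture("h2")
  # quartic model: FD error is exactly c*h^2, so halving the step divides
  # the error by 4
  quart <- function(m) sum(m$xyz^4)
  exact <- 4 * mol$xyz^3
  e1 <- finite_difference_gradient(mol, minimal_basis(), step = 1e-1,
                                   energy_fn = quart)$gradient - exact
  e2 <- finite_difference_gradient(mol, minimal_basis(), step = 5e-2,
                                   energy_fn = quart)$gradient - exact
  sel <- abs(e1) > 1e-10
  expect_true(all(abs(e1[sel] / e2[sel] - 4) < 1e-3))
})

test_that("finite-difference SCF failures name the displacement", {
  mol <- make_fixture("h2")
  boom <- function(m) stop("synthetic failure")
  expect_error(finite_difference_gradient(mol, minimal_basis(),
                                          energy_fn = boom),
               "atom 1 \\(x")
})

test_that("analytical gradients match finite differences across field types", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  configs <- list(
    none = field_config(),
    single = qed_mode_z(0.05),
    single_strong = qed_mode_z(0.1),
    two_mode = field_config(modes = list(cavity_mode(c(0, 0, 0.08), 0.5),
                                         cavity_mode(c(0.05, 0.02, 0), 1.0))),
    electric = field_config(E_ext = c(0, 0, 0.01)),
    dual = field_config(modes = list(cavity_mode(c(0, 0, 0.08), 0.5)),
                        E_ext = c(0, 0, 0.01)))
  for (nm in names(configs)) {
    fl <- configs[[nm]]
    ga <- qed_hf_gradient(scf_solve(mol, bas, fl))
    gf <- finite_difference_gradient(mol, bas, fl, step = 1e-3)
    expect_lt(max(abs(ga$gradient - gf$gradient)), 1e-6)
  }
})

test_that("neutral molecules feel no net force in uniform fields", {
  mol <- make_fixture("water")
  bas <- minimal_basis()
  fl <- field_config(modes = list(cavity_mode(c(0, 0, 0.1), 0.5)),
                     E_ext = c(0, 0, 0.01))
  g <- qed_hf_gradient(scf_solve(mol, bas, fl))
  expect_lt(max(abs(colSums(g$gradient))), 1e-8)
})

test_that("nuclear repulsion gradient matches finite differences", {
  mol <- make_fixture("water")
  g <- nuclear_repulsion_gradient(mol)
  h <- 1e-5
  for (a in 1:3) for (dir in 1:3) {
    mp <- mol; mp$xyz[a, dir] <- mp$xyz[a, dir] + h
    mm <- mol; mm$xyz[a, dir] <- mm$xyz[a, dir] - h
    fd <- (nuclear_repulsion(mp) - nuclear_repulsion(mm)) / (2 * h)
    expect_lt(abs(g[a, dir] - fd), 1e-9)
  }
})

test_that("magnetic finite-difference gradient drives the energy downhill", {
  mol <- make_fixture("h2")
  # stretch the bond so the gradient is clearly nonzero
  mol$xyz[2, 3] <- mol$xyz[2, 3] + 0.3
  bas <- minimal_basis()
  fl <- field_config(B_ext = c(0, 0, 0.1))
  g <- finite_difference_gradient(mol, bas, fl, step = 1e-3)
  e0 <- scf_solve(mol, bas, fl)$E_total
  step_mol <- mol
  step_mol$xyz <- mol$xyz - 0.05 * g$gradient / max(abs(g$gradient))
  e1 <- scf_solve(step_mol, bas, fl)$E_total
  expect_lt(e1, e0)
})

test_that("gradient output renders as an XYZ-like block and a table", {
  mol <- make_fixture("h2")
  g <- qed_hf_gradient(scf_solve(mol, minimal_basis()))
  out <- capture.output(print(g))
  expect_true(any(grepl("^  H ", out)))
  df <- as.data.frame(g)
  expect_named(df, c("element", "gx", "gy", "gz"))
  expect_equal(nrow(df), 2L)
})
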