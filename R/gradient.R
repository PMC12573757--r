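# Nuclear gradients of the QED-HF energy.
#
# The analytical gradient combines the standard restricted-HF pieces (core
# derivative, two-electron derivative contraction, energy-weighted overlap
# term, nuclear repulsion) with the cavity terms carrying the composite
# dipole derivative, and the static-electric-field contraction.  The Fock
# matrix entering the overlap term is the full QED Fock of the converged
# state.  Magnetic gradients are finite-difference only (fixed gauge origin,
# no field-dependent orbitals).

#' Analytic nuclear-repulsion gradient
#' @param mol a [molecule()].
#' @return natom x 3 matrix (hartree/bohr).
#' @export
nuclear_repulsion_gradient <- function(mol) {
  g <- matrix(0, mol$natom, 3)
  if (mol$natom < 2L) return(g)
  for (i in seq_len(mol$natom)) for (j in seq_len(mol$natom)) {
    if (i == j) next
    rij <- mol$xyz[i, ] - mol$xyz[j, ]
    r <- sqrt(sum(rij^2))
    if (r < 1e-8)
      stop("coincident nuclei ", i, " and ", j, ": repulsion gradient singular")
    g[i, ] <- g[i, ] - mol$Z[i] * mol$Z[j] * rij / r^3
  }
  g
}

#' Analytical QED-HF nuclear gradient
#'
#' Evaluates the analytical gradient of the converged QED-HF energy,
#' including cavity-mode terms (with the composite dipole derivative: the
#' electronic moment-integral derivatives, the nuclear-share overlap
#' derivative, and the nuclear-dipole derivative) and the static
#' electric-field term.  Magnetic fields are refused here; use
#' [finite_difference_gradient()] for those.
#'
#' @param state a converged `qed_scf` state.
#' @param eri_threshold screening threshold for the two-electron derivative
#'   contraction.
#' @return an object of class `qed_gradient`: total per-atom gradient and a
#'   per-term breakdown that sums to the total.
#' @export
qed_hf_gradient <- function(state, eri_threshold = 1e-13) {
  stopifnot(inherits(state, "qed_scf"))
  if (!isTRUE(state$converged))
    stop("gradient refused: SCF state is not converged (residual trace in ",
         "state$trace)")
  if (has_magnetic(state$fields))
    stop("analytical magnetic-field gradients are not available at a fixed ",
         "gauge origin; use finite_difference_gradient()")
  mol <- state$molecule
  ints <- state$ints
  fields <- state$fields
  D <- Re(state$D)
  F <- Re(state$F)
  natom <- mol$natom
  Ne <- ints$nelec

  der <- derivative_set(mol, state$basis, ints)
  g2e <- eri_gradient_contraction(mol, state$basis, D, eri_threshold)
  gnuc <- nuclear_repulsion_gradient(mol)
  DFD <- D %*% F %*% D

  Amats <- mode_matrices(ints, fields)
  lambdas <- lapply(fields$modes, `[[`, "lambda")
  W1 <- lapply(Amats, function(A) D %*% A %*% (ints$Sinv - D))
  W2 <- lapply(Amats, function(A) {
    avg <- 2 * tr_prod(D, A)
    ints$Sinv %*% A %*% D %*% A %*% ints$Sinv - (avg^2 / Ne) * D
  })
  E <- fields$E_ext

  core1 <- ov1 <- dip1 <- ef1 <- matrix(0, natom, 3)
  for (a in seq_len(natom)) for (dir in 1:3) {
    dd <- der[[a]][[dir]]
    core1[a, dir] <- 2 * tr_prod(D, dd$h1)
    ov1[a, dir] <- -2 * tr_prod(DFD, dd$S1)
    acc <- 0
    for (m in seq_along(Amats)) {
      l <- lambdas[[m]]
      A1 <- l[1] * dd$d1$x + l[2] * dd$d1$y + l[3] * dd$d1$z
      acc <- acc + 2 * tr_prod(W1[[m]], A1) - tr_prod(W2[[m]], dd$S1)
    }
    dip1[a, dir] <- acc
    if (any(E != 0))
      ef1[a, dir] <- -2 * (E[1] * tr_prod(D, dd$d1$x) +
                           E[2] * tr_prod(D, dd$d1$y) +
                           E[3] * tr_prod(D, dd$d1$z))
  }

  total <- core1 + g2e + ov1 + gnuc + dip1 + ef1
  structure(list(
    gradient = total,
    term_breakdown = list(core1 = core1, two_electron1 = g2e,
                          overlap1 = ov1, nuclear1 = gnuc,
                          dipole_terms = dip1, electric_field = ef1),
    molecule = mol,
    max_component = max(abs(total)),
    rms = sqrt(mean(total^2))), class = "qed_gradient")
}

#' Finite-difference nuclear gradient
#'
#' Central differences of converged SCF energies; the verification oracle
#' for the analytical gradient, and the production path for magnetic fields
#' (whose analytical form would inherit gauge artifacts at a fixed origin).
#'
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param fields a [field_config()].
#' @param step displacement (bohr).
#' @param settings [scf_settings()] used at every displaced geometry.
#' @param energy_fn optional replacement energy callback `function(mol)`;
#'   by default the converged SCF total energy.
#' @return a `qed_gradient` (no term breakdown).
#' @export
finite_difference_gradient <- function(mol, basis, fields = field_config(),
                                       step = 1e-3,
                                       settings = scf_settings(),
                                       energy_fn = NULL) {
  stopifnot(step > 0)
  if (is.null(energy_fn))
    energy_fn <- function(m) scf_solve(m, basis, fields, settings)$E_total
  g <- matrix(0, mol$natom, 3)
  for (a in seq_len(mol$natom)) for (dir in 1:3) {
    ep <- em <- mol
    ep$xyz[a, dir] <- ep$xyz[a, dir] + step
    em$xyz[a, dir] <- em$xyz[a, dir] - step
    val <- tryCatch(
      (energy_fn(ep) - energy_fn(em)) / (2 * step),
      error = function(e)
        stop("finite-difference gradient failed at displacement of atom ", a,
             " (", c("x", "y", "z")[dir], ", step ", step, " bohr): ",
             conditionMessage(e), call. = FALSE))
    g[a, dir] <- val
  }
  structure(list(gradient = g, term_breakdown = NULL, molecule = mol,
                 max_component = max(abs(g)), rms = sqrt(mean(g^2))),
            class = "qed_gradient")
}

#' @export
print.qed_gradient <- function(x, ...) {
  cat("<qed_gradient> (hartree/bohr)\n")
  for (i in seq_len(nrow(x$gradient)))
    cat(sprintf("  %-2s %14.8f %14.8f %14.8f\n", x$molecule$symbols[i],
                x$gradient[i, 1], x$gradient[i, 2], x$gradient[i, 3]))
  cat(sprintf("  max |g| = %.3e  rms = %.3e\n", x$max_component, x$rms))
  invisible(x)
}

#' @export
as.data.frame.qed_gradient <- function(x, ...) {
  data.frame(element = x$molecule$symbols,
             gx = x$gradient[, 1], gy = x$gradient[, 2], gz = x$gradient[, 3])
}
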