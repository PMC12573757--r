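# Closed-shell QED-HF self-consistent field in the coherent-state basis.
#
# The cavity enters through the composite dipole operator d (electronic +
# nuclear share): for each mode with coupling vector lambda the matrix
# A = lambda . d modifies the one-electron Hamiltonian as
#   h  = h_e + sum_m ( 1/2 A S^-1 A - <A> A + <A>^2/(2 Ne) S ) + static terms
# and the two-electron contraction as
#   G(D) = G_e(D) + sum_m ( 2 Tr(D A) A - A D A ).
# The coherent-state reference <A> = 2 Tr(D A) is refreshed from the current
# density every iteration; at convergence the dipole self-energy equals the
# non-negative fluctuation Tr(D A (S^-1 - D) A) per mode.

# Tr(A B) for square matrices (B need not be symmetric)
tr_prod <- function(A, B) sum(A * t(B))

#' SCF settings
#'
#' @param tol_residual convergence threshold on max|FDS - SDF|.
#' @param tol_energy convergence threshold on the energy change (hartree).
#' @param max_iter maximum number of SCF iterations.
#' @param diis_size number of Fock/error pairs kept for DIIS extrapolation.
#' @param eri_threshold Cauchy-Schwarz screening threshold.
#' @param cond_tol smallest admissible overlap eigenvalue.
#' @return a list of settings for [scf_solve()].
#' @export
scf_settings <- function(tol_residual = 1e-7, tol_energy = 1e-9,
                         max_iter = 128L, diis_size = 8L,
                         eri_threshold = 1e-12, cond_tol = 1e-10) {
  stopifnot(tol_residual > 0, tol_energy > 0, max_iter >= 1)
  list(tol_residual = tol_residual, tol_energy = tol_energy,
       max_iter = as.integer(max_iter), diis_size = as.integer(diis_size),
       eri_threshold = eri_threshold, cond_tol = cond_tol)
}

# lambda . d matrices, one per cavity mode
mode_matrices <- function(ints, fields) {
  lapply(fields$modes, function(m)
    m$lambda[1] * ints$d$x + m$lambda[2] * ints$d$y + m$lambda[3] * ints$d$z)
}

#' Molecular dipole expectation value
#'
#' Returns the full molecular dipole (electronic + nuclear) in a.u.,
#' \eqn{\langle d_k\rangle = 2\,\mathrm{Tr}(D d_k)}.
#'
#' @param D AO density matrix (real or complex Hermitian).
#' @param ints an [integral_set()].
#' @return numeric length-3 dipole vector (a.u.).
#' @export
dipole_expectation <- function(D, ints) {
  vapply(ints$d, function(dk) 2 * Re(tr_prod(D, dk)), numeric(1))
}

#' Assemble the field-modified one-electron Hamiltonian
#'
#' Adds to the core Hamiltonian the cavity dipole-fluctuation terms
#' (evaluated with \eqn{\langle A\rangle} from the reference density), the
#' static electric-field term \eqn{-E\cdot d}, and the magnetic one-electron
#' terms (orbital Zeeman + diamagnetic) when present.
#'
#' @param ints an [integral_set()].
#' @param D_ref reference density for the coherent-state terms.
#' @param fields a [field_config()].
#' @return one-electron matrix (complex when a magnetic field is present).
#' @export
assemble_modified_oei <- function(ints, D_ref, fields) {
  h <- ints$h_e
  Ne <- ints$nelec
  for (A in mode_matrices(ints, fields)) {
    avg <- 2 * Re(tr_prod(D_ref, A))
    h <- h + 0.5 * A %*% ints$Sinv %*% A - avg * A +
      (avg^2 / (2 * Ne)) * ints$S
  }
  E <- fields$E_ext
  if (any(E != 0))
    h <- h - (E[1] * ints$d$x + E[2] * ints$d$y + E[3] * ints$d$z)
  if (has_magnetic(fields))
    h <- h + magnetic_oei_terms(ints, fields$B_ext, fields$gauge_origin)
  h
}

#' Build the QED Fock matrix
#'
#' \eqn{F = h + G_e(D) + \sum_m (2 Tr(D A_m) A_m - A_m D A_m)}.
#'
#' @param D AO density (Hermitian).
#' @param h modified one-electron matrix from [assemble_modified_oei()].
#' @param eri a `qed_eri` store.
#' @param ints an [integral_set()].
#' @param fields a [field_config()].
#' @return Fock matrix (same mode, real/complex, as `h` and `D`).
#' @export
fock_build <- function(D, h, eri, ints, fields) {
  if (is.complex(D) || is.complex(h)) {
    G <- fock_2e(eri, Re(D)) + 1i * fock_2e(eri, Im(D))
  } else {
    G <- fock_2e(eri, D)
  }
  F <- h + G
  for (A in mode_matrices(ints, fields)) {
    avg <- 2 * Re(tr_prod(D, A))
    F <- F + avg * A - A %*% D %*% A
  }
  F
}

# energy decomposition; valid for any density with Tr(DS) = Ne/2
energy_breakdown <- function(D, ints, fields, G_e) {
  e_electronic <- 2 * Re(tr_prod(D, ints$h_e)) + Re(tr_prod(D, G_e))
  dse <- vapply(mode_matrices(ints, fields), function(A) {
    Re(tr_prod(D %*% A %*% (ints$Sinv - D), A))
  }, numeric(1))
  mu <- dipole_expectation(D, ints)
  e_field <- -sum(fields$E_ext * mu)
  e_mag <- 0
  if (has_magnetic(fields)) {
    hm <- magnetic_oei_terms(ints, fields$B_ext, fields$gauge_origin)
    e_mag <- 2 * Re(tr_prod(D, hm))
  }
  list(electronic = e_electronic, dipole_self_energy = dse,
       electric_field = e_field, magnetic_field = e_mag, dipole = mu)
}

#' Solve the QED-HF self-consistent field equations
#'
#' Restricted closed-shell SCF with DIIS acceleration on the orbital
#' gradient residual FDS - SDF.  With an empty [field_config()] this is
#' plain restricted Hartree-Fock; cavity modes add the dipole self-energy
#' in the coherent-state basis (refreshed from the current density every
#' iteration); a static magnetic field switches the whole SCF to complex
#' arithmetic.
#'
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param fields a [field_config()].
#' @param settings a [scf_settings()] list.
#' @param ints,eri optional precomputed [integral_set()] / [eri_screened()]
#'   (reused across calls at fixed geometry).
#' @param D0 optional initial density guess (e.g. the converged density of a
#'   neighbouring geometry); default is a core-Hamiltonian guess.
#' @param h_extra optional extra one-electron matrix added to the
#'   Hamiltonian (used e.g. for real-constrained diamagnetic-only runs).
#' @return an object of class `qed_scf` with MO coefficients `C`, density
#'   `D`, Fock matrix `F`, orbital energies, total energy `E_total`, the
#'   energy decomposition `energy_terms`, convergence data, and the
#'   integral set.
#' @export
scf_solve <- function(mol, basis, fields = field_config(),
                      settings = scf_settings(), ints = NULL, eri = NULL,
                      D0 = NULL, h_extra = NULL) {
  if (is.null(ints))
    ints <- integral_set(mol, basis, gauge_origin = fields$gauge_origin,
                         cond_tol = settings$cond_tol)
  if (is.null(eri))
    eri <- eri_screened(mol, basis, threshold = settings$eri_threshold)

  n <- ints$n
  nocc <- ints$nelec %/% 2L
  complex_mode <- has_magnetic(fields)
  X <- ints$X
  e_nuc <- nuclear_repulsion(mol)

  # static one-electron parts (D-independent)
  h_static <- ints$h_e
  E <- fields$E_ext
  if (any(E != 0))
    h_static <- h_static - (E[1] * ints$d$x + E[2] * ints$d$y + E[3] * ints$d$z)
  if (complex_mode)
    h_static <- h_static + magnetic_oei_terms(ints, fields$B_ext,
                                              fields$gauge_origin)
  if (!is.null(h_extra)) h_static <- h_static + h_extra
  Amats <- mode_matrices(ints, fields)
  AhalfSinv <- lapply(Amats, function(A) 0.5 * A %*% ints$Sinv %*% A)

  occupy <- function(Fm) {
    Fo <- Conj(t(X)) %*% Fm %*% X
    Fo <- (Fo + Conj(t(Fo))) / 2
    ev <- eigen(Fo, symmetric = TRUE)
    ord <- order(ev$values)
    eps <- ev$values[ord]
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    if (n > nocc && (eps[nocc + 1] - eps[nocc]) < 1e-6)
      warning("HOMO-LUMO gap below 1e-6 hartree: degenerate Aufbau occupation ",
              "resolved by lowest-index selection", call. = FALSE)
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- Cocc %*% Conj(t(Cocc))
    list(C = C, D = D, eps = eps)
  }

  # initial guess: supplied density, else core Hamiltonian (coherent-state
  # terms with <A> = 0)
  if (!is.null(D0)) {
    stopifnot(nrow(D0) == n)
    if (complex_mode && !is.complex(D0)) D0 <- D0 + 0i
    st <- list(C = NULL, D = D0, eps = NULL)
  } else {
    F0 <- h_static
    for (AS in AhalfSinv) F0 <- F0 + AS
    if (complex_mode) F0 <- F0 + 0i
    st <- occupy(F0)
  }

  diis_F <- list(); diis_e <- list()
  trace <- data.frame(iter = integer(), energy = numeric(),
                      residual = numeric())
  E_old <- Inf; E_tot <- NA_real_; G_e <- NULL; Fm <- NULL
  converged <- FALSE
  S <- ints$S
  Ne <- ints$nelec

  for (it in seq_len(settings$max_iter)) {
    D <- st$D
    # modified one-electron matrix with current <A>
    h <- h_static
    for (m in seq_along(Amats)) {
      A <- Amats[[m]]
      avg <- 2 * Re(tr_prod(D, A))
      h <- h + AhalfSinv[[m]] - avg * A + (avg^2 / (2 * Ne)) * S
    }
    if (complex_mode) {
      G_e <- fock_2e(eri, Re(D)) + 1i * fock_2e(eri, Im(D))
    } else {
      G_e <- fock_2e(eri, D)
    }
    Fm <- h + G_e
    for (A in Amats) {
      avg <- 2 * Re(tr_prod(D, A))
      Fm <- Fm + avg * A - A %*% D %*% A
    }
    G_tot <- Fm - h            # full G(D) including cavity two-electron terms
    E_tot <- 2 * Re(tr_prod(D, h)) + Re(tr_prod(D, G_tot)) + e_nuc

    R <- Fm %*% D %*% S - S %*% D %*% Fm
    resid <- max(Mod(R))
    trace <- rbind(trace, data.frame(iter = it, energy = E_tot,
                                     residual = resid))
    if (resid <= settings$tol_residual &&
        abs(E_tot - E_old) <= settings$tol_energy) {
      converged <- TRUE
      break
    }
    E_old <- E_tot

    # DIIS on the orthonormal-basis residual
    err <- Conj(t(X)) %*% R %*% X
    diis_F[[length(diis_F) + 1L]] <- Fm
    diis_e[[length(diis_e) + 1L]] <- err
    if (length(diis_F) > settings$diis_size) {
      diis_F <- diis_F[-1]; diis_e <- diis_e[-1]
    }
    Fuse <- Fm
    m <- length(diis_F)
    if (m >= 2L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- Re(sum(Conj(diis_e[[i]]) * diis_e[[j]]))
      B[m + 1L, seq_len(m)] <- -1; B[seq_len(m), m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (!is.null(cf)) {
        Fuse <- matrix(0, n, n)
        if (complex_mode) Fuse <- Fuse + 0i
        for (i in seq_len(m)) Fuse <- Fuse + cf[i] * diis_F[[i]]
      }
    }
    st <- occupy(Fuse)
  }

  if (!converged) {
    cond <- structure(
      class = c("qedhf_scf_error", "error", "condition"),
      list(message = sprintf(
        paste0("SCF failed to converge in %d iterations ",
               "(last residual %.3e, last energy %.10f); ",
               "iteration trace attached as conditionCall$trace"),
        settings$max_iter, tail(trace$residual, 1), E_tot),
        call = sys.call(-1), trace = trace))
    stop(cond)
  }

  if (is.null(st$C)) {                  # D0 guess that converged immediately
    aux <- occupy(Fm)
    st$C <- aux$C; st$eps <- aux$eps
  }
  terms <- energy_breakdown(st$D, ints, fields, G_e)
  E_terms_sum <- terms$electronic + sum(terms$dipole_self_energy) +
    terms$electric_field + terms$magnetic_field + e_nuc

  structure(list(
    C = st$C, D = st$D, F = Fm, orbital_energies = st$eps,
    E_total = E_tot, E_terms_sum = E_terms_sum,
    energy_terms = c(list(nuclear = e_nuc), terms),
    converged = TRUE, iterations = it, trace = trace,
    fields = fields, settings = settings, ints = ints,
    molecule = mol, basis = basis, complex_mode = complex_mode,
    nocc = nocc), class = "qed_scf")
}

#' @export
print.qed_scf <- function(x, ...) {
  cat(sprintf("<qed_scf> converged in %d iterations\n", x$iterations))
  cat(sprintf("  E_total            %18.10f hartree\n", x$E_total))
  et <- x$energy_terms
  cat(sprintf("  electronic         %18.10f\n", et$electronic))
  cat(sprintf("  nuclear repulsion  %18.10f\n", et$nuclear))
  if (length(et$dipole_self_energy))
    cat(sprintf("  dipole self-energy %18.10f (mode %d)\n",
                et$dipole_self_energy, seq_along(et$dipole_self_energy)))
  if (et$electric_field != 0)
    cat(sprintf("  electric field     %18.10f\n", et$electric_field))
  if (et$magnetic_field != 0)
    cat(sprintf("  magnetic field     %18.10f\n", et$magnetic_field))
  cat(sprintf("  dipole moment      (%.6f, %.6f, %.6f) a.u.\n",
              et$dipole[1], et$dipole[2], et$dipole[3]))
  invisible(x)
}

#' Energy decomposition of a converged SCF state
#'
#' Recomputes the breakdown {electronic, per-mode dipole self-energy,
#' electric-field, magnetic-field, nuclear} from the converged density; the
#' terms sum to the total energy.  Each mode's dipole self-energy is the
#' non-negative dipole fluctuation along its polarization.
#'
#' @param state a converged `qed_scf` state.
#' @return named list of energy terms plus `total` (hartree).
#' @export
qed_hf_energy <- function(state) {
  stopifnot(inherits(state, "qed_scf"))
  et <- state$energy_terms
  c(et[c("nuclear", "electronic", "dipole_self_energy", "electric_field",
         "magnetic_field")],
    list(total = state$E_total))
}
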