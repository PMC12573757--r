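# AO integral sets over the uncontracted basis, with the dipole-operator
# convention used throughout the package:
#
#   d_k = -<mu| r_k |nu>  +  (d_nuc,k / N_e) S
#
# so that 2 Tr(D d) is the physical molecular dipole (nuclear positive,
# electronic negative).  The nuclear share is folded into the AO matrices,
# matching the composite dipole operator of the cavity Hamiltonian.

#' Compute the one-electron integral set
#'
#' Builds overlap, core Hamiltonian (kinetic + nuclear attraction), dipole
#' matrices (including the nuclear share, see Details), angular-momentum
#' matrices about the gauge origin, and second-moment matrices about the
#' gauge origin, over the uncontracted basis.
#'
#' @details The dipole matrices returned satisfy `2*sum(D * d_k)` = physical
#' molecular dipole component k (a.u.) for any closed-shell density `D`
#' normalised to `Tr(DS) = N_e/2`.  The angular-momentum matrices `L` store
#' the real antisymmetric part \eqn{\Lambda = \langle\mu|(r-O)\times\nabla|\nu\rangle};
#' the Hermitian operator is \eqn{-i\Lambda}.
#'
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param gauge_origin Cartesian gauge origin (bohr) for magnetic-moment
#'   integrals; default is the centre of nuclear charge.
#' @param cond_tol smallest admissible eigenvalue of the overlap matrix.
#' @return an object of class `qed_integrals`.
#' @export
integral_set <- function(mol, basis, gauge_origin = NULL, cond_tol = 1e-10) {
  if (is.null(gauge_origin)) gauge_origin <- center_of_nuclear_charge(mol)
  stopifnot(all(is.finite(gauge_origin)), length(gauge_origin) == 3L)
  st <- shell_table(mol, basis)
  oei <- cpp_oei(st, atom_table(mol), as.numeric(gauge_origin))
  S <- oei$S
  ev <- eigen(S, symmetric = TRUE, only.values = FALSE)
  if (min(ev$values) < cond_tol)
    stop(sprintf(paste0("overlap matrix is near-singular: smallest eigenvalue ",
                        "%.3e below threshold %.1e (linear dependence in the ",
                        "uncontracted basis)"), min(ev$values), cond_tol))
  n <- nrow(S)
  Ne <- mol$nelec
  dnuc <- nuclear_dipole(mol)
  d <- list(x = -oei$MX + (dnuc[1] / Ne) * S,
            y = -oei$MY + (dnuc[2] / Ne) * S,
            z = -oei$MZ + (dnuc[3] / Ne) * S)
  # symmetric orthogonalisation and inverse from the eigendecomposition
  V <- ev$vectors
  Sinv <- V %*% (t(V) / ev$values)
  X <- V %*% (t(V) / sqrt(ev$values))
  structure(list(
    S = S, h_e = oei$T + oei$V, T = oei$T, V = oei$V,
    d = d, M = list(x = oei$MX, y = oei$MY, z = oei$MZ),
    L = list(x = oei$LX, y = oei$LY, z = oei$LZ),
    Q = list(xx = oei$QXX, xy = oei$QXY, xz = oei$QXZ,
             yy = oei$QYY, yz = oei$QYZ, zz = oei$QZZ),
    Sinv = Sinv, X = X, s_min_eig = min(ev$values),
    gauge_origin = as.numeric(gauge_origin),
    n = n, nelec = Ne, d_nuc = dnuc,
    shell_table = st, natom = mol$natom), class = "qed_integrals")
}

#' Nuclear-derivative one-electron integrals
#'
#' For every atom and Cartesian direction: the overlap derivative `S1`, core
#' Hamiltonian derivative `h1` (including the Hellmann-Feynman
#' operator-centre term of the nuclear attraction), and the full composite
#' dipole derivative `d1` carrying all three contributions: electronic
#' moment-integral derivatives, `(d_nuc/N_e) S1`, and the nuclear-dipole
#' derivative term `(Z_A/N_e) S` along the displaced coordinate.
#'
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param ints the matching [integral_set()] (for S and N_e).
#' @return list over atoms of lists over directions (x,y,z), each holding
#'   `S1`, `h1`, and `d1` (itself a list x,y,z).
#' @export
derivative_set <- function(mol, basis, ints) {
  st <- shell_table(mol, basis)
  raw <- cpp_oei_grad(st, atom_table(mol))
  Ne <- mol$nelec
  dnuc <- nuclear_dipole(mol)
  lapply(seq_len(mol$natom), function(a) {
    lapply(1:3, function(dir) {
      rr <- raw[[a]][[dir]]
      S1 <- rr$S1
      d1 <- list(
        x = -rr$MX1 + (dnuc[1] / Ne) * S1,
        y = -rr$MY1 + (dnuc[2] / Ne) * S1,
        z = -rr$MZ1 + (dnuc[3] / Ne) * S1)
      # nuclear-dipole derivative: moving atom a along `dir` changes
      # d_nuc[dir] at rate Z_a
      d1[[dir]] <- d1[[dir]] + (mol$Z[a] / Ne) * ints$S
      list(S1 = S1, h1 = rr$H1, d1 = d1)
    })
  })
}

# ------------------------------------------------------------ two-electron

#' Screened two-electron integrals
#'
#' Computes all two-electron repulsion integrals over the uncontracted basis
#' into a permutationally packed store, skipping shell quartets whose
#' Cauchy-Schwarz bound \eqn{\sqrt{(\mu\nu|\mu\nu)(\rho\sigma|\rho\sigma)}}
#' falls below `threshold` (screened integrals are treated as zero).
#'
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param threshold Cauchy-Schwarz screening threshold (0 disables screening).
#' @return an object of class `qed_eri`.
#' @export
eri_screened <- function(mol, basis, threshold = 1e-12) {
  stopifnot(threshold >= 0)
  st <- shell_table(mol, basis)
  r <- cpp_eri(st, threshold)
  structure(list(packed = r$packed, n = r$n, schwarz = r$schwarz,
                 threshold = threshold, shell_table = st),
            class = "qed_eri")
}

#' Look up a single two-electron integral
#' @param eri a `qed_eri` store.
#' @param i,j,k,l 1-based AO indices; returns \eqn{(ij|kl)}.
#' @export
eri_element <- function(eri, i, j, k, l) {
  tri <- function(x) x * (x + 1) / 2
  i <- i - 1; j <- j - 1; k <- k - 1; l <- l - 1
  P1 <- if (i >= j) tri(i) + j else tri(j) + i
  P2 <- if (k >= l) tri(k) + l else tri(l) + k
  idx <- if (P1 >= P2) tri(P1) + P2 else tri(P2) + P1
  eri$packed[idx + 1]
}

# dense (n,n,n,n) tensor, test oracles only
eri_dense <- function(mol, basis) {
  st <- shell_table(mol, basis)
  cpp_eri_dense(st)
}

# G_e(D) = sum_rs D_rs (2 g_uvrs - g_usrv); works for any real D
# (a faster contraction is used when D is symmetric)
fock_2e <- function(eri, D) {
  sym <- max(abs(D - t(D))) < 1e-14
  cpp_fock2e(eri$packed, eri$n, D, general = !sym)
}

# per-atom Tr(D Ge^(1)(D)) for symmetric D
eri_gradient_contraction <- function(mol, basis, D, threshold = 1e-13) {
  st <- shell_table(mol, basis)
  cpp_eri_grad(st, D, mol$natom, threshold)
}
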