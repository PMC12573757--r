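# Field-aware geometry optimization and potential-energy scans.
#
# The optimizer is a BFGS-updated quasi-Newton scheme with a trust radius,
# working in Cartesian coordinates.  Overall translations are always
# projected out of gradient and step; overall rotations are projected out
# ONLY when no external field is present — in a field the orientation is a
# physical degree of freedom and must be allowed to relax.  Dihedral
# constraints are enforced by gradient/step projection plus a Newton
# restoration of the constraint value; frozen Cartesian coordinates are
# removed from the variable space.

#' Geometry-optimization settings
#'
#' @param max_steps maximum accepted optimization steps.
#' @param grad_max convergence threshold on the largest projected gradient
#'   component (hartree/bohr).
#' @param grad_rms convergence threshold on the projected gradient RMS.
#' @param energy_change auxiliary energy-change threshold (hartree).
#' @param trust initial trust radius (bohr).
#' @param trust_max upper bound on the trust radius (bohr).
#' @return a settings list for [optimize_geometry()].
#' @export
opt_settings <- function(max_steps = 200L, grad_max = 4.5e-4,
                         grad_rms = 3e-4, energy_change = 1e-7,
                         trust = 0.3, trust_max = 0.5) {
  stopifnot(grad_max > 0, grad_rms > 0, energy_change > 0, trust > 0,
            trust <= trust_max)
  list(max_steps = as.integer(max_steps), grad_max = grad_max,
       grad_rms = grad_rms, energy_change = energy_change,
       trust = trust, trust_max = trust_max)
}

# ------------------------------------------------------------- internals

vnorm <- function(v) sqrt(sum(v^2))

bond_length <- function(xyz, i, j) vnorm(xyz[i, ] - xyz[j, ])

bond_angle <- function(xyz, i, j, k) {
  u <- xyz[i, ] - xyz[j, ]; v <- xyz[k, ] - xyz[j, ]
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 1e-10 || nv < 1e-10)
    stop("undefined angle: coincident atoms in definition (", i, ",", j, ",", k, ")")
  cth <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cth)))
}

dihedral_angle <- function(xyz, idx) {
  # signed dihedral (radians), IUPAC convention: looking from atom 2 to
  # atom 3, positive when 4 is clockwise from 1
  b1 <- xyz[idx[2], ] - xyz[idx[1], ]
  b2 <- xyz[idx[3], ] - xyz[idx[2], ]
  b3 <- xyz[idx[4], ] - xyz[idx[3], ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined dihedral: collinear atoms in definition (",
         paste(idx, collapse = ","), ")")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2); y <- sum(m1 * n2) / vnorm(b2)
  atan2(y, x)
}

#' Measure internal coordinates
#'
#' Bond lengths in Angstrom, angles in degrees (0..180), signed dihedrals
#' in degrees (-180, 180] following the IUPAC convention, and
#' hydrogen-bond lengths (plain distances, Angstrom).
#'
#' @param mol a [molecule()].
#' @param definitions list with optional elements `bonds` (list of index
#'   pairs), `angles` (triples), `dihedrals` (quadruples), `hbonds` (pairs).
#' @return an object of class `internal_coordinates`: a named list of
#'   numeric vectors.
#' @export
measure_internals <- function(mol, definitions) {
  xyz <- mol$xyz
  out <- list()
  if (!is.null(definitions$bonds))
    out$bonds <- vapply(definitions$bonds, function(b)
      angstrom_from_bohr(bond_length(xyz, b[1], b[2])), numeric(1))
  if (!is.null(definitions$angles))
    out$angles <- vapply(definitions$angles, function(a)
      bond_angle(xyz, a[1], a[2], a[3]) * 180 / pi, numeric(1))
  if (!is.null(definitions$dihedrals))
    out$dihedrals <- vapply(definitions$dihedrals, function(d) {
      val <- dihedral_angle(xyz, d) * 180 / pi
      if (val <= -180) val <- val + 360
      val
    }, numeric(1))
  if (!is.null(definitions$hbonds))
    out$hbonds <- vapply(definitions$hbonds, function(b)
      angstrom_from_bohr(bond_length(xyz, b[1], b[2])), numeric(1))
  structure(out, class = "internal_coordinates")
}

# ------------------------------------------------- projection machinery

# orthonormal basis of directions to remove from gradient/step
removed_space <- function(mol, x, project_rotations, constraints) {
  natom <- mol$natom
  cols <- list()
  for (d in 1:3) {
    t <- matrix(0, natom, 3); t[, d] <- 1
    cols[[length(cols) + 1L]] <- as.numeric(t(t))
  }
  if (project_rotations) {
    xyz <- matrix(x, natom, 3, byrow = TRUE)
    com <- colMeans(xyz)
    for (d in 1:3) {
      e <- c(0, 0, 0); e[d] <- 1
      r <- sweep(xyz, 2, com)
      v <- t(apply(r, 1, function(ri)
        c(e[2] * ri[3] - e[3] * ri[2], e[3] * ri[1] - e[1] * ri[3],
          e[1] * ri[2] - e[2] * ri[1])))
      cols[[length(cols) + 1L]] <- as.numeric(t(v))
    }
  }
  if (!is.null(constraints$dihedrals)) {
    xyz <- matrix(x, natom, 3, byrow = TRUE)
    for (con in constraints$dihedrals)
      cols[[length(cols) + 1L]] <- dihedral_jacobian(xyz, con$atoms)
  }
  B <- do.call(cbind, cols)
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

# numeric Jacobian of one dihedral w.r.t. all Cartesians (radians/bohr)
dihedral_jacobian <- function(xyz, idx, h = 1e-6) {
  natom <- nrow(xyz)
  J <- numeric(3 * natom)
  base <- dihedral_angle(xyz, idx)
  for (a in idx) for (d in 1:3) {
    xp <- xyz; xp[a, d] <- xp[a, d] + h
    xm <- xyz; xm[a, d] <- xm[a, d] - h
    dp <- dihedral_angle(xp, idx); dm <- dihedral_angle(xm, idx)
    # unwrap across the +-pi seam
    diff <- dp - dm
    if (diff > pi) diff <- diff - 2 * pi
    if (diff < -pi) diff <- diff + 2 * pi
    J[3 * (a - 1) + d] <- diff / (2 * h)
  }
  invisible(base)
  J
}

project_vector <- function(v, Qr, free_mask) {
  v[!free_mask] <- 0
  if (!is.null(Qr) && ncol(Qr) > 0) v <- v - Qr %*% crossprod(Qr, v)
  v[!free_mask] <- 0
  as.numeric(v)
}

# Newton restoration of dihedral constraints (targets in radians)
restore_constraints <- function(xyz, constraints, free_mask, tol_deg = 0.005,
                                max_iter = 25L) {
  if (is.null(constraints$dihedrals)) return(xyz)
  natom <- nrow(xyz)
  for (it in seq_len(max_iter)) {
    resid <- vapply(constraints$dihedrals, function(con) {
      r <- con$value * pi / 180 - dihedral_angle(xyz, con$atoms)
      if (r > pi) r <- r - 2 * pi
      if (r < -pi) r <- r + 2 * pi
      r
    }, numeric(1))
    if (max(abs(resid)) < tol_deg * pi / 180) return(xyz)
    B <- do.call(rbind, lapply(constraints$dihedrals, function(con)
      dihedral_jacobian(xyz, con$atoms)))
    B[, !free_mask] <- 0
    dx <- t(B) %*% solve(B %*% t(B) + 1e-12 * diag(nrow(B)), resid)
    xyz <- xyz + matrix(dx, natom, 3, byrow = TRUE)
  }
  resid_deg <- max(abs(vapply(constraints$dihedrals, function(con) {
    r <- con$value - dihedral_angle(xyz, con$atoms) * 180 / pi
    ((r + 180) %% 360) - 180
  }, numeric(1))))
  stop(sprintf("constraint restoration did not converge (residual %.4f deg)",
               resid_deg))
}

# ------------------------------------------------------------- optimizer

#' Optimize a molecular geometry in external fields
#'
#' Quasi-Newton (BFGS) trust-region minimisation of the QED-HF energy.
#' Translations are projected out; rotations are retained whenever any
#' field is non-zero, since the orientation relative to the field is
#' physical.  The gradient is analytical for cavity/electric fields and
#' finite-difference when a magnetic field is present.
#'
#' @param mol starting [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param fields a [field_config()].
#' @param settings an [opt_settings()] list.
#' @param constraints optional list: `frozen` (flattened coordinate indices
#'   `(atom-1)*3 + dir` to hold fixed), `dihedrals` (list of
#'   `list(atoms = c(i,j,k,l), value = degrees)`).
#' @param scf_settings [scf_settings()] for the underlying SCF solves.
#' @return an object of class `qed_opt`: optimized molecule, energy,
#'   trajectory, final gradient, step count, convergence flag.
#' @export
optimize_geometry <- function(mol, basis, fields = field_config(),
                              settings = opt_settings(), constraints = NULL,
                              scf_settings = qedhf::scf_settings()) {
  natom <- mol$natom
  nfree <- 3L * natom
  free_mask <- rep(TRUE, nfree)
  if (!is.null(constraints$frozen)) free_mask[constraints$frozen] <- FALSE
  project_rot <- fields_are_empty(fields) && is.null(constraints)

  use_fd <- has_magnetic(fields)
  prev_D <- NULL

  eval_point <- function(x) {
    m <- set_coords(mol, matrix(x, natom, 3, byrow = TRUE))
    state <- tryCatch(
      scf_solve(m, basis, fields, scf_settings, D0 = prev_D),
      error = function(e)
        stop("SCF failure during optimization at step geometry; last good ",
             "geometry is in the trajectory. Underlying error: ",
             conditionMessage(e), call. = FALSE))
    prev_D <<- Re(state$D)
    g <- if (use_fd) {
      finite_difference_gradient(m, basis, fields, settings = scf_settings)
    } else {
      qed_hf_gradient(state)
    }
    list(E = state$E_total, g = as.numeric(t(g$gradient)), state = state,
         grad_obj = g, mol = m)
  }

  x <- as.numeric(t(mol$xyz))
  if (!is.null(constraints$dihedrals))
    x <- as.numeric(t(restore_constraints(matrix(x, natom, 3, byrow = TRUE),
                                          constraints, free_mask)))
  cur <- eval_point(x)
  H <- diag(0.5, nfree)
  trust <- settings$trust
  traj <- list(list(xyz = matrix(x, natom, 3, byrow = TRUE), energy = cur$E))
  converged <- FALSE
  nstep <- 0L
  gp_old <- NULL; x_old <- NULL

  for (step in seq_len(settings$max_steps)) {
    Qr <- removed_space(mol, x, project_rot, constraints)
    gp <- project_vector(cur$g, Qr, free_mask)
    gmax <- max(abs(gp)); grms <- sqrt(mean(gp[free_mask]^2))
    if (gmax <= settings$grad_max && grms <= settings$grad_rms) {
      converged <- TRUE
      break
    }
    # BFGS update from the previous accepted step
    if (!is.null(gp_old)) {
      s <- x - x_old; y <- gp - gp_old
      sy <- sum(s * y)
      if (sy > 1e-10 * vnorm(s) * vnorm(y)) {
        Hs <- H %*% s
        H <- H + tcrossprod(y) / sy -
          tcrossprod(Hs) / as.numeric(crossprod(s, Hs))
      }
    }
    gp_old <- gp; x_old <- x

    # trust-region quasi-Newton step with Levenberg shift
    accepted <- FALSE
    for (attempt in 1:12) {
      mu <- 0
      repeat {
        dn <- tryCatch(-solve(H + mu * diag(nfree), gp),
                       error = function(e) NULL)
        if (!is.null(dn)) {
          dn <- project_vector(dn, Qr, free_mask)
          if (vnorm(dn) <= trust * 1.0001) break
        }
        mu <- if (mu == 0) 1e-4 else mu * 3
        if (mu > 1e6) { dn <- -trust * gp / max(vnorm(gp), 1e-12); break }
      }
      x_new <- x + dn
      if (!is.null(constraints$dihedrals))
        x_new <- as.numeric(t(restore_constraints(
          matrix(x_new, natom, 3, byrow = TRUE), constraints, free_mask)))
      nxt <- eval_point(x_new)
      if (nxt$E <= cur$E + 1e-12) {
        if (vnorm(dn) > 0.8 * trust)
          trust <- min(trust * 1.4, settings$trust_max)
        x <- x_new; cur <- nxt
        accepted <- TRUE
        break
      }
      trust <- trust * 0.3
      if (trust < 1e-7) break
    }
    if (!accepted) break
    nstep <- step
    traj[[length(traj) + 1L]] <- list(xyz = matrix(x, natom, 3, byrow = TRUE),
                                      energy = cur$E)
  }

  final_mol <- set_coords(mol, matrix(x, natom, 3, byrow = TRUE))
  structure(list(molecule = final_mol, energy = cur$E,
                 state = cur$state, gradient = cur$grad_obj,
                 trajectory = traj, converged = converged, n_steps = nstep,
                 settings = settings, fields = fields),
            class = "qed_opt")
}

#' @export
print.qed_opt <- function(x, ...) {
  cat(sprintf("<qed_opt> %s after %d steps, E = %.10f hartree\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_steps, x$energy))
  invisible(x)
}

# --------------------------------------------------------------- scans

label_stationary <- function(E, periodic = FALSE) {
  n <- length(E)
  lab <- rep("", n)
  for (i in seq_len(n)) {
    if (periodic) {
      im <- if (i == 1) n - 1 else i - 1   # grid includes duplicated endpoint
      ip <- if (i == n) 2 else i + 1
    } else {
      if (i == 1 || i == n) next
      im <- i - 1; ip <- i + 1
    }
    if (E[i] < E[im] && E[i] < E[ip]) lab[i] <- "minimum"
    if (E[i] > E[im] && E[i] > E[ip]) lab[i] <- "maximum"
  }
  lab
}

#' Rigid-rotation potential-energy scan
#'
#' Rotates the molecule rigidly about an axis through its centre of mass
#' while the external fields stay fixed in the laboratory frame, computing
#' the SCF energy at every grid point.  The 0/360-degree endpoints are both
#' computed as a periodicity check.
#'
#' @param mol reference [molecule()] (treated as rigid).
#' @param basis an uncontracted `qed_basis`.
#' @param axis rotation axis: `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @param increment_deg grid increment in degrees.
#' @param fields a [field_config()].
#' @param scf_settings [scf_settings()].
#' @return an object of class `qed_scan` with columns `grid` (deg),
#'   `energy` (hartree) and stationary-point `label`s.
#' @export
rigid_rotation_scan <- function(mol, basis, axis = "x", increment_deg = 5,
                                fields = field_config(),
                                scf_settings = qedhf::scf_settings()) {
  if (is.character(axis))
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("axis must be x, y, z or a 3-vector"))
  if (vnorm(axis) < 1e-12) stop("zero-length rotation axis")
  com <- center_of_mass(mol)
  grid <- seq(0, 360, by = increment_deg)
  prev_D <- NULL
  E <- vapply(grid, function(a) {
    m <- rotate_molecule(mol, axis, a, center = com)
    st <- scf_solve(m, basis, fields, scf_settings, D0 = prev_D)
    prev_D <<- Re(st$D)
    st$E_total
  }, numeric(1))
  structure(list(grid = grid, energy = E,
                 label = label_stationary(E, periodic = TRUE),
                 periodicity_error = abs(E[1] - E[length(E)]),
                 axis = axis, fields = fields), class = "qed_scan")
}

#' @export
print.qed_scan <- function(x, ...) {
  df <- data.frame(grid = x$grid, energy = x$energy, label = x$label)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Constrained-dihedral relaxed scan
#'
#' At every grid value the named dihedral is held fixed while all other
#' degrees of freedom are relaxed; consecutive points are warm-started from
#' the previous optimized geometry.
#'
#' @param mol starting [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param dihedral_spec integer vector of four atom indices.
#' @param grid_deg dihedral grid (degrees), strictly monotone.
#' @param fields a [field_config()].
#' @param settings [opt_settings()].
#' @param scf_settings [scf_settings()].
#' @return a `qed_scan` whose elements also carry the relaxed geometries.
#' @export
constrained_scan <- function(mol, basis, dihedral_spec, grid_deg,
                             fields = field_config(),
                             settings = opt_settings(),
                             scf_settings = qedhf::scf_settings()) {
  stopifnot(length(dihedral_spec) == 4L)
  if (length(grid_deg) > 1L &&
      !(all(diff(grid_deg) > 0) || all(diff(grid_deg) < 0)))
    stop("scan grid must be strictly monotone")
  cur <- mol
  E <- numeric(length(grid_deg))
  geoms <- vector("list", length(grid_deg))
  for (i in seq_along(grid_deg)) {
    cons <- list(dihedrals = list(list(atoms = dihedral_spec,
                                       value = grid_deg[i])))
    res <- optimize_geometry(cur, basis, fields, settings, cons, scf_settings)
    E[i] <- res$energy
    geoms[[i]] <- res$molecule
    cur <- res$molecule
  }
  structure(list(grid = grid_deg, energy = E,
                 label = label_stationary(E), geometries = geoms,
                 dihedral = dihedral_spec, fields = fields),
            class = "qed_scan")
}

#' Sweep of optimized internal coordinates versus coupling strength
#'
#' Optimizes the geometry at each coupling strength (warm-starting from the
#' previous optimum), measures the requested internal coordinates, and
#' reports signed changes relative to the first grid point.
#'
#' @param mol starting [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @param mode_direction unit polarization vector of the cavity mode.
#' @param lambdas monotone grid of coupling magnitudes (a.u.).
#' @param definitions internal-coordinate definitions for
#'   [measure_internals()].
#' @param omega mode frequency (hartree; energies do not depend on it).
#' @param settings [opt_settings()].
#' @param scf_settings [scf_settings()].
#' @param E_ext optional static field applied at every grid point.
#' @return data.frame with lambda, energy, the measured internals and their
#'   deltas from the first point.
#' @export
coupling_sweep <- function(mol, basis, mode_direction = c(0, 0, 1),
                           lambdas = seq(0, 0.1, by = 0.02),
                           definitions = list(), omega = 0.5,
                           settings = opt_settings(),
                           scf_settings = qedhf::scf_settings(),
                           E_ext = c(0, 0, 0)) {
  stopifnot(all(diff(lambdas) > 0) || all(diff(lambdas) < 0))
  u <- mode_direction / vnorm(mode_direction)
  cur <- mol
  rows <- list()
  for (i in seq_along(lambdas)) {
    fl <- if (lambdas[i] == 0 && all(E_ext == 0)) field_config(E_ext = E_ext)
          else field_config(modes = list(cavity_mode(lambdas[i] * u, omega)),
                            E_ext = E_ext)
    res <- optimize_geometry(cur, basis, fl, settings,
                             scf_settings = scf_settings)
    cur <- res$molecule
    ic <- measure_internals(cur, definitions)
    rows[[i]] <- c(lambda = lambdas[i], energy = res$energy, unlist(ic))
  }
  df <- as.data.frame(do.call(rbind, rows))
  icnames <- setdiff(names(df), c("lambda", "energy"))
  for (nm in icnames) df[[paste0("delta_", nm)]] <- df[[nm]] - df[[nm]][1]
  df
}

#' Inversion barrier of a pyramidal molecule versus coupling
#'
#' Surrogate workflow for bowl-inversion studies: for each coupling the
#' pyramidal minimum is freely optimized and the planar transition
#' configuration is optimized with all out-of-plane (z) coordinates frozen
#' at zero.  The molecule must start oriented with its symmetry axis along
#' z (as the bundled ammonia fixture is); the cavity polarization is along
#' z as well.
#'
#' @param mol pyramidal starting [molecule()] with symmetry axis along z.
#' @param basis an uncontracted `qed_basis`.
#' @param lambdas coupling grid (a.u.).
#' @param omega cavity frequency (hartree).
#' @param settings [opt_settings()].
#' @param scf_settings [scf_settings()].
#' @return data.frame with lambda, E_min, E_planar, and barrier (hartree).
#' @export
inversion_barrier_sweep <- function(mol, basis, lambdas = c(0, 0.025, 0.05),
                                    omega = 0.5, settings = opt_settings(),
                                    scf_settings = qedhf::scf_settings()) {
  natom <- mol$natom
  planar_start <- set_coords(mol, cbind(mol$xyz[, 1:2], 0))
  frozen_z <- 3L * seq_len(natom)
  cur_min <- mol; cur_pl <- planar_start
  rows <- list()
  for (i in seq_along(lambdas)) {
    fl <- if (lambdas[i] == 0) field_config()
          else field_config(modes = list(cavity_mode(c(0, 0, lambdas[i]), omega)))
    rmin <- optimize_geometry(cur_min, basis, fl, settings,
                              scf_settings = scf_settings)
    rpl <- optimize_geometry(cur_pl, basis, fl, settings,
                             constraints = list(frozen = frozen_z),
                             scf_settings = scf_settings)
    cur_min <- rmin$molecule; cur_pl <- rpl$molecule
    rows[[i]] <- c(lambda = lambdas[i], E_min = rmin$energy,
                   E_planar = rpl$energy,
                   barrier = rpl$energy - rmin$energy)
  }
  as.data.frame(do.call(rbind, rows))
}
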