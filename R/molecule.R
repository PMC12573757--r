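# Molecules: construction, XYZ I/O, fixtures, rigid transforms.

#' Construct a molecule
#'
#' A molecule is an ordered list of atoms (element symbol, nuclear charge,
#' Cartesian position in bohr) plus a total charge.  The closed-shell SCF
#' requires an even electron count, which is validated here.
#'
#' @param symbols character vector of element symbols.
#' @param xyz numeric matrix (natom x 3) of Cartesian coordinates, bohr.
#' @param charge integer total molecular charge.
#' @return an object of class `qed_molecule`.
#' @export
molecule <- function(symbols, xyz, charge = 0L) {
  xyz <- as.matrix(xyz)
  if (length(symbols) < 1L) stop("a molecule needs at least one atom")
  if (nrow(xyz) != length(symbols) || ncol(xyz) != 3L)
    stop("xyz must be a length(symbols) x 3 matrix")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  Z <- element_Z(symbols)
  nelec <- sum(Z) - charge
  if (nelec <= 0L) stop("no electrons left at charge ", charge)
  if (nelec %% 2L != 0L)
    stop("odd electron count (", nelec, "): only closed-shell systems are supported")
  structure(list(symbols = as.character(symbols), Z = Z,
                 xyz = unname(xyz), charge = as.integer(charge),
                 natom = length(symbols), nelec = as.integer(nelec)),
            class = "qed_molecule")
}

#' @export
print.qed_molecule <- function(x, ...) {
  cat(sprintf("<qed_molecule> %d atoms, charge %d, %d electrons\n",
              x$natom, x$charge, x$nelec))
  ang <- angstrom_from_bohr(x$xyz)
  for (i in seq_len(x$natom))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$symbols[i],
                ang[i, 1], ang[i, 2], ang[i, 3]))
  invisible(x)
}

nuclear_dipole <- function(mol) as.numeric(crossprod(mol$Z, mol$xyz))

center_of_nuclear_charge <- function(mol) nuclear_dipole(mol) / sum(mol$Z)

center_of_mass <- function(mol) {
  m <- element_mass(mol$symbols)
  as.numeric(crossprod(m, mol$xyz)) / sum(m)
}

#' Nuclear repulsion energy
#' @param mol a [molecule()].
#' @return energy in hartree.
#' @export
nuclear_repulsion <- function(mol) {
  e <- 0
  if (mol$natom < 2L) return(0)
  for (i in 2:mol$natom) for (j in 1:(i - 1)) {
    r <- sqrt(sum((mol$xyz[i, ] - mol$xyz[j, ])^2))
    if (r < 1e-8)
      stop("coincident nuclei ", i, " and ", j, ": nuclear repulsion is singular")
    e <- e + mol$Z[i] * mol$Z[j] / r
  }
  e
}

set_coords <- function(mol, xyz) {
  mol$xyz <- unname(as.matrix(xyz))
  mol
}

translate_molecule <- function(mol, t) set_coords(mol, sweep(mol$xyz, 2, t, "+"))

rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotate_molecule <- function(mol, axis, angle_deg, center = c(0, 0, 0)) {
  R <- rotation_matrix(axis, angle_deg)
  xyz <- sweep(mol$xyz, 2, center)
  set_coords(mol, sweep(xyz %*% t(R), 2, center, "+"))
}

# ------------------------------------------------------------------ XYZ I/O

#' Read a molecule from an XYZ file
#'
#' Coordinates in the file are in Angstrom and are converted to bohr.
#' Windows line endings are tolerated.
#'
#' @param path path to an XYZ file.
#' @param charge total charge to assign (XYZ carries none).
#' @return a [molecule()].
#' @export
read_xyz <- function(path, charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 2L) stop("XYZ parse error: file too short (line 1)")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("XYZ parse error: bad atom count (line 1)")
  if (length(lines) < n + 2L)
    stop("XYZ parse error: expected ", n, " atom records, file ends at line ",
         length(lines))
  sym <- character(n); xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L)
      stop("XYZ parse error: malformed atom record (line ", ln, ")")
    sym[i] <- tok[1]
    co <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(co))
      stop("XYZ parse error: non-numeric coordinate (line ", ln, ")")
    xyz[i, ] <- co
  }
  if (anyNA(match(sym, .elements$symbol))) {
    bad <- which(is.na(match(sym, .elements$symbol)))[1]
    stop("XYZ parse error: unknown element '", sym[bad], "' (line ", bad + 2L, ")")
  }
  molecule(sym, bohr_from_angstrom(xyz), charge = charge)
}

#' Write molecules to an XYZ file
#'
#' Accepts a single molecule or a list of molecules (multi-frame trajectory).
#'
#' @param mol a [molecule()] or list of molecules.
#' @param path output path.
#' @param comment comment line(s), recycled across frames.
#' @export
write_xyz <- function(mol, path, comment = "") {
  frames <- if (inherits(mol, "qed_molecule")) list(mol) else mol
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    ang <- angstrom_from_bohr(m$xyz)
    writeLines(as.character(m$natom), con)
    writeLines(comment[f], con)
    for (i in seq_len(m$natom))
      writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", m$symbols[i],
                         ang[i, 1], ang[i, 2], ang[i, 3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------- fixtures

#' Built-in starting geometries
#'
#' Deterministic, literature-typical starting structures for the systems the
#' package is exercised on.  These are generic textbook geometries intended
#' as optimization starts, not optimized results: water is C2v with
#' r(OH) = 0.9572 A and a(HOH) = 104.52 deg (dipole along +z); ammonia is a
#' C3v pyramid with r(NH) = 1.012 A and a(HNH) = 106.7 deg (C3 axis along z);
#' h2 is symmetric about the origin; water_dimer is a Cs hydrogen-bonded
#' donor-acceptor arrangement with O...O = 2.98 A in which the tracked
#' donor-acceptor dihedral (atoms H_donor-free, O_donor, O_acceptor,
#' H_acceptor) is well defined.
#'
#' @param name one of `"water"`, `"water_dimer"`, `"ammonia"`, `"h2"`.
#' @return a [molecule()].
#' @export
make_fixture <- function(name) {
  A <- qed_constants$angstrom_per_bohr
  geom <- switch(name,
    water = {
      r <- 0.9572 / A; th <- 104.52 * pi / 180
      # dipole along +z: O below, H above
      list(sym = c("O", "H", "H"),
           xyz = rbind(c(0, 0, 0),
                       c(0,  r * sin(th / 2), r * cos(th / 2)),
                       c(0, -r * sin(th / 2), r * cos(th / 2))))
    },
    h2 = {
      d <- 0.7414 / A
      list(sym = c("H", "H"), xyz = rbind(c(0, 0, -d / 2), c(0, 0, d / 2)))
    },
    ammonia = {
      r <- 1.012 / A; a_hnh <- 106.7 * pi / 180
      # ring radius rho and height h from bond length and H-N-H angle
      rho <- r * sqrt(2 * (1 - cos(a_hnh)) / 3)
      h <- sqrt(r^2 - rho^2)
      ang <- c(90, 210, 330) * pi / 180
      list(sym = c("N", "H", "H", "H"),
           xyz = rbind(c(0, 0, h),
                       t(sapply(ang, function(p) c(rho * cos(p), rho * sin(p), 0)))))
    },
    water_dimer = {
      # Cs donor-acceptor arrangement, O...O along +x.  Donor in the xz
      # (mirror) plane: bridging H on the O-O axis, free H pointing down
      # (-z).  Acceptor H atoms mirror-symmetric about xz, with the
      # acceptor bisector pointing away from the donor and tilted up by
      # ~57 deg from the O-O axis (trans to the donor free H), the
      # textbook hydrogen-bond geometry.  The tracked donor-acceptor
      # dihedral (atoms 3-1-4-5: free H, donor O, acceptor O, first
      # acceptor H) is approximately -120 deg in this arrangement.
      roh <- 0.9572 / A; th <- 104.52 * pi / 180; roo <- 2.98 / A
      tilt <- 57 * pi / 180          # acceptor tilt from the O-O axis
      hb <- c(roh, 0, 0)             # bridging H (nearly linear H bond)
      hf <- c(roh * cos(th), 0, -roh * sin(th))  # free H of the donor, down
      bis <- c(cos(tilt), 0, sin(tilt))          # acceptor bisector, up/away
      half <- th / 2
      oa <- c(roo, 0, 0)
      h1 <- oa + roh * (cos(half) * bis + sin(half) * c(0, 1, 0))
      h2 <- oa + roh * (cos(half) * bis - sin(half) * c(0, 1, 0))
      list(sym = c("O", "H", "H", "O", "H", "H"),
           xyz = rbind(c(0, 0, 0), hb, hf, oa, h1, h2))
    },
    stop("unknown fixture '", name, "'; available: water, water_dimer, ammonia, h2")
  )
  molecule(geom$sym, geom$xyz)
}
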