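# Gaussian basis sets: reading the standard exchange text format,
# uncontraction, and assembly of the per-molecule shell table consumed by
# the compiled integral engine.

.l_letter <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)

#' Read a basis set in Gaussian94 exchange text format
#'
#' Parses the plain-text basis format used by basis-set exchanges
#' (`****`-separated element blocks, shell headers like `S 3 1.00`, and
#' combined `SP` shells which are split into S and P).  Bundled sets can be
#' referred to by name (`"sto-3g"`, `"aug-cc-pvdz"`).
#'
#' @param name_or_path name of a bundled basis or path to a `.gbs` file.
#' @return an object of class `qed_basis`: a named list (per element) of
#'   shells, each with `l`, `exponents`, `coefficients`; attribute
#'   `uncontracted` is `FALSE`.
#' @export
read_basis <- function(name_or_path) {
  path <- name_or_path
  if (!file.exists(path)) {
    cand <- system.file("extdata", "basis", paste0(tolower(name_or_path), ".gbs"),
                        package = "qedhf")
    if (!nzchar(cand))
      stop("basis '", name_or_path, "' not found (no such file or bundled set)")
    path <- cand
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*!", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "****") { i <- i + 1L; next }
    tok <- strsplit(lines[i], "\\s+")[[1]]
    elem <- tok[1]
    i <- i + 1L
    shells <- list()
    while (i <= n && lines[i] != "****") {
      hd <- strsplit(lines[i], "\\s+")[[1]]
      ltag <- toupper(hd[1])
      nprim <- as.integer(hd[2])
      i <- i + 1L
      rows <- do.call(rbind, lapply(lines[i:(i + nprim - 1L)], function(s) {
        as.numeric(strsplit(gsub("[dD]([+-])", "e\\1", s), "\\s+")[[1]])
      }))
      i <- i + nprim
      if (ltag == "SP") {
        shells[[length(shells) + 1L]] <-
          list(l = 0L, exponents = rows[, 1], coefficients = rows[, 2])
        shells[[length(shells) + 1L]] <-
          list(l = 1L, exponents = rows[, 1], coefficients = rows[, 3])
      } else {
        if (!ltag %in% names(.l_letter))
          stop("unsupported shell type '", ltag, "' in ", path)
        shells[[length(shells) + 1L]] <-
          list(l = .l_letter[[ltag]], exponents = rows[, 1],
               coefficients = rows[, 2])
      }
    }
    out[[elem]] <- shells
  }
  structure(out, class = "qed_basis", uncontracted = FALSE,
            name = if (identical(path, name_or_path)) basename(path) else name_or_path)
}

#' Uncontract a basis set
#'
#' Drops all contraction coefficients, promotes every primitive Gaussian to
#' its own single-primitive shell with unit coefficient, and removes
#' duplicate (element, l, exponent) primitives, following the usual meaning
#' of an "unc-" basis prefix.  Uncontracted bases give the orbitals the
#' radial flexibility needed under external fields, where contraction
#' coefficients optimized field-free are a bias.
#'
#' @param basis a `qed_basis` from [read_basis()].
#' @return a `qed_basis` with attribute `uncontracted = TRUE` in which every
#'   shell holds exactly one primitive.
#' @export
uncontract_basis <- function(basis) {
  if (isTRUE(attr(basis, "uncontracted"))) return(basis)
  out <- lapply(basis, function(shells) {
    seen <- character()
    res <- list()
    for (sh in shells) {
      for (e in sh$exponents) {
        key <- paste(sh$l, format(e, digits = 15))
        if (key %in% seen) next
        seen <- c(seen, key)
        res[[length(res) + 1L]] <- list(l = sh$l, exponents = e,
                                        coefficients = 1)
      }
    }
    res
  })
  attributes(out) <- attributes(basis)
  attr(out, "uncontracted") <- TRUE
  out
}

#' Number of basis functions a basis yields for a molecule
#' @param mol a [molecule()].
#' @param basis an uncontracted `qed_basis`.
#' @return integer count of spherical AO basis functions.
#' @export
n_basis_functions <- function(mol, basis) {
  st <- shell_table(mol, basis)
  sum(2L * st[, 2L] + 1L)
}

# shell table for the C++ engine: columns atom, l, exponent, x, y, z
shell_table <- function(mol, basis) {
  if (!isTRUE(attr(basis, "uncontracted")))
    stop("the integral engine operates on uncontracted bases; ",
         "call uncontract_basis() first")
  missing <- setdiff(unique(mol$symbols), names(basis))
  if (length(missing))
    stop("basis-coverage error: no basis functions for element(s) ",
         paste(missing, collapse = ", "))
  rows <- list()
  for (a in seq_len(mol$natom)) {
    for (sh in basis[[mol$symbols[a]]]) {
      rows[[length(rows) + 1L]] <-
        c(a, sh$l, sh$exponents[1], mol$xyz[a, ])
    }
  }
  st <- do.call(rbind, rows)
  colnames(st) <- c("atom", "l", "exponent", "x", "y", "z")
  st
}

atom_table <- function(mol) {
  cbind(Z = mol$Z, mol$xyz)
}
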