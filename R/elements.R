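# Element data: symbols, nuclear charges, standard atomic weights (for the
# centre of mass used by rigid-rotation scans).

.elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z      = 1:18,
  mass   = c(1.008, 4.0026, 6.94, 9.0122, 10.81, 12.011, 14.007, 15.999,
             18.998, 20.180, 22.990, 24.305, 26.982, 28.085, 30.974, 32.06,
             35.45, 39.948),
  stringsAsFactors = FALSE
)

element_Z <- function(symbol) {
  i <- match(symbol, .elements$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  .elements$Z[i]
}

element_symbol <- function(Z) {
  i <- match(Z, .elements$Z)
  if (anyNA(i)) stop("unknown nuclear charge: ", Z[is.na(i)][1], call. = FALSE)
  .elements$symbol[i]
}

element_mass <- function(symbol) .elements$mass[match(symbol, .elements$symbol)]
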