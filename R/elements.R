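# Element tables: nuclear charges and Bondi van der Waals radii.

.element_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
                S = 16, Cl = 17, Ar = 18)

# Bondi van der Waals radii (angstrom)
.bondi_radii_ang <- c(H = 1.20, He = 1.40, Li = 1.82, B = 1.92, C = 1.70,
                      N = 1.55, O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27,
                      Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
                      Ar = 1.88)

normalize_element <- function(sym) {
  s <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
  s
}

element_charge <- function(sym) {
  s <- normalize_element(sym)
  z <- .element_Z[s]
  if (any(is.na(z))) stop("unknown element: ", paste(sym[is.na(z)], collapse = ", "))
  unname(z)
}

#' Bondi van der Waals radius
#'
#' @param sym element symbol(s)
#' @return radius in bohr
#' @export
vdw_radius <- function(sym) {
  s <- normalize_element(sym)
  r <- .bondi_radii_ang[s]
  if (any(is.na(r))) stop("no van der Waals radius for: ",
                          paste(sym[is.na(r)], collapse = ", "))
  ang2bohr(unname(r))
}
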