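# QM and MM subsystem containers.

#' Create a QM region
#'
#' The QM region holds the quantum subsystem: element symbols, nuclear charges
#' and Cartesian coordinates in bohr.
#'
#' @param elements character vector of element symbols
#' @param xyz numeric matrix (n x 3) of coordinates in bohr
#' @param charge total molecular charge
#' @param multiplicity spin multiplicity (only 1 supported: closed shell)
#' @return an object of class `qm_region`
#' @export
qm_region <- function(elements, xyz, charge = 0L, multiplicity = 1L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(elements) != nrow(xyz)) stop("elements/coordinates length mismatch")
  if (length(elements) < 1) stop("QM region needs at least one atom")
  if (multiplicity != 1L) stop("only closed-shell (multiplicity 1) is supported")
  el <- normalize_element(elements)
  obj <- list(elements = el, Z = element_charge(el), xyz = xyz,
              charge = as.integer(charge), multiplicity = 1L)
  class(obj) <- "qm_region"
  obj
}

#' @export
print.qm_region <- function(x, ...) {
  cat("QM region:", length(x$elements), "atoms, charge", x$charge, "\n")
  invisible(x)
}

#' Create an MM region
#'
#' The MM subsystem: fixed force-field point charges, Lennard-Jones sites and
#' intramolecular bonded terms. Charges are fixed (no polarization).
#'
#' @param elements element symbols per site
#' @param xyz coordinates (bohr), n x 3
#' @param charges fixed force-field charges (au)
#' @param sigma Lennard-Jones sigma per site (bohr)
#' @param epsilon Lennard-Jones epsilon per site (hartree)
#' @param molecule integer molecule membership index per site
#' @param bonds data.frame(i, j, k, r0): harmonic bonds, k in hartree/bohr^2
#' @param angles data.frame(i, j, k, kth, th0): harmonic angles, kth in
#'   hartree/rad^2, th0 in radians, j is the apex
#' @param torsions data.frame(i, j, k, l, vn, n, gamma): periodic torsions,
#'   E = vn (1 + cos(n phi - gamma))
#' @return object of class `mm_region`
#' @export
mm_region <- function(elements, xyz, charges, sigma, epsilon, molecule,
                      bonds = NULL, angles = NULL, torsions = NULL) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  stopifnot(length(charges) == n, length(sigma) == n, length(epsilon) == n,
            length(molecule) == n)
  empty_b <- data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
  empty_a <- data.frame(i = integer(), j = integer(), k = integer(),
                        kth = numeric(), th0 = numeric())
  empty_t <- data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
                        vn = numeric(), n = numeric(), gamma = numeric())
  obj <- list(elements = normalize_element(elements), xyz = xyz,
              charges = as.numeric(charges), sigma = as.numeric(sigma),
              epsilon = as.numeric(epsilon), molecule = as.integer(molecule),
              bonds = if (is.null(bonds)) empty_b else bonds,
              angles = if (is.null(angles)) empty_a else angles,
              torsions = if (is.null(torsions)) empty_t else torsions)
  # each molecule's bonded terms must reference only its own sites
  chk <- function(df, cols) {
    for (r in seq_len(nrow(df))) {
      idx <- unlist(df[r, cols])
      if (length(unique(obj$molecule[idx])) > 1)
        stop("bonded term crosses molecule boundary: row ", r)
    }
  }
  chk(obj$bonds, c("i", "j")); chk(obj$angles, c("i", "j", "k"))
  chk(obj$torsions, c("i", "j", "k", "l"))
  class(obj) <- "mm_region"
  obj
}

#' @export
print.mm_region <- function(x, ...) {
  cat("MM region:", nrow(x$xyz), "sites,", length(unique(x$molecule)),
      "molecules, total charge", sprintf("%.4f", sum(x$charges)), "\n")
  invisible(x)
}

#' Empty MM region (gas phase)
#'
#' @return an `mm_region` with zero sites
#' @export
mm_empty <- function() {
  mm_region(character(0), matrix(numeric(0), ncol = 3), numeric(0),
            numeric(0), numeric(0), integer(0))
}
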