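# Potential-energy-surface scans along the branching-plane vectors, with the
# solvent-vs-solute weight decomposition of each vector.

#' Scan state energies along the branching-plane vectors
#'
#' Displaces the full (QM + MM) geometry along the normalized difference
#' vector and, separately, the orthogonal vector of a branching plane, and
#' computes single-point state energies on the 1D grids. Also reports the
#' solute/solvent weight decomposition of each plane vector (sum of squared
#' components over the QM vs MM blocks).
#'
#' @param surf a [qmmm_surface()] (or any surface)
#' @param center coordinate vector at the scan center
#' @param plane a [branching_plane()]
#' @param extent maximal displacement (bohr) in each direction
#' @param n_points points per side (total `2 n + 1` per vector); with
#'   `extent = 0` only the center is evaluated
#' @param states state indices to evaluate
#' @param nqm3 size of the QM block of the coordinate vector (for the weight
#'   decomposition; defaults to the full dimension)
#' @return data.frame with vector label, displacement, energies (hartree and
#'   eV) per state, plus attribute `weights`
#' @export
scan_branching_plane <- function(surf, center, plane, extent, n_points,
                                 states = c(1, 2), nqm3 = length(center)) {
  disp <- if (extent == 0 || n_points == 0) 0 else
    seq(-extent, extent, length.out = 2 * n_points + 1)
  vecs <- list(d = plane$d, o = plane$o)
  rows <- list()
  for (vn in names(vecs)) {
    v <- vecs[[vn]]
    for (s in disp) {
      E <- tryCatch(surface_eval(surf, center + s * v, states,
                                 gradients = FALSE)$E,
                    error = function(e) rep(NA_real_, length(states)))
      rows[[length(rows) + 1]] <- data.frame(
        vector = vn, displacement = s,
        state = states, energy_hartree = E,
        energy_ev = E * units_au$ev_per_hartree)
    }
    if (identical(disp, 0)) break  # zero extent: single reference row set
  }
  out <- do.call(rbind, rows)
  wsolute <- vapply(vecs, function(v) sum(v[seq_len(nqm3)]^2), 0.0)
  wsolvent <- vapply(vecs, function(v)
    if (length(v) > nqm3) sum(v[-seq_len(nqm3)]^2) else 0.0, 0.0)
  attr(out, "weights") <- data.frame(vector = names(vecs),
                                     solute = wsolute, solvent = wsolvent)
  out
}
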