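# Analytic model surfaces for optimizer verification, and the surface
# abstraction shared by the model and QM/MM backends.
#
# A "surface" is an object with an eval method returning, at a coordinate
# vector x, the total energies of the requested states and (optionally) their
# gradients. States are indexed 1..n ascending in energy.

#' Evaluate a surface
#'
#' @param surf a surface object (see [model_two_state()], [qmmm_surface()])
#' @param x coordinate vector
#' @param states integer vector of state indices (1-based adiabatic order)
#' @param gradients compute gradients too
#' @return list with `E` (named by state) and `grads` (list of vectors)
#' @export
surface_eval <- function(surf, x, states, gradients = TRUE) {
  UseMethod("surface_eval")
}

#' Two-state linear-coupling conical-intersection model
#'
#' Diabatic Hamiltonian `H(x, y) = [[kappa x, lambda y], [lambda y, -kappa x]]`
#' with adiabatic energies `+- sqrt(kappa^2 x^2 + lambda^2 y^2)`; the conical
#' intersection sits at the origin. Optional spectator coordinates are bound
#' harmonically (added to both states), embedding the 2D model in a higher
#' dimension.
#'
#' @param kappa,lambda coupling constants
#' @param n_spectators extra harmonic coordinates
#' @param k_spec spectator force constant
#' @param spec_center spectator minimum position (recycled)
#' @return a surface object
#' @export
model_two_state <- function(kappa = 1, lambda = 1, n_spectators = 0L,
                            k_spec = 0.5, spec_center = 0) {
  surf <- list(kappa = kappa, lambda = lambda, n_spectators = n_spectators,
               k_spec = k_spec,
               spec_center = rep(spec_center, length.out = n_spectators),
               dim = 2L + n_spectators, n_states = 2L)
  class(surf) <- c("model_two_state", "surface")
  surf
}

#' @export
surface_eval.model_two_state <- function(surf, x, states, gradients = TRUE) {
  stopifnot(length(x) == surf$dim)
  r <- sqrt(surf$kappa^2 * x[1]^2 + surf$lambda^2 * x[2]^2)
  espec <- 0; gspec <- numeric(surf$n_spectators)
  if (surf$n_spectators > 0) {
    ds <- x[-(1:2)] - surf$spec_center
    espec <- 0.5 * surf$k_spec * sum(ds^2)
    gspec <- surf$k_spec * ds
  }
  E <- c(espec - r, espec + r)
  grads <- NULL
  if (gradients) {
    if (r < 1e-300) r <- 1e-300
    dr <- c(surf$kappa^2 * x[1], surf$lambda^2 * x[2]) / r
    grads <- lapply(states, function(s) {
      sgn <- if (s == 1) -1 else 1
      c(sgn * dr, gspec)
    })
  }
  list(E = E[states], grads = grads)
}

#' QM/MM potential-energy surface adaptor
#'
#' Wraps a [qmmm_system()] as a surface over the concatenated (QM, MM)
#' Cartesian coordinates. State 1 is the ground state, state `I + 1` the
#' I-th excited state. Electronic states are tracked across calls by the
#' overlap of their AO transition densities; when the maximal overlap is
#' ambiguous (< 0.5) energy order is used.
#'
#' @param sys a [qmmm_system()]
#' @param n_excited excited states to carry
#' @return a surface object
#' @export
qmmm_surface <- function(sys, n_excited = 0L) {
  surf <- list(sys = sys, n_excited = as.integer(n_excited),
               nqm3 = 3L * nrow(sys$qm$xyz), nmm3 = 3L * nrow(sys$mm$xyz),
               dim = 3L * (nrow(sys$qm$xyz) + nrow(sys$mm$xyz)),
               n_states = 1L + as.integer(n_excited),
               track = new.env(parent = emptyenv()))
  class(surf) <- c("qmmm_surface", "surface")
  surf
}

# overlap-based state reordering; returns permutation of 1..n_excited
track_states <- function(surf, pt) {
  n <- length(pt$states)
  if (n == 0) return(integer(0))
  S <- pt$handle$S
  Rs <- lapply(pt$states, function(st)
    pt$scf$C[, seq_len(pt$handle$nocc), drop = FALSE] %*% st$X %*%
      t(pt$scf$C[, -seq_len(pt$handle$nocc), drop = FALSE]))
  perm <- seq_len(n)
  prev <- surf$track$R_prev
  if (!is.null(prev) && length(prev) == n) {
    ov <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      ov[i, j] <- abs(sum((S %*% prev[[i]] %*% S) * Rs[[j]]))
    # normalize by the metric norms of both sets
    nrm_prev <- vapply(prev, function(r) abs(sum((S %*% r %*% S) * r)), 0.0)
    nrm_cur <- vapply(Rs, function(r) abs(sum((S %*% r %*% S) * r)), 0.0)
    ov <- ov / sqrt(outer(nrm_prev, nrm_cur))
    perm <- apply(ov, 1, which.max)
    if (any(duplicated(perm)) || any(apply(ov, 1, max) < 0.5))
      perm <- seq_len(n)   # ambiguous: fall back to energy order
  }
  surf$track$R_prev <- Rs[perm]
  perm
}

#' @export
surface_eval.qmmm_surface <- function(surf, x, states, gradients = TRUE) {
  sys <- sys_with_coords(surf$sys, x[seq_len(surf$nqm3)],
                         if (surf$nmm3 > 0) x[surf$nqm3 + seq_len(surf$nmm3)])
  pt <- prepare_point(sys, n_states = surf$n_excited)
  perm <- track_states(surf, pt)
  if (length(perm)) pt$states <- pt$states[perm]
  E <- vapply(states, function(s)
    total_energy(pt, state = if (s > 1) s - 1L else NULL), 0.0)
  grads <- NULL
  if (gradients) {
    grads <- lapply(states, function(s) {
      gv <- if (s == 1) ground_gradient(pt) else excited_gradient(pt, s - 1L)
      as_vector(gv)
    })
  }
  list(E = E, grads = grads, point = pt)
}
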