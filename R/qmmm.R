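# QM/MM assembly: total ESPF-embedded energies and analytic gradients for
# ground and excited states, state-difference gradients, and the
# finite-difference validator.
#
# Gradient block conventions: `x` denotes QM-atom coordinates, `x~` MM-site
# coordinates. The nuclear-MM electrostatic term sum_A Z_A phi_A uses exact
# point-point Coulomb sums (not fitted charges); QM-MM dispersion/repulsion
# is the MM engine's Lennard-Jones wall.

#' Define a QM/MM system
#'
#' Bundles the QM region, MM region and the electronic-structure/grid/optimizer
#' settings. All downstream computations (energies, gradients, optimizations)
#' are functions of this object plus coordinates.
#'
#' @param qm [qm_region()]
#' @param mm [mm_region()] (may be empty, see [mm_empty()])
#' @param basis basis set name
#' @param functional backend model identifier (`"hf"`)
#' @param angular_order,n_shells ESPF grid settings
#' @param scf_conv SCF convergence threshold
#' @return object of class `qmmm_system`
#' @export
qmmm_system <- function(qm, mm = mm_empty(), basis = "sto-3g",
                        functional = "hf", angular_order = 50L,
                        n_shells = 9L, scf_conv = 1e-10) {
  sys <- list(qm = qm, mm = mm, basis = basis, functional = functional,
              angular_order = as.integer(angular_order),
              n_shells = as.integer(n_shells), scf_conv = scf_conv)
  class(sys) <- "qmmm_system"
  sys
}

#' @export
print.qmmm_system <- function(x, ...) {
  cat("QM/MM system:", length(x$qm$elements), "QM atoms /", nrow(x$mm$xyz),
      "MM sites;", x$basis, "\n")
  invisible(x)
}

# replace coordinates (bohr) in a system; x is c(qm_block, mm_block)
sys_with_coords <- function(sys, xqm = NULL, xmm = NULL) {
  if (!is.null(xqm)) sys$qm$xyz <- matrix(xqm, ncol = 3)
  if (!is.null(xmm) && nrow(sys$mm$xyz) > 0) sys$mm$xyz <- matrix(xmm, ncol = 3)
  sys
}

#' Prepare a single point: integrals, grid, fit, embedding, SCF
#'
#' Builds everything needed at the current geometry: the electronic-structure
#' handle, the ESPF grid and charge operators, the external potential, the
#' embedding Hamiltonian and the converged SCF.
#'
#' @param sys a [qmmm_system()]
#' @param n_states excited states to solve for (0 = ground state only)
#' @return environment of class `qmmm_point`
#' @export
prepare_point <- function(sys, n_states = 0L) {
  pt <- new.env(parent = emptyenv())
  pt$sys <- sys
  pt$handle <- electronic_structure(sys$qm, sys$basis, sys$functional)
  pt$grid <- build_grid(sys$qm, sys$angular_order, sys$n_shells)
  pt$ops <- fit_charge_operators(pt$grid, sys$qm, pt$handle)
  pt$pot <- external_potential(sys$mm, sys$qm)
  pt$h_embed <- build_embedding_hamiltonian(pt$ops, pt$pot, pt$handle$S)
  pt$scf <- solve_scf(pt$handle, unclass(pt$h_embed), conv = sys$scf_conv)
  pt$mm_eg <- mm_energy_gradient(sys$mm, sys$qm)
  pt$states <- if (n_states > 0) solve_tda(pt$scf, n_states) else list()
  class(pt) <- "qmmm_point"
  pt
}

# ensure relaxed densities for state I are available
point_state <- function(pt, I) {
  if (I < 1 || I > length(pt$states)) stop("state ", I, " not solved")
  st <- pt$states[[I]]
  if (!isTRUE(st$relaxed)) {
    st <- relaxed_densities(pt$scf, st)
    pt$states[[I]] <- st
  }
  st
}

#' Total QM/MM energy
#'
#' `E = Tr[P(F0 + h')]-consistent QM energy + E_MM + sum_A Z_A phi_A`,
#' plus the excitation energy when a state index is given.
#'
#' @param pt a [prepare_point()] result
#' @param state excited-state index or `NULL`/0 for the ground state
#' @return energy in hartree
#' @export
total_energy <- function(pt, state = NULL) {
  e <- pt$scf$energy + pt$mm_eg$energy + sum(pt$sys$qm$Z * pt$pot$phi)
  if (!is.null(state) && state > 0) {
    if (state > length(pt$states)) stop("state ", state, " not solved")
    e <- e + pt$states[[state]]$omega
  }
  e
}

# gradient container
gradient_vector <- function(g_qm, g_mm, tag = "ground") {
  gv <- list(qm = g_qm, mm = g_mm, tag = tag)
  class(gv) <- "gradient_vector"
  gv
}

#' @export
print.gradient_vector <- function(x, ...) {
  cat("gradient (", x$tag, "): |QM| rms ",
      sprintf("%.3e", sqrt(mean(x$qm^2))), sep = "")
  if (length(x$mm) > 0) cat(", |MM| rms ", sprintf("%.3e", sqrt(mean(x$mm^2))), sep = "")
  cat(" hartree/bohr\n")
  invisible(x)
}

# flatten both blocks
as_vector <- function(gv) c(as.numeric(gv$qm), as.numeric(gv$mm))

# ESPF embedding derivative terms contracted with a (symmetric) density-like
# matrix M: returns list(qm = nqm x 3, mm = nmm x 3) containing
#   d/dx [ sum_A Tr(M Q_A)(Phi_av - phi_A) - Phi_av Tr(M S) ]
espf_embed_gradient <- function(pt, M) {
  sys <- pt$sys
  qm <- sys$qm; pot <- pt$pot
  nqm <- nrow(qm$xyz); nmm <- pot$n_mm
  QA <- espf_populations(M, pt$ops)
  trMS <- sum(M * pt$handle$S)
  # QM block
  dQ <- espf_deriv_contract(M, pt$ops, qm, pt$handle)  # [A, atom, 3]
  g_qm <- matrix(0, nqm, 3)
  for (b in seq_len(nqm)) for (k in 1:3)
    g_qm[b, k] <- sum(dQ[, b, k] * (pot$phi_av - pot$phi))
  # phi_A depends only on R_A among QM coordinates
  # d Phi_av/dx_b = dphi_dqm[b,]/nqm
  for (b in seq_len(nqm)) {
    dphiav <- pot$dphi_dqm[b, ] / nqm
    g_qm[b, ] <- g_qm[b, ] + sum(QA) * dphiav - QA[b] * pot$dphi_dqm[b, ] -
      dphiav * trMS
  }
  g_qm <- g_qm - pot$phi_av * cpp_grad_overlap(pt$handle$shells, M, nqm)
  # MM block: Q_A and S carry no MM dependence
  g_mm <- matrix(0, max(nmm, 1), 3)
  if (nmm > 0) {
    for (k in 1:3) {
      dmm <- pot$dphi_dmm[, , k, drop = FALSE]
      dim(dmm) <- c(nqm, nmm)
      dphiav <- colMeans(dmm)
      g_mm[, k] <- sum(QA) * dphiav - as.numeric(t(dmm) %*% QA) - dphiav * trMS
    }
  }
  list(qm = g_qm, mm = g_mm[seq_len(max(nmm, 0)), , drop = FALSE])
}

# nuclear-MM electrostatics sum_A Z_A phi_A gradients (exact Coulomb)
nuc_mm_gradient <- function(pt) {
  qm <- pt$sys$qm; pot <- pt$pot
  nqm <- nrow(qm$xyz); nmm <- pot$n_mm
  g_qm <- qm$Z * pot$dphi_dqm
  g_mm <- matrix(0, max(nmm, 1), 3)
  if (nmm > 0)
    for (k in 1:3) {
      dmm <- pot$dphi_dmm[, , k, drop = FALSE]
      dim(dmm) <- c(nqm, nmm)
      g_mm[, k] <- as.numeric(t(dmm) %*% qm$Z)
    }
  list(qm = g_qm, mm = g_mm[seq_len(max(nmm, 0)), , drop = FALSE])
}

#' Ground-state analytic QM/MM gradient
#'
#' QM block: `Tr P(F0^x + h'^x) - Tr W S^x + E_MM^x + sum Z_A phi_A^x`;
#' MM block: `sum_A Q_A (Phi_av - phi_A)^x~ + E_MM^x~ + sum Z_A phi_A^x~ -
#' Phi_av^x~ N_el`.
#'
#' @param pt a [prepare_point()] result
#' @return a `gradient_vector`
#' @export
ground_gradient <- function(pt) {
  if (!is.null(pt$g0_cache)) return(pt$g0_cache)
  scf <- pt$scf
  gas <- rhf_gradient_gas(scf)
  emb <- espf_embed_gradient(pt, scf$P)
  nuc <- nuc_mm_gradient(pt)
  g_qm <- gas + emb$qm + nuc$qm + pt$mm_eg$g_qm
  g_mm <- pt$mm_eg$g_mm
  if (length(g_mm) > 0) g_mm <- g_mm + emb$mm + nuc$mm
  pt$g0_cache <- gradient_vector(g_qm, g_mm, "ground")
  pt$g0_cache
}

#' Excited-state analytic QM/MM gradient
#'
#' Lagrangian (Z-vector) gradient of `E_0 + omega_I`: the ground-state
#' gradient plus the excitation-energy gradient, whose embedding part
#' contracts the ESPF operator derivatives with the relaxed difference
#' density and uses the ESPF state populations `Q_A,I = Tr(P_I Q_A)`.
#'
#' @param pt a [prepare_point()] result with states solved
#' @param I state index
#' @return a `gradient_vector`
#' @export
excited_gradient <- function(pt, I) {
  st <- point_state(pt, I)
  g0 <- ground_gradient(pt)
  go <- omega_gradient_embedded(pt, st)
  gradient_vector(g0$qm + go$qm,
                  if (length(g0$mm) > 0) g0$mm + go$mm else g0$mm,
                  sprintf("state %d", I))
}

# omega_I^x and omega_I^x~ (excitation-energy gradient blocks), cached per point
omega_gradient_embedded <- function(pt, st) {
  key <- paste0("go_cache_", st$index)
  if (!is.null(pt[[key]])) return(pt[[key]])
  scf <- pt$scf
  P_I <- st$P_I
  gas <- omega_gradient_gas(scf, st)
  emb <- espf_embed_gradient(pt, P_I)
  pt[[key]] <- list(qm = gas + emb$qm, mm = emb$mm)
  pt[[key]]
}

#' State-difference gradient
#'
#' For two excited states I < J the difference gradient uses the density
#' differences `P_J - P_I`, `W_J - W_I` and `Delta Q_A,IJ`; for `I = 0`
#' (ground) it is the gradient of the excitation energy alone. Implemented as
#' the literal difference of the state-gradient expressions, which realizes
#' the cancellation of the MM and nuclear terms at fixed geometry.
#'
#' @param pt a [prepare_point()] result
#' @param I lower state (0 = ground)
#' @param J upper state
#' @return a `gradient_vector` of `grad(E_J - E_I)`
#' @export
difference_gradient <- function(pt, I, J) {
  if (I == J) stop("degenerate request: I and J must differ")
  gJ <- omega_gradient_embedded(pt, point_state(pt, J))
  if (I == 0) {
    return(gradient_vector(gJ$qm, gJ$mm, sprintf("diff %d-0", J)))
  }
  gI <- omega_gradient_embedded(pt, point_state(pt, I))
  gradient_vector(gJ$qm - gI$qm,
                  if (length(gJ$mm) > 0) gJ$mm - gI$mm else gJ$mm,
                  sprintf("diff %d-%d", J, I))
}

#' Validate an analytic gradient against central finite differences
#'
#' Displaces every coordinate of both blocks, rebuilding the grid, the fit and
#' the SCF at each displaced geometry, and reports the elementwise errors.
#'
#' @param sys a [qmmm_system()]
#' @param state 0 for the ground state, or an excited-state index
#' @param step FD step (bohr), in `[1e-5, 1e-3]`
#' @return list with `analytic`, `fd` and `max_error` per block
#' @export
fd_validate <- function(sys, state = 0L, step = 1e-4) {
  if (step < 1e-5 || step > 1e-3) stop("step outside [1e-5, 1e-3] bohr")
  nst <- max(state, 0L)
  pt <- prepare_point(sys, n_states = nst)
  gan <- if (state > 0) excited_gradient(pt, state) else ground_gradient(pt)
  efun <- function(xq, xm) {
    s2 <- sys_with_coords(sys, xq, xm)
    p2 <- prepare_point(s2, n_states = nst)
    total_energy(p2, state = if (state > 0) state else NULL)
  }
  xq0 <- as.numeric(sys$qm$xyz); xm0 <- as.numeric(sys$mm$xyz)
  fd_qm <- matrix(0, nrow(sys$qm$xyz), 3)
  for (i in seq_along(xq0)) {
    xp <- xq0; xp[i] <- xp[i] + step
    xm <- xq0; xm[i] <- xm[i] - step
    fd_qm[i] <- (efun(xp, xm0) - efun(xm, xm0)) / (2 * step)
  }
  fd_mm <- matrix(0, nrow(sys$mm$xyz), 3)
  for (i in seq_along(xm0)) {
    xp <- xm0; xp[i] <- xp[i] + step
    xm <- xm0; xm[i] <- xm[i] - step
    fd_mm[i] <- (efun(xq0, xp) - efun(xq0, xm)) / (2 * step)
  }
  list(analytic = gan, fd = gradient_vector(fd_qm, fd_mm, "fd"),
       max_error_qm = max(abs(gan$qm - fd_qm)),
       max_error_mm = if (length(fd_mm) > 0) max(abs(gan$mm - fd_mm)) else 0,
       step = step)
}
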