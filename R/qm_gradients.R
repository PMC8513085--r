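# Backend-level analytic nuclear gradients (gas-phase pieces): RHF ground
# state and CIS excitation-energy gradients via the Lagrangian relaxed
# densities. ESPF embedding derivative terms are added by the QM/MM assembly
# layer; here only h0 = T - V_nuc, the two-electron integrals and the overlap
# enter.

# symmetrize a 4-index array over the 8 permutations of (mn|ls)
sym8 <- function(G) {
  (G + aperm(G, c(2, 1, 3, 4)) + aperm(G, c(1, 2, 4, 3)) +
     aperm(G, c(2, 1, 4, 3)) + aperm(G, c(3, 4, 1, 2)) +
     aperm(G, c(4, 3, 1, 2)) + aperm(G, c(3, 4, 2, 1)) +
     aperm(G, c(4, 3, 2, 1))) / 8
}

# outer product of two AO matrices -> 4-index array [mu,nu,la,si]
outer4 <- function(A, B) {
  n <- nrow(A)
  array(tcrossprod(as.numeric(A), as.numeric(B)), rep(n, 4))
}

# contraction of M with the derivative of h0 = T - Vnuc -> natoms x 3
grad_h0_contract <- function(h, M) {
  cpp_grad_kinetic(h$shells, M, h$natoms) -
    cpp_grad_nuclear(h$shells, M, h$qm$Z, h$qm$xyz, h$natoms)
}

grad_enuc <- function(qm) {
  n <- nrow(qm$xyz)
  g <- matrix(0, n, 3)
  if (n < 2) return(g)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d <- qm$xyz[a, ] - qm$xyz[b, ]
    r <- sqrt(sum(d^2))
    f <- -qm$Z[a] * qm$Z[b] / r^3 * d
    g[a, ] <- g[a, ] + f
    g[b, ] <- g[b, ] - f
  }
  g
}

# RHF ground-state gradient without embedding terms (gas-phase part).
# Returns natoms x 3 in hartree/bohr.
rhf_gradient_gas <- function(scf) {
  h <- scf$handle
  P <- scf$P
  G0 <- 0.5 * outer4(P, P) - 0.25 * aperm(outer4(P, P), c(1, 3, 2, 4))
  G0 <- sym8(G0)
  grad_h0_contract(h, P) +
    cpp_grad_eri(h$shells, G0, h$natoms) -
    cpp_grad_overlap(h$shells, scf$W, h$natoms) +
    grad_enuc(h$qm)
}

# CIS excitation-energy gradient, gas-phase part: contributions of h0, the
# two-electron integrals and the overlap. The embedding operator derivative
# (contracted with the relaxed difference density) is added by the caller.
omega_gradient_gas <- function(scf, state) {
  if (!isTRUE(state$relaxed)) stop("state not relaxed: call relaxed_densities()")
  h <- scf$handle
  P <- scf$P
  PD <- state$Du + state$PZ
  R <- state$Rao
  G <- outer4(PD, P) - 0.5 * aperm(outer4(PD, P), c(1, 3, 2, 4)) +
    2 * outer4(R, R) - aperm(outer4(R, R), c(1, 3, 2, 4))
  G <- sym8(G)
  grad_h0_contract(h, PD) +
    cpp_grad_eri(h$shells, G, h$natoms) -
    cpp_grad_overlap(h$shells, state$W_I, h$natoms)
}

# consistency check: excitation energy recomputed from AO-basis quantities
omega_from_ao <- function(scf, state) {
  h <- scf$handle
  no <- h$nocc; nv <- h$nao - no
  o <- seq_len(no); v <- no + seq_len(nv)
  Fmo <- crossprod(scf$C, scf$F %*% scf$C)
  X <- state$X
  Tvv <- crossprod(X); Too <- -tcrossprod(X)
  Rao <- scf$C[, o, drop = FALSE] %*% X %*% t(scf$C[, v, drop = FALSE])
  sum(Tvv * Fmo[v, v]) + sum(Too * Fmo[o, o]) +
    2 * sum(Rao * op_J(h, Rao)) - sum(Rao * op_K(h, Rao))
}
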