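# Electronic-structure backend: restricted Hartree-Fock with DIIS and
# configuration-interaction singles (the Tamm-Dancoff approximation with a
# pure Hartree + exact-exchange kernel), including Z-vector relaxed densities
# for analytic excited-state gradients. The embedding one-electron operator
# h' is injected into every Fock build.

#' Build an electronic-structure handle
#'
#' Computes and caches the one- and two-electron integrals for a QM region in
#' a given Gaussian basis. The handle supplies the overlap matrix, core
#' Hamiltonian, electron repulsion integrals, electrostatic integrals at
#' arbitrary points and their derivatives, and the nuclear repulsion energy.
#'
#' @param qm a [qm_region()]
#' @param basis basis set name: `"sto-3g"`, `"6-31g"` or `"6-31g*"`
#' @param functional electronic-structure model; only `"hf"` (restricted
#'   Hartree-Fock reference, CIS excited states) is provided by the built-in
#'   backend
#' @return an environment of class `es_handle`
#' @export
electronic_structure <- function(qm, basis = "sto-3g", functional = "hf") {
  if (tolower(functional) != "hf")
    stop("built-in backend supports functional = 'hf' only")
  h <- new.env(parent = emptyenv())
  h$qm <- qm
  h$basis_name <- basis
  h$shells <- build_shells(qm, basis)
  h$nao <- attr(h$shells, "nao")
  h$natoms <- nrow(qm$xyz)
  h$nel <- sum(qm$Z) - qm$charge
  if (h$nel %% 2 != 0) stop("odd electron count: closed-shell backend only")
  h$nocc <- h$nel %/% 2L
  oe <- cpp_overlap_kinetic(h$shells)
  h$S <- oe$S
  h$T <- oe$T
  h$Vn <- cpp_nuclear(h$shells, qm$Z, qm$xyz)
  h$hcore <- h$T - h$Vn
  d <- as.matrix(stats::dist(qm$xyz))
  zz <- outer(qm$Z, qm$Z)
  h$enuc <- sum(zz[upper.tri(zz)] / d[upper.tri(d)])
  # symmetric orthogonalizer
  es <- eigen(h$S, symmetric = TRUE)
  if (min(es$values) <= 1e-10) stop("overlap matrix is near-singular")
  h$Shalf_inv <- es$vectors %*% diag(1 / sqrt(es$values), h$nao) %*% t(es$vectors)
  class(h) <- "es_handle"
  h
}

#' @export
print.es_handle <- function(x, ...) {
  cat("electronic-structure handle:", x$nao, "AOs,", x$nel, "electrons, basis",
      x$basis_name, "\n")
  invisible(x)
}

# lazy two-electron integrals; ERImat is (mu nu|la si) as nao^2 x nao^2 with
# row index (mu,nu); Kmat has element (mu,nu;la,si) = (mu la|nu si).
get_eri <- function(h) {
  if (is.null(h$eri)) {
    h$eri <- cpp_eri(h$shells)
    n <- h$nao
    h$ERImat <- matrix(h$eri, n * n, n * n)
    h$Kmat <- matrix(aperm(h$eri, c(1, 3, 2, 4)), n * n, n * n)
  }
  h$eri
}

# Coulomb and exchange-type contractions
op_J <- function(h, M) {
  n <- h$nao
  matrix(h$ERImat %*% as.numeric(M), n, n)
}
op_K <- function(h, M) {
  n <- h$nao
  matrix(h$Kmat %*% as.numeric(M), n, n)
}
# closed-shell Fock two-electron part for a (generalized) density M
op_G <- function(h, M) op_J(h, M) - 0.5 * op_K(h, M)

# eigen() sorted ascending (R returns decreasing order)
eigen_asc <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  idx <- order(e$values)
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

# energy of a given density under the current (possibly embedded) Hamiltonian
scf_energy_of_density <- function(h, P, h_embed = NULL) {
  hc <- h$hcore
  if (!is.null(h_embed)) hc <- hc + h_embed
  sum(P * (hc + 0.5 * op_G(h, P))) + h$enuc
}

#' Solve the self-consistent field with an embedding operator
#'
#' Restricted Hartree-Fock with DIIS convergence acceleration. The embedding
#' Hamiltonian `h_embed` (possibly zero) is added to the one-electron part of
#' the Fock matrix at every iteration.
#'
#' @param handle an [electronic_structure()] handle
#' @param h_embed symmetric `nao x nao` embedding operator, or `NULL`
#' @param conv convergence threshold on the DIIS error norm (au)
#' @param maxit maximum SCF cycles
#' @return object of class `scf_result` with the converged density `P`,
#'   orbital coefficients `C`, orbital energies `eps`, Fock matrix `F`,
#'   energy-weighted matrix `W` and total QM energy `energy`
#' @export
solve_scf <- function(handle, h_embed = NULL, conv = 1e-10, maxit = 300L) {
  h <- handle
  get_eri(h)
  n <- h$nao
  if (is.null(h_embed)) h_embed <- matrix(0, n, n)
  if (!isTRUE(all.equal(h_embed, t(h_embed), tolerance = 1e-9)))
    stop("embedding operator must be symmetric")
  hc <- h$hcore + h_embed
  X <- h$Shalf_inv
  # core guess
  Fp <- t(X) %*% hc %*% X
  ev <- eigen_asc(Fp)
  C <- X %*% ev$vectors
  occ <- seq_len(h$nocc)
  P <- 2 * tcrossprod(C[, occ, drop = FALSE])
  e_old <- Inf
  diis_F <- list(); diis_e <- list()
  for (it in seq_len(maxit)) {
    G <- op_G(h, P)
    Fm <- hc + G
    err <- Fm %*% P %*% h$S - h$S %*% P %*% Fm
    err <- t(X) %*% err %*% X
    diis_F[[length(diis_F) + 1]] <- Fm
    diis_e[[length(diis_e) + 1]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m > 1) {
      B <- matrix(0, m + 1, m + 1)
      for (a in 1:m) for (b in 1:m) B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        Fd <- matrix(0, n, n)
        for (a in 1:m) Fd <- Fd + cf[a] * diis_F[[a]]
        Fm <- Fd
      }
    }
    Fp <- t(X) %*% Fm %*% X
    ev <- eigen_asc(Fp)
    C <- X %*% ev$vectors
    P_new <- 2 * tcrossprod(C[, occ, drop = FALSE])
    e_el <- sum(P_new * (hc + 0.5 * op_G(h, P_new)))
    de <- abs(e_el - e_old)
    err_norm <- max(abs(err))
    if (err_norm < conv && de < conv * 10) {
      G <- op_G(h, P_new)
      Fm <- hc + G
      eps <- ev$values
      W <- 2 * C[, occ, drop = FALSE] %*% diag(eps[occ], h$nocc) %*%
        t(C[, occ, drop = FALSE])
      res <- list(P = P_new, C = C, eps = eps, F = Fm,
                  W = W, h_embed = h_embed, handle = h,
                  energy_elec = e_el, energy = e_el + h$enuc,
                  converged = TRUE, niter = it)
      class(res) <- "scf_result"
      return(res)
    }
    P <- P_new
    e_old <- e_el
  }
  stop(structure(class = c("scf_error", "error", "condition"),
                 list(message = sprintf("SCF failed to converge in %d cycles (err %.2e)",
                                        maxit, err_norm),
                      call = sys.call(-1), last_density = P)))
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("SCF energy: %.10f hartree (%d iterations)\n", x$energy, x$niter))
  invisible(x)
}

# full AO->MO transform of the ERI tensor
mo_eri <- function(h, C) {
  n <- h$nao
  m <- get_eri(h)
  for (d in 1:4) {
    dim(m) <- c(n, n^3)
    m <- crossprod(C, m)
    dim(m) <- rep(n, 4)
    m <- aperm(m, c(2, 3, 4, 1))
  }
  m
}

# cache per-scf MO integrals
get_moeri <- function(scf) {
  if (is.null(attr(scf, "moeri_env"))) stop("internal: moeri env missing")
  e <- attr(scf, "moeri_env")
  if (is.null(e$moeri)) e$moeri <- mo_eri(scf$handle, scf$C)
  e$moeri
}

with_moeri <- function(scf) {
  if (is.null(attr(scf, "moeri_env"))) attr(scf, "moeri_env") <- new.env(parent = emptyenv())
  scf
}

#' Solve the TDA eigenproblem (CIS)
#'
#' Builds the full TDA matrix
#' `A[ia,jb] = delta (eps_a - eps_i) + 2 (ia|jb) - (ij|ab)`
#' from the embedded Fock orbital energies and returns the lowest states.
#'
#' @param scf a converged [solve_scf()] result
#' @param n_states number of excited states requested
#' @return list of `excited_state` objects, ascending in excitation energy
#' @export
solve_tda <- function(scf, n_states = 1L) {
  h <- scf$handle
  no <- h$nocc; nv <- h$nao - no
  if (n_states < 1) stop("n_states must be >= 1")
  if (n_states > no * nv)
    stop(sprintf("requested %d states but excitation space has dimension %d",
                 n_states, no * nv))
  scf <- with_moeri(scf)
  moe <- get_moeri(scf)
  o <- seq_len(no); v <- no + seq_len(nv)
  eo <- scf$eps[o]; ev <- scf$eps[v]
  # (ia|jb) ordered [i,a,j,b]
  iajb <- moe[o, v, o, v, drop = FALSE]
  # (ij|ab) -> [i,a,j,b]
  ijab <- aperm(moe[o, o, v, v, drop = FALSE], c(1, 3, 2, 4))
  d <- no * nv
  A <- 2 * matrix(iajb, d, d) - matrix(ijab, d, d)
  diag(A) <- diag(A) + as.numeric(outer(eo, ev, function(ei, ea) ea - ei))
  A <- (A + t(A)) / 2
  es <- eigen(A, symmetric = TRUE)
  idx <- order(es$values)[seq_len(n_states)]
  states <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    X <- matrix(es$vectors[, i], no, nv)
    st <- list(index = k, omega = es$values[i], X = X,
               relaxed = FALSE, scf_tag = TRUE)
    class(st) <- "excited_state"
    st
  })
  attr(states, "scf") <- scf
  states
}

#' @export
print.excited_state <- function(x, ...) {
  cat(sprintf("excited state %d: omega = %.6f hartree (%.4f eV)%s\n",
              x$index, x$omega, x$omega * units_au$ev_per_hartree,
              if (isTRUE(x$relaxed)) ", relaxed" else ""))
  invisible(x)
}

# Orbital Hessian for the Z-vector equations: only the orbital-energy
# differences and two-electron terms enter (the embedding operator is present
# solely through the orbital energies).
orbital_hessian <- function(scf) {
  h <- scf$handle
  no <- h$nocc; nv <- h$nao - no
  scf <- with_moeri(scf)
  moe <- get_moeri(scf)
  o <- seq_len(no); v <- no + seq_len(nv)
  aibj <- moe[v, o, v, o, drop = FALSE]            # (ai|bj) [a,i,b,j]
  aibj <- aperm(aibj, c(2, 1, 4, 3))               # [i,a,j,b]
  abij <- aperm(moe[v, v, o, o, drop = FALSE], c(3, 1, 4, 2))  # [i,a,j,b]
  ajib <- aperm(moe[v, o, o, v, drop = FALSE], c(3, 1, 2, 4))  # [i,a,j,b]
  d <- no * nv
  H <- 4 * matrix(aibj, d, d) - matrix(abij, d, d) - matrix(ajib, d, d)
  diag(H) <- diag(H) +
    as.numeric(outer(scf$eps[o], scf$eps[v], function(ei, ea) ea - ei))
  (H + t(H)) / 2
}

#' Complete an excited state with Z-vector relaxed densities
#'
#' Solves the coupled-perturbed (Z-vector) equations and attaches the relaxed
#' one-particle difference density `P_I`, its energy-weighted analog `W_I`,
#' and the two-electron contraction ingredients used by the analytic gradient.
#' The Z-vector right-hand side contains only two-electron terms; the
#' embedding operator enters exclusively through the orbital energies.
#'
#' @param scf converged SCF
#' @param state an `excited_state` from [solve_tda()]
#' @return the completed `excited_state`
#' @export
relaxed_densities <- function(scf, state) {
  if (is.null(state$X)) stop("state has no amplitudes")
  h <- scf$handle
  no <- h$nocc; nv <- h$nao - no
  n <- h$nao
  o <- seq_len(no); v <- no + seq_len(nv)
  Co <- scf$C[, o, drop = FALSE]; Cv <- scf$C[, v, drop = FALSE]
  X <- state$X                                     # no x nv
  Tvv <- crossprod(X)                              # X^T X
  Too <- -tcrossprod(X)
  Du <- Cv %*% Tvv %*% t(Cv) + Co %*% Too %*% t(Co)
  Rao <- Co %*% X %*% t(Cv)
  MR <- 4 * op_J(h, Rao) - 2 * op_K(h, Rao)
  m <- crossprod(scf$C, MR %*% scf$C)
  g <- crossprod(scf$C, op_G(h, Du) %*% scf$C)
  # Lagrangian (coefficient of the free occupied-virtual rotations), [a,i]
  L <- 4 * g[v, o, drop = FALSE] +
    m[v, v, drop = FALSE] %*% t(X) - t(X) %*% m[o, o, drop = FALSE]
  H <- orbital_hessian(scf)
  # vectorization [i,a] (i fastest)
  Lvec <- as.numeric(t(L))
  Zvec <- solve(H, Lvec)
  Z <- t(matrix(Zvec, no, nv))                     # [a,i]
  DZ <- Cv %*% Z %*% t(Co)
  DZ <- DZ + t(DZ)
  PZ <- -0.5 * DZ
  P_I <- Du + PZ
  gp <- crossprod(scf$C, op_G(h, DZ) %*% scf$C)
  eps <- scf$eps
  Omega <- matrix(0, n, n)
  Omega[o, o] <- Too * rep(eps[o], each = no) +
    0.5 * X %*% t(m[o, v, drop = FALSE]) + 2 * g[o, o] - gp[o, o]
  Omega[v, v] <- Tvv * rep(eps[v], each = nv) +
    0.5 * t(X) %*% m[o, v, drop = FALSE]
  Omega[o, v] <- crossprod(m[o, o, drop = FALSE], X)
  Omega[v, o] <- -Z * rep(eps[o], each = nv)
  W_I <- scf$C %*% Omega %*% t(scf$C)
  W_I <- (W_I + t(W_I)) / 2  # only the symmetric part couples to S^x
  state$P_I <- P_I
  state$W_I <- W_I
  state$Du <- Du
  state$PZ <- PZ
  state$Rao <- Rao
  state$relaxed <- TRUE
  state
}
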