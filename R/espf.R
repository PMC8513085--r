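# Electrostatic-potential fitting: molecular-shaped grid, charge operators
# Q_A obtained by least-squares fitting of the electrostatic integrals, ESPF
# atomic charges, and the charge-conservation-corrected embedding Hamiltonian.

# --- angular point sets -------------------------------------------------------

# Exact Lebedev-style octahedral sets for 6, 26 and 50 points; other counts
# fall back to a Fibonacci sphere (quasi-uniform, still a valid fit grid).
angular_points <- function(n) {
  oct6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  sgn <- as.matrix(expand.grid(c(1, -1), c(1, -1)))
  edge12 <- rbind(cbind(sgn[, 1], sgn[, 2], 0), cbind(sgn[, 1], 0, sgn[, 2]),
                  cbind(0, sgn[, 1], sgn[, 2])) / sqrt(2)
  sgn3 <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  corner8 <- sgn3 / sqrt(3)
  if (n == 6) return(oct6)
  if (n == 26) return(rbind(oct6, edge12, corner8))
  if (n == 50) {
    l <- 1 / sqrt(11); m <- 3 / sqrt(11)
    p24 <- rbind(cbind(sgn3[, 1] * l, sgn3[, 2] * l, sgn3[, 3] * m),
                 cbind(sgn3[, 1] * l, sgn3[, 2] * m, sgn3[, 3] * l),
                 cbind(sgn3[, 1] * m, sgn3[, 2] * l, sgn3[, 3] * l))
    return(rbind(oct6, edge12, corner8, p24))
  }
  # Fibonacci sphere
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build the ESP fitting grid
#'
#' Atom-centered shells of angular points at radii spanning a multiple of the
#' Bondi van der Waals radius; any point falling inside the van der Waals
#' sphere of any atom (at `exclusion_scale` times the Bondi radius) is
#' discarded. Point ordering is deterministic: atom, then shell, then angular
#' index.
#'
#' @param qm a [qm_region()]
#' @param angular_order points per spherical shell (50 is the exact
#'   octahedral set used by default; 6 and 26 are also exact)
#' @param n_shells radial shells per atom
#' @param shell_span inner and outer shell radii as multiples of the Bondi
#'   radius
#' @param exclusion_scale van der Waals exclusion radius multiplier
#' @param orientation 3x3 rotation applied to the angular sets; the default
#'   identity keeps the grid lab-frame (grid points translate rigidly with
#'   their parent atom, which is what the analytic gradients assume). Rotating
#'   the system and the orientation together rotates the grid rigidly.
#' @return object of class `espf_grid` with `points` (kept points, bohr),
#'   `parent` (owning atom per point) and the full pre-exclusion table
#' @export
build_grid <- function(qm, angular_order = 50L, n_shells = 9L,
                       shell_span = c(1.2, 2.8), exclusion_scale = 1.0,
                       orientation = diag(3)) {
  nat <- nrow(qm$xyz)
  ang <- angular_points(angular_order) %*% t(orientation)
  rvdw <- vdw_radius(qm$elements)
  pts <- list(); parent <- list(); shell <- list()
  for (a in seq_len(nat)) {
    radii <- seq(shell_span[1], shell_span[2], length.out = n_shells) * rvdw[a]
    for (s in seq_len(n_shells)) {
      p <- ang * radii[s]
      p <- sweep(p, 2, qm$xyz[a, ], "+")
      pts[[length(pts) + 1]] <- p
      parent[[length(parent) + 1]] <- rep(a, nrow(ang))
      shell[[length(shell) + 1]] <- rep(s, nrow(ang))
    }
  }
  pts <- do.call(rbind, pts)
  parent <- unlist(parent)
  shell <- unlist(shell)
  keep <- rep(TRUE, nrow(pts))
  for (a in seq_len(nat)) {
    d2 <- rowSums(sweep(pts, 2, qm$xyz[a, ], "-")^2)
    keep <- keep & (d2 > (exclusion_scale * rvdw[a])^2 * (1 - 1e-12))
  }
  if (!any(keep)) stop("all grid points excluded: pathological geometry")
  g <- list(points = pts[keep, , drop = FALSE], parent = parent[keep],
            shell = shell[keep], all_points = pts, all_parent = parent,
            kept = keep, angular_order = as.integer(angular_order),
            n_shells = as.integer(n_shells), shell_span = shell_span)
  class(g) <- "espf_grid"
  g
}

#' @export
print.espf_grid <- function(x, ...) {
  cat("ESPF grid:", nrow(x$points), "points kept of", nrow(x$all_points),
      sprintf("(%d angular x %d shells)\n", x$angular_order, x$n_shells))
  invisible(x)
}

#' Dump a grid as a plain table
#'
#' @param grid an `espf_grid`
#' @return data.frame with parent atom, coordinates (bohr) and kept flag
#' @export
grid_table <- function(grid) {
  data.frame(parent = grid$all_parent,
             x = grid$all_points[, 1], y = grid$all_points[, 2],
             z = grid$all_points[, 3], kept = grid$kept)
}

# distance matrix grid points x atoms
grid_T_matrix <- function(points, xyz) {
  nk <- nrow(points); nat <- nrow(xyz)
  T <- matrix(0, nk, nat)
  for (a in seq_len(nat))
    T[, a] <- 1 / sqrt(rowSums(sweep(points, 2, xyz[a, ], "-")^2))
  T
}

#' Fit the ESPF charge operators
#'
#' Solves the least-squares problem `T Q = V` mapping the electrostatic
#' integrals on the grid onto atom-centered charge operators,
#' `Q_A = sum_k T+_{A,k} V_k`, with the pseudo-inverse computed by singular
#' value decomposition (relative cutoff 1e-10). Also records the
#' charge-conservation closure defect `D = sum_A Q_A - S`.
#'
#' @param grid an [build_grid()] result
#' @param qm the QM region
#' @param handle the [electronic_structure()] handle
#' @return object of class `charge_ops` with the operator tensor `Q`
#'   (`nao x nao x n_QM`), `T`, `Tplus` and closure defect `D`
#' @export
fit_charge_operators <- function(grid, qm, handle) {
  nk <- nrow(grid$points); nqm <- nrow(qm$xyz)
  if (nk < nqm) stop("fewer grid points than QM atoms")
  T <- grid_T_matrix(grid$points, qm$xyz)
  sv <- svd(T)
  cut <- 1e-10 * sv$d[1]
  rank <- sum(sv$d > cut)
  if (rank < nqm)
    stop(sprintf("rank-deficient fit matrix (rank %d < %d atoms)", rank, nqm))
  Tplus <- sv$v %*% (t(sv$u) / sv$d)
  Q <- cpp_espf_q(handle$shells, grid$points, Tplus)
  D <- apply(Q, c(1, 2), sum) - handle$S
  ops <- list(T = T, Tplus = Tplus, Q = Q, D = D, grid = grid,
              svd_cutoff = cut)
  class(ops) <- "charge_ops"
  ops
}

#' @export
print.charge_ops <- function(x, ...) {
  cat("ESPF charge operators:", dim(x$Q)[3], "atoms,",
      nrow(x$T), "grid points; max closure defect",
      sprintf("%.3e\n", max(abs(x$D))))
  invisible(x)
}

#' ESPF atomic charges
#'
#' `q_A = Z_A - Tr(P Q_A)`, together with the total-charge deviation from the
#' formal molecular charge (bounded by the closure defect).
#'
#' @param P converged density matrix
#' @param ops [fit_charge_operators()] result
#' @param qm QM region
#' @return numeric vector of charges with attributes `total` and
#'   `formal_deviation`
#' @export
espf_charges <- function(P, ops, qm) {
  nqm <- dim(ops$Q)[3]
  q <- qm$Z - vapply(seq_len(nqm), function(a) sum(P * ops$Q[, , a]), 0.0)
  attr(q, "total") <- sum(q)
  attr(q, "formal_deviation") <- sum(q) - qm$charge
  q
}

# populations Tr(M Q_A) for an arbitrary symmetric matrix
espf_populations <- function(M, ops) {
  nqm <- dim(ops$Q)[3]
  vapply(seq_len(nqm), function(a) sum(M * ops$Q[, , a]), 0.0)
}

#' Build the embedding Hamiltonian
#'
#' The charge-conservation-corrected one-electron embedding operator
#' `h' = sum_A Q_A (Phi_av - phi_A) - Phi_av S`. With `corrected = FALSE` the
#' uncorrected operator `h = -sum_A Q_A phi_A` is returned instead (testing
#' aid).
#'
#' @param ops charge operators
#' @param pot an [external_potential()] result (fields `phi`, `phi_av`)
#' @param S overlap matrix
#' @param corrected apply the operator-form charge-conservation correction
#' @return symmetric `nao x nao` matrix of class `embedding_hamiltonian`
#' @export
build_embedding_hamiltonian <- function(ops, pot, S, corrected = TRUE) {
  nqm <- dim(ops$Q)[3]
  if (length(pot$phi) != nqm) stop("one potential value per QM atom required")
  n <- nrow(S)
  hp <- matrix(0, n, n)
  if (corrected) {
    for (a in seq_len(nqm)) hp <- hp + ops$Q[, , a] * (pot$phi_av - pot$phi[a])
    hp <- hp - pot$phi_av * S
  } else {
    for (a in seq_len(nqm)) hp <- hp - ops$Q[, , a] * pot$phi[a]
  }
  structure(hp, class = c("embedding_hamiltonian", class(hp)), pot = pot)
}

# ---- derivatives of the fitted operators ------------------------------------

# d Tr(M Q_A) / d(QM atom coordinates) for every fitted atom A.
# Three sources: motion of R_A in T, rigid motion of grid points with their
# parent atom (in both T and V), and the basis-center dependence of V.
# `grid_motion = FALSE` drops the grid-attachment terms (ablation/testing).
# Returns array [nqm, natoms, 3].
espf_deriv_contract <- function(M, ops, qm, handle, grid_motion = TRUE) {
  grid <- ops$grid
  pts <- grid$points
  nk <- nrow(pts); nqm <- nrow(qm$xyz); nat <- handle$natoms
  T <- ops$T; Tplus <- ops$Tplus
  v <- cpp_point_contract(handle$shells, pts, M)          # Tr(M V_k)
  dv <- cpp_point_grad_contract(handle$shells, pts, M, nat) # nk x (3nat+3)
  TtTinv <- solve(crossprod(T))
  w1 <- as.numeric(Tplus %*% v)          # T+ v (nqm)
  resid <- v - as.numeric(T %*% w1)      # (1 - T T+) v
  out <- array(0, c(nqm, nat, 3))
  # displacement vectors r_k - R_A and 1/d^3 factors
  for (b in seq_len(nat)) {
    par_b <- grid$parent == b
    for (k3 in 1:3) {
      # dT for coordinate (b, k3)
      dT <- matrix(0, nk, nqm)
      # R_b moves: column b, all points
      db <- sweep(pts, 2, qm$xyz[b, ], "-")
      r3 <- (db[, 1]^2 + db[, 2]^2 + db[, 3]^2)^1.5
      dT[, b] <- db[, k3] / r3
      # grid points attached to atom b move: rows with parent b, all columns
      if (grid_motion && any(par_b)) {
        for (a in seq_len(nqm)) {
          da <- sweep(pts[par_b, , drop = FALSE], 2, qm$xyz[a, ], "-")
          ra3 <- (da[, 1]^2 + da[, 2]^2 + da[, 3]^2)^1.5
          dT[par_b, a] <- dT[par_b, a] - da[, k3] / ra3
        }
      }
      # dTplus * v  = -T+ dT (T+ v) + (T'T)^-1 dT' (1 - T T+) v
      term1 <- -as.numeric(Tplus %*% (dT %*% w1))
      term2 <- as.numeric(TtTinv %*% crossprod(dT, resid))
      # T+ dv: basis-center part for atom b plus point-motion part
      dvb <- dv[, 3 * (b - 1) + k3]
      if (grid_motion && any(par_b)) dvb[par_b] <- dvb[par_b] + dv[par_b, 3 * nat + k3]
      term3 <- as.numeric(Tplus %*% dvb)
      out[, b, k3] <- term1 + term2 + term3
    }
  }
  out
}
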