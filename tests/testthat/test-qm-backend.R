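# Electronic-structure backend: SCF, TDA, relaxed densities.

test_that("SCF reproduces reference gas-phase energies and density invariants", {
  qm <- qm_region(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  h <- electronic_structure(qm, "sto-3g")
  expect_equal(h$S, t(h$S))
  expect_gt(min(eigen(h$S, symmetric = TRUE)$values), 0)
  scf <- solve_scf(h)
  # textbook restricted Hartree-Fock value for H2/STO-3G at R = 1.4 bohr
  expect_equal(scf$energy, -1.1167, tolerance = 1e-4)
  expect_equal(sum(scf$P * h$S), h$nel, tolerance = 1e-10)
  expect_max_abs(scf$P %*% h$S %*% scf$P - 2 * scf$P, 1e-9)
  # water, split-valence + polarization: literature HF/6-31G* total energy
  scfw <- water_631gs_scf()
  expect_equal(scfw$energy, -76.0106, tolerance = 1e-3)
})

test_that("a uniform external potential shifts the energy by -c N_el and leaves density and spectrum intact", {
  h <- electronic_structure(water_qm(), "sto-3g")
  s0 <- solve_scf(h, conv = 1e-11)
  cval <- 0.01
  su <- solve_scf(h, -cval * h$S, conv = 1e-11)
  expect_equal(su$energy - s0$energy, -cval * h$nel, tolerance = 1e-10)
  expect_max_abs(su$P - s0$P, 1e-8)
  w0 <- solve_tda(s0, 3)
  wu <- solve_tda(su, 3)
  for (i in 1:3) expect_lt(abs(w0[[i]]$omega - wu[[i]]$omega), 1e-8)
})

test_that("TDA states are normalized, positive, sorted, and bounded by the excitation space", {
  scf <- solve_scf(electronic_structure(water_qm(), "sto-3g"), conv = 1e-11)
  states <- solve_tda(scf, 4)
  om <- vapply(states, `[[`, 0.0, "omega")
  expect_true(all(om > 0))
  expect_true(!is.unsorted(om))
  for (st in states) expect_equal(sum(st$X^2), 1, tolerance = 1e-8)
  h <- scf$handle
  dim_full <- h$nocc * (h$nao - h$nocc)
  expect_error(solve_tda(scf, dim_full + 1L), "dimension")
  # explicit zero embedding operator is identical to no operator
  s0 <- solve_scf(h, matrix(0, h$nao, h$nao), conv = 1e-11)
  expect_equal(s0$energy, scf$energy, tolerance = 1e-11)
})

test_that("relaxed densities conserve particle number and reproduce derivative oracles", {
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  scf <- solve_scf(h, conv = 1e-12)
  st <- relaxed_densities(scf, solve_tda(scf, 1)[[1]])
  expect_lt(abs(sum(st$P_I * h$S)), 1e-10)
  # ESPF state populations sum to ~0, bounded by the fit-closure defect
  ops <- fit_charge_operators(build_grid(qm), qm, h)
  qI <- espfqmm:::espf_populations(st$P_I, ops)
  bound <- max(abs(ops$D)) * sum(abs(st$P_I))
  expect_lt(abs(sum(qI)), bound + 1e-12)
  # one-electron perturbation: d omega / d lambda = Tr(P_I V)
  set.seed(3)
  V <- matrix(rnorm(h$nao^2), h$nao); V <- (V + t(V)) / 100
  lam <- 1e-5
  wp <- solve_tda(solve_scf(h, lam * V, conv = 1e-12), 1)[[1]]$omega
  wm <- solve_tda(solve_scf(h, -lam * V, conv = 1e-12), 1)[[1]]$omega
  expect_equal((wp - wm) / (2 * lam), sum(st$P_I * V), tolerance = 1e-6)
})

test_that("gas-phase excited-state analytic gradient matches central finite differences", {
  # H2, stretched: first excited state of E0 + omega_1
  els <- c("H", "H")
  xyz <- rbind(c(0, 0, 0), c(0.1, 0.2, 1.5))
  efun <- function(x) {
    s <- solve_scf(electronic_structure(qm_region(els, matrix(x, ncol = 3)), "sto-3g"),
                   conv = 1e-12)
    s$energy + solve_tda(s, 1)[[1]]$omega
  }
  scf <- solve_scf(electronic_structure(qm_region(els, xyz), "sto-3g"), conv = 1e-12)
  st <- relaxed_densities(scf, solve_tda(scf, 1)[[1]])
  gan <- espfqmm:::rhf_gradient_gas(scf) + espfqmm:::omega_gradient_gas(scf, st)
  x0 <- as.numeric(xyz); step <- 1e-4
  gfd <- matrix(0, 2, 3)
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    gfd[i] <- (efun(xp) - efun(xm)) / (2 * step)
  }
  expect_max_abs(gan - gfd, 1e-6)
})

test_that("the SCF solution is variational under orbital rotations", {
  h <- electronic_structure(water_qm(), "sto-3g")
  scf <- solve_scf(h, conv = 1e-12)
  no <- h$nocc; nv <- h$nao - no
  e0 <- espfqmm:::scf_energy_of_density(h, scf$P)
  set.seed(11)
  for (k in 1:5) {
    # idempotency- and trace-preserving perturbation: rotate occ into virt
    kappa <- matrix(rnorm(no * nv, sd = 1e-3), no, nv)
    U <- diag(h$nao)
    U[1:no, no + 1:nv] <- kappa
    U[no + 1:nv, 1:no] <- -t(kappa)
    C2 <- scf$C %*% (diag(h$nao) + U + U %*% U / 2)
    # re-orthonormalize in the S metric
    M <- t(C2) %*% h$S %*% C2
    es <- eigen(M, symmetric = TRUE)
    C2 <- C2 %*% es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
    P2 <- 2 * tcrossprod(C2[, 1:no])
    expect_gt(espfqmm:::scf_energy_of_density(h, P2), e0 - 1e-12)
  }
})
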