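# ESPF grid construction, charge-operator fitting and embedding Hamiltonian.

test_that("grid construction: counts, brute-force exclusion, translation covariance", {
  one <- qm_region("O", matrix(c(0, 0, 0), 1))
  g1 <- build_grid(one, 50L, 9L)
  expect_equal(nrow(g1$points), 450L)   # single atom: nothing to exclude
  # two atoms very close: survivor count equals a brute-force filter
  two <- qm_region(c("O", "H"), rbind(c(0, 0, 0), c(0.1, 0, 0)))
  g2 <- build_grid(two, 26L, 5L)
  rv <- vdw_radius(two$elements)
  keep_bf <- apply(g2$all_points, 1, function(p) {
    all(sqrt(colSums((t(two$xyz) - p)^2)) > rv * (1 - 1e-12))
  })
  expect_equal(nrow(g2$points), sum(keep_bf))
  expect_equal(which(g2$kept), which(keep_bf))
  # rigid translation
  shift <- c(3.3, -1.1, 0.4)
  two_t <- qm_region(c("O", "H"), sweep(two$xyz, 2, shift, "+"))
  g2t <- build_grid(two_t, 26L, 5L)
  expect_equal(nrow(g2t$points), nrow(g2$points))
  expect_max_abs(g2t$points - sweep(g2$points, 2, shift, "+"), 1e-12)
})

test_that("charge-operator fit is an optimal least-squares solution", {
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  g <- build_grid(qm, 26L, 5L)
  ops <- fit_charge_operators(g, qm, h)
  expect_max_abs(ops$Q - aperm(ops$Q, c(2, 1, 3)), 1e-12)  # Q_A symmetric
  # residual orthogonal to the column space of T (normal equations)
  V <- espfqmm:::cpp_point_matrices(h$shells, g$points)
  nk <- nrow(g$points)
  Vm <- t(matrix(as.numeric(V), h$nao^2, nk))        # nk x nao^2
  Qm <- t(matrix(as.numeric(ops$Q), h$nao^2, 3))     # nqm x nao^2
  resid <- Vm - ops$T %*% Qm
  rel <- max(abs(crossprod(ops$T, resid))) / max(abs(crossprod(ops$T, Vm)))
  expect_lt(rel, 1e-10)
  # dual-algorithm cross-check: normal equations vs SVD pseudo-inverse
  Tplus_ne <- solve(crossprod(ops$T)) %*% t(ops$T)
  expect_max_abs(ops$Tplus - Tplus_ne, 1e-10)
  # single-atom fit: T+ T = 1 and the fitted operator is the weighted average
  one <- qm_region("O", matrix(c(0, 0, 0), 1))
  h1 <- electronic_structure(one, "sto-3g")
  g1 <- build_grid(one, 6L, 3L)
  ops1 <- fit_charge_operators(g1, one, h1)
  expect_equal(as.numeric(ops1$Tplus %*% ops1$T), 1, tolerance = 1e-12)
  # interpolation limit: square nonsingular T reproduces V at the grid exactly
  gsq <- structure(list(points = rbind(c(0, 0, 3.5), c(0, 4.2, -1.0), c(4.0, -1.5, 0)),
                        parent = c(1L, 2L, 3L), shell = c(1L, 1L, 1L)),
                   class = "espf_grid")
  opssq <- fit_charge_operators(gsq, qm, h)
  Vsq <- espfqmm:::cpp_point_matrices(h$shells, gsq$points)
  fitted <- array(0, dim(Vsq))
  for (k in 1:3) for (a in 1:3)
    fitted[, , k] <- fitted[, , k] + opssq$T[k, a] * opssq$Q[, , a]
  expect_max_abs(fitted - Vsq, 1e-8)
})

test_that("ESPF charges: symmetry, closure bound, rotational covariance", {
  # H2: equal charges by symmetry
  qh <- qm_region(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)))
  hh <- electronic_structure(qh, "sto-3g")
  sh <- solve_scf(hh, conv = 1e-12)
  oh <- fit_charge_operators(build_grid(qh), qh, hh)
  qch <- espf_charges(sh$P, oh, qh)
  expect_lt(abs(qch[1] - qch[2]), 1e-10)
  # neutral molecule: total charge deviation bounded by |Tr(P D)|
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  s <- solve_scf(h, conv = 1e-12)
  ops <- fit_charge_operators(build_grid(qm), qm, h)
  qc <- espf_charges(s$P, ops, qm)
  expect_lte(abs(attr(qc, "formal_deviation")),
             abs(sum(s$P * ops$D)) + 1e-12)
  # rotating system and grid orientation together leaves charges invariant
  th <- 0.61
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  qmr <- qm_region(qm$elements, qm$xyz %*% t(Rz))
  hr <- electronic_structure(qmr, "sto-3g")
  sr <- solve_scf(hr, conv = 1e-12)
  gr <- build_grid(qmr, orientation = Rz)
  opsr <- fit_charge_operators(gr, qmr, hr)
  qcr <- espf_charges(sr$P, opsr, qmr)
  expect_max_abs(qcr - qc, 1e-9)
})

test_that("embedding Hamiltonian: zero, uniform and correction-identity cases", {
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  ops <- fit_charge_operators(build_grid(qm), qm, h)
  pot0 <- list(phi = rep(0, 3), phi_av = 0)
  expect_max_abs(unclass(build_embedding_hamiltonian(ops, pot0, h$S)), 0 + 1e-15)
  cval <- 0.0173
  potu <- list(phi = rep(cval, 3), phi_av = cval)
  hu <- build_embedding_hamiltonian(ops, potu, h$S)
  expect_max_abs(unclass(hu) + cval * h$S, 1e-14)
  # corrected minus uncorrected equals Phi_av times the closure defect
  set.seed(5)
  pr <- rnorm(3)
  potr <- list(phi = pr, phi_av = mean(pr))
  h9 <- build_embedding_hamiltonian(ops, potr, h$S, corrected = TRUE)
  h6 <- build_embedding_hamiltonian(ops, potr, h$S, corrected = FALSE)
  expect_max_abs((unclass(h9) - unclass(h6)) - potr$phi_av * ops$D, 1e-12)
})

test_that("operator derivatives match finite differences; grid-motion terms are essential", {
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  set.seed(1)
  M <- matrix(rnorm(h$nao^2), h$nao); M <- (M + t(M)) / 2
  ops <- fit_charge_operators(build_grid(qm), qm, h)
  dQ <- espfqmm:::espf_deriv_contract(M, ops, qm, h)
  dQ_nomotion <- espfqmm:::espf_deriv_contract(M, ops, qm, h, grid_motion = FALSE)
  trQ <- function(x) {
    qm2 <- qm_region(qm$elements, matrix(x, ncol = 3))
    h2 <- electronic_structure(qm2, "sto-3g")
    o2 <- fit_charge_operators(build_grid(qm2), qm2, h2)
    espfqmm:::espf_populations(M, o2)
  }
  x0 <- as.numeric(qm$xyz); step <- 1e-4
  err <- 0; err_ablate <- 0
  for (i in c(1, 5, 6, 9)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    fd <- (trQ(xp) - trQ(xm)) / (2 * step)
    b <- (i - 1) %% 3 + 1; k <- (i - 1) %/% 3 + 1
    err <- max(err, max(abs(dQ[, b, k] - fd)))
    err_ablate <- max(err_ablate, max(abs(dQ_nomotion[, b, k] - fd)))
  }
  expect_lt(err, 1e-7)
  expect_gt(err_ablate, 1e-4)   # dropping grid-attachment terms breaks the FD match
})

test_that("closure defect shrinks when the angular order is doubled", {
  qm <- water_qm()
  h <- electronic_structure(qm, "sto-3g")
  d50 <- max(abs(fit_charge_operators(build_grid(qm, 50L), qm, h)$D))
  d100 <- max(abs(fit_charge_operators(build_grid(qm, 100L), qm, h)$D))
  expect_lt(d100, d50)
})
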