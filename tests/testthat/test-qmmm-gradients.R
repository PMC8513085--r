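# Total QM/MM energies and analytic gradients (minimal basis for speed; the
# polarized-basis run of the same oracle lives in the acceptance suite).

test_that("total energy limits: gas phase, LJ-only environment, far-field decay", {
  qm <- water_qm()
  # zero MM charges, LJ off: total equals the gas-phase QM energy
  mm0 <- mm_region("O", matrix(c(8, 0, 0), 1), 0, 0, 0, 1L)
  sys0 <- qmmm_system(qm, mm0, basis = "sto-3g", scf_conv = 1e-11)
  pt0 <- prepare_point(sys0)
  gas <- solve_scf(electronic_structure(qm, "sto-3g"), conv = 1e-11)$energy
  expect_equal(total_energy(pt0), gas, tolerance = 1e-9)
  # distant single charge: interaction decays as q mu / r^2 with the charge
  # dipole of the fitted ESPF distribution
  eint <- function(r) {
    mmq <- mm_region("H", matrix(c(0, 0, -r), 1), 0.5, 0, 0, 1L)
    sysq <- qmmm_system(qm, mmq, basis = "sto-3g", scf_conv = 1e-12)
    total_energy(prepare_point(sysq)) - gas
  }
  e20 <- eint(20); e40 <- eint(40)
  # r^-2 leading order: ratio 4 within a few percent at 20 vs 40 bohr
  expect_equal(e20 / e40, 4, tolerance = 0.05)
})

test_that("analytic QM/MM gradients match central finite differences (both blocks)", {
  sys <- qmmm_system(water_qm(), mm_three_charges(), basis = "sto-3g",
                     scf_conv = 1e-11)
  r0 <- fd_validate(sys, state = 0, step = 1e-4)
  expect_lt(r0$max_error_qm, 1e-6)
  expect_lt(r0$max_error_mm, 1e-6)
  r1 <- fd_validate(sys, state = 1, step = 1e-4)
  expect_lt(r1$max_error_qm, 1e-6)
  expect_lt(r1$max_error_mm, 1e-6)
})

test_that("summed forces vanish and difference gradients obey linearity", {
  pt <- qmmm_water_sto3g()
  g0 <- ground_gradient(pt)
  g1 <- excited_gradient(pt, 1)
  g2 <- excited_gradient(pt, 2)
  for (g in list(g0, g1, g2))
    expect_max_abs(colSums(g$qm) + colSums(g$mm), 1e-6)
  d12 <- difference_gradient(pt, 1, 2)
  expect_max_abs(espfqmm:::as_vector(d12) -
                   (espfqmm:::as_vector(g2) - espfqmm:::as_vector(g1)), 1e-9)
  d01 <- difference_gradient(pt, 0, 1)
  expect_max_abs(espfqmm:::as_vector(d01) -
                   (espfqmm:::as_vector(g1) - espfqmm:::as_vector(g0)), 1e-9)
  expect_error(difference_gradient(pt, 1, 1), "degenerate")
  # FD of (E_2 - E_1) along a random direction
  sys <- pt$sys
  set.seed(9)
  v <- rnorm(18); v <- v / sqrt(sum(v^2))
  ediff <- function(t) {
    s2 <- espfqmm:::sys_with_coords(sys,
                                    as.numeric(sys$qm$xyz) + t * v[1:9],
                                    as.numeric(sys$mm$xyz) + t * v[10:18])
    p <- prepare_point(s2, n_states = 2)
    total_energy(p, 2) - total_energy(p, 1)
  }
  fd <- (ediff(1e-4) - ediff(-1e-4)) / 2e-4
  expect_equal(sum(espfqmm:::as_vector(d12) * v), fd, tolerance = 1e-6)
})

test_that("omitting the average-potential trace term breaks the FD match", {
  pt <- qmmm_water_sto3g()
  sys <- pt$sys
  g0 <- ground_gradient(pt)
  nel <- sum(pt$scf$P * pt$handle$S)
  nqm <- nrow(sys$qm$xyz); nmm <- nrow(sys$mm$xyz)
  # reconstruct the MM block with the -Phi_av^x~ N_el term deliberately dropped
  g_mm_ablate <- g0$mm
  for (k in 1:3) {
    dmm <- pt$pot$dphi_dmm[, , k, drop = FALSE]
    dim(dmm) <- c(nqm, nmm)
    g_mm_ablate[, k] <- g_mm_ablate[, k] + colMeans(dmm) * nel
  }
  efun <- function(xm) {
    s2 <- espfqmm:::sys_with_coords(sys, xmm = xm)
    total_energy(prepare_point(s2))
  }
  x0 <- as.numeric(sys$mm$xyz); step <- 1e-4
  err <- 0
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + step
    xm <- x0; xm[i] <- xm[i] - step
    fd <- (efun(xp) - efun(xm)) / (2 * step)
    err <- max(err, abs(g_mm_ablate[(i - 1) %% nmm + 1, (i - 1) %/% nmm + 1] - fd))
  }
  expect_gt(err, 1e-4)
})

test_that("gradients are covariant under relabeling of identical MM molecules", {
  qm <- water_qm()
  mm <- pack_droplet(qm, solvent_template("water"), 2, ang2bohr(6), seed = 5)
  sys <- qmmm_system(qm, mm, basis = "sto-3g", scf_conv = 1e-10)
  pt <- prepare_point(sys, n_states = 1)
  g <- excited_gradient(pt, 1)
  # swap the two solvent molecules (sites 1:3 <-> 4:6)
  perm <- c(4:6, 1:3)
  mm2 <- mm
  mm2$xyz <- mm$xyz[perm, ]
  sys2 <- qmmm_system(qm, mm2, basis = "sto-3g", scf_conv = 1e-10)
  pt2 <- prepare_point(sys2, n_states = 1)
  g2 <- excited_gradient(pt2, 1)
  expect_max_abs(g2$mm - g$mm[perm, ], 1e-8)
  expect_max_abs(g2$qm - g$qm, 1e-8)
})
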