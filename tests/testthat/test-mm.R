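# MM engine: external potential, classical energy/gradient, droplet packer.

test_that("external potential: Coulomb value, cancellation, brute-force oracle", {
  q1 <- qm_region("H", matrix(c(0, 0, 0), 1))
  mm1 <- mm_region("H", matrix(c(2, 0, 0), 1), 1.0, 0, 0, 1L)
  expect_equal(external_potential(mm1, q1)$phi, 0.5)
  # opposite charges symmetric about the QM atom cancel
  mm2 <- mm_region(c("H", "H"), rbind(c(3, 0, 0), c(-3, 0, 0)),
                   c(1, -1), c(0, 0), c(0, 0), c(1L, 2L))
  expect_lt(abs(external_potential(mm2, q1)$phi), 1e-14)
  # 300-site random cloud vs direct double loop
  set.seed(8)
  n <- 300
  xyz <- matrix(rnorm(3 * n, sd = 8), n, 3)
  xyz <- xyz[sqrt(rowSums(xyz^2)) > 4, , drop = FALSE]
  qv <- runif(nrow(xyz), -0.5, 0.5)
  mm <- mm_region(rep("H", nrow(xyz)), xyz, qv, rep(0, nrow(xyz)),
                  rep(0, nrow(xyz)), seq_len(nrow(xyz)))
  qm <- water_qm()
  pot <- external_potential(mm, qm)
  for (A in 1:3) {
    direct <- sum(qv / sqrt(rowSums(sweep(xyz, 2, qm$xyz[A, ], "-")^2)))
    expect_equal(pot$phi[A], direct, tolerance = 1e-12)
  }
  expect_equal(pot$phi_av, mean(pot$phi), tolerance = 1e-15)
  # derivative antisymmetry between the QM- and MM-side closures
  dsum <- apply(pot$dphi_dmm, c(1, 3), sum)
  expect_max_abs(dsum + pot$dphi_dqm, 1e-12)
  # coincident site rejected
  mmc <- mm_region("H", matrix(qm$xyz[1, ], 1), 0.3, 0, 0, 1L)
  expect_error(external_potential(mmc, qm), "coincident")
})

test_that("Lennard-Jones minimum and Newton's third law", {
  sig <- 5.0; eps <- 2e-3
  rmin <- 2^(1 / 6) * sig
  mm <- mm_region(c("O", "O"), rbind(c(0, 0, 0), c(rmin, 0, 0)),
                  c(0, 0), c(sig, sig), c(eps, eps), c(1L, 2L))
  eg <- mm_energy_gradient(mm)
  expect_equal(eg$energy, -eps, tolerance = 1e-12)
  expect_max_abs(eg$g_mm, 1e-12)
  # third law on a random cluster with charges + LJ
  set.seed(2)
  mm3 <- mm_region(rep("O", 4), matrix(rnorm(12, sd = 4), 4, 3),
                   runif(4, -0.3, 0.3), rep(sig, 4), rep(eps, 4), 1:4)
  eg3 <- mm_energy_gradient(mm3)
  expect_max_abs(colSums(eg3$g_mm), 1e-12)
})

test_that("bundled solvent parameters give FD-exact gradients", {
  for (solvent in c("water", "methanol")) {
    tpl <- solvent_template(solvent)
    expect_equal(sum(tpl$charges), 0, tolerance = 1e-12)
    mm <- pack_droplet(NULL, tpl, 2, ang2bohr(6), seed = 3)
    set.seed(4)
    mm$xyz <- mm$xyz + matrix(rnorm(length(mm$xyz), sd = 0.08), ncol = 3)
    eg <- mm_energy_gradient(mm)
    x0 <- as.numeric(mm$xyz); step <- 1e-6
    n <- nrow(mm$xyz)
    err <- 0
    for (i in seq_along(x0)) {
      xp <- x0; xp[i] <- xp[i] + step
      xm <- x0; xm[i] <- xm[i] - step
      m2 <- mm
      m2$xyz <- matrix(xp, ncol = 3); ep <- mm_energy_gradient(m2)$energy
      m2$xyz <- matrix(xm, ncol = 3); em <- mm_energy_gradient(m2)$energy
      err <- max(err, abs(eg$g_mm[(i - 1) %% n + 1, (i - 1) %/% n + 1] -
                            (ep - em) / (2 * step)))
    }
    expect_lt(err, 1e-8)
  }
  # a single molecule has only its intramolecular bonded energy
  one <- pack_droplet(NULL, solvent_template("water"), 1, ang2bohr(4), seed = 1)
  eg1 <- mm_energy_gradient(one)
  expect_equal(eg1$energy, eg1$bonded, tolerance = 1e-14)
  expect_equal(eg1$coulomb + eg1$lj + eg1$qm_lj, 0, tolerance = 1e-14)
})

test_that("droplet packing: determinism, minimum distances, containment", {
  tpl <- solvent_template("methanol")
  # single molecule keeps its distance from the solute
  qm <- water_qm()
  one <- pack_droplet(qm, tpl, 1, ang2bohr(6), seed = 9)
  dmin <- min(as.matrix(stats::dist(rbind(qm$xyz, one$xyz)))[1:3, 4:9])
  expect_gte(dmin, ang2bohr(2.0))
  expect_true(all(sqrt(rowSums(one$xyz^2)) <= ang2bohr(6) + 1e-9))
  # determinism
  d1 <- pack_droplet(NULL, tpl, 25, ang2bohr(9), seed = 7)
  d2 <- pack_droplet(NULL, tpl, 25, ang2bohr(9), seed = 7)
  expect_identical(d1$xyz, d2$xyz)
  # exhaustive audit at the paper-like density: 100 methanol in a 12 A sphere
  d100 <- pack_droplet(NULL, tpl, 100, ang2bohr(12), seed = 1)
  dall <- as.matrix(stats::dist(d100$xyz))
  inter <- outer(d100$molecule, d100$molecule, "!=")
  expect_gte(min(dall[inter]), ang2bohr(2.0))
  expect_true(all(sqrt(rowSums(d100$xyz^2)) <= ang2bohr(12) + 1e-9))
  # infeasible density is rejected up front
  expect_error(pack_droplet(NULL, tpl, 100, ang2bohr(5), seed = 1), "density")
})
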