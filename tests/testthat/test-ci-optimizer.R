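# Branching-plane algebra and the conical-intersection / minimum optimizers.

test_that("composite gradient: degeneracy limit, degenerate-plane error, closed form", {
  surf <- model_two_state(1.3, 0.6)
  # at exact degeneracy only the projected average gradient survives
  pl <- branching_plane(c(1, 0), c(0, 1))
  cg <- composite_gradient(c(0.2, 0.1), c(0.5, -0.3), 1.0, 1.0, pl)
  expect_equal(cg$grad, cg$g_avg_proj)
  expect_error(composite_gradient(c(1, 2), c(1, 2), 0, 1, pl), "degenerate")
  # closed form on the linear-coupling model: the average gradient vanishes,
  # so the composite equals the exact gradient of sigma (E2 - E1)^2
  set.seed(6)
  for (k in 1:10) {
    x <- runif(2, -1, 1)
    ev <- surface_eval(surf, x, c(1, 2))
    d <- (ev$grads[[2]] - ev$grads[[1]]) / 2
    pl <- branching_plane(d, rnorm(2))
    cg <- composite_gradient(ev$grads[[1]], ev$grads[[2]], ev$E[1], ev$E[2], pl,
                             sigma = 0.7)
    exact <- 8 * 0.7 * c(surf$kappa^2 * x[1], surf$lambda^2 * x[2])
    expect_max_abs(cg$grad - exact, 1e-10)
  }
})

test_that("orthogonal-vector update: fixed point, in-plane rotation, 50-step sweep", {
  set.seed(10)
  d0 <- rnorm(12); o0 <- rnorm(12)
  pl <- branching_plane(d0, o0)
  # unchanged difference direction is a fixed point
  pl2 <- update_orthogonal(pl, pl$d)
  expect_max_abs(pl2$o - pl$o, 1e-12)
  # rotating d by 90 degrees within the plane: new o stays in the old span
  dr <- pl$o  # d rotated onto the old orthogonal vector
  pl3 <- update_orthogonal(pl, dr)
  span <- cbind(pl$d, pl$o)
  resid <- pl3$o - span %*% solve(crossprod(span), crossprod(span, pl3$o))
  expect_max_abs(resid, 1e-10)
  expect_lt(abs(sum(pl3$o * pl3$d)), 1e-10)
  # random sequence of 50 updates keeps orthonormality and projector algebra
  for (k in 1:50) {
    pl <- update_orthogonal(pl, rnorm(12))
    expect_lt(abs(sqrt(sum(pl$o^2)) - 1), 1e-10)
    expect_lt(abs(sum(pl$o * pl$d)), 1e-10)
  }
  B <- plane_projector_matrix(pl)
  expect_max_abs(B %*% B - B, 1e-9)
  expect_equal(sum(diag(B)), 12 - 2, tolerance = 1e-9)  # rank 3N - 2
  expect_max_abs(project_out_plane(pl, pl$d), 1e-10)
  expect_max_abs(project_out_plane(pl, pl$o), 1e-10)
})

test_that("the optimizer finds the model conical intersection from 20 random starts", {
  surf <- model_two_state(1, 1)
  set.seed(42)
  for (k in 1:20) {
    x0 <- runif(2, -1, 1)
    r <- optimize_ci(surf, 1, 2, x0, gap_tol = 1e-8, grad_tol = 1e-4,
                     max_steps = 100)
    expect_true(r$converged)
    expect_lt(r$steps, 100)
    expect_lt(r$gap, 1e-8)
    expect_lt(sqrt(sum(r$x^2)), 1e-4)
  }
  # anisotropic couplings (sloped-like scaling)
  r2 <- optimize_ci(model_two_state(2, 0.5), 1, 2, c(1, 1), gap_tol = 1e-8,
                    grad_tol = 1e-4, max_steps = 100)
  expect_true(r2$converged)
  expect_lt(sqrt(sum(r2$x^2)), 1e-4)
})

test_that("harmonically bound spectators relax while the gap closes", {
  surf <- model_two_state(1.4, 0.7, n_spectators = 4, k_spec = 0.5,
                          spec_center = 0.7)
  r <- optimize_ci(surf, 1, 2, c(1, 1, 0.3, -0.2, 0.5, 0.9),
                   gap_tol = 1e-8, grad_tol = 1e-6, max_steps = 500,
                   o_init = "random")
  expect_true(r$converged)
  expect_lt(r$gap, 1e-8)
  expect_max_abs(r$x[1:2], 1e-4)
  expect_max_abs(r$x[3:6] - 0.7, 1e-4)
})

test_that("composite energy is non-increasing over accepted steps", {
  surf <- model_two_state(1, 0.8, n_spectators = 2, k_spec = 0.4, spec_center = 0.2)
  r <- optimize_ci(surf, 1, 2, c(0.8, -0.6, 0, 0), o_init = "random",
                   gap_tol = 1e-8, grad_tol = 1e-6, max_steps = 300)
  vals <- vapply(r$history, `[[`, 0.0, "value")
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("minimum optimizer: harmonic surface and an independent-optimizer cross-check", {
  # pure harmonic spectators with the electronic part pinned far away
  surf <- model_two_state(1, 1, n_spectators = 3, k_spec = 1.2, spec_center = 0.4)
  r <- optimize_minimum(surf, 2, c(2, 0, 0, 0, 0), grad_tol = 1e-8,
                        max_steps = 50)
  # upper-state minimum: spectators at their centers
  expect_max_abs(r$x[3:5] - 0.4, 1e-6)
  # water ground state: package optimizer vs an independent quasi-Newton route
  qm <- water_qm()
  sys <- qmmm_system(qm, basis = "sto-3g", scf_conv = 1e-10)
  surfw <- qmmm_surface(sys)
  x0 <- as.numeric(qm$xyz)
  rmin <- optimize_minimum(surfw, 1, x0, grad_tol = 1e-5, max_steps = 60)
  expect_true(rmin$converged)
  ofun <- function(x) surface_eval(surfw, x, 1, gradients = FALSE)$E[1]
  ogr <- function(x) surface_eval(surfw, x, 1)$grads[[1]]
  ref <- stats::optim(x0, ofun, ogr, method = "BFGS",
                      control = list(reltol = 1e-13, maxit = 200))
  expect_equal(rmin$E, ref$value, tolerance = 1e-6)
})

test_that("microiterations relax the environment at frozen QM density", {
  qm <- water_qm()
  # LJ-only solvent: reduces to plain cluster minimization
  mm_lj <- mm_region(c("O", "O"), rbind(c(7, 0, 0), c(0, 7.5, 0)),
                     c(0, 0), rep(5.0, 2), rep(2e-3, 2), c(1L, 2L))
  sys_lj <- qmmm_system(qm, mm_lj, basis = "sto-3g", scf_conv = 1e-9)
  mi_lj <- microiterations(sys_lj, mm_tol = 1e-6)
  expect_lt(mi_lj$mm_grad_rms, 1e-6)
  expect_lte(mi_lj$energy_after, mi_lj$energy_before)
  # 5-water shell: descent and threshold
  mm5 <- pack_droplet(qm, solvent_template("water"), 5, ang2bohr(5.5), seed = 2)
  sys5 <- qmmm_system(qm, mm5, basis = "sto-3g", scf_conv = 1e-9)
  mi <- microiterations(sys5, mm_tol = 1e-4)
  expect_lte(mi$mm_grad_rms, 1e-4)
  expect_lt(mi$energy_after, mi$energy_before)
  # one microiteration pass shrinks the true full-gradient MM-block norm
  g_before <- ground_gradient(prepare_point(sys5))
  g_after <- ground_gradient(mi$point)
  expect_lt(sqrt(mean(g_after$mm^2)), sqrt(mean(g_before$mm^2)))
})

test_that("microiteration-assisted intersection search relaxes the environment between macro-steps", {
  qm <- water_qm()
  mm <- pack_droplet(qm, solvent_template("water"), 2, ang2bohr(6), seed = 4)
  sys <- qmmm_system(qm, mm, basis = "sto-3g", scf_conv = 1e-9)
  surf <- qmmm_surface(sys, n_excited = 2)
  x0 <- c(as.numeric(qm$xyz), as.numeric(mm$xyz))
  # two chunks only: checks plumbing, not convergence (a minimal-basis water
  # intersection is far away)
  r <- optimize_ci(surf, 2, 3, x0, gap_tol = 1e-4, grad_tol = 1e-4,
                   max_steps = 12, micro_mm = TRUE, o_init = "random")
  expect_s3_class(r, "optimization_state")
  expect_gt(r$steps, 0)
  xm0 <- x0[-seq_len(9)]
  xm1 <- r$x[-seq_len(9)]
  expect_gt(max(abs(xm1 - xm0)), 1e-4)   # environment actually moved
})
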