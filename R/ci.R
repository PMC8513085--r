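# Conical-intersection and minimum optimizers using the branching-plane
# update method: the branching plane is spanned by the normalized
# state-difference gradient and an orthogonal vector estimated iteratively
# from the difference-gradient history instead of computed nonadiabatic
# couplings. The composite objective is
#   E = (E_I + E_J)/2 + sigma (E_J - E_I)^2
# whose gradient is  B grad(E_av) + 2 sigma (E_J - E_I)(grad E_J - grad E_I),
# with B projecting the branching plane out of the average gradient.

#' Construct a branching plane
#'
#' Normalizes the difference-gradient direction, orthonormalizes the second
#' vector against it, and carries the projector
#' `B = 1 - d d^T - o o^T` in implicit form.
#'
#' @param d_raw difference-gradient vector (unnormalized)
#' @param o_raw second (orthogonal) vector, any length
#' @param k optimization step index
#' @return object of class `branching_plane` with unit vectors `d`, `o`
#' @export
branching_plane <- function(d_raw, o_raw, k = 0L) {
  nd <- sqrt(sum(d_raw^2))
  if (nd < 1e-14) stop("degenerate plane: zero difference gradient")
  d <- d_raw / nd
  o <- o_raw - sum(o_raw * d) * d
  no <- sqrt(sum(o^2))
  if (no < 1e-12) {
    # pick an arbitrary direction orthogonal to d
    e <- numeric(length(d)); e[which.min(abs(d))] <- 1
    o <- e - sum(e * d) * d
    no <- sqrt(sum(o^2))
  }
  o <- o / no
  bp <- list(d = d, o = o, k = as.integer(k))
  class(bp) <- "branching_plane"
  bp
}

#' Apply the branching-plane projector
#'
#' @param plane a [branching_plane()]
#' @param v vector
#' @return `B v = v - d (d.v) - o (o.v)`
#' @export
project_out_plane <- function(plane, v) {
  v - plane$d * sum(plane$d * v) - plane$o * sum(plane$o * v)
}

#' Dense projector matrix (small systems / diagnostics)
#' @param plane a [branching_plane()]
#' @return `length(d) x length(d)` matrix
#' @export
plane_projector_matrix <- function(plane) {
  n <- length(plane$d)
  diag(n) - tcrossprod(plane$d) - tcrossprod(plane$o)
}

#' Update the orthogonal branching-plane vector
#'
#' Given the previous plane `(d_{k-1}, o_{k-1})` and the new normalized
#' difference gradient `d_k`, estimates the new orthogonal vector
#' `o_k = [ (d_k . d_{k-1}) o_{k-1} - (d_k . o_{k-1}) d_{k-1} ] /
#' sqrt((d_{k-1} . d_k)^2 + (o_{k-1} . d_k)^2)`,
#' then re-orthonormalizes against `d_k`. When `d_k` is orthogonal to the
#' previous plane the update is singular; the previous `o` is re-used via
#' Gram-Schmidt against `d_k`.
#'
#' @param plane_prev previous [branching_plane()]
#' @param d_new new difference-gradient vector (will be normalized)
#' @return updated `branching_plane`
#' @export
update_orthogonal <- function(plane_prev, d_new) {
  nd <- sqrt(sum(d_new^2))
  if (nd < 1e-14) stop("degenerate plane: zero difference gradient")
  dk <- d_new / nd
  a <- sum(dk * plane_prev$d)
  b <- sum(dk * plane_prev$o)
  den <- sqrt(a^2 + b^2)
  if (den < 1e-10) {
    o_raw <- plane_prev$o
  } else {
    o_raw <- (a * plane_prev$o - b * plane_prev$d) / den
  }
  branching_plane(d_new, o_raw, plane_prev$k + 1L)
}

#' Composite conical-intersection gradient
#'
#' `B grad(E_av) + 2 sigma (E_J - E_I)(grad E_J - grad E_I)`; at exact
#' degeneracy the penalty vanishes and only the projected average gradient
#' remains.
#'
#' @param gI,gJ state gradient vectors (flattened)
#' @param EI,EJ state energies
#' @param plane current [branching_plane()]
#' @param sigma gap-penalty weight (1/hartree)
#' @return list with `grad`, the projected average gradient `g_avg_proj`, and
#'   the composite energy value `value`
#' @export
composite_gradient <- function(gI, gJ, EI, EJ, plane, sigma = 1) {
  dvec <- gJ - gI
  if (sqrt(sum(dvec^2)) < 1e-14) stop("degenerate plane: equal state gradients")
  g_av <- (gI + gJ) / 2
  g_proj <- project_out_plane(plane, g_av)
  g <- g_proj + 2 * sigma * (EJ - EI) * dvec
  list(grad = g, g_avg_proj = g_proj,
       value = (EI + EJ) / 2 + sigma * (EJ - EI)^2)
}

# ---- generic trust-radius BFGS on a closure ---------------------------------
# fg(x) must return list(value=, grad=, aux=...); extra per-step hook allows
# the CI driver to refresh the branching plane.
bfgs_trust <- function(x0, fg, max_steps = 200L, trust0 = 0.3,
                       conv_check, keep_history = FALSE,
                       accept = c("value", "gradient")) {
  accept <- match.arg(accept)
  n <- length(x0)
  x <- x0
  H <- diag(n)           # inverse-Hessian approximation
  trust <- trust0
  cur <- fg(x)
  hist <- list()
  for (k in seq_len(max_steps)) {
    if (keep_history) hist[[k]] <- list(x = x, value = cur$value, aux = cur$aux)
    cc <- conv_check(cur)
    if (isTRUE(cc)) {
      return(list(x = x, value = cur$value, aux = cur$aux, converged = TRUE,
                  steps = k - 1L, history = hist))
    }
    p <- -as.numeric(H %*% cur$grad)
    np <- sqrt(sum(p^2))
    if (np > trust) p <- p * trust / np
    accepted <- FALSE
    gnorm <- sqrt(sum(cur$grad^2))
    for (ls in 1:8) {
      # a failed electronic-structure solution at a trial point rejects the step
      nw <- tryCatch(fg(x + p), error = function(e) NULL)
      ok <- !is.null(nw) &&
        (if (accept == "value") nw$value <= cur$value + 1e-12
         else (sqrt(sum(nw$grad^2)) <= gnorm + 1e-12 ||
               nw$value <= cur$value + 1e-12))
      if (ok) { accepted <- TRUE; break }
      p <- p / 2
      trust <- trust / 2
    }
    if (!accepted) { # stuck: shrink further and reset curvature
      H <- diag(n); trust <- max(trust / 2, 1e-6)
      next
    }
    s <- p
    y <- nw$grad - cur$grad
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I_ <- diag(n)
      H <- (I_ - rho * tcrossprod(s, y)) %*% H %*% (I_ - rho * tcrossprod(y, s)) +
        rho * tcrossprod(s)
    }
    x <- x + s
    cur <- nw
    trust <- min(trust * 1.2, trust0)
  }
  list(x = x, value = cur$value, aux = cur$aux, converged = FALSE,
       steps = max_steps, history = hist)
}

#' Optimize a minimum-energy conical intersection
#'
#' Branching-update method: at each step the difference-gradient direction is
#' recomputed, the orthogonal vector updated per the history recursion, and a
#' trust-radius BFGS step taken on the composite gradient. Convergence
#' requires both the energy gap and the projected average-gradient RMS to
#' fall below their thresholds.
#'
#' @param surf a surface ([model_two_state()] or [qmmm_surface()])
#' @param I,J state indices (1-based adiabatic, I < J)
#' @param x0 starting coordinates
#' @param gap_tol gap threshold (hartree)
#' @param grad_tol projected average-gradient RMS threshold (hartree/bohr)
#' @param sigma gap-penalty weight (1/hartree)
#' @param max_steps macro-step limit
#' @param trust initial trust radius (bohr)
#' @param micro_mm relax the MM environment by [microiterations()] after each
#'   accepted step (QM/MM surfaces only)
#' @param accept step acceptance rule: `"value"` requires the composite
#'   energy to decrease (a true descent on peaked intersections and model
#'   surfaces); `"gradient"` accepts steps that do not increase the composite
#'   gradient norm. The projector makes the composite gradient a
#'   non-conservative field: on *sloped* intersections the average energy
#'   legitimately rises along the difference direction while the gap closes,
#'   so value-descent line searches stall there and the gradient-norm rule is
#'   the appropriate one.
#' @param o_init initialization of the orthogonal vector: `"gradient"`
#'   (Gram-Schmidt of the average gradient against the difference direction)
#'   or `"random"` (seeded random unit vector orthogonal to it). The update
#'   recursion keeps the orthogonal vector inside the span of its initial
#'   value and the difference-direction history, so a gradient component
#'   captured by the initial vector and orthogonal to every later difference
#'   direction stays projected out; the random initialization avoids placing
#'   the full average gradient in that blind spot.
#' @return object of class `optimization_state`
#' @export
optimize_ci <- function(surf, I, J, x0, gap_tol = 1e-3, grad_tol = 3e-4,
                        sigma = 1, max_steps = 200L, trust = 0.3,
                        micro_mm = FALSE, o_init = c("gradient", "random"),
                        accept = c("value", "gradient")) {
  stopifnot(I < J)
  o_init <- match.arg(o_init)
  accept <- match.arg(accept)
  env <- new.env(parent = emptyenv())
  env$plane <- NULL
  fg <- function(x) {
    ev <- surface_eval(surf, x, c(I, J), gradients = TRUE)
    gI <- ev$grads[[1]]; gJ <- ev$grads[[2]]
    EI <- ev$E[1]; EJ <- ev$E[2]
    d_raw <- (gJ - gI) / 2
    if (is.null(env$plane)) {
      o0 <- if (o_init == "random") {
        set.seed(length(x0) + 17L)
        stats::rnorm(length(x0))
      } else (gI + gJ) / 2
      env$plane <- branching_plane(d_raw, o0, 0L)
    } else {
      env$plane <- update_orthogonal(env$plane, d_raw)
    }
    cg <- composite_gradient(gI, gJ, EI, EJ, env$plane, sigma)
    list(value = cg$value, grad = cg$grad,
         aux = list(EI = EI, EJ = EJ, gap = abs(EJ - EI),
                    rms_proj = sqrt(mean(cg$g_avg_proj^2)),
                    plane = env$plane))
  }
  conv <- function(cur)
    cur$aux$gap <= gap_tol && cur$aux$rms_proj <= grad_tol
  if (micro_mm && inherits(surf, "qmmm_surface") && surf$nmm3 > 0) {
    # alternate electronic macro-steps with MM-environment microiterations
    x <- x0
    used <- 0L
    history <- list()
    repeat {
      chunk <- min(10L, max_steps - used)
      res <- bfgs_trust(x, fg, max_steps = chunk, trust0 = trust,
                        conv_check = conv, keep_history = TRUE,
                        accept = accept)
      history <- c(history, res$history)
      used <- used + max(res$steps, 1L)
      x <- res$x
      if (res$converged || used >= max_steps) break
      sys2 <- sys_with_coords(surf$sys, x[seq_len(surf$nqm3)],
                              x[surf$nqm3 + seq_len(surf$nmm3)])
      mi <- microiterations(sys2, mm_tol = grad_tol)
      x[surf$nqm3 + seq_len(surf$nmm3)] <- as.numeric(mi$mm$xyz)
    }
    res$history <- history
    res$steps <- used
  } else {
    res <- bfgs_trust(x0, fg, max_steps = max_steps, trust0 = trust,
                      conv_check = conv, keep_history = TRUE,
                      accept = accept)
  }
  out <- list(x = res$x, EI = res$aux$EI, EJ = res$aux$EJ,
              gap = res$aux$gap, rms_proj = res$aux$rms_proj,
              plane = res$aux$plane, converged = res$converged,
              steps = res$steps, history = res$history,
              states = c(I, J))
  class(out) <- "optimization_state"
  out
}

#' @export
print.optimization_state <- function(x, ...) {
  cat(sprintf("optimization: %s after %d steps",
              if (x$converged) "converged" else "NOT converged", x$steps))
  if (!is.null(x$gap)) cat(sprintf("; gap %.3e", x$gap))
  if (!is.null(x$rms_proj)) cat(sprintf(", proj-grad rms %.3e", x$rms_proj))
  cat("\n")
  invisible(x)
}

#' Optimize a single-state minimum
#'
#' Quasi-Newton (trust-radius BFGS) minimization of one adiabatic state.
#'
#' @param surf a surface
#' @param state 1-based adiabatic state index (1 = ground)
#' @param x0 starting coordinates
#' @param grad_tol gradient RMS threshold
#' @param max_steps step limit
#' @param trust initial trust radius
#' @return `optimization_state`
#' @export
optimize_minimum <- function(surf, state, x0, grad_tol = 3e-4,
                             max_steps = 200L, trust = 0.3) {
  fg <- function(x) {
    ev <- surface_eval(surf, x, state, gradients = TRUE)
    list(value = ev$E[1], grad = ev$grads[[1]],
         aux = list(E = ev$E[1], rms = sqrt(mean(ev$grads[[1]]^2))))
  }
  res <- bfgs_trust(x0, fg, max_steps = max_steps, trust0 = trust,
                    conv_check = function(cur) cur$aux$rms <= grad_tol,
                    keep_history = TRUE)
  out <- list(x = res$x, E = res$aux$E, rms = res$aux$rms,
              converged = res$converged, steps = res$steps,
              history = res$history, states = state, gap = NULL,
              rms_proj = NULL)
  class(out) <- "optimization_state"
  out
}

#' Relax the MM environment at fixed QM geometry (microiterations)
#'
#' The QM region is represented by its frozen ESPF populations (density held
#' fixed): the MM-coordinate-dependent part of the total energy,
#' `Tr(P h') + sum_A Z_A phi_A + E_MM`, is minimized over the MM coordinates
#' with L-BFGS. The SCF is re-run at the relaxed environment before returning.
#'
#' @param sys a [qmmm_system()]
#' @param mm_tol MM gradient RMS threshold (hartree/bohr)
#' @param maxit iteration cap
#' @param n_states excited states to solve at the relaxed environment
#' @return list with the relaxed `mm` region, the re-converged `point`,
#'   energies before/after and the final MM gradient RMS
#' @export
microiterations <- function(sys, mm_tol = 1e-4, maxit = 2000L, n_states = 0L) {
  pt0 <- prepare_point(sys)
  e0 <- total_energy(pt0)
  QA <- espf_populations(pt0$scf$P, pt0$ops)
  nel <- sum(pt0$scf$P * pt0$handle$S)
  Z <- sys$qm$Z
  env_fg <- function(xm) {
    s2 <- sys_with_coords(sys, xmm = xm)
    pot <- external_potential(s2$mm, s2$qm)
    eg <- mm_energy_gradient(s2$mm, s2$qm)
    e <- sum(QA * (pot$phi_av - pot$phi)) - pot$phi_av * nel +
      sum(Z * pot$phi) + eg$energy
    nqm <- nrow(s2$qm$xyz); nmm <- nrow(s2$mm$xyz)
    g <- eg$g_mm
    for (k in 1:3) {
      dmm <- pot$dphi_dmm[, , k, drop = FALSE]
      dim(dmm) <- c(nqm, nmm)
      dphiav <- colMeans(dmm)
      g[, k] <- g[, k] + sum(QA) * dphiav - as.numeric(t(dmm) %*% QA) -
        dphiav * nel + as.numeric(t(dmm) %*% Z)
    }
    list(value = e, grad = as.numeric(g))
  }
  x0 <- as.numeric(sys$mm$xyz)
  res <- stats::optim(x0, fn = function(x) env_fg(x)$value,
                      gr = function(x) env_fg(x)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e4, pgtol = mm_tol / 10))
  final <- env_fg(res$par)
  rms <- sqrt(mean(final$grad^2))
  sys2 <- sys_with_coords(sys, xmm = res$par)
  pt1 <- prepare_point(sys2, n_states = n_states)
  list(mm = sys2$mm, point = pt1, energy_before = e0,
       energy_after = total_energy(pt1), mm_grad_rms = rms,
       env_energy = final$value)
}
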