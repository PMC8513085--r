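# Classical (MM) engine: solvent parameter files, external electrostatic
# potential on the QM centers, MM energy and analytic gradients, and the
# droplet packer. Finite droplets: all pairs are summed exactly, no cutoffs,
# no periodicity. MM charges are fixed (no polarization).
#
# Conventions: intramolecular nonbonded interactions are fully excluded (the
# bonded terms describe the molecule); intermolecular Coulomb and
# Lennard-Jones act between all site pairs of different molecules. QM-MM
# electrostatics lives exclusively in the ESPF terms; the MM engine adds only
# the QM-MM Lennard-Jones wall.

# element-default LJ parameters for QM atoms (Amber94-style; sigma angstrom,
# epsilon kcal/mol), combined with MM sites by Lorentz-Berthelot
.qm_lj_defaults <- list(
  H = c(sigma = 2.47135, eps = 0.0157),
  C = c(sigma = 3.39967, eps = 0.1094),
  N = c(sigma = 3.25000, eps = 0.1700),
  O = c(sigma = 2.95992, eps = 0.2100)
)

qm_lj_params <- function(elements) {
  t(vapply(elements, function(e) {
    p <- .qm_lj_defaults[[normalize_element(e)]]
    if (is.null(p)) stop("no default LJ parameters for element ", e)
    c(ang2bohr(p["sigma"]), p["eps"] / units_au$kcalmol_per_hartree)
  }, numeric(2)))
}

#' Load a bundled solvent template
#'
#' Reads the packaged parameter file (plain keyed tables: site charges and LJ
#' parameters, bonded term lists, reference geometry) and returns a
#' one-molecule [mm_region()].
#'
#' @param name `"water"` or `"methanol"`
#' @return single-molecule `mm_region` (coordinates in bohr)
#' @export
solvent_template <- function(name) {
  path <- system.file("extdata", "params", paste0(tolower(name), ".txt"),
                      package = "espfqmm")
  if (path == "") stop("unknown solvent: ", name)
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  i <- 1
  need <- function(tag) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] != tag) stop("parameter file: expected ", tag, " got ", lines[i])
    tok
  }
  tok <- need("SITES"); ns <- as.integer(tok[2]); i <- i + 1
  sites <- do.call(rbind, lapply(lines[i:(i + ns - 1)], function(l)
    strsplit(l, "\\s+")[[1]]))
  i <- i + ns
  labels <- sites[, 1]; elem <- sites[, 2]
  charges <- as.numeric(sites[, 3])
  sigma <- ang2bohr(as.numeric(sites[, 4]))
  eps <- as.numeric(sites[, 5]) / units_au$kcalmol_per_hartree
  lab_idx <- function(l) {
    k <- match(l, labels)
    if (any(is.na(k))) stop("parameter file references unknown site label")
    k
  }
  tok <- need("BONDS"); nb <- as.integer(tok[2]); i <- i + 1
  bonds <- NULL
  if (nb > 0) {
    m <- do.call(rbind, lapply(lines[i:(i + nb - 1)], function(l) strsplit(l, "\\s+")[[1]]))
    bonds <- data.frame(i = lab_idx(m[, 1]), j = lab_idx(m[, 2]),
                        k = as.numeric(m[, 3]) / units_au$kcalmol_per_hartree *
                          units_au$angstrom_per_bohr^2,
                        r0 = ang2bohr(as.numeric(m[, 4])))
    i <- i + nb
  }
  tok <- need("ANGLES"); na_ <- as.integer(tok[2]); i <- i + 1
  angles <- NULL
  if (na_ > 0) {
    m <- do.call(rbind, lapply(lines[i:(i + na_ - 1)], function(l) strsplit(l, "\\s+")[[1]]))
    angles <- data.frame(i = lab_idx(m[, 1]), j = lab_idx(m[, 2]),
                         k = lab_idx(m[, 3]),
                         kth = as.numeric(m[, 4]) / units_au$kcalmol_per_hartree,
                         th0 = as.numeric(m[, 5]) * pi / 180)
    i <- i + na_
  }
  tok <- need("TORSIONS"); nt <- as.integer(tok[2]); i <- i + 1
  torsions <- NULL
  if (nt > 0) {
    m <- do.call(rbind, lapply(lines[i:(i + nt - 1)], function(l) strsplit(l, "\\s+")[[1]]))
    torsions <- data.frame(i = lab_idx(m[, 1]), j = lab_idx(m[, 2]),
                           k = lab_idx(m[, 3]), l = lab_idx(m[, 4]),
                           vn = as.numeric(m[, 5]) / units_au$kcalmol_per_hartree,
                           n = as.numeric(m[, 6]),
                           gamma = as.numeric(m[, 7]) * pi / 180)
    i <- i + nt
  }
  need("GEOMETRY"); i <- i + 1
  xyz <- matrix(0, ns, 3)
  for (s in seq_len(ns)) {
    tok <- strsplit(lines[i + s - 1], "\\s+")[[1]]
    xyz[lab_idx(tok[1]), ] <- ang2bohr(as.numeric(tok[2:4]))
  }
  mm_region(elem, xyz, charges, sigma, eps, rep(1L, ns),
            bonds = bonds, angles = angles, torsions = torsions)
}

#' MM electrostatic potential on the QM centers
#'
#' `phi_A = sum_i q_i / |R_A - R_i|` and the average potential
#' `Phi_av = mean(phi)`, with analytic derivatives with respect to both the
#' QM-atom and the MM-site coordinates.
#'
#' @param mm the MM region
#' @param qm the QM region
#' @return object of class `embedding_potential`: `phi`, `phi_av`,
#'   `dphi_dqm[A, 3]` (derivative of phi_A w.r.t. R_A) and
#'   `dphi_dmm[A, i, 3]`
#' @export
external_potential <- function(mm, qm) {
  nqm <- nrow(qm$xyz); nmm <- nrow(mm$xyz)
  phi <- numeric(nqm)
  dphi_dqm <- matrix(0, nqm, 3)
  dphi_dmm <- array(0, c(nqm, max(nmm, 1), 3))
  if (nmm > 0) {
    for (A in seq_len(nqm)) {
      d <- sweep(mm$xyz, 2, qm$xyz[A, ], "-")   # R_i - R_A
      r <- sqrt(rowSums(d^2))
      if (any(r < 1e-6)) {
        i <- which(r < 1e-6)[1]
        stop(sprintf("MM site %d coincident with QM atom %d", i, A))
      }
      phi[A] <- sum(mm$charges / r)
      # d phi_A / d R_A = sum_i q_i (R_i - R_A)/r^3
      w <- mm$charges / r^3
      dphi_dqm[A, ] <- colSums(d * w)
      dphi_dmm[A, , ] <- -d * w
    }
  }
  pot <- list(phi = phi, phi_av = mean(phi), dphi_dqm = dphi_dqm,
              dphi_dmm = dphi_dmm, n_mm = nmm)
  class(pot) <- "embedding_potential"
  pot
}

# scatter-add val into an n-vector at (possibly repeated) indices
tabulate2 <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Lennard-Jones pair energy/force helper (sigma/eps combined already)
lj_pair <- function(r2, sig, eps) {
  s6 <- (sig * sig / r2)^3
  e <- 4 * eps * (s6 * s6 - s6)
  # dE/dr2
  de <- 4 * eps * (-6 * s6 * s6 + 3 * s6) / r2
  c(e, de)
}

#' MM energy and gradient
#'
#' `E_MM` = intermolecular MM Coulomb + MM LJ + intramolecular bonded terms +
#' QM-MM Lennard-Jones. Gradients are returned for both blocks; QM-MM
#' electrostatics is *not* included here (it lives in the ESPF terms).
#'
#' @param mm MM region
#' @param qm QM region (or `NULL` for a pure MM computation)
#' @return list with `energy`, components, `g_mm` (n_mm x 3) and `g_qm`
#'   (n_qm x 3)
#' @export
mm_energy_gradient <- function(mm, qm = NULL) {
  nmm <- nrow(mm$xyz)
  g_mm <- matrix(0, max(nmm, 1), 3)
  e_coul <- e_lj <- e_bonded <- e_qmlj <- 0
  xyz <- mm$xyz
  if (nmm > 1) {
    # full pairwise intermolecular nonbonded sums (vectorized)
    dx <- outer(xyz[, 1], xyz[, 1], "-")   # x_i - x_j
    dy <- outer(xyz[, 2], xyz[, 2], "-")
    dz <- outer(xyz[, 3], xyz[, 3], "-")
    r2 <- dx^2 + dy^2 + dz^2
    inter <- outer(mm$molecule, mm$molecule, "!=")
    r2[!inter] <- Inf
    r <- sqrt(r2)
    qq <- tcrossprod(mm$charges)
    e_coul <- sum(qq / r) / 2
    # W_ij such that g_i = sum_j W_ij (R_j - R_i): Coulomb part
    W <- qq / r^3
    eps <- tcrossprod(sqrt(pmax(mm$epsilon, 0)))
    act <- eps > 0 & is.finite(r2)
    if (any(act)) {
      sig <- outer(mm$sigma, mm$sigma, "+") / 2
      s6 <- matrix(0, nmm, nmm)
      s6[act] <- (sig[act]^2 / r2[act])^3
      e_lj <- sum(4 * eps[act] * (s6[act]^2 - s6[act])) / 2
      # dE/dr2 * 2; sign flips it into the same W convention
      de <- matrix(0, nmm, nmm)
      de[act] <- 4 * eps[act] * (-12 * s6[act]^2 + 6 * s6[act]) / r2[act]
      W <- W - de
    }
    W[!is.finite(W)] <- 0
    rs <- rowSums(W)
    g_mm <- g_mm + (W %*% xyz) - rs * xyz
  }
  # bonded terms (vectorized over the term lists)
  if (nmm > 0 && nrow(mm$bonds) > 0) {
    bi <- mm$bonds$i; bj <- mm$bonds$j
    d <- xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    e_bonded <- e_bonded + sum(mm$bonds$k * (r - mm$bonds$r0)^2)
    f <- d * (2 * mm$bonds$k * (r - mm$bonds$r0) / r)
    for (k in 1:3) {
      g_mm[, k] <- g_mm[, k] + tabulate2(bi, f[, k], nmm) -
        tabulate2(bj, f[, k], nmm)
    }
  }
  if (nmm > 0 && nrow(mm$angles) > 0) {
    ai <- mm$angles$i; aj <- mm$angles$j; ak <- mm$angles$k
    u <- xyz[ai, , drop = FALSE] - xyz[aj, , drop = FALSE]
    v <- xyz[ak, , drop = FALSE] - xyz[aj, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ct <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(ct)
    st <- sqrt(pmax(1e-12, 1 - ct^2))
    e_bonded <- e_bonded + sum(mm$angles$kth * (th - mm$angles$th0)^2)
    pref <- 2 * mm$angles$kth * (th - mm$angles$th0)
    dthi <- (u * (ct / nu) - v / nv) / (nu * st)
    dthk <- (v * (ct / nv) - u / nu) / (nv * st)
    for (k in 1:3) {
      g_mm[, k] <- g_mm[, k] + tabulate2(ai, pref * dthi[, k], nmm) +
        tabulate2(ak, pref * dthk[, k], nmm) -
        tabulate2(aj, pref * (dthi[, k] + dthk[, k]), nmm)
    }
  }
  if (nmm > 0 && nrow(mm$torsions) > 0) {
    ti_ <- mm$torsions$i; tj_ <- mm$torsions$j
    tk_ <- mm$torsions$k; tl_ <- mm$torsions$l
    b1 <- xyz[tj_, , drop = FALSE] - xyz[ti_, , drop = FALSE]
    b2 <- xyz[tk_, , drop = FALSE] - xyz[tj_, , drop = FALSE]
    b3 <- xyz[tl_, , drop = FALSE] - xyz[tk_, , drop = FALSE]
    cross_rows <- function(u, v)
      cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
            u[, 3] * v[, 1] - u[, 1] * v[, 3],
            u[, 1] * v[, 2] - u[, 2] * v[, 1])
    n1 <- cross_rows(b1, b2)
    n2 <- cross_rows(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    m1 <- cross_rows(n1, n2)
    phi <- atan2(rowSums(m1 * b2) / nb2, rowSums(n1 * n2))
    vn <- mm$torsions$vn; nf <- mm$torsions$n; gam <- mm$torsions$gamma
    e_bonded <- e_bonded + sum(vn * (1 + cos(nf * phi - gam)))
    dEdphi <- -vn * nf * sin(nf * phi - gam)
    ti_v <- -n1 * (nb2 / rowSums(n1^2))
    tl_v <- n2 * (nb2 / rowSums(n2^2))
    s1 <- rowSums(b1 * b2) / nb2^2
    s2 <- rowSums(b3 * b2) / nb2^2
    tj_v <- -ti_v - ti_v * s1 + tl_v * s2
    tk_v <- -tl_v + ti_v * s1 - tl_v * s2
    for (k in 1:3) {
      g_mm[, k] <- g_mm[, k] + tabulate2(ti_, dEdphi * ti_v[, k], nmm) +
        tabulate2(tj_, dEdphi * tj_v[, k], nmm) +
        tabulate2(tk_, dEdphi * tk_v[, k], nmm) +
        tabulate2(tl_, dEdphi * tl_v[, k], nmm)
    }
  }
  # QM-MM Lennard-Jones (Lorentz-Berthelot combination)
  nqm <- if (is.null(qm)) 0 else nrow(qm$xyz)
  g_qm <- matrix(0, max(nqm, 1), 3)
  if (nqm > 0 && nmm > 0) {
    qlj <- qm_lj_params(qm$elements)
    for (A in seq_len(nqm)) {
      d <- sweep(mm$xyz, 2, qm$xyz[A, ], "-")  # R_i - R_A
      r2 <- rowSums(d^2)
      sig <- (qlj[A, 1] + mm$sigma) / 2
      eps <- sqrt(qlj[A, 2] * mm$epsilon)
      act <- eps > 0
      if (!any(act)) next
      s6 <- (sig[act]^2 / r2[act])^3
      e_qmlj <- e_qmlj + sum(4 * eps[act] * (s6^2 - s6))
      de <- 4 * eps[act] * (-12 * s6^2 + 6 * s6) / r2[act]
      gv <- d[act, , drop = FALSE] * de
      g_qm[A, ] <- g_qm[A, ] - colSums(gv)
      g_mm[act, ] <- g_mm[act, ] + gv
    }
  }
  list(energy = e_coul + e_lj + e_bonded + e_qmlj,
       coulomb = e_coul, lj = e_lj, bonded = e_bonded, qm_lj = e_qmlj,
       g_mm = g_mm[seq_len(max(nmm, 0)), , drop = FALSE],
       g_qm = g_qm[seq_len(max(nqm, 0)), , drop = FALSE])
}

# random rigid rotation matrix from a unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Pack a solvent droplet
#'
#' Rejection-sampling placement of rigid solvent molecules in a sphere around
#' the solute: random positions and rigid-body orientations, accepted when
#' every new site keeps a minimum distance from all already-placed sites and
#' the solute, and stays within the droplet radius. Reproducible for a fixed
#' seed.
#'
#' @param solute [qm_region()] at the droplet center (may be `NULL`)
#' @param solvent_template single-molecule [mm_region()]
#' @param n_molecules molecules to place
#' @param radius droplet radius (bohr)
#' @param seed RNG seed
#' @param min_dist minimum intersite distance (bohr); default 2 angstrom
#' @param max_attempts placement attempts per molecule
#' @return packed `mm_region`
#' @export
pack_droplet <- function(solute, solvent_template, n_molecules, radius,
                         seed = 1L, min_dist = ang2bohr(2.0),
                         max_attempts = 20000L) {
  tpl <- solvent_template
  ns <- nrow(tpl$xyz)
  # liquid-like density feasibility check (~40 A^3 per solvent site pair head)
  vol <- 4 / 3 * pi * radius^3
  vol_per_site <- ang2bohr(1)^3 * 10  # ~10 A^3 per site, generous liquid-like
  if (n_molecules * ns * vol_per_site > vol)
    stop(sprintf("radius %.1f bohr too small for %d molecules at liquid-like density",
                 radius, n_molecules))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctr <- colMeans(tpl$xyz)
  tpl0 <- sweep(tpl$xyz, 2, ctr, "-")
  placed <- matrix(numeric(0), ncol = 3)
  solxyz <- if (is.null(solute)) matrix(numeric(0), ncol = 3) else solute$xyz
  mols <- list()
  for (mno in seq_len(n_molecules)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      u <- stats::runif(1)^(1 / 3) * radius
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      pos <- u * v
      Rm <- random_rotation()
      cand <- tpl0 %*% t(Rm)
      cand <- sweep(cand, 2, pos, "+")
      if (any(sqrt(rowSums(cand^2)) > radius)) next
      ok2 <- TRUE
      for (other in list(placed, solxyz)) {
        if (nrow(other) == 0) next
        for (s in seq_len(ns)) {
          d2 <- rowSums(sweep(other, 2, cand[s, ], "-")^2)
          if (any(d2 < min_dist^2)) { ok2 <- FALSE; break }
        }
        if (!ok2) break
      }
      if (ok2) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("droplet packing failed: placed %d of %d molecules",
                   mno - 1, n_molecules))
    mols[[mno]] <- cand
    placed <- rbind(placed, cand)
  }
  xyz <- do.call(rbind, mols)
  nrep <- n_molecules
  shift <- rep((seq_len(nrep) - 1) * ns, each = ns)
  rep_df <- function(df, cols) {
    if (nrow(df) == 0) return(df)
    out <- df[rep(seq_len(nrow(df)), nrep), , drop = FALSE]
    for (cl in cols) out[[cl]] <- out[[cl]] + rep((seq_len(nrep) - 1) * ns,
                                                  each = nrow(df))
    rownames(out) <- NULL
    out
  }
  mm_region(rep(tpl$elements, nrep), xyz,
            rep(tpl$charges, nrep), rep(tpl$sigma, nrep),
            rep(tpl$epsilon, nrep), rep(seq_len(nrep), each = ns),
            bonds = rep_df(tpl$bonds, c("i", "j")),
            angles = rep_df(tpl$angles, c("i", "j", "k")),
            torsions = rep_df(tpl$torsions, c("i", "j", "k", "l")))
}
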