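# Structure and configuration I/O. Coordinates in files are angstrom; they
# are converted to bohr on read and back on write.

#' Read an XYZ file
#'
#' @param path file path
#' @param frame frame index for multi-frame files
#' @return list with `elements`, `xyz` (bohr) and the comment line
#' @export
read_xyz <- function(path, frame = 1L) {
  lines <- readLines(path)
  i <- 1; fr <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i)
    fr <- fr + 1
    if (fr == frame) {
      rows <- lines[(i + 2):(i + 1 + n)]
      tok <- strsplit(trimws(rows), "\\s+")
      el <- vapply(tok, `[`, "", 1)
      xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
      bad <- which(!is.finite(rowSums(xyz)))
      if (length(bad)) stop("malformed XYZ record at line ", i + 1 + bad[1])
      return(list(elements = normalize_element(el), xyz = ang2bohr(xyz),
                  comment = lines[i + 1]))
    }
    i <- i + 2 + n
  }
  stop("frame ", frame, " not found in ", path)
}

#' Write an XYZ file (optionally multi-frame)
#'
#' @param elements element symbols
#' @param xyz coordinates in bohr, or a list of such matrices for a trajectory
#' @param path output file
#' @param comment comment line (recycled over frames)
#' @export
write_xyz <- function(elements, xyz, path, comment = "") {
  frames <- if (is.list(xyz)) xyz else list(xyz)
  comment <- rep(comment, length.out = length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    a <- bohr2ang(frames[[f]])
    writeLines(as.character(nrow(a)), con)
    writeLines(comment[f], con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", elements,
                       a[, 1], a[, 2], a[, 3]), con)
  }
  invisible(path)
}

#' Read a structure and QM/MM partition
#'
#' PDB: the solute is the first chain (or `solute_chain`), remaining residues
#' become MM solvent molecules (grouped by residue number). XYZ: a sidecar
#' index file (`<path>.qm`) lists the 1-based QM atom indices, one per line;
#' without it all atoms are QM.
#'
#' @param path structure file
#' @param format `"xyz"` or `"pdb"` (default from extension)
#' @param solvent solvent template name used to parameterize MM residues
#' @param solute_chain PDB chain ID of the solute (default: first chain)
#' @param charge,multiplicity passed to [qm_region()]
#' @return list with `qm` and `mm`
#' @export
read_structure <- function(path, format = tools::file_ext(path),
                           solvent = "water", solute_chain = NULL,
                           charge = 0L, multiplicity = 1L) {
  format <- tolower(format)
  if (format == "xyz") {
    s <- read_xyz(path)
    idxfile <- paste0(path, ".qm")
    if (file.exists(idxfile)) {
      qm_idx <- as.integer(readLines(idxfile))
      qm_idx <- qm_idx[!is.na(qm_idx)]
    } else qm_idx <- seq_along(s$elements)
    qm <- qm_region(s$elements[qm_idx], s$xyz[qm_idx, , drop = FALSE],
                    charge, multiplicity)
    mm_idx <- setdiff(seq_along(s$elements), qm_idx)
    mm <- if (length(mm_idx) == 0) mm_empty() else
      solvent_from_sites(s$elements[mm_idx], s$xyz[mm_idx, , drop = FALSE], solvent)
    return(list(qm = qm, mm = mm))
  }
  if (format == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("PDB support requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    el <- at$elesy
    if (any(is.na(el) | el == "")) el <- substr(trimws(at$atom), 1, 1)
    chains <- unique(at$chain)
    sc <- if (is.null(solute_chain)) chains[1] else solute_chain
    qsel <- at$chain == sc
    xyz <- cbind(at$x, at$y, at$z)
    qm <- qm_region(el[qsel], ang2bohr(xyz[qsel, , drop = FALSE]),
                    charge, multiplicity)
    mm <- if (all(qsel)) mm_empty() else
      solvent_from_sites(el[!qsel], ang2bohr(xyz[!qsel, , drop = FALSE]),
                         solvent,
                         resno = at$resno[!qsel])
    return(list(qm = qm, mm = mm))
  }
  stop("unsupported format: ", format)
}

# build an MM region from raw solvent sites by tiling the template parameters
solvent_from_sites <- function(elements, xyz, solvent, resno = NULL) {
  tpl <- solvent_template(solvent)
  ns <- nrow(tpl$xyz)
  n <- length(elements)
  if (n %% ns != 0)
    stop("solvent sites (", n, ") not a multiple of the ", solvent,
         " template size (", ns, ")")
  nmol <- n %/% ns
  if (!is.null(resno)) {
    # sanity: residue grouping must agree with template size
    if (length(unique(resno)) != nmol)
      stop("PDB residue count does not match solvent partition")
  }
  nrep <- nmol
  shift <- function(df, cols) {
    if (nrow(df) == 0) return(df)
    out <- df[rep(seq_len(nrow(df)), nrep), , drop = FALSE]
    for (cl in cols) out[[cl]] <- out[[cl]] + rep((seq_len(nrep) - 1) * ns,
                                                  each = nrow(df))
    rownames(out) <- NULL
    out
  }
  mm_region(elements, xyz, rep(tpl$charges, nmol), rep(tpl$sigma, nmol),
            rep(tpl$epsilon, nmol), rep(seq_len(nmol), each = ns),
            bonds = shift(tpl$bonds, c("i", "j")),
            angles = shift(tpl$angles, c("i", "j", "k")),
            torsions = shift(tpl$torsions, c("i", "j", "k", "l")))
}

#' Write a QM/MM system as PDB (solute chain A, solvent chain B)
#'
#' @param qm QM region
#' @param mm MM region
#' @param path output file
#' @export
write_structure_pdb <- function(qm, mm, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("PDB support requires the bio3d package")
  nq <- nrow(qm$xyz); nm <- nrow(mm$xyz)
  xyz <- bohr2ang(rbind(qm$xyz, mm$xyz))
  el <- c(qm$elements, mm$elements)
  chain <- c(rep("A", nq), rep("B", nm))
  resno <- c(rep(1L, nq), if (nm > 0) 1L + mm$molecule else integer(0))
  resid <- c(rep("QM", nq), rep("SOL", nm))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), type = "ATOM",
                   resno = resno, resid = resid, chain = chain,
                   elety = make.unique(el, sep = ""), elesy = el)
  invisible(path)
}

#' Read a run configuration
#'
#' Flat `key = value` text with optional `[section]` headers (sections become
#' key prefixes, e.g. `grid.angular_order`). Unknown keys are rejected.
#'
#' @param path config file
#' @return named list of class `run_config`
#' @export
read_config <- function(path) {
  known <- c("functional", "basis", "job", "structure", "solvent",
             "charge", "n_states",
             "grid.angular_order", "grid.n_shells",
             "opt.gap_tol", "opt.grad_tol", "opt.mm_tol", "opt.max_steps",
             "opt.sigma", "opt.trust",
             "droplet.solvent", "droplet.n", "droplet.radius", "droplet.seed",
             "scan.extent", "scan.n_points", "scf.conv")
  numeric_keys <- c("charge", "n_states", "grid.angular_order", "grid.n_shells",
                    "opt.gap_tol", "opt.grad_tol", "opt.mm_tol", "opt.max_steps",
                    "opt.sigma", "opt.trust", "droplet.n", "droplet.radius",
                    "droplet.seed", "scan.extent", "scan.n_points", "scf.conv")
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  section <- ""
  cfg <- list()
  for (l in lines) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      next
    }
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    if (nchar(section)) key <- paste0(section, ".", key)
    if (!key %in% known) stop("unknown configuration key: ", key)
    val <- trimws(kv[2])
    if (key %in% numeric_keys) val <- as.numeric(val)
    cfg[[key]] <- val
  }
  thr <- grep("tol|conv", names(cfg), value = TRUE)
  for (k in thr) if (cfg[[k]] <= 0) stop("threshold must be positive: ", k)
  class(cfg) <- "run_config"
  cfg
}

#' Align one structure onto another (Kabsch)
#'
#' Optimal rigid-body superposition (rotation + translation) minimizing the
#' RMSD, via the SVD of the covariance matrix.
#'
#' @param X structure to move (n x 3)
#' @param Y reference (n x 3)
#' @return aligned copy of `X`
#' @export
kabsch_align <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  sv <- svd(crossprod(X0, Y0))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(X0 %*% t(R), 2, cy, "+")
}

#' Piecewise-linear interpolation path between structures
#'
#' Consecutive structures are rigid-body aligned (Kabsch), then interpolated
#' linearly in Cartesian coordinates. Endpoints are preserved exactly.
#'
#' @param structures ordered list of coordinate matrices (bohr)
#' @param n_segments interpolation segments per consecutive pair
#' @return list of geometries (including the endpoints)
#' @export
interpolate_path <- function(structures, n_segments = 5L) {
  if (length(structures) < 2) stop("need at least two structures")
  nat <- nrow(structures[[1]])
  for (s in structures) if (nrow(s) != nat) stop("atom-count mismatch")
  out <- list(structures[[1]])
  prev <- structures[[1]]
  for (i in 2:length(structures)) {
    nxt <- kabsch_align(structures[[i]], prev)
    for (s in seq_len(n_segments)) {
      t <- s / n_segments
      out[[length(out) + 1]] <- (1 - t) * prev + t * nxt
    }
    prev <- nxt
  }
  out
}
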