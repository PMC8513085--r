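# Gaussian basis handling: parse plain-text basis files, normalize primitives,
# expand atoms into Cartesian shells for the integral engine.

.basis_cache <- new.env(parent = emptyenv())

read_basis_file <- function(name) {
  key <- tolower(name)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  fname <- switch(key,
    "sto-3g" = "sto-3g.txt",
    "6-31g"  = "6-31g.txt",
    "6-31g*" = "6-31gs.txt",
    "6-31gs" = "6-31gs.txt",
    stop("unknown basis set: ", name))
  path <- system.file("extdata", "basis", fname, package = "espfqmm")
  if (path == "") stop("basis file not found for ", name)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  basis <- list()
  i <- 1
  while (i <= length(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] != "ELEM") stop("malformed basis file at line: ", lines[i])
    elem <- normalize_element(tok[2])
    i <- i + 1
    shells <- list()
    while (i <= length(lines)) {
      tok <- strsplit(lines[i], "\\s+")[[1]]
      if (tok[1] == "ELEM") break
      type <- tok[1]
      nprim <- as.integer(tok[2])
      rows <- do.call(rbind, lapply(lines[(i + 1):(i + nprim)], function(l)
        as.numeric(strsplit(l, "\\s+")[[1]])))
      i <- i + nprim + 1
      if (type == "SP") {
        shells[[length(shells) + 1]] <- list(l = 0L, alpha = rows[, 1], coef = rows[, 2])
        shells[[length(shells) + 1]] <- list(l = 1L, alpha = rows[, 1], coef = rows[, 3])
      } else {
        l <- match(type, c("S", "P", "D", "F")) - 1L
        if (is.na(l)) stop("unknown shell type: ", type)
        shells[[length(shells) + 1]] <- list(l = l, alpha = rows[, 1], coef = rows[, 2])
      }
    }
    basis[[elem]] <- shells
  }
  .basis_cache[[key]] <- basis
  basis
}

dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# normalize contraction for the (l,0,0) Cartesian component
normalize_shell <- function(l, alpha, coef) {
  # primitive norms
  cn <- coef * (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(dfact(2 * l - 1))
  # contracted self-overlap of the (l,0,0) component
  p <- outer(alpha, alpha, "+")
  ovl <- (pi / p)^1.5 * dfact(2 * l - 1) / (2 * p)^l
  s <- as.numeric(t(cn) %*% ovl %*% cn)
  cn / sqrt(s)
}

# Build the shell list consumed by the C++ integral engine.
build_shells <- function(qm, basis_name) {
  bas <- read_basis_file(basis_name)
  shells <- list()
  offset <- 1L
  for (i in seq_len(nrow(qm$xyz))) {
    el <- qm$elements[i]
    if (is.null(bas[[el]]))
      stop("basis ", basis_name, " has no entry for element ", el)
    for (sh in bas[[el]]) {
      cn <- normalize_shell(sh$l, sh$alpha, sh$coef)
      shells[[length(shells) + 1]] <- list(
        l = sh$l, atom = i, center = as.numeric(qm$xyz[i, ]),
        alpha = sh$alpha, coef = cn, offset = offset)
      offset <- offset + ((sh$l + 1L) * (sh$l + 2L)) %/% 2L
    }
  }
  attr(shells, "nao") <- offset - 1L
  shells
}
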