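#' @section Potential files:
#' The supported embedding-potential dialect follows the Dalton/PyFraME
#' convention: an `@COORDINATES` section (count, unit `AA` or `AU`, element +
#' xyz rows), an `@MULTIPOLES` section with `ORDER 0/1/2` blocks (site index
#' followed by 1, 3 or 6 components; quadrupoles packed xx xy xz yy yz zz),
#' an `@POLARIZABILITIES` section with an `ORDER 1 1` block (6 packed
#' components per site), and an `EXCLISTS` section whose rows list a site and
#' the sites it does not interact with classically (zero-padded). Exclusion
#' rows must be mutual; fragment membership is reconstructed as the connected
#' components of the exclusion graph. Coordinates on disk may be angstrom or
#' bohr; in memory everything is bohr.
#' @name pe-potfile
#' @keywords internal
NULL

#' Read a PE potential file
#'
#' @param path Path to a `.pot` file in the dialect described in
#'   [pe-potfile].
#' @return A [pe_sites()] object (sites grouped into fragments via the
#'   exclusion lists).
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  strip <- function(x) trimws(sub("!.*$", "", x))
  content <- strip(lines)
  nonempty <- which(nzchar(content))
  i <- 1
  S <- 0
  position <- NULL; element <- NULL
  charge <- NULL; dipole <- NULL; quadru <- NULL; max_order <- NULL
  polar <- NULL
  excl <- NULL
  next_line <- function() {
    while (i <= length(content) && !nzchar(content[i])) i <<- i + 1
    if (i > length(content)) return(NULL)
    out <- content[i]; i <<- i + 1
    out
  }
  peek_line <- function() {
    j <- i
    while (j <= length(content) && !nzchar(content[j])) j <- j + 1
    if (j > length(content)) NULL else content[j]
  }
  read_coordinates <- function() {
    n <- as.integer(next_line())
    unit <- toupper(next_line())
    if (!unit %in% c("AA", "AU")) stop("unknown coordinate unit: ", unit)
    pos <- matrix(0, n, 3); el <- character(n)
    for (k in seq_len(n)) {
      f <- strsplit(next_line(), "\\s+")[[1]]
      if (length(f) != 4) stop("malformed coordinate row ", k)
      el[k] <- f[1]
      pos[k, ] <- as.numeric(f[2:4])
    }
    if (unit == "AA") pos <- pos * pe_constants$bohr_per_angstrom
    S <<- n; position <<- pos; element <<- el
    charge <<- numeric(n); dipole <<- matrix(0, n, 3)
    quadru <<- matrix(0, n, 6); max_order <<- integer(n)
    polar <<- array(0, c(3, 3, n))
    excl <<- rep(list(integer(0)), n)
  }
  read_multipoles <- function() {
    repeat {
      nxt <- peek_line()
      if (is.null(nxt) || !grepl("^ORDER\\b", nxt)) break
      ord <- as.integer(strsplit(next_line(), "\\s+")[[1]][2])
      if (is.na(ord) || ord > 2) {
        stop("unsupported multipole order in potential file: ", ord)
      }
      n <- as.integer(next_line())
      ncomp <- c(1, 3, 6)[ord + 1]
      for (k in seq_len(n)) {
        f <- as.numeric(strsplit(next_line(), "\\s+")[[1]])
        if (length(f) != ncomp + 1) {
          stop("multipole row of order ", ord, " needs ", ncomp + 1,
               " fields (site ", k, ")")
        }
        s <- as.integer(f[1])
        if (s < 1 || s > S) stop("multipole row references unknown site ", s)
        if (ord == 0) charge[s] <<- f[2]
        if (ord == 1) dipole[s, ] <<- f[2:4]
        if (ord == 2) quadru[s, ] <<- f[2:7]
        max_order[s] <<- max(max_order[s], ord)
      }
    }
  }
  read_polarizabilities <- function() {
    hdr <- next_line()
    if (!grepl("^ORDER\\s+1\\s+1$", hdr)) {
      stop("only ORDER 1 1 (dipole-dipole) polarizabilities are supported, got: ",
           hdr)
    }
    n <- as.integer(next_line())
    for (k in seq_len(n)) {
      f <- as.numeric(strsplit(next_line(), "\\s+")[[1]])
      if (length(f) != 7) stop("polarizability row needs 7 fields (row ", k, ")")
      s <- as.integer(f[1])
      if (s < 1 || s > S) stop("polarizability row references unknown site ", s)
      m <- matrix(0, 3, 3)
      m[1, 1] <- f[2]; m[1, 2] <- m[2, 1] <- f[3]; m[1, 3] <- m[3, 1] <- f[4]
      m[2, 2] <- f[5]; m[2, 3] <- m[3, 2] <- f[6]; m[3, 3] <- f[7]
      polar[, , s] <<- m
    }
  }
  read_exclists <- function() {
    hdr <- as.integer(strsplit(next_line(), "\\s+")[[1]])
    n <- hdr[1]
    for (k in seq_len(n)) {
      f <- as.integer(strsplit(next_line(), "\\s+")[[1]])
      s <- f[1]
      if (is.na(s) || s < 1 || s > S) stop("exclusion row references unknown site ", f[1])
      ids <- f[-1]; ids <- ids[!is.na(ids) & ids > 0]
      if (any(ids > S)) stop("exclusion row for site ", s,
                             " references unknown site ", max(ids))
      excl[[s]] <<- sort(unique(c(excl[[s]], ids[ids != s])))
    }
    # symmetrize, then validate that no one-sided rows were declared
    for (s in seq_len(S)) for (t in excl[[s]]) {
      excl[[t]] <<- sort(unique(c(excl[[t]], s)))
    }
  }
  repeat {
    ln <- next_line()
    if (is.null(ln)) break
    if (ln == "@COORDINATES") read_coordinates()
    else if (ln == "@MULTIPOLES") read_multipoles()
    else if (ln == "@POLARIZABILITIES") read_polarizabilities()
    else if (ln == "EXCLISTS" || ln == "@EXCLISTS") read_exclists()
    else stop("unknown section in potential file at line ",
              which(content == ln)[1], ": '", ln, "'")
  }
  if (is.null(position)) stop("potential file has no @COORDINATES section")
  # fragments = connected components of the exclusion graph
  frag <- integer(S)
  nf <- 0
  for (s in seq_len(S)) {
    if (frag[s] != 0) next
    nf <- nf + 1
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (frag[u] != 0) next
      frag[u] <- nf
      queue <- c(queue, setdiff(excl[[u]], which(frag != 0)))
    }
  }
  pe_sites(position = position, fragment = frag, charge = charge,
           dipole = dipole, quadrupole = quadru, max_order = max_order,
           polarizability = polar, exclusions = excl, element = element)
}

fmt_num <- function(x) sprintf("% .12e", x)

#' Write a PE potential file
#'
#' Inverse of [read_potential()]: emits coordinates (in the requested unit),
#' multipole blocks for each order present, polarizabilities for polarizable
#' sites, and zero-padded mutual exclusion lists. Deterministic ordering: the
#' sites are written in storage order (fragments contiguous in the shipped
#' fixtures).
#'
#' @param sites A [pe_sites()] object.
#' @param path Output path.
#' @param unit `"AU"` (bohr, default) or `"AA"` (angstrom) on disk.
#' @return `path`, invisibly.
#' @export
write_potential <- function(sites, path, unit = c("AU", "AA")) {
  unit <- match.arg(unit)
  S <- n_sites(sites)
  pos <- sites$position
  if (unit == "AA") pos <- pos / pe_constants$bohr_per_angstrom
  out <- c("@COORDINATES", as.character(S), unit)
  for (s in seq_len(S)) {
    out <- c(out, paste(sites$element[s],
                        paste(fmt_num(pos[s, ]), collapse = " ")))
  }
  out <- c(out, "@MULTIPOLES")
  out <- c(out, "ORDER 0", as.character(S))
  for (s in seq_len(S)) {
    out <- c(out, paste(s, fmt_num(sites$charge[s])))
  }
  w1 <- which(sites$max_order >= 1)
  if (length(w1)) {
    out <- c(out, "ORDER 1", as.character(length(w1)))
    for (s in w1) {
      out <- c(out, paste(s, paste(fmt_num(sites$dipole[s, ]), collapse = " ")))
    }
  }
  w2 <- which(sites$max_order >= 2)
  if (length(w2)) {
    out <- c(out, "ORDER 2", as.character(length(w2)))
    for (s in w2) {
      out <- c(out, paste(s, paste(fmt_num(sites$quadrupole[s, ]),
                                   collapse = " ")))
    }
  }
  wp <- which(polarizable_mask(sites))
  if (length(wp)) {
    out <- c(out, "@POLARIZABILITIES", "ORDER 1 1", as.character(length(wp)))
    for (s in wp) {
      a <- sites$polarizability[, , s]
      out <- c(out, paste(s, paste(fmt_num(c(a[1, 1], a[1, 2], a[1, 3],
                                             a[2, 2], a[2, 3], a[3, 3])),
                                   collapse = " ")))
    }
  }
  maxlen <- max(1L, vapply(sites$exclusions, length, 1L)) + 1L
  out <- c(out, "EXCLISTS", paste(S, maxlen))
  for (s in seq_len(S)) {
    row <- c(s, sites$exclusions[[s]])
    row <- c(row, rep(0L, maxlen - length(row)))
    out <- c(out, paste(row, collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write standard XYZ geometry files
#'
#' XYZ files carry angstrom on disk; positions are converted to bohr in
#' memory.
#'
#' @param path File path.
#' @return `read_xyz`: list with `element` (character), `position`
#'   (N x 3 matrix, bohr) and `comment`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2) stop("malformed XYZ: expected ", n, " atom rows")
  el <- character(n); pos <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 2]), "\\s+")[[1]]
    if (length(f) < 4) stop("malformed XYZ atom row ", k)
    el[k] <- f[1]
    pos[k, ] <- as.numeric(f[2:4])
  }
  list(element = el, position = pos * pe_constants$bohr_per_angstrom,
       comment = lines[2])
}

#' @rdname read_xyz
#' @param x Object with `element` and `position` (bohr) fields, e.g. a
#'   [pe_core()] object or a [read_xyz()] result.
#' @param comment Comment line.
#' @export
write_xyz <- function(x, path, comment = "") {
  pos <- x$position / pe_constants$bohr_per_angstrom
  out <- c(as.character(nrow(pos)), comment)
  for (k in seq_len(nrow(pos))) {
    out <- c(out, paste(x$element[k], paste(fmt_num(pos[k, ]), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write plain-text property dumps
#'
#' A documented whitespace container for externally computed (or internally
#' assembled) property matrices: geometry and masses, the Cartesian Hessian
#' (hartree bohr^-2), and optionally the dipole gradient (3N x 3, e) and the
#' packed polarizability gradient (3N x 6, e^2 bohr^2 hartree^-1). The reader
#' enforces Hessian symmetry (1e-10 relative) and mutual dimension
#' consistency.
#'
#' @param path File path.
#' @return `read_property_dump`: object of class `property_dump` with fields
#'   `element`, `position`, `masses`, `hessian`, `dipole_gradient`,
#'   `polarizability_gradient` (the latter two possibly `NULL`).
#' @export
read_property_dump <- function(path) {
  lines <- readLines(path)
  content <- trimws(lines)
  i <- 1
  take <- function() { out <- content[i]; i <<- i + 1; out }
  if (!grepl("^# polembed property dump", take())) {
    stop("not a polembed property dump")
  }
  hdr <- strsplit(take(), "\\s+")[[1]]
  if (hdr[1] != "NATOMS") stop("property dump missing NATOMS")
  n <- as.integer(hdr[2])
  read_matrix <- function(nr, nc) {
    m <- matrix(0, nr, nc)
    for (r in seq_len(nr)) {
      v <- as.numeric(strsplit(take(), "\\s+")[[1]])
      if (length(v) != nc) stop("matrix row has ", length(v),
                                " entries, expected ", nc)
      m[r, ] <- v
    }
    m
  }
  el <- character(n); pos <- matrix(0, n, 3)
  masses <- NULL; hess <- NULL; dgrad <- NULL; pgrad <- NULL
  while (i <= length(content)) {
    ln <- take()
    if (!nzchar(ln)) next
    key <- strsplit(ln, "\\s+")[[1]][1]
    if (key == "GEOMETRY") {
      for (k in seq_len(n)) {
        f <- strsplit(take(), "\\s+")[[1]]
        el[k] <- f[1]; pos[k, ] <- as.numeric(f[2:4])
      }
    } else if (key == "MASSES") {
      masses <- as.numeric(strsplit(take(), "\\s+")[[1]])
      if (length(masses) != n) stop("MASSES length != NATOMS")
    } else if (key == "HESSIAN") {
      hess <- read_matrix(3 * n, 3 * n)
    } else if (key == "DIPOLE_GRADIENT") {
      dgrad <- read_matrix(3 * n, 3)
    } else if (key == "POLARIZABILITY_GRADIENT") {
      pgrad <- read_matrix(3 * n, 6)
    } else {
      stop("unknown property-dump section: ", key)
    }
  }
  if (is.null(masses) || is.null(hess)) {
    stop("property dump must contain MASSES and HESSIAN sections")
  }
  rel <- max(abs(hess - t(hess))) / max(1e-300, max(abs(hess)))
  if (rel > 1e-10) stop("Hessian in property dump is not symmetric ",
                        "(relative asymmetry ", format(rel, digits = 3), ")")
  structure(list(element = el, position = pos, masses = masses,
                 hessian = hess, dipole_gradient = dgrad,
                 polarizability_gradient = pgrad),
            class = "property_dump")
}

#' @rdname read_property_dump
#' @param dump A `property_dump`-like list (fields as above).
#' @export
write_property_dump <- function(dump, path) {
  n <- length(dump$masses)
  stopifnot(nrow(dump$hessian) == 3 * n, ncol(dump$hessian) == 3 * n)
  out <- c("# polembed property dump v1", paste("NATOMS", n),
           "GEOMETRY (bohr)")
  for (k in seq_len(n)) {
    out <- c(out, paste(dump$element[k],
                        paste(fmt_num(dump$position[k, ]), collapse = " ")))
  }
  out <- c(out, "MASSES (amu)",
           paste(fmt_num(dump$masses), collapse = " "))
  emit <- function(tag, m) {
    c(tag, apply(m, 1, function(r) paste(fmt_num(r), collapse = " ")))
  }
  out <- c(out, emit("HESSIAN (hartree/bohr^2)", dump$hessian))
  if (!is.null(dump$dipole_gradient)) {
    stopifnot(nrow(dump$dipole_gradient) == 3 * n)
    out <- c(out, emit("DIPOLE_GRADIENT (e)", dump$dipole_gradient))
  }
  if (!is.null(dump$polarizability_gradient)) {
    stopifnot(nrow(dump$polarizability_gradient) == 3 * n)
    out <- c(out, emit("POLARIZABILITY_GRADIENT (e^2 bohr^2/hartree)",
                       dump$polarizability_gradient))
  }
  writeLines(out, path)
  invisible(path)
}
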