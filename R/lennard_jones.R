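#' @section Lennard-Jones:
#' Nonelectrostatic repulsion and dispersion between core atoms and
#' environment sites are modeled by the 6-12 potential
#'   E_LJ = sum_pairs 4 eps_sn \[ (sigma_sn / r)^12 - (sigma_sn / r)^6 \]
#' with Lorentz-Berthelot combination sigma_sn = (sigma_s + sigma_n) / 2 and
#' eps_sn = sqrt(eps_s eps_n). The interaction is strictly pairwise
#' core-environment, so the Hessian has no blocks coupling two core atoms.
#' Environment sites without LJ parameters contribute nothing (warned once
#' per call).
#' @name pe-lennard-jones
#' @keywords internal
NULL

#' Lorentz-Berthelot pair parameters
#'
#' @param sigma_s,eps_s Environment-site parameters (bohr, hartree).
#' @param sigma_n,eps_n Core-atom parameters.
#' @return List with `sigma` and `eps` for the pair.
#' @export
lj_pair_parameters <- function(sigma_s, eps_s, sigma_n, eps_n) {
  list(sigma = (sigma_s + sigma_n) / 2, eps = sqrt(eps_s * eps_n))
}

# pairs with defined parameters on both sides; env side warned when dropped
lj_active_pairs <- function(core, sites, warn = TRUE) {
  env_ok <- which(!is.na(sites$lj_sigma) & !is.na(sites$lj_epsilon))
  if (warn && length(env_ok) < n_sites(sites)) {
    warning(n_sites(sites) - length(env_ok),
            " environment site(s) lack LJ parameters and are skipped",
            call. = FALSE)
  }
  core_ok <- which(!is.na(core$lj_sigma) & !is.na(core$lj_epsilon))
  list(env = env_ok, core = core_ok)
}

lj_pair_terms <- function(r, sigma, eps) {
  sr6 <- (sigma / r)^6
  e  <- 4 * eps * (sr6^2 - sr6)
  de <- 4 * eps * (-12 * sr6^2 + 6 * sr6) / r          # du/dr
  d2 <- 4 * eps * (156 * sr6^2 - 42 * sr6) / r^2       # d2u/dr2
  list(e = e, de = de, d2 = d2)
}

#' Lennard-Jones energy between core and environment
#'
#' @param core A [pe_core()] object.
#' @param sites A [pe_sites()] environment (LJ parameters taken per site).
#' @param warn Warn when sites lacking parameters are skipped.
#' @return Scalar energy (hartree).
#' @export
lj_energy <- function(core, sites, warn = TRUE) {
  act <- lj_active_pairs(core, sites, warn)
  e <- 0
  for (n in act$core) for (s in act$env) {
    d <- core$position[n, ] - sites$position[s, ]
    r <- sqrt(sum(d * d))
    if (r < PE_SINGULAR_DIST) stop("coincident LJ pair (site ", s,
                                   ", atom ", n, ")")
    p <- lj_pair_parameters(sites$lj_sigma[s], sites$lj_epsilon[s],
                            core$lj_sigma[n], core$lj_epsilon[n])
    e <- e + lj_pair_terms(r, p$sigma, p$eps)$e
  }
  e
}

#' Analytic gradient of the Lennard-Jones energy
#'
#' @inheritParams lj_energy
#' @return Numeric vector of length 3 N_core (hartree / bohr).
#' @export
lj_gradient <- function(core, sites, warn = TRUE) {
  act <- lj_active_pairs(core, sites, warn)
  g <- numeric(3 * n_core_atoms(core))
  for (n in act$core) for (s in act$env) {
    d <- core$position[n, ] - sites$position[s, ]
    r <- sqrt(sum(d * d))
    p <- lj_pair_parameters(sites$lj_sigma[s], sites$lj_epsilon[s],
                            core$lj_sigma[n], core$lj_epsilon[n])
    t <- lj_pair_terms(r, p$sigma, p$eps)
    g[3 * n - 2:0] <- g[3 * n - 2:0] + t$de * d / r
  }
  g
}

#' Analytic Hessian of the Lennard-Jones energy
#'
#' @inheritParams lj_energy
#' @return Symmetric 3 N_core x 3 N_core matrix, block-diagonal over core
#'   atoms (hartree / bohr^2).
#' @export
lj_hessian <- function(core, sites, warn = TRUE) {
  act <- lj_active_pairs(core, sites, warn)
  N <- n_core_atoms(core)
  H <- matrix(0, 3 * N, 3 * N)
  I3 <- diag(3)
  for (n in act$core) for (s in act$env) {
    d <- core$position[n, ] - sites$position[s, ]
    r <- sqrt(sum(d * d))
    rh <- d / r
    p <- lj_pair_parameters(sites$lj_sigma[s], sites$lj_epsilon[s],
                            core$lj_sigma[n], core$lj_epsilon[n])
    t <- lj_pair_terms(r, p$sigma, p$eps)
    blk <- t$d2 * tcrossprod(rh) + (t$de / r) * (I3 - tcrossprod(rh))
    idx <- 3 * n - 2:0
    H[idx, idx] <- H[idx, idx] + blk
  }
  H
}

#' Read a Lennard-Jones parameter table
#'
#' Whitespace-separated columns `element sigma epsilon` preceded by a header
#' line `# units sigma=<angstrom|bohr> epsilon=<kJ/mol|hartree>`. Values are
#' converted to bohr / hartree on read.
#'
#' @param path File path.
#' @return Data frame with columns `element`, `sigma` (bohr), `epsilon`
#'   (hartree).
#' @export
read_lj_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[1]
  if (!grepl("^#\\s*units", hdr)) {
    stop("LJ table must start with a '# units sigma=... epsilon=...' header")
  }
  sig_unit <- sub(".*sigma=(\\S+).*", "\\1", hdr)
  eps_unit <- sub(".*epsilon=(\\S+).*", "\\1", hdr)
  body <- lines[-1]
  body <- body[!grepl("^#", body)]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 3)
  if (length(bad)) stop("malformed LJ table row: ", body[bad[1]])
  df <- data.frame(
    element = vapply(parts, `[`, "", 1),
    sigma = as.numeric(vapply(parts, `[`, "", 2)),
    epsilon = as.numeric(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE
  )
  df$sigma <- switch(sig_unit,
    angstrom = df$sigma * pe_constants$bohr_per_angstrom,
    bohr = df$sigma,
    stop("unknown sigma unit: ", sig_unit))
  df$epsilon <- switch(eps_unit,
    `kJ/mol` = df$epsilon * pe_constants$hartree_per_kjmol,
    hartree = df$epsilon,
    stop("unknown epsilon unit: ", eps_unit))
  df
}

#' Attach LJ parameters from a table to sites or core atoms by element
#'
#' @param x A [pe_sites()] or [pe_core()] object.
#' @param table A [read_lj_table()] data frame.
#' @return `x` with `lj_sigma` / `lj_epsilon` filled where the element is in
#'   the table.
#' @export
assign_lj_parameters <- function(x, table) {
  idx <- match(x$element, table$element)
  hit <- !is.na(idx)
  x$lj_sigma[hit] <- table$sigma[idx[hit]]
  x$lj_epsilon[hit] <- table$epsilon[idx[hit]]
  x
}
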