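## Pairwise interaction energy: 12-6 Lennard-Jones plus Coulomb term,
## summed over inter-residue atom pairs.
##
##   E = sum_ij [ A_ij / r^12 - B_ij / r^6 + q_i q_j / (eps * r) ]
##   A_ij = eps*_ij (R*_ij)^12,  B_ij = 2 eps*_ij (R*_ij)^6
##   R*_ij = R*_i + R*_j,        eps*_ij = sqrt(eps*_i eps*_j)
##
## R* and eps* are AMBER-style van der Waals radius and well depth; the
## parameter table is a configuration artifact (editable file), not a
## constant of the method.

.COULOMB_K <- 332.0637  # kcal A / (mol e^2)

#' Load Lennard-Jones / charge parameters
#'
#' Reads a columnar parameter file (`atom_type`, `rstar`, `epsstar`, `q`)
#' or returns the packaged AMBER-style defaults covering the backbone and
#' representative heavy-atom types used by the synthetic fixtures.
#'
#' @param path optional TSV file; default uses the table shipped in
#'   `inst/extdata/energy_params.tsv`
#' @param table optional data frame supplied directly instead of a file
#' @param dielectric relative dielectric constant (default 1.0)
#' @param distance_dependent when TRUE use the distance-dependent
#'   screening eps = r_ij (common implicit-solvent approximation)
#' @return Object of class `energy_params`: list with `table` (data
#'   frame keyed by atom type), `dielectric`, `distance_dependent`.
#' @export
energy_params <- function(path = NULL, table = NULL, dielectric = 1.0,
                          distance_dependent = FALSE) {
  if (is.null(table)) {
    if (is.null(path)) {
      path <- system.file("extdata", "energy_params.tsv", package = "dotrna")
    }
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             quote = "", stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(table)
  }
  stopifnot(all(c("atom_type", "rstar", "epsstar", "q") %in% names(tab)))
  if (any(tab$rstar <= 0) || any(tab$epsstar < 0)) {
    stop("invalid parameters: need rstar > 0 and epsstar >= 0")
  }
  rownames(tab) <- tab$atom_type
  structure(list(table = tab, dielectric = dielectric,
                 distance_dependent = distance_dependent),
            class = "energy_params")
}

## Parameter lookup for an atom: by "RESID:NAME" first, then by bare atom
## name, then by element.  Returns row or NULL.
.param_row <- function(params, resid, name, element) {
  tab <- params$table
  for (key in c(paste0(resid, ":", name), name, element)) {
    if (key %in% rownames(tab)) return(tab[key, ])
  }
  NULL
}

.atom_params <- function(atoms, params, strict = TRUE) {
  n <- nrow(atoms)
  rstar <- numeric(n); eps <- numeric(n); q <- numeric(n)
  miss <- character(0)
  for (i in seq_len(n)) {
    row <- .param_row(params, atoms$resid[i], atoms$elety[i], atoms$elesy[i])
    if (is.null(row)) {
      miss <- c(miss, paste0(atoms$resid[i], ":", atoms$elety[i]))
      next
    }
    rstar[i] <- row$rstar; eps[i] <- row$epsstar; q[i] <- row$q
  }
  if (length(miss) > 0L) {
    miss <- unique(miss)
    if (strict) {
      stop("no energy parameters for atom(s): ", paste(miss, collapse = ", "))
    }
    warning("no energy parameters for atom(s), charges/LJ set to 0: ",
            paste(miss, collapse = ", "))
  }
  list(rstar = rstar, epsstar = eps, q = q)
}

#' Lennard-Jones 12-6 term
#'
#' Evaluated through the A/B form: `A/r^12 - B/r^6` with
#' `A = eps* R*^12`, `B = 2 eps* R*^6`, which equals
#' `eps*((R*/r)^12 - 2 (R*/r)^6)`; the minimum is exactly `-eps*` at
#' `r = R*`.
#'
#' @param epsstar_ij combined well depth (kcal/mol), geometric mean
#' @param rstar_ij combined van der Waals radius (A), sum of the two
#' @param r interatomic distance (A), > 0
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
lj_term <- function(epsstar_ij, rstar_ij, r) {
  if (any(r <= 0)) stop("interatomic distance must be positive")
  A <- epsstar_ij * rstar_ij^12
  B <- 2 * epsstar_ij * rstar_ij^6
  A / r^12 - B / r^6
}

#' Coulomb term
#'
#' `332.0637 q_i q_j / (eps r)` kcal/mol with charges in electron units
#' and `r` in Angstrom.  With `distance_dependent` screening the
#' denominator becomes `r^2`.
#'
#' @param qi,qj partial charges (e)
#' @param r distance (A), > 0
#' @param dielectric relative dielectric constant (default 1)
#' @param distance_dependent use eps = r screening (default FALSE)
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
coulomb_term <- function(qi, qj, r, dielectric = 1.0,
                         distance_dependent = FALSE) {
  if (any(r <= 0)) stop("interatomic distance must be positive")
  eps <- if (distance_dependent) dielectric * r else dielectric
  .COULOMB_K * qi * qj / (eps * r)
}

#' Interaction energy of one residue-nucleotide pair
#'
#' Sums the Lennard-Jones and Coulomb terms over all inter-residue atom
#' pairs whose separation is at most `shell` (default 10 A; both terms
#' are negligible beyond that at the interface scale).
#'
#' @param atoms_a,atoms_b atom data frames (columns `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`) of the two residues
#' @param params an `energy_params` object
#' @param shell atom-pair evaluation cutoff in A (default 10)
#' @param strict error (TRUE, default) or warn-and-zero on atoms without
#'   parameters
#' @return Energy in kcal/mol.
#' @export
residue_pair_energy <- function(atoms_a, atoms_b, params, shell = 10,
                                strict = TRUE) {
  pa <- .atom_params(atoms_a, params, strict)
  pb <- .atom_params(atoms_b, params, strict)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-9)) stop("coincident atoms (r = 0) between the two residues")
  sel <- which(r <= shell, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(0)
  i <- sel[, 1L]; j <- sel[, 2L]; rij <- r[sel]
  eps_ij <- sqrt(pa$epsstar[i] * pb$epsstar[j])
  rstar_ij <- pa$rstar[i] + pb$rstar[j]
  e_lj <- lj_term(eps_ij, rstar_ij, rij)
  e_c <- coulomb_term(pa$q[i], pb$q[j], rij, params$dielectric,
                      params$distance_dependent)
  sum(e_lj + e_c)
}

#' Mean interaction energy per amino-acid x nucleotide cell
#'
#' Computes [residue_pair_energy()] for every contacting residue pair
#' and averages per residue-type x nucleotide-type cell, separately for
#' pairs whose protein residue lies in a DOT region and for all other
#' pairs.  Cells without pairs are reported as 0.00 with count 0.
#'
#' @param struct bound `dot_structure`
#' @param contacts `contact_table` (defines the interface pairs scored)
#' @param dot_residues character vector of DOT residue keys
#' @param params `energy_params`
#' @param shell atom-pair cutoff passed to [residue_pair_energy()]
#' @param strict parameter strictness (see [residue_pair_energy()])
#' @return List of class `energy_matrix` with 20 x 4 matrices
#'   `dot`, `nondot` (mean kcal/mol) and `dot_n`, `nondot_n` (pair
#'   counts).
#' @export
energy_matrix <- function(struct, contacts, dot_residues, params,
                          shell = 10, strict = TRUE) {
  heavy <- struct$atoms[!struct$atoms$hydrogen, ]
  zero <- matrix(0, length(AA3), 4, dimnames = list(AA3, NUCLEOTIDES))
  sums <- list(dot = zero, nondot = zero)
  ns <- list(dot = zero, nondot = zero)
  for (k in seq_len(nrow(contacts))) {
    aa <- heavy[heavy$key == contacts$protein_key[k], ]
    nt <- heavy[heavy$key == contacts$nt_key[k], ]
    e <- residue_pair_energy(aa, nt, params, shell, strict)
    stratum <- if (contacts$protein_key[k] %in% dot_residues) "dot" else "nondot"
    i <- contacts$resid[k]; j <- contacts$nt[k]
    sums[[stratum]][i, j] <- sums[[stratum]][i, j] + e
    ns[[stratum]][i, j] <- ns[[stratum]][i, j] + 1
  }
  mean_or_zero <- function(s, n) ifelse(n > 0, s / pmax(n, 1), 0)
  structure(list(
    dot = mean_or_zero(sums$dot, ns$dot),
    nondot = mean_or_zero(sums$nondot, ns$nondot),
    dot_n = ns$dot, nondot_n = ns$nondot
  ), class = "energy_matrix")
}
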