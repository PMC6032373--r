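## Solvent-accessible surface area by the Shrake-Rupley numerical method.
##
## Each heavy atom is covered with a deterministic golden-spiral point
## set on its solvent-expanded sphere (radius + probe); a point is
## accessible when it lies outside every neighbouring expanded sphere.
## Atom SASA = accessible fraction x sphere area, summed into residues.

## n roughly uniform unit vectors (Fibonacci / golden-angle spiral);
## fully deterministic, no RNG involved.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA over heavy atoms with NACCESS-compatible element
#' radii and a 1.4 A water probe.  Deterministic: the spherical point
#' set is a fixed golden-angle spiral.
#'
#' @param struct a `dot_structure` (or an atom data frame with columns
#'   `key`, `resid`, `elesy`, `x`, `y`, `z`)
#' @param probe_radius probe radius in Angstrom (default 1.4)
#' @param n_points sample points per atom (default 960)
#' @param radii named vector of per-element van der Waals radii;
#'   defaults to the package table
#' @return Data frame: `key`, `resid`, `sasa` (A^2 per residue);
#'   attribute `atom_sasa` holds the per-atom values.
#' @examples
#' atoms <- data.frame(key = "A|1|", resid = "ALA", elesy = "C",
#'                     x = 0, y = 0, z = 0)
#' compute_sasa(atoms)$sasa            # ~ 4*pi*(1.7+1.4)^2
#' @export
compute_sasa <- function(struct, probe_radius = 1.4, n_points = 960L,
                         radii = NULL) {
  atoms <- if (inherits(struct, "dot_structure")) struct$atoms else struct
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no heavy atoms to compute SASA for")
  if (is.null(radii)) radii <- .DEFAULT_VDW
  r <- radii[atoms$elesy]
  if (anyNA(r)) {
    bad <- unique(atoms$elesy[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  r <- unname(r) + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)

  ## neighbour lists from squared distances (expanded spheres)
  d2 <- as.matrix(stats::dist(xyz))^2
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    p <- sweep(pts * r[i], 2L, xyz[i, ], "+")
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      buried <- logical(n_points)
      for (j in nb) {
        dj <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
          (p[, 3L] - xyz[j, 3L])^2
        buried <- buried | dj < r[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    }
    atom_sasa[i] <- 4 * pi * r[i]^2 * acc / n_points
  }

  keys <- unique(atoms$key)
  res_sasa <- vapply(keys, function(k) sum(atom_sasa[atoms$key == k]), 0)
  out <- data.frame(
    key = keys,
    resid = atoms$resid[match(keys, atoms$key)],
    sasa = unname(res_sasa),
    stringsAsFactors = FALSE
  )
  attr(out, "atom_sasa") <- atom_sasa
  out
}

#' Relative accessible surface area (percent of residue-type reference)
#'
#' `100 * absolute / reference`, with the reference the residue type's
#' maximal accessibility in an extended Ala-X-Ala tripeptide (package
#' default: the theoretical maxima of Tien et al. 2013).  Values can
#' exceed 100 for unusually extended conformations.
#'
#' @param sasa data frame from [compute_sasa()]
#' @param reference named vector residue -> max SASA (A^2)
#' @return `sasa` with an added `rasa` column (percent).
#' @export
relative_sasa <- function(sasa, reference = NULL) {
  if (is.null(reference)) reference <- .MAX_SASA
  ref <- reference[sasa$resid]
  if (anyNA(ref)) {
    stop("no reference SASA for residue type(s): ",
         paste(unique(sasa$resid[is.na(ref)]), collapse = ", "))
  }
  sasa$rasa <- 100 * sasa$sasa / unname(ref)
  sasa
}

#' Mean relative accessibility of DOT residues vs the whole protein
#'
#' Per amino-acid type: mean RASA over DOT residues, mean RASA over all
#' protein residues, and their ratio (fold difference, 3 decimals).
#' Types absent from the DOT set get `NA` in the DOT columns.
#'
#' @param sasa data frame from [relative_sasa()] (protein residues)
#' @param dot_residues character vector of DOT residue keys
#' @return Data frame over [AA3]: `rasa_dot`, `rasa_protein`, `fold`.
#' @export
rasa_comparison_table <- function(sasa, dot_residues) {
  stopifnot("rasa" %in% names(sasa))
  sasa <- sasa[is_amino3(sasa$resid), ]
  out <- data.frame(resid = AA3, rasa_dot = NA_real_,
                    rasa_protein = NA_real_, fold = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(AA3)) {
    sel <- sasa$resid == AA3[i]
    if (!any(sel)) next
    out$rasa_protein[i] <- mean(sasa$rasa[sel])
    dsel <- sel & sasa$key %in% dot_residues
    if (any(dsel)) {
      out$rasa_dot[i] <- mean(sasa$rasa[dsel])
      out$fold[i] <- round_half_up(out$rasa_dot[i] / out$rasa_protein[i], 3)
    }
  }
  out
}
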