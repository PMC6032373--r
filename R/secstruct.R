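## Secondary structure: dot-bracket RNA annotation, DSSP-style protein
## letters, and a backbone-dihedral fallback assigner for structures
## built with ideal geometry.

.PSEUDOKNOT_OPEN <- c("{", "[", "<")
.PSEUDOKNOT_CLOSE <- c("}", "]", ">")

#' Parse a dot-bracket RNA secondary-structure string
#'
#' `"."` marks an unpaired nucleotide, `"("`/`")"` a nested base pair, and
#' `"{}"`, `"[]"`, `"<>"` pseudoknotted pairs.  Bracket balance is checked
#' per family.
#'
#' @param sequence nucleotide string (A/C/G/U)
#' @param annotation dot-bracket string of the same length
#' @return Object of class `rna_ss`: list with `sequence`, `annotation`
#'   and `classes` (per-position factor with levels unpaired, basepaired,
#'   pseudoknot).
#' @examples
#' parse_dotbracket("ACGGCU", "((..))")$classes
#' @export
parse_dotbracket <- function(sequence, annotation) {
  stopifnot(is.character(sequence), is.character(annotation))
  if (nchar(sequence) != nchar(annotation)) {
    stop(sprintf("sequence (%d nt) and annotation (%d chars) differ in length",
                 nchar(sequence), nchar(annotation)))
  }
  ann <- strsplit(annotation, "")[[1L]]
  allowed <- c(".", "(", ")", .PSEUDOKNOT_OPEN, .PSEUDOKNOT_CLOSE)
  if (!all(ann %in% allowed)) {
    stop("annotation contains characters outside .(){}[]<>: ",
         paste(unique(setdiff(ann, allowed)), collapse = " "))
  }
  for (fam in list(c("(", ")"), c("{", "}"), c("[", "]"), c("<", ">"))) {
    depth <- cumsum((ann == fam[1L]) - (ann == fam[2L]))
    if (any(depth < 0L) || depth[length(depth)] != 0L) {
      stop(sprintf("unbalanced '%s%s' brackets in annotation", fam[1L], fam[2L]))
    }
  }
  classes <- rep("unpaired", length(ann))
  classes[ann %in% c("(", ")")] <- "basepaired"
  classes[ann %in% c(.PSEUDOKNOT_OPEN, .PSEUDOKNOT_CLOSE)] <- "pseudoknot"
  structure(list(
    sequence = sequence,
    annotation = annotation,
    classes = factor(classes, levels = c("unpaired", "basepaired", "pseudoknot"))
  ), class = "rna_ss")
}

#' Map DSSP letters to the 3-state protein secondary-structure classes
#'
#' H/G/I (all helix types) map to `helix`, E/B to `sheet`, and everything
#' else (turn, bend, coil, blank, PPII) to `other`.
#'
#' @param letters character vector of single DSSP letters ("" or " " for
#'   unassigned)
#' @param keys optional residue keys naming each position
#' @return Factor with levels helix, sheet, other (named when `keys`
#'   given).
#' @export
protein_ss <- function(letters, keys = NULL) {
  letters <- toupper(trimws(letters))
  cls <- rep("other", length(letters))
  cls[letters %in% c("H", "G", "I")] <- "helix"
  cls[letters %in% c("E", "B")] <- "sheet"
  out <- factor(cls, levels = c("helix", "sheet", "other"))
  if (!is.null(keys)) names(out) <- keys
  out
}

#' Read per-residue secondary structure from classic DSSP output
#'
#' Parses the per-residue table of a DSSP output file (the block after
#' the `#  RESIDUE AA STRUCTURE ...` header) and returns 3-state classes
#' keyed by chain and author residue number.
#'
#' @param path DSSP output file
#' @return Named factor as from [protein_ss()]; names are residue keys.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s+#\\s+RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP output file: residue table header not found")
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17L]
  body <- body[substr(body, 14L, 14L) != "!"]  # chain breaks
  resno <- suppressWarnings(as.integer(trimws(substr(body, 6L, 10L))))
  keep <- !is.na(resno)
  body <- body[keep]
  resno <- resno[keep]
  icode <- trimws(substr(body, 11L, 11L))
  chain <- substr(body, 12L, 12L)
  ss <- substr(body, 17L, 17L)
  protein_ss(ss, keys = residue_key(chain, resno, icode))
}

## Dihedral of four points (degrees, IUPAC sign convention)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' Fallback assigner for structures without DSSP output: residues whose
#' phi/psi fall in the helical basin (phi in [-100, -30], psi in
#' [-80, -5]) or the extended basin (phi in [-180, -80], psi in
#' [90, 180] or below -150) over at least `min_run` consecutive residues
#' are labelled helix or sheet; everything else is other.  Intended for
#' ideal-geometry synthetic structures, not as a replacement for the
#' hydrogen-bond based DSSP algorithm on experimental data.
#'
#' @param struct a `dot_structure`
#' @param chain protein chain identifier (default: first protein chain)
#' @param min_run minimum consecutive residues in one basin (default 4)
#' @return Named factor (residue keys) with levels helix, sheet, other.
#' @export
assign_secondary_structure <- function(struct, chain = NULL, min_run = 4L) {
  if (is.null(chain)) {
    chain <- names(struct$chain_type)[struct$chain_type == "protein"][1L]
    if (is.na(chain)) stop("structure has no protein chain")
  }
  a <- struct$atoms[struct$atoms$chain == chain & !struct$atoms$hydrogen, ]
  keys <- unique(a$key)
  kk <- split_residue_key(keys)
  keys <- keys[order_residues(kk$resno, kk$icode)]
  n <- length(keys)

  getxyz <- function(key, name) {
    r <- a[a$key == key & a$elety == name, c("x", "y", "z")]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1L, ])
  }

  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- getxyz(keys[i], "N"); CA <- getxyz(keys[i], "CA"); C <- getxyz(keys[i], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1L) {
      Cp <- getxyz(keys[i - 1L], "C")
      if (!is.null(Cp)) phi[i] <- .dihedral(Cp, N, CA, C)
    }
    if (i < n) {
      Nn <- getxyz(keys[i + 1L], "N")
      if (!is.null(Nn)) psi[i] <- .dihedral(N, CA, C, Nn)
    }
  }

  in_helix <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  in_sheet <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -80 & (psi >= 90 | psi <= -150)
  ## termini lack one dihedral: extend a flanking basin over them
  if (n >= 2L) {
    if (is.na(phi[1L]) && !is.na(psi[1L])) {
      in_helix[1L] <- in_helix[2L] && psi[1L] >= -80 & psi[1L] <= -5
      in_sheet[1L] <- in_sheet[2L] && (psi[1L] >= 90 || psi[1L] <= -150)
    }
    if (is.na(psi[n]) && !is.na(phi[n])) {
      in_helix[n] <- in_helix[n - 1L] && phi[n] >= -100 && phi[n] <= -30
      in_sheet[n] <- in_sheet[n - 1L] && phi[n] >= -180 && phi[n] <= -80
    }
  }

  cls <- rep("other", n)
  for (basin in list(list(mask = in_helix, lab = "helix"),
                     list(mask = in_sheet, lab = "sheet"))) {
    r <- rle(basin$mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] && r$lengths[j] >= min_run) {
        cls[starts[j]:ends[j]] <- basin$lab
      }
    }
  }
  out <- factor(cls, levels = c("helix", "sheet", "other"))
  names(out) <- keys
  out
}
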