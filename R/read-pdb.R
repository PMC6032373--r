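## PDB structure input/output.
##
## The reader is deliberately narrow: ATOM/HETATM coordinate records
## (first model only), the REMARK 465 missing-residue block, and MODRES
## parent mapping.  Residues keep author numbering and insertion codes
## throughout -- REMARK 465 keys must compare equal to ATOM keys.

# resnames silently dropped when seen as HETATM (solvent/common ions)
.HET_IGNORE <- c("HOH", "WAT", "DOD", "MG", "K", "NA", "CL", "ZN", "MN",
                 "CA", "SO4", "PO4", "GOL", "EDO")

.substr_trim <- function(x, start, stop) {
  trimws(substr(x, start, stop))
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (first model only), the REMARK 465
#' missing-residue block and MODRES records from PDB-format text.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties: first in file order).  HETATM residues are mapped to their
#' standard parent residue when a MODRES record is present; otherwise
#' non-standard residues are skipped with a warning.  Each chain is
#' classified as protein (>= 80\% standard amino acids), RNA (>= 80\%
#' A/C/G/U) or other; chains mixing the two polymer types are rejected.
#'
#' @param pdb Either a path to a PDB file or a character vector of
#'   PDB-format lines.
#' @return An object of class `dot_structure`: a list with elements
#'   \describe{
#'     \item{atoms}{data frame of atom records: `elety` (atom name),
#'       `resid`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`,
#'       `elesy` (element), `hydrogen` (logical), `key` (residue key)}
#'     \item{missing}{data frame of REMARK 465 residues: `resid`,
#'       `chain`, `resno`, `icode`, `key`}
#'     \item{chain_type}{named character vector, one of `"protein"`,
#'       `"rna"`, `"other"` per chain}
#'   }
#' @examples
#' pair <- generate_pair(fixture_spec(n_protein = 8, seed = 1))
#' s <- read_structure(pair$bound)
#' head(s$atoms)
#' @export
read_structure <- function(pdb) {
  lines <- .as_pdb_lines(pdb)

  missing <- parse_missing_residues(lines)
  modres <- .parse_modres(lines)

  ## first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]

  rec <- substr(lines, 1L, 6L)
  sel <- which(rec == "ATOM  " | rec == "HETATM")
  if (length(sel) == 0L) stop("no atoms: structure contains no ATOM/HETATM records")

  at <- lines[sel]
  x <- suppressWarnings(as.numeric(substr(at, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(at, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(at, 47L, 54L)))
  resno <- suppressWarnings(as.integer(.substr_trim(at, 23L, 26L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno))
  if (length(bad) > 0L) {
    stop(sprintf("malformed ATOM record at line %d: %s",
                 sel[bad[1L]], at[bad[1L]]))
  }
  occ <- suppressWarnings(as.numeric(substr(at, 55L, 60L)))
  occ[is.na(occ)] <- 1.0

  atoms <- data.frame(
    record = substr(at, 1L, 6L),
    elety = .substr_trim(at, 13L, 16L),
    alt = substr(at, 17L, 17L),
    resid = .substr_trim(at, 18L, 20L),
    chain = substr(at, 22L, 22L),
    resno = resno,
    icode = trimws(substr(at, 27L, 27L)),
    x = x, y = y, z = z, occ = occ,
    elesy = toupper(.substr_trim(at, 77L, 78L)),
    stringsAsFactors = FALSE
  )
  noel <- atoms$elesy == ""
  if (any(noel)) atoms$elesy[noel] <- .element_from_name(atoms$elety[noel])

  ## MODRES: remap modified residues to their standard parent
  if (nrow(modres) > 0L) {
    mk <- paste(atoms$chain, atoms$resid)
    hit <- match(mk, paste(modres$chain, modres$resid))
    atoms$resid[!is.na(hit)] <- modres$stdres[hit[!is.na(hit)]]
  }

  ## keep standard polymer residues; warn about other HETATM resnames
  std <- is_amino3(atoms$resid) | is_nucleotide(atoms$resid)
  odd <- unique(atoms$resid[!std & !(atoms$resid %in% .HET_IGNORE)])
  if (length(odd) > 0L) {
    warning("skipping residues with no MODRES parent: ",
            paste(odd, collapse = ", "))
  }
  atoms <- atoms[std, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms: no standard protein/RNA residues found")

  ## alternate locations: keep highest occupancy, ties resolved to the
  ## first conformer in file order
  aid <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety)
  keep <- !logical(nrow(atoms))
  dup_groups <- unique(aid[duplicated(aid)])
  for (g in dup_groups) {
    idx <- which(aid == g)
    best <- idx[which.max(atoms$occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms <- atoms[keep, , drop = FALSE]

  atoms$hydrogen <- atoms$elesy %in% c("H", "D")
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  atoms$record <- NULL
  atoms$alt <- NULL
  rownames(atoms) <- NULL

  chain_type <- .classify_chains(atoms)

  ## REMARK 465 residues must not also carry coordinates
  clash <- intersect(missing$key, unique(atoms$key))
  if (length(clash) > 0L) {
    stop("residues listed in REMARK 465 also have coordinates: ",
         paste(clash, collapse = ", "))
  }

  structure(list(atoms = atoms, missing = missing, chain_type = chain_type),
            class = "dot_structure")
}

#' @export
print.dot_structure <- function(x, ...) {
  nres <- length(unique(x$atoms$key))
  cat(sprintf("<dot_structure> %d atoms, %d observed residues, %d missing\n",
              nrow(x$atoms), nres, nrow(x$missing)))
  tt <- table(x$chain_type)
  cat("  chains:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

.as_pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1L && grepl("\n", pdb)) {
    strsplit(pdb, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(pdb)
  }
}

.element_from_name <- function(name) {
  ## PDB atom names put the element in columns 13-14; names such as
  ## "1HB" or "HG21" are hydrogens, primes mark sugar atoms.
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- gsub("[0-9']", "", name[i])
    out[i] <- if (nzchar(nm)) substr(nm, 1L, 1L) else "C"
  }
  out
}

.classify_chains <- function(atoms) {
  chains <- unique(atoms$chain)
  out <- stats::setNames(character(length(chains)), chains)
  for (ch in chains) {
    a <- atoms[atoms$chain == ch, ]
    res <- a$resid[!duplicated(a$key)]
    fp <- mean(is_amino3(res))
    fr <- mean(is_nucleotide(res))
    if (fp >= 0.8) {
      out[ch] <- "protein"
    } else if (fr >= 0.8) {
      out[ch] <- "rna"
    } else if (fp + fr < 0.2) {
      out[ch] <- "other"
    } else {
      stop(sprintf("chain %s mixes polymer types (%.0f%% protein, %.0f%% RNA)",
                   ch, 100 * fp, 100 * fr))
    }
  }
  out
}

.parse_modres <- function(lines) {
  m <- lines[startsWith(lines, "MODRES")]
  if (length(m) == 0L) {
    return(data.frame(chain = character(), resid = character(),
                      stdres = character()))
  }
  data.frame(
    chain = substr(m, 17L, 17L),
    resid = .substr_trim(m, 13L, 15L),
    stdres = .substr_trim(m, 25L, 27L),
    stringsAsFactors = FALSE
  )
}

#' Parse the REMARK 465 missing-residue block
#'
#' Returns one row per residue listed as present in the construct but
#' unresolved in the structure, in file order.  The standard header lines
#' of the block are skipped; each data line carries an optional model
#' number, a residue name, a chain identifier and a residue number with
#' optional insertion code (e.g. `52A`).
#'
#' @param pdb Path, single string, or character vector of PDB lines.
#' @return Data frame with columns `resid`, `chain`, `resno`, `icode`,
#'   `key`; zero rows when the block is absent.
#' @export
parse_missing_residues <- function(pdb) {
  lines <- .as_pdb_lines(pdb)
  idx <- which(startsWith(lines, "REMARK 465"))
  empty <- data.frame(resid = character(), chain = character(),
                      resno = integer(), icode = character(),
                      key = character(), stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(empty)

  rows <- list()
  for (i in idx) {
    body <- trimws(substr(lines[i], 11L, nchar(lines[i])))
    if (body == "" || body == "MISSING RESIDUES") next
    toks <- strsplit(body, "\\s+")[[1L]]
    ## header / prose lines of the standard block
    if (identical(toks, c("M", "RES", "C", "SSSEQI"))) next
    if (length(toks) < 3L || length(toks) > 4L) next
    if (any(grepl("[=;:().]", toks))) next
    if (length(toks) == 4L) {
      if (!grepl("^[0-9]+$", toks[1L])) next  # prose, not a model number
      toks <- toks[-1L]
    }
    resid <- toks[1L]
    chain <- toks[2L]
    seqtok <- toks[3L]
    if (!grepl("^-?[0-9]+[A-Za-z]?$", seqtok)) {
      stop(sprintf("REMARK 465 line %d: unparsable residue number '%s'",
                   i, seqtok))
    }
    icode <- ifelse(grepl("[A-Za-z]$", seqtok),
                    substr(seqtok, nchar(seqtok), nchar(seqtok)), "")
    resno <- as.integer(sub("[A-Za-z]$", "", seqtok))
    rows[[length(rows) + 1L]] <- data.frame(
      resid = resid, chain = chain, resno = resno, icode = icode,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$key <- residue_key(out$chain, out$resno, out$icode)
  rownames(out) <- NULL
  out
}

#' Write a structure as PDB-format text
#'
#' Inverse of [read_structure()] for structures built by the synthetic
#' generator: emits a standard REMARK 465 block followed by ATOM records
#' at PDB coordinate precision (3 decimals).
#'
#' @param atoms atom data frame (columns as in a `dot_structure`)
#' @param missing missing-residue data frame (may have zero rows)
#' @param file optional path; when `NULL` the lines are returned
#' @return Character vector of PDB lines (invisibly when `file` given).
#' @export
write_pdb <- function(atoms, missing = NULL, file = NULL) {
  lines <- character(0)
  if (!is.null(missing) && nrow(missing) > 0L) {
    lines <- c(lines,
      "REMARK 465",
      "REMARK 465 MISSING RESIDUES",
      "REMARK 465 THE FOLLOWING RESIDUES WERE NOT LOCATED IN THE",
      "REMARK 465 EXPERIMENT. (M=MODEL NUMBER; RES=RESIDUE NAME;",
      "REMARK 465 C=CHAIN IDENTIFIER; SSSEQ=SEQUENCE NUMBER;",
      "REMARK 465 I=INSERTION CODE.)",
      "REMARK 465",
      "REMARK 465   M RES C SSSEQI",
      sprintf("REMARK 465     %-3s %s %5d%s",
              missing$resid, missing$chain, missing$resno,
              ifelse(missing$icode == "", " ", missing$icode)))
  }
  name4 <- ifelse(nchar(atoms$elety) >= 4L, substr(atoms$elety, 1L, 4L),
                  sprintf(" %-3s", atoms$elety))
  lines <- c(lines, sprintf(
    "ATOM  %5d %s %-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), name4, atoms$resid, atoms$chain, atoms$resno,
    ifelse(is.na(atoms$icode) | atoms$icode == "", " ", atoms$icode),
    atoms$x, atoms$y, atoms$z,
    if (is.null(atoms$occ)) rep(1, nrow(atoms)) else atoms$occ,
    0, atoms$elesy), "END")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
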