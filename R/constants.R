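#' @keywords internal
"_PACKAGE"

## Standard residue vocabularies --------------------------------------------

#' Three-letter codes of the 20 standard amino acids
#'
#' Ordered alphabetically by three-letter code, the row order used by all
#' per-residue-type tables in the package.
#'
#' @format Character vector of length 20.
#' @export
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' One-letter codes matching [AA3]
#' @format Named character vector (names are three-letter codes).
#' @export
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' The four RNA nucleotides
#' @format Character vector of length 4.
#' @export
NUCLEOTIDES <- c("A", "C", "G", "U")

## van der Waals radii (Angstrom) used for surface-area calculation.
## NACCESS-compatible element radii; probe water is 1.4 A.
.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                  I = 1.98)

## Per-residue maximal accessible surface (A^2), Ala-X-Ala extended
## tripeptide convention (theoretical maxima of Tien et al. 2013).
.MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
               GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
               LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
               SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

## Internal helpers ----------------------------------------------------------

#' Round half away from zero
#'
#' Table percentages are conventionally rounded half-up (1.25 -> 1.3 at one
#' decimal), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Canonical residue identifier: "chain|resno|icode".  icode is "" when
## absent.  Keys are plain character so they can live in data frame columns
## and be set-compared directly.
residue_key <- function(chain, resno, icode = "") {
  if (length(resno) == 0L) return(character(0))
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, as.integer(resno), icode, sep = "|")
}

split_residue_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    icode = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

is_amino3 <- function(resid) resid %in% AA3
is_nucleotide <- function(resid) resid %in% NUCLEOTIDES

## Order residues within one chain: author numbering, insertion codes sort
## after the un-coded residue ("" < "A" < "B" ...).
order_residues <- function(resno, icode) {
  order(resno, icode, method = "radix")
}
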