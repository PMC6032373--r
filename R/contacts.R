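## Protein-RNA interface contacts.
##
## A residue-nucleotide pair is in contact when the minimum distance over
## all heavy-atom pairs is <= the cutoff (closed interval).  3.5 and 6 A
## are the two literature cutoffs used throughout.

#' Detect protein-RNA residue contacts
#'
#' Computes, for every amino-acid residue / nucleotide pair, the minimum
#' Euclidean distance over heavy (non-hydrogen) atom pairs, and reports
#' the pairs at or below `cutoff`.
#'
#' @param struct a `dot_structure` containing at least one protein and
#'   one RNA chain
#' @param cutoff contact distance in Angstrom (3.5 or 6.0 conventionally;
#'   any positive value accepted)
#' @param dot_residues optional character vector of DOT residue keys used
#'   to set the `in_dot` flag
#' @return Data frame of class `contact_table`: `protein_key`, `resid`
#'   (3-letter), `nt_key`, `nt` (A/C/G/U), `min_distance`, `in_dot`.
#' @examples
#' pair <- generate_pair(fixture_spec(
#'   n_protein = 6, n_rna = 2,
#'   contact_plan = data.frame(resno = 3, nt = 1, distance = 3.0),
#'   seed = 7))
#' find_contacts(read_structure(pair$bound), 3.5)
#' @export
find_contacts <- function(struct, cutoff, dot_residues = character(0)) {
  stopifnot(cutoff > 0)
  ctype <- struct$chain_type
  pchains <- names(ctype)[ctype == "protein"]
  rchains <- names(ctype)[ctype == "rna"]
  if (length(rchains) == 0L) stop("structure has no RNA chain")
  if (length(pchains) == 0L) stop("structure has no protein chain")

  a <- struct$atoms[!struct$atoms$hydrogen, ]
  pa <- a[a$chain %in% pchains & is_amino3(a$resid), ]
  ra <- a[a$chain %in% rchains & is_nucleotide(a$resid), ]

  pm <- as.matrix(pa[, c("x", "y", "z")])
  rm_ <- as.matrix(ra[, c("x", "y", "z")])

  ## squared cross-distances via the Gram expansion, chunked over protein
  ## atoms to bound memory on large complexes
  pres <- factor(pa$key, levels = unique(pa$key))
  rres <- factor(ra$key, levels = unique(ra$key))
  np <- nlevels(pres); nr <- nlevels(rres)
  min2 <- matrix(Inf, np, nr)
  r2 <- rowSums(rm_^2)
  chunk <- 4000L
  for (s in seq(1L, nrow(pm), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pm))
    p2 <- rowSums(pm[s:e, , drop = FALSE]^2)
    d2 <- outer(p2, r2, "+") - 2 * pm[s:e, , drop = FALSE] %*% t(rm_)
    ## aggregate atom-level minima into residue blocks
    pi_ <- as.integer(pres[s:e])
    for (ri in seq_len(nr)) {
      cols <- which(as.integer(rres) == ri)
      block <- d2[, cols, drop = FALSE]
      mins <- tapply(do.call(pmin, as.data.frame(block)), pi_, min)
      ids <- as.integer(names(mins))
      min2[ids, ri] <- pmin(min2[ids, ri], mins)
    }
  }
  min2[min2 < 0] <- 0

  hit <- which(min2 <= cutoff^2, arr.ind = TRUE)
  pk <- levels(pres)[hit[, 1L]]
  rk <- levels(rres)[hit[, 2L]]
  out <- data.frame(
    protein_key = pk,
    resid = pa$resid[match(pk, pa$key)],
    nt_key = rk,
    nt = ra$resid[match(rk, ra$key)],
    min_distance = sqrt(min2[hit]),
    in_dot = pk %in% dot_residues,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_key, out$nt_key, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}
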