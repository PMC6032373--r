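# Shared fixture builders and independent oracles.

# Minimal hand-written PDB text: one helix-less 5-residue protein with a
# REMARK 465 block listing residues 10-11.
tiny_pdb <- function() {
  c("REMARK 465",
    "REMARK 465 MISSING RESIDUES",
    "REMARK 465   M RES C SSSEQI",
    "REMARK 465     GLY A    10",
    "REMARK 465     ALA A    11",
    sprintf("ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, c("MET", "LYS", "VAL"), 1:3, c(0, 3.8, 7.6), 0, 0))
}

# random rigid-body transform (rotation + translation) applied to a
# dot_structure's coordinates
rigid_transform <- function(struct, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")]) %*% t(R)
  struct$atoms$x <- xyz[, 1] + tr[1]
  struct$atoms$y <- xyz[, 2] + tr[2]
  struct$atoms$z <- xyz[, 3] + tr[3]
  struct
}

# Independent contact oracle: exhaustive double loop over every
# atom pair of every residue pair (no shared code with find_contacts).
oracle_contacts <- function(struct, cutoff) {
  a <- struct$atoms[!struct$atoms$hydrogen, ]
  prot <- names(struct$chain_type)[struct$chain_type == "protein"]
  rna <- names(struct$chain_type)[struct$chain_type == "rna"]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pres <- split(which(a$chain %in% prot), a$key[a$chain %in% prot])
  rres <- split(which(a$chain %in% rna), a$key[a$chain %in% rna])
  out <- list()
  for (p in names(pres)) {
    for (r in names(rres)) {
      dmin <- Inf
      for (i in pres[[p]]) {
        for (j in rres[[r]]) {
          d <- sqrt((xyz[i, 1] - xyz[j, 1])^2 + (xyz[i, 2] - xyz[j, 2])^2 +
                      (xyz[i, 3] - xyz[j, 3])^2)
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          protein_key = p, nt_key = r, min_distance = dmin,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_key = character(), nt_key = character(),
                      min_distance = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$protein_key, res$nt_key, method = "radix"), , drop = FALSE]
}

# Independent region oracle: brute-force scan over sorted residue
# numbers (single chain, no insertion codes).
oracle_regions <- function(dot_resno, min_length = 3) {
  dot_resno <- sort(dot_resno)
  if (length(dot_resno) == 0L) return(integer(0))
  grp <- cumsum(c(1, diff(dot_resno) != 1))
  lens <- vapply(split(dot_resno, grp), length, 0L)
  unname(lens[lens >= min_length])
}
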