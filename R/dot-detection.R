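## Disorder-to-order transition (DOT) detection.
##
## A DOT residue is missing (REMARK 465) in the free protein but carries
## coordinates in the RNA-bound complex; a DOT region is a maximal run of
## >= 3 such residues that are consecutive in author numbering.

## Full residue inventory of one chain: observed residues plus REMARK 465
## entries, ordered by author numbering (insertion codes after the bare
## number).  Returns data frame with key, resid, resno, icode.
.chain_inventory <- function(struct, chain) {
  a <- struct$atoms[struct$atoms$chain == chain, ]
  obs <- a[!duplicated(a$key), c("key", "resid", "resno", "icode")]
  mis <- struct$missing[struct$missing$chain == chain,
                        c("key", "resid", "resno", "icode")]
  inv <- rbind(obs, mis)
  inv <- inv[order_residues(inv$resno, inv$icode), ]
  rownames(inv) <- NULL
  inv
}

.protein_chains <- function(struct) {
  names(struct$chain_type)[struct$chain_type == "protein"]
}

#' Build the free/bound residue correspondence
#'
#' Residues are matched by identical (residue number, insertion code)
#' within each chain pair when the two numbering schemes agree; otherwise
#' by global pairwise alignment of the full sequences (observed plus
#' missing residues in numbering order), which must reach at least 99\%
#' identity over aligned positions -- the criterion for calling two
#' crystal forms "the same protein".
#'
#' @param free,bound `dot_structure` objects
#' @param chain_pairs optional data frame (`free_chain`, `bound_chain`)
#'   pairing protein chains explicitly; by default single protein chains
#'   are paired with each other, and multiple chains by shared identifier
#' @param min_identity required percent identity (default 99)
#' @return Data frame with columns `free_key`, `bound_key`, `resid`.
#' @export
build_mapping <- function(free, bound, chain_pairs = NULL, min_identity = 99) {
  fch <- .protein_chains(free)
  bch <- .protein_chains(bound)
  if (length(fch) == 0L || length(bch) == 0L) {
    stop("both structures need at least one protein chain")
  }
  if (is.null(chain_pairs)) {
    if (length(fch) == 1L && length(bch) == 1L) {
      chain_pairs <- data.frame(free_chain = fch, bound_chain = bch)
    } else if (all(fch %in% bch)) {
      chain_pairs <- data.frame(free_chain = fch, bound_chain = fch)
    } else {
      stop("ambiguous chain pairing; supply a chain_pairs table ",
           "(free_chain, bound_chain)")
    }
  }

  maps <- lapply(seq_len(nrow(chain_pairs)), function(i) {
    .map_chain(free, bound, chain_pairs$free_chain[i],
               chain_pairs$bound_chain[i], min_identity)
  })
  out <- do.call(rbind, maps)
  rownames(out) <- NULL
  out
}

.map_chain <- function(free, bound, fc, bc, min_identity) {
  finv <- .chain_inventory(free, fc)
  binv <- .chain_inventory(bound, bc)

  ## fast path: numbering schemes agree
  fnum <- paste(finv$resno, finv$icode)
  bnum <- paste(binv$resno, binv$icode)
  common <- intersect(fnum, bnum)
  if (length(common) >= 0.9 * max(nrow(finv), nrow(binv))) {
    fi <- match(common, fnum); bi <- match(common, bnum)
    same <- finv$resid[fi] == binv$resid[bi]
    if (mean(same) * 100 >= min_identity) {
      return(data.frame(free_key = finv$key[fi][same],
                        bound_key = binv$key[bi][same],
                        resid = finv$resid[fi][same],
                        stringsAsFactors = FALSE))
    }
  }

  ## general path: global alignment of the full sequences
  fseq <- paste(AA1[finv$resid], collapse = "")
  bseq <- paste(AA1[binv$resid], collapse = "")
  al <- Biostrings::pairwiseAlignment(fseq, bseq, type = "global",
                                      gapOpening = 10, gapExtension = 0.5)
  ap <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  both <- ap != "-" & as_ != "-"
  if (sum(both) == 0L || 100 * sum(ap[both] == as_[both]) / sum(both) < min_identity) {
    stop(sprintf("chains %s/%s are not the same protein (identity < %g%%)",
                 fc, bc, min_identity))
  }
  fi <- cumsum(ap != "-"); bi <- cumsum(as_ != "-")
  sel <- both & ap == as_
  data.frame(free_key = finv$key[fi[sel]],
             bound_key = binv$key[bi[sel]],
             resid = finv$resid[fi[sel]],
             stringsAsFactors = FALSE)
}

#' Pair a free protein with its RNA-bound complex
#'
#' Convenience constructor bundling the two structures with their residue
#' correspondence ([build_mapping()]).
#'
#' @inheritParams build_mapping
#' @return Object of class `structure_pair`: list with `free`, `bound`,
#'   `mapping`.
#' @export
structure_pair <- function(free, bound, chain_pairs = NULL, min_identity = 99) {
  mapping <- build_mapping(free, bound, chain_pairs, min_identity)
  structure(list(free = free, bound = bound, mapping = mapping),
            class = "structure_pair")
}

#' Find disorder-to-order transition residues
#'
#' A residue is DOT when its counterpart is listed as missing in the free
#' structure while it carries coordinates (is ordered) in the bound
#' complex.  Residues missing in both forms are not DOT.
#'
#' @param pair a `structure_pair`
#' @return Character vector of bound-structure residue keys, in chain /
#'   numbering order (possibly empty).
#' @export
find_dot_residues <- function(pair) {
  stopifnot(inherits(pair, "structure_pair"))
  free_missing <- pair$free$missing$key
  if (length(free_missing) == 0L) return(character(0))
  m <- pair$mapping
  cand <- m$bound_key[m$free_key %in% free_missing]
  ordered_keys <- unique(pair$bound$atoms$key)
  dot <- intersect(cand, ordered_keys)
  kk <- split_residue_key(dot)
  dot[order(kk$chain, kk$resno, kk$icode, method = "radix")]
}

#' Segment DOT residues into maximal regions
#'
#' Residues are consecutive when they are adjacent in the chain's full
#' residue inventory (observed plus missing) and their author numbers
#' differ by at most one -- an insertion-coded residue (52, 52A) is
#' consecutive, while a bare numbering jump (30 -> 41) breaks the run.
#' Runs shorter than `min_length` are discarded.
#'
#' @param dot_residues character vector of residue keys (bound frame)
#' @param struct the bound `dot_structure` (supplies residue ordering)
#' @param min_length minimum region length (default 3)
#' @return Data frame with one row per region: `chain`, `start`, `end`
#'   (author numbers with insertion codes), `length`, and list-column
#'   `residues` of keys.
#' @export
segment_regions <- function(dot_residues, struct, min_length = 3L) {
  empty <- data.frame(chain = character(), start = character(),
                      end = character(), length = integer(),
                      stringsAsFactors = FALSE)
  empty$residues <- list()
  if (length(dot_residues) == 0L) return(empty)

  kk <- split_residue_key(dot_residues)
  out <- list()
  for (ch in unique(kk$chain)) {
    inv <- .chain_inventory(struct, ch)
    is_dot <- inv$key %in% dot_residues
    adjacent <- c(FALSE, diff(inv$resno) <= 1L)  # to previous inventory row
    run_id <- cumsum(!(is_dot & adjacent & c(FALSE, is_dot[-nrow(inv)])))
    for (g in split(which(is_dot), run_id[is_dot])) {
      if (length(g) < min_length) next
      lab <- function(i) paste0(inv$resno[i], inv$icode[i])
      reg <- data.frame(chain = ch, start = lab(g[1L]),
                        end = lab(g[length(g)]),
                        length = length(g), stringsAsFactors = FALSE)
      reg$residues <- list(inv$key[g])
      out[[length(out) + 1L]] <- reg
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise DOT regions across complexes
#'
#' @param regions_by_complex list (one element per complex) of region
#'   tables from [segment_regions()]
#' @param breaks upper edges of the region-length bins (default
#'   `c(10, 20, 50, Inf)`, i.e. 3-10 / 11-20 / 21-50 / >50)
#' @return List with `n_regions` (named count distribution of regions
#'   per complex), `length_bins` (named counts), `frac_lt3` (fraction of
#'   complexes with fewer than three regions, percent).
#' @export
region_summary <- function(regions_by_complex, breaks = c(10, 20, 50, Inf)) {
  nreg <- vapply(regions_by_complex, nrow, 0L)
  lens <- unlist(lapply(regions_by_complex, function(r) r$length))

  lo <- c(3, head(breaks, -1) + 1)
  labels <- ifelse(is.finite(breaks), paste0(lo, "-", breaks),
                   paste0(">", lo - 1))
  bins <- stats::setNames(integer(length(breaks)), labels)
  if (length(lens) > 0L) {
    idx <- vapply(lens, function(L) which(L <= breaks)[1L], 0L)
    tt <- table(factor(labels[idx], levels = labels))
    bins[names(tt)] <- as.integer(tt)
  }
  list(
    n_regions = table(nreg),
    length_bins = bins,
    frac_lt3 = 100 * mean(nreg < 3)
  )
}
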