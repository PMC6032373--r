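## Interface statistics: per-residue-type count tables, binding
## frequencies and propensities, bootstrap errors, depletion test and
## secondary-structure cross-tabulations.

#' Tally the per-type counts behind the frequency/propensity statistics
#'
#' For each amino-acid type i the table records: `N_ip` residues of type
#' i observed in the protein, `N_id` of those in DOT regions, `N_ib`
#' binding RNA anywhere in the protein, `N_ibd` binding within a DOT
#' region; plus the grand total `N_p`.  For each nucleotide: `N_prot`
#' distinct nucleotides contacting any protein residue and `N_idt`
#' distinct nucleotides contacting a DOT residue (a nucleotide touching
#' both a DOT and a non-DOT residue is counted once in each column).
#'
#' @param struct bound `dot_structure`
#' @param dot_residues character vector of DOT residue keys
#' @param contacts `contact_table` from [find_contacts()]
#' @return Object of class `count_table`: list with data frames `aa`
#'   (rows [AA3]) and `nt` (rows [NUCLEOTIDES]), scalar `N_p`.
#' @export
count_table <- function(struct, dot_residues, contacts) {
  ctype <- struct$chain_type
  pchains <- names(ctype)[ctype == "protein"]
  a <- struct$atoms[struct$atoms$chain %in% pchains, ]
  res <- a[!duplicated(a$key), c("key", "resid")]
  res <- res[is_amino3(res$resid), ]

  binders <- unique(contacts$protein_key)
  dot_binders <- unique(contacts$protein_key[contacts$protein_key %in% dot_residues])

  tally <- function(keys) {
    tt <- table(factor(res$resid[res$key %in% keys], levels = AA3))
    as.integer(tt)
  }
  aa <- data.frame(
    resid = AA3,
    N_ip = tally(res$key),
    N_id = tally(intersect(res$key, dot_residues)),
    N_ib = tally(binders),
    N_ibd = tally(dot_binders),
    stringsAsFactors = FALSE
  )

  nt_any <- contacts[!duplicated(contacts$nt_key), c("nt_key", "nt")]
  dotc <- contacts[contacts$protein_key %in% dot_residues, ]
  nt_dot <- dotc[!duplicated(dotc$nt_key), c("nt_key", "nt")]
  nt <- data.frame(
    nt = NUCLEOTIDES,
    N_prot = as.integer(table(factor(nt_any$nt, levels = NUCLEOTIDES))),
    N_idt = as.integer(table(factor(nt_dot$nt, levels = NUCLEOTIDES))),
    stringsAsFactors = FALSE
  )

  structure(list(aa = aa, nt = nt, N_p = nrow(res)), class = "count_table")
}

#' Pool count tables over complexes
#' @param tables list of `count_table` objects
#' @return A single pooled `count_table` (element-wise sums).
#' @export
pool_counts <- function(tables) {
  stopifnot(length(tables) >= 1L)
  out <- tables[[1L]]
  for (t in tables[-1L]) {
    for (cn in c("N_ip", "N_id", "N_ib", "N_ibd")) {
      out$aa[[cn]] <- out$aa[[cn]] + t$aa[[cn]]
    }
    for (cn in c("N_prot", "N_idt")) {
      out$nt[[cn]] <- out$nt[[cn]] + t$nt[[cn]]
    }
    out$N_p <- out$N_p + t$N_p
  }
  out
}

#' Frequency of binding residues within DOT regions
#'
#' Per amino-acid type, the fraction of its DOT residues that contact
#' RNA: `N_ibd / N_id`.  Types absent from DOT regions are `NA`
#' (undefined), not zero.
#'
#' @param counts a `count_table` (typically pooled)
#' @return Named numeric vector over [AA3].
#' @export
freq_binding_in_dot <- function(counts) {
  with(counts$aa, stats::setNames(ifelse(N_id > 0, N_ibd / N_id, NA_real_), resid))
}

#' Share of a type's RNA-binding residues that lie in DOT regions
#'
#' Per amino-acid type, `N_ibd / N_ib`: of all residues of type i that
#' contact RNA, the fraction doing so from a DOT region.  Types that
#' never bind are `NA`.
#'
#' @inheritParams freq_binding_in_dot
#' @return Named numeric vector over [AA3], values in [0, 1].
#' @export
freq_dot_among_binders <- function(counts) {
  with(counts$aa, stats::setNames(ifelse(N_ib > 0, N_ibd / N_ib, NA_real_), resid))
}

#' Binding propensity of residue types in DOT regions
#'
#' `(N_ibd / N_id) / (N_ip / N_p)`: the DOT-binding frequency of type i
#' normalised by the type's background frequency in the protein.  1 means
#' no enrichment; types with `N_id = 0` or `N_ip = 0` are `NA`.
#'
#' @inheritParams freq_binding_in_dot
#' @return Named numeric vector over [AA3].
#' @export
propensity <- function(counts) {
  with(counts$aa, {
    num <- ifelse(N_id > 0, N_ibd / N_id, NA_real_)
    den <- ifelse(N_ip > 0, N_ip / counts$N_p, NA_real_)
    stats::setNames(num / den, resid)
  })
}

#' Relative percentage as printed in the report tables
#'
#' `100 * n_sub / n_total`, rounded half-up to `digits` decimals.
#'
#' @param n_sub,n_total counts
#' @param digits decimals (default 1, matching the published tables)
#' @return Numeric (NA when `n_total` is 0).
#' @examples
#' relative_percentage(22, 145)  # 15.2
#' @export
relative_percentage <- function(n_sub, n_total, digits = 1) {
  ifelse(n_total > 0, round_half_up(100 * n_sub / n_total, digits), NA_real_)
}

#' Exact binomial test for depletion at the interface
#'
#' Probability of observing at most `observed` residues of a type among
#' `n_trials` interface residues when the type's background fraction is
#' `expected_fraction`.  With `observed = 0` this is the closed form
#' `(1 - p)^n`.
#'
#' @param observed observed count
#' @param expected_fraction background fraction in (0, 1)
#' @param n_trials number of interface residues
#' @return Lower-tail p-value.
#' @examples
#' depletion_test(0, 0.027, 96)  # (1 - 0.027)^96
#' @export
depletion_test <- function(observed, expected_fraction, n_trials) {
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    stop("expected_fraction must lie strictly between 0 and 1")
  }
  stats::pbinom(observed, n_trials, expected_fraction)
}

#' Bootstrap a count-table statistic over complexes
#'
#' Resamples whole complexes (not residues) with replacement, keeping the
#' sample size equal to the number of complexes, and recomputes the
#' statistic on each resample.  The point estimate is computed on the
#' full set.  Deterministic for a fixed `seed`.
#'
#' @param tables list of per-complex `count_table` objects (length >= 2)
#' @param statistic function taking a list of `count_table`s and
#'   returning a numeric scalar or vector (e.g.
#'   `function(x) propensity(pool_counts(x))`)
#' @param n_samples bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return List of class `boot_stat`: `estimate`, `se` (bootstrap
#'   standard error per component), `n_samples`.
#' @export
bootstrap_stat <- function(tables, statistic, n_samples = 1000L, seed = 1L) {
  stopifnot(length(tables) >= 2L, n_samples >= 1L)
  estimate <- statistic(tables)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- length(tables)
  reps <- matrix(NA_real_, nrow = n_samples, ncol = length(estimate))
  for (b in seq_len(n_samples)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b, ] <- as.numeric(statistic(tables[idx]))
  }
  se <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  names(se) <- names(estimate)
  structure(list(estimate = estimate, se = se, n_samples = n_samples),
            class = "boot_stat")
}

#' Amino-acid x nucleotide contact frequency matrix
#'
#' Tallies residue-type by nucleotide-type contact pairs; with
#' `normalize = TRUE` (default) entries are divided by the total contact
#' count so the matrix sums to 1.
#'
#' @param contacts `contact_table`
#' @param normalize divide by total count (default TRUE)
#' @return 20 x 4 numeric matrix (rows [AA3], columns [NUCLEOTIDES]).
#' @export
aa_nt_contact_matrix <- function(contacts, normalize = TRUE) {
  m <- table(factor(contacts$resid, levels = AA3),
             factor(contacts$nt, levels = NUCLEOTIDES))
  m <- unclass(m)
  dimnames(m) <- list(AA3, NUCLEOTIDES)
  m <- m * 1.0
  if (normalize && sum(m) > 0) m <- m / sum(m)
  m
}

#' Protein secondary-structure cross-tab of DOT residues
#'
#' For each 3-state class: the number of DOT residues assigned to it
#' (`N_d`), how many of those contact RNA (`N_idt`), and the relative
#' binding percentage `N_idt / N_d * 100`.
#'
#' @param dot_residues character vector of DOT residue keys
#' @param contacts `contact_table`
#' @param ss named factor from [protein_ss()], [read_dssp()] or
#'   [assign_secondary_structure()]; DOT residues missing from it are
#'   classed `other` with a warning
#' @return Data frame with rows helix / sheet / other: `N_idt`, `N_d`,
#'   `relative_binding_pct`.
#' @export
protein_ss_crosstab <- function(dot_residues, contacts, ss) {
  lv <- c("helix", "sheet", "other")
  cls <- as.character(ss[dot_residues])
  if (anyNA(cls)) {
    warning(sum(is.na(cls)), " DOT residues lack a secondary-structure ",
            "assignment; classed as 'other'")
    cls[is.na(cls)] <- "other"
  }
  cls <- factor(cls, levels = lv)
  binding <- dot_residues %in% contacts$protein_key
  N_d <- as.integer(table(cls))
  N_idt <- as.integer(table(cls[binding]))
  data.frame(
    ss = lv,
    N_idt = N_idt,
    N_d = N_d,
    relative_binding_pct = relative_percentage(N_idt, N_d),
    stringsAsFactors = FALSE
  )
}

#' Nucleotide contact table (DOT vs whole protein)
#'
#' Per nucleotide type: distinct nucleotides contacting DOT residues
#' (`N_idt`), distinct nucleotides contacting any residue (`N_prot`), and
#' the relative contact percentage.
#'
#' @param counts pooled `count_table`
#' @return Data frame over [NUCLEOTIDES].
#' @export
nt_contact_table <- function(counts) {
  nt <- counts$nt
  data.frame(
    nt = nt$nt,
    N_idt = nt$N_idt,
    N_prot = nt$N_prot,
    relative_contact_pct = relative_percentage(nt$N_idt, nt$N_prot),
    stringsAsFactors = FALSE
  )
}

#' Attach dot-bracket classes to a chain's nucleotides
#'
#' Aligns an [parse_dotbracket()] annotation with the nucleotides of one
#' RNA chain (observed residues in numbering order) and returns the
#' per-nucleotide pairing class named by residue key.
#'
#' @param struct `dot_structure`
#' @param chain RNA chain identifier
#' @param rnass `rna_ss` object whose length matches the chain
#' @return Named factor (levels unpaired/basepaired/pseudoknot).
#' @export
annotate_rna <- function(struct, chain, rnass) {
  a <- struct$atoms[struct$atoms$chain == chain, ]
  res <- a[!duplicated(a$key), c("key", "resid", "resno", "icode")]
  res <- res[order_residues(res$resno, res$icode), ]
  if (nrow(res) != length(rnass$classes)) {
    stop(sprintf("chain %s has %d nucleotides but annotation has %d positions",
                 chain, nrow(res), length(rnass$classes)))
  }
  seq_chain <- paste(res$resid, collapse = "")
  if (seq_chain != rnass$sequence) {
    stop(sprintf("chain %s sequence does not match the annotated sequence", chain))
  }
  stats::setNames(rnass$classes, res$key)
}

#' RNA secondary-structure cross-tab of contacted nucleotides
#'
#' Per nucleotide type and pairing class (plus `All` rows): distinct
#' nucleotides contacting DOT residues (`N_idt`), distinct nucleotides
#' contacting any residue (`N_prot`), and the relative contact
#' percentage.  Zero-count combinations are retained.
#'
#' @param contacts `contact_table`
#' @param nt_classes named factor from [annotate_rna()] (concatenate
#'   chains with `c()` for multi-chain RNA)
#' @param dot_residues character vector of DOT residue keys
#' @param digits decimals for the percentage (default 2)
#' @return Data frame with columns `nt`, `ss`, `N_idt`, `N_prot`,
#'   `relative_contact_pct`.
#' @export
rna_ss_crosstab <- function(contacts, nt_classes, dot_residues, digits = 2) {
  lv <- c("unpaired", "basepaired", "pseudoknot")
  un_annot <- setdiff(unique(contacts$nt_key), names(nt_classes))
  if (length(un_annot) > 0L) {
    stop("contacted nucleotides lack dot-bracket annotation: ",
         paste(un_annot, collapse = ", "))
  }
  any_nt <- contacts[!duplicated(contacts$nt_key), c("nt_key", "nt")]
  dotc <- contacts[contacts$protein_key %in% dot_residues, ]
  dot_nt <- dotc[!duplicated(dotc$nt_key), c("nt_key", "nt")]

  cell <- function(df, ntype, cls) {
    sum(df$nt == ntype & as.character(nt_classes[df$nt_key]) == cls)
  }
  rows <- list()
  for (ntype in c(NUCLEOTIDES, "All")) {
    for (cls in lv) {
      if (ntype == "All") {
        n_idt <- sum(as.character(nt_classes[dot_nt$nt_key]) == cls)
        n_prot <- sum(as.character(nt_classes[any_nt$nt_key]) == cls)
      } else {
        n_idt <- cell(dot_nt, ntype, cls)
        n_prot <- cell(any_nt, ntype, cls)
      }
      pct <- if (n_prot > 0) relative_percentage(n_idt, n_prot, digits) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        nt = ntype, ss = cls, N_idt = n_idt, N_prot = n_prot,
        relative_contact_pct = pct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
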