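## Synthetic structure fixtures with known ground truth.
##
## Proteins are built with ideal backbone geometry (helical phi=-57,
## psi=-47 or extended phi=-120, psi=120) and a reduced atom set
## (N, CA, C, O, CB); RNA chains carry representative heavy atoms
## (P, C1', N9/N1).  Nucleotides named in a contact plan are translated
## along an outward direction until the minimum heavy-atom distance to
## their target residue matches the requested value; all other
## nucleotides are parked well beyond the 6 A cutoff.

## Internal coordinates (A / degrees)
.GEO <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4
)

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Natural-extension-reference-frame placement of atom d from a-b-c.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ar <- angle * pi / 180
  tr <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- .cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  ## z-component negated so the placed torsion matches the IUPAC sign
  ## convention measured by .dihedral()
  d2 <- c(-bond * cos(ar),
          bond * cos(tr) * sin(ar),
          -bond * sin(tr) * sin(ar))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Ideal-geometry backbone + CB for n residues.  phi/psi in degrees
## (vectors of length n; phi[1]/psi[n] unused for placement of interior
## atoms but psi drives the next N).  Returns list of per-residue named
## coordinate lists.
.build_backbone <- function(n, phi, psi) {
  g <- .GEO
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C <- CA + c(-g$b_ca_c * cos(ang), g$b_ca_c * sin(ang), 0)
  res[[1L]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1L)) {
    Np <- .place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                      g$b_c_n, g$a_ca_c_n, psi[i])
    CAp <- .place_atom(res[[i]]$CA, res[[i]]$C, Np,
                       g$b_n_ca, g$a_c_n_ca, 180)
    Cp <- .place_atom(res[[i]]$C, Np, CAp,
                      g$b_ca_c, g$a_n_ca_c, phi[i + 1L])
    res[[i + 1L]] <- list(N = Np, CA = CAp, C = Cp)
  }
  ## carbonyl O (anti to the next N) and CB (L-configuration)
  for (i in seq_len(n)) {
    ref <- if (i < n) res[[i + 1L]]$N else res[[i]]$N
    res[[i]]$O <- .place_atom(ref, res[[i]]$CA, res[[i]]$C,
                              g$b_c_o, g$a_ca_c_o, 180)
    res[[i]]$CB <- .place_atom(res[[i]]$C, res[[i]]$N, res[[i]]$CA,
                               g$b_ca_cb, g$a_n_ca_cb, -122.6)
  }
  res
}

#' Specify a synthetic free/bound fixture
#'
#' Collects the knobs of [generate_pair()] with the defaults used across
#' the test-suite: a 30-residue helical protein (chain A), a 4-nucleotide
#' RNA (chain R), no missing runs and no planned contacts.
#'
#' @param n_protein protein residues
#' @param n_rna nucleotides (0 for a free-only fixture pair)
#' @param sequence optional 3-letter residue vector (default: sampled
#'   from `composition`)
#' @param rna_sequence optional nucleotide vector
#' @param composition named probability vector over [AA3] (default
#'   uniform)
#' @param ss_plan per-residue "H" (helix) or "E" (extended), recycled
#' @param missing_free,missing_bound data frames (`start`, `length`) of
#'   missing-residue runs written to REMARK 465 (author numbering)
#' @param contact_plan data frame (`resno`, `nt`, `distance`): place
#'   nucleotide `nt` so its minimum heavy-atom distance to protein
#'   residue `resno` equals `distance` (A, > 2 steric floor)
#' @param bound_offset added to bound-structure residue numbers (tests
#'   the alignment-based mapping)
#' @param first_resno first author residue number (default 1)
#' @param seed integer seed (sequence sampling only; geometry is
#'   deterministic)
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_protein = 30L, n_rna = 4L, sequence = NULL,
                         rna_sequence = NULL, composition = NULL,
                         ss_plan = "H",
                         missing_free = NULL, missing_bound = NULL,
                         contact_plan = NULL, bound_offset = 0L,
                         first_resno = 1L, seed = 1L) {
  if (!is.null(contact_plan) && nrow(contact_plan) > 0 &&
      any(contact_plan$distance <= 2.0)) {
    stop("contact distances must exceed the 2 A steric floor")
  }
  chk_runs <- function(runs) {
    if (is.null(runs) || nrow(runs) == 0L) return(invisible())
    lo <- runs$start
    hi <- runs$start + runs$length - 1L
    if (any(lo < first_resno) || any(hi > first_resno + n_protein - 1L)) {
      stop("missing run outside chain bounds")
    }
    if (nrow(runs) > 1L) {
      o <- order(lo)
      if (any(lo[o][-1L] <= hi[o][-nrow(runs)])) stop("missing runs overlap")
    }
  }
  chk_runs(missing_free)
  chk_runs(missing_bound)
  structure(list(
    n_protein = as.integer(n_protein), n_rna = as.integer(n_rna),
    sequence = sequence, rna_sequence = rna_sequence,
    composition = composition, ss_plan = ss_plan,
    missing_free = missing_free, missing_bound = missing_bound,
    contact_plan = contact_plan, bound_offset = as.integer(bound_offset),
    first_resno = as.integer(first_resno), seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Generate a free/bound PDB fixture pair with ground truth
#'
#' Writes PDB-format text for a free protein and its RNA-bound complex
#' built to `spec`, together with the ground-truth record the pipeline
#' must recover: expected DOT residues and regions, and the expected
#' contact sets at 3.5 and 6 A (tallied by an exhaustive atom-pair scan
#' over the generated coordinates).
#'
#' @param spec a [fixture_spec()]
#' @return List with `free`, `bound` (character vectors of PDB lines)
#'   and `truth`: list with `dot_keys`, `regions` (data frame), and
#'   `contacts` (named list `"3.5"`, `"6"` of `protein_key`/`nt_key`
#'   data frames).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_protein
  comp <- spec$composition
  if (is.null(comp)) comp <- stats::setNames(rep(1 / 20, 20), AA3)
  seqres <- spec$sequence
  if (is.null(seqres)) seqres <- sample(AA3, n, replace = TRUE, prob = comp[AA3])
  ss <- rep_len(strsplit(paste(spec$ss_plan, collapse = ""), "")[[1L]], n)
  phi <- ifelse(ss == "H", -57, -120)
  psi <- ifelse(ss == "H", -47, 120)
  bb <- .build_backbone(n, phi, psi)

  resno <- spec$first_resno + seq_len(n) - 1L
  prot_atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    names_i <- c("N", "CA", "C", "O", if (seqres[i] != "GLY") "CB")
    xyz <- do.call(rbind, bb[[i]][names_i])
    data.frame(elety = names_i, resid = seqres[i], chain = "A",
               resno = resno[i], icode = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
               elesy = substr(names_i, 1L, 1L), stringsAsFactors = FALSE)
  }))

  run_keys <- function(runs) {
    if (is.null(runs) || nrow(runs) == 0L) return(integer(0))
    unlist(lapply(seq_len(nrow(runs)), function(i) {
      runs$start[i] + seq_len(runs$length[i]) - 1L
    }))
  }
  miss_free <- run_keys(spec$missing_free)
  miss_bound <- run_keys(spec$missing_bound)

  make_chain <- function(missing_resno, offset) {
    at <- prot_atoms[!(prot_atoms$resno %in% missing_resno), , drop = FALSE]
    at$resno <- at$resno + offset
    mis <- if (length(missing_resno) > 0L) {
      data.frame(resid = seqres[match(missing_resno, resno)],
                 chain = "A", resno = missing_resno + offset, icode = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(resid = character(), chain = character(),
                 resno = integer(), icode = character(),
                 stringsAsFactors = FALSE)
    }
    list(atoms = at, missing = mis)
  }
  free <- make_chain(miss_free, 0L)
  bound <- make_chain(miss_bound, spec$bound_offset)

  ## RNA chain: representative atoms per nucleotide
  rna_atoms <- NULL
  if (spec$n_rna > 0L) {
    rseq <- spec$rna_sequence
    if (is.null(rseq)) rseq <- sample(NUCLEOTIDES, spec$n_rna, replace = TRUE)
    base_atom <- ifelse(rseq %in% c("A", "G"), "N9", "N1")
    bb_xyz <- as.matrix(bound$atoms[, c("x", "y", "z")])
    centroid <- colMeans(bb_xyz)
    span <- max(sqrt(rowSums(sweep(bb_xyz, 2L, centroid)^2)))
    park <- span + 12  # beyond the 6 A cutoff from every protein atom

    nt_xyz <- vector("list", spec$n_rna)
    for (k in seq_len(spec$n_rna)) {
      u <- c(sin(2 * pi * k / spec$n_rna), cos(2 * pi * k / spec$n_rna), 0.7)
      u <- u / sqrt(sum(u^2))
      p0 <- centroid + (park + 6 * k) * u
      nt_xyz[[k]] <- rbind(p0, p0 + 1.5 * u, p0 + 3.0 * u)
    }

    cp <- spec$contact_plan
    if (!is.null(cp) && nrow(cp) > 0L) {
      for (k in seq_len(nrow(cp))) {
        tgt <- cp$resno[k] + spec$bound_offset
        ta <- bound$atoms[bound$atoms$resno == tgt, , drop = FALSE]
        if (nrow(ta) == 0L) stop("contact plan targets a missing residue")
        txyz <- as.matrix(ta[, c("x", "y", "z")])
        d <- cp$distance[k]
        ## the contact atom sits exactly d from one anchor atom of the
        ## target residue; pick the anchor/direction pair whose other
        ## atoms (every atom of the complex) clear distance d, so the
        ## global minimum is realised against the target residue
        dirs <- .sphere_points(200L)
        best <- NULL; best_clear <- -Inf
        for (ai in seq_len(nrow(txyz))) {
          anchor <- txyz[ai, ]
          for (di in seq_len(nrow(dirs))) {
            u <- dirs[di, ]
            pts <- rbind(anchor + d * u,
                         anchor + (d + 1.5) * u,
                         anchor + (d + 3.0) * u)
            dd <- outer(rowSums(bb_xyz^2), rowSums(pts^2), "+") -
              2 * bb_xyz %*% t(pts)
            dd <- sqrt(pmax(dd, 0))
            ## clearance over every atom except the anchor contact itself
            dd[which.min(dd[, 1L]), 1L] <- Inf
            clear <- min(dd)
            if (clear > best_clear) {
              best_clear <- clear
              best <- pts
            }
          }
        }
        if (best_clear <= d + 0.01) {
          stop(sprintf(
            "infeasible contact plan: residue %d is shadowed by a neighbour",
            cp$resno[k]))
        }
        nt_xyz[[cp$nt[k]]] <- best
      }
    }

    rna_atoms <- do.call(rbind, lapply(seq_len(spec$n_rna), function(k) {
      xyz <- nt_xyz[[k]]
      data.frame(elety = c("P", "C1'", base_atom[k]), resid = rseq[k],
                 chain = "R", resno = k, icode = "",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1,
                 elesy = c("P", "C", "N"), stringsAsFactors = FALSE)
    }))
  }

  bound_all <- rbind(bound$atoms, rna_atoms)

  ## ground truth ------------------------------------------------------
  dot_resno <- setdiff(miss_free, miss_bound) + spec$bound_offset
  dot_keys <- residue_key("A", sort(dot_resno))
  regions <- .truth_regions(sort(dot_resno))

  contacts_truth <- list(`3.5` = NULL, `6` = NULL)
  if (!is.null(rna_atoms)) {
    contacts_truth <- .brute_force_contacts(bound$atoms, rna_atoms, c(3.5, 6))
  }

  list(
    free = write_pdb(free$atoms, free$missing),
    bound = write_pdb(bound_all, bound$missing),
    truth = list(dot_keys = dot_keys, regions = regions,
                 contacts = contacts_truth)
  )
}

## maximal runs of consecutive numbers, >= 3 long
.truth_regions <- function(resno) {
  if (length(resno) == 0L) {
    return(data.frame(chain = character(), start = integer(),
                      end = integer(), length = integer()))
  }
  grp <- cumsum(c(1L, diff(resno) != 1L))
  out <- do.call(rbind, lapply(split(resno, grp), function(g) {
    data.frame(chain = "A", start = g[1L], end = g[length(g)],
               length = length(g))
  }))
  out <- out[out$length >= 3L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Exhaustive residue-pair minimum-distance tally; the independent
## oracle frozen into every fixture's ground truth.
.brute_force_contacts <- function(prot_atoms, rna_atoms, cutoffs) {
  pk <- residue_key(prot_atoms$chain, prot_atoms$resno, prot_atoms$icode)
  rk <- residue_key(rna_atoms$chain, rna_atoms$resno, rna_atoms$icode)
  out <- stats::setNames(vector("list", length(cutoffs)),
                         as.character(cutoffs))
  rows <- list()
  for (p in unique(pk)) {
    pm <- as.matrix(prot_atoms[pk == p, c("x", "y", "z")])
    for (r in unique(rk)) {
      rm_ <- as.matrix(rna_atoms[rk == r, c("x", "y", "z")])
      dmin <- Inf
      for (i in seq_len(nrow(pm))) {
        for (j in seq_len(nrow(rm_))) {
          dmin <- min(dmin, sqrt(sum((pm[i, ] - rm_[j, ])^2)))
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_key = p, nt_key = r, min_distance = dmin,
        stringsAsFactors = FALSE)
    }
  }
  all_pairs <- do.call(rbind, rows)
  for (cc in as.character(cutoffs)) {
    sel <- all_pairs[all_pairs$min_distance <= as.numeric(cc), , drop = FALSE]
    sel <- sel[order(sel$protein_key, sel$nt_key, method = "radix"), ]
    rownames(sel) <- NULL
    out[[cc]] <- sel
  }
  out
}

#' Generate a random protein-RNA complex (contact-oracle fixture)
#'
#' Uniform random heavy-atom coordinates in a cubic box: no realistic
#' geometry, used to exercise contact detection against the brute-force
#' oracle over arbitrary configurations.
#'
#' @param n_res protein residues (4 atoms each)
#' @param n_nt nucleotides (3 atoms each)
#' @param box box edge in A (default 30)
#' @param seed integer seed
#' @return A `dot_structure`.
#' @export
random_complex <- function(n_res = 50L, n_nt = 10L, box = 30, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pa <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(elety = c("N", "CA", "C", "O"),
               resid = sample(AA3, 1L), chain = "A", resno = i, icode = "",
               x = stats::runif(4, 0, box), y = stats::runif(4, 0, box),
               z = stats::runif(4, 0, box), occ = 1,
               elesy = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
  }))
  ra <- do.call(rbind, lapply(seq_len(n_nt), function(i) {
    nt <- sample(NUCLEOTIDES, 1L)
    data.frame(elety = c("P", "C1'", ifelse(nt %in% c("A", "G"), "N9", "N1")),
               resid = nt, chain = "R", resno = i, icode = "",
               x = stats::runif(3, 0, box), y = stats::runif(3, 0, box),
               z = stats::runif(3, 0, box), occ = 1,
               elesy = c("P", "C", "N"), stringsAsFactors = FALSE)
  }))
  atoms <- rbind(pa, ra)
  atoms$hydrogen <- FALSE
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  structure(list(
    atoms = atoms,
    missing = data.frame(resid = character(), chain = character(),
                         resno = integer(), icode = character(),
                         key = character(), stringsAsFactors = FALSE),
    chain_type = c(A = "protein", R = "rna")
  ), class = "dot_structure")
}

#' Generate count tables with known binding propensities
#'
#' Draws `n_complexes` per-complex count tables in which a DOT residue
#' of type i binds RNA with probability `target[i] * composition[i]`, so
#' the expected binding propensity equals `target[i]`
#' exactly.  Non-DOT residues bind at the background rate.  Complexes
#' are count-level fixtures (no coordinates); they plug directly into
#' [pool_counts()], [propensity()] and [bootstrap_stat()].
#'
#' @param target named numeric vector of target propensities over [AA3]
#'   (default all 1)
#' @param n_complexes number of complexes
#' @param n_protein residues per complex (default 2400)
#' @param n_dot DOT residues per complex (default 1200)
#' @param composition named probability vector over [AA3] (default
#'   uniform)
#' @param seed integer seed
#' @return List with `tables` (list of `count_table`) and `expected`
#'   (the target propensities, named over [AA3]).
#' @export
generate_count_scenario <- function(target = NULL, n_complexes = 200L,
                                    n_protein = 2400L, n_dot = 1200L,
                                    composition = NULL, seed = 1L) {
  if (is.null(target)) target <- stats::setNames(rep(1, 20), AA3)
  if (is.null(composition)) composition <- stats::setNames(rep(1 / 20, 20), AA3)
  stopifnot(all(target > 0), all(is.finite(target)),
            all(target * composition[names(target)] <= 1),
            n_dot <= n_protein)
  if (n_complexes == 0L) {
    return(list(tables = list(), expected = target))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  base_rate <- sum(target * composition[names(target)] * composition[names(target)])
  tables <- vector("list", n_complexes)
  for (b in seq_len(n_complexes)) {
    types <- sample(AA3, n_protein, replace = TRUE, prob = composition[AA3])
    in_dot <- seq_len(n_protein) <= n_dot
    p_bind <- ifelse(in_dot, target[types] * composition[types], base_rate)
    binds <- stats::runif(n_protein) < p_bind
    tab <- function(sel) as.integer(table(factor(types[sel], levels = AA3)))
    aa <- data.frame(
      resid = AA3,
      N_ip = tab(rep(TRUE, n_protein)),
      N_id = tab(in_dot),
      N_ib = tab(binds),
      N_ibd = tab(in_dot & binds),
      stringsAsFactors = FALSE
    )
    nt <- data.frame(nt = NUCLEOTIDES, N_prot = 0L, N_idt = 0L,
                     stringsAsFactors = FALSE)
    tables[[b]] <- structure(list(aa = aa, nt = nt, N_p = n_protein),
                             class = "count_table")
  }
  list(tables = tables, expected = target)
}

#' Generate a random dot-bracket annotation with set class fractions
#'
#' Produces a balanced annotation in which `round(length *
#' paired_fraction)` positions (decremented to the nearest even number)
#' are nested `()` pairs and likewise `pseudoknot_fraction` of positions
#' are `[]` pseudoknot pairs; the rest are dots.  The sequence is uniform
#' random A/C/G/U.
#'
#' @param length number of nucleotides
#' @param paired_fraction,pseudoknot_fraction class fractions in [0, 1],
#'   summing to at most 1
#' @param seed integer seed
#' @return List with `sequence` and `annotation` strings.
#' @export
generate_dotbracket <- function(length, paired_fraction = 0,
                                pseudoknot_fraction = 0, seed = 1L) {
  stopifnot(paired_fraction >= 0, pseudoknot_fraction >= 0,
            paired_fraction + pseudoknot_fraction <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  even <- function(k) k - (k %% 2L)
  n_bp <- even(round(length * paired_fraction))
  n_pk <- even(round(length * pseudoknot_fraction))
  if (n_bp + n_pk > length) n_pk <- even(length - n_bp)

  ann <- rep(".", length)
  pos <- sample.int(length, n_bp + n_pk)
  bp <- sort(pos[seq_len(n_bp)])
  pk <- sort(pos[seq_len(n_pk) + n_bp])
  if (n_bp > 0L) {
    ann[bp[seq_len(n_bp / 2)]] <- "("
    ann[bp[n_bp / 2 + seq_len(n_bp / 2)]] <- ")"
  }
  if (n_pk > 0L) {
    ann[pk[seq_len(n_pk / 2)]] <- "["
    ann[pk[n_pk / 2 + seq_len(n_pk / 2)]] <- "]"
  }
  list(sequence = paste(sample(NUCLEOTIDES, length, replace = TRUE),
                        collapse = ""),
       annotation = paste(ann, collapse = ""))
}
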