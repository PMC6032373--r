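## End-to-end analysis over a manifest of free/bound structure pairs.
##
## Every tunable of the analysis lives in run_config(); all randomness
## (the bootstrap) flows from its single seed, and no output carries a
## timestamp, so a rerun with the same manifest and seed is byte
## identical.

#' Analysis configuration
#'
#' @param cutoffs contact cutoffs in A (default `c(3.5, 6)`)
#' @param bootstrap_n bootstrap replicates (default 1000)
#' @param seed root seed for all randomness
#' @param dielectric,distance_dependent Coulomb screening (see
#'   [energy_params()])
#' @param shell atom-pair evaluation cutoff for energies (A)
#' @param length_breaks upper edges of the region-length bins
#' @param min_region minimum DOT region length (default 3)
#' @param compute_energy,compute_sasa toggles for the expensive stages
#' @param params_path optional energy parameter file
#' @return List of class `run_config`.
#' @export
run_config <- function(cutoffs = c(3.5, 6), bootstrap_n = 1000L, seed = 1L,
                       dielectric = 1.0, distance_dependent = FALSE,
                       shell = 10, length_breaks = c(10, 20, 50, Inf),
                       min_region = 3L, compute_energy = TRUE,
                       compute_sasa = TRUE, params_path = NULL) {
  stopifnot(all(cutoffs > 0), !is.unsorted(cutoffs), bootstrap_n >= 1L)
  structure(list(cutoffs = cutoffs, bootstrap_n = as.integer(bootstrap_n),
                 seed = as.integer(seed), dielectric = dielectric,
                 distance_dependent = distance_dependent, shell = shell,
                 length_breaks = length_breaks,
                 min_region = as.integer(min_region),
                 compute_energy = compute_energy,
                 compute_sasa = compute_sasa,
                 params_path = params_path),
            class = "run_config")
}

.read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE)
  }
  need <- c("complex_id", "free_pdb", "bound_pdb", "class")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(manifest) == 0L) stop("empty manifest")
  manifest
}

#' Run the full DOT analysis over a manifest
#'
#' For each complex: reads the free/bound pair, maps residues, detects
#' DOT residues and regions, finds contacts at every configured cutoff
#' and tallies count tables.  Results are aggregated per dataset stratum
#' (the manifest `class` column, conventionally NR / RB) and per cutoff:
#' binding frequencies, propensities (with complex-level
#' bootstrap standard errors when the stratum has at least two
#' complexes), contact matrices, protein secondary-structure and
#' nucleotide tables, relative accessibility and interaction-energy
#' matrices.  A complex failing validation is skipped and logged; the
#' run fails only when every complex fails.
#'
#' @param manifest data frame or TSV path with columns `complex_id`,
#'   `free_pdb`, `bound_pdb`, `class`, optional `rna_ss` (two-line file:
#'   sequence, dot-bracket) and `dssp` (DSSP output path)
#' @param config a [run_config()]
#' @param outdir output directory (created); TSV tables plus
#'   `run_log.txt`
#' @return Invisibly, a list with the aggregated results (`regions`,
#'   `summary`, per stratum/cutoff statistics) as written to `outdir`.
#' @export
run_pipeline <- function(manifest, config = run_config(), outdir) {
  manifest <- .read_manifest(manifest)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("dotrna run log",
                 sprintf("seed: %d", config$seed),
                 sprintf("cutoffs: %s", paste(config$cutoffs, collapse = ", ")),
                 sprintf("bootstrap_n: %d", config$bootstrap_n),
                 sprintf("complexes: %d", nrow(manifest)))

  per_complex <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$complex_id[i]
    res <- tryCatch(
      .analyse_complex(manifest[i, ], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines,
                     sprintf("SKIP %s: %s", id, conditionMessage(res)))
      next
    }
    log_lines <- c(log_lines, sprintf("OK %s: %d DOT residues, %d regions",
                                      id, length(res$dot), nrow(res$regions)))
    per_complex[[id]] <- res
  }
  if (length(per_complex) == 0L) stop("all complexes failed; see run log")

  wtsv <- function(x, name) {
    utils::write.table(x, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## region tables ------------------------------------------------------
  regions <- do.call(rbind, lapply(names(per_complex), function(id) {
    r <- per_complex[[id]]$regions
    if (nrow(r) == 0L) return(NULL)
    cbind(complex_id = id, r[, c("chain", "start", "end", "length")])
  }))
  if (is.null(regions)) {
    regions <- data.frame(complex_id = character(), chain = character(),
                          start = character(), end = character(),
                          length = integer())
  }
  wtsv(regions, "dot_regions.tsv")

  summ <- region_summary(lapply(per_complex, `[[`, "regions"),
                         breaks = config$length_breaks)
  wtsv(data.frame(n_regions = names(summ$n_regions),
                  n_complexes = as.integer(summ$n_regions)),
       "region_counts.tsv")
  wtsv(data.frame(length_bin = names(summ$length_bins),
                  n_regions = as.integer(summ$length_bins),
                  frac_complexes_lt3_regions_pct =
                    round_half_up(summ$frac_lt3, 1)),
       "region_lengths.tsv")

  ## per stratum x cutoff statistics ------------------------------------
  strata <- unique(manifest$class[manifest$complex_id %in% names(per_complex)])
  results <- list(regions = regions, summary = summ, strata = list())

  for (st in strata) {
    ids <- manifest$complex_id[manifest$class == st]
    ids <- intersect(ids, names(per_complex))
    cx <- per_complex[ids]
    for (cc in as.character(config$cutoffs)) {
      tag <- sprintf("%s_%s", st, cc)
      tables <- lapply(cx, function(x) x$counts[[cc]])
      pooled <- pool_counts(tables)
      stat_tab <- data.frame(
        resid = AA3,
        freq_binding_in_dot = unname(freq_binding_in_dot(pooled)),
        freq_dot_among_binders = unname(freq_dot_among_binders(pooled)),
        propensity = unname(propensity(pooled)))
      if (length(tables) >= 2L) {
        bs <- bootstrap_stat(tables,
                             function(x) propensity(pool_counts(x)),
                             n_samples = config$bootstrap_n,
                             seed = config$seed)
        stat_tab$propensity_se <- unname(bs$se)
      }
      wtsv(stat_tab, sprintf("frequencies_%s.tsv", tag))
      wtsv(nt_contact_table(pooled), sprintf("nt_contacts_%s.tsv", tag))

      cm <- Reduce(`+`, lapply(cx, function(x)
        aa_nt_contact_matrix(x$contacts[[cc]], normalize = FALSE)))
      if (sum(cm) > 0) cm <- cm / sum(cm)
      wtsv(cbind(resid = rownames(cm), as.data.frame(cm)),
           sprintf("contact_matrix_%s.tsv", tag))

      sstab <- Reduce(function(a, b) {
        a[, c("N_idt", "N_d")] <- a[, c("N_idt", "N_d")] +
          b[, c("N_idt", "N_d")]
        a
      }, lapply(cx, function(x) x$ss_crosstab[[cc]]))
      sstab$relative_binding_pct <- relative_percentage(sstab$N_idt, sstab$N_d)
      wtsv(sstab, sprintf("protein_ss_%s.tsv", tag))

      rn <- lapply(cx, function(x) x$rna_crosstab[[cc]])
      rn <- rn[!vapply(rn, is.null, TRUE)]
      if (length(rn) > 0L) {
        rtab <- Reduce(function(a, b) {
          a[, c("N_idt", "N_prot")] <- a[, c("N_idt", "N_prot")] +
            b[, c("N_idt", "N_prot")]
          a
        }, rn)
        rtab$relative_contact_pct <- ifelse(
          rtab$N_prot > 0, relative_percentage(rtab$N_idt, rtab$N_prot, 2), 0)
        wtsv(rtab, sprintf("rna_ss_%s.tsv", tag))
      }
      results$strata[[tag]] <- list(pooled = pooled, stats = stat_tab)
    }

    if (config$compute_sasa) {
      sasa_all <- do.call(rbind, lapply(cx, function(x) x$rasa))
      rt <- rasa_comparison_table(sasa_all,
                                  unlist(lapply(cx, `[[`, "dot")))
      wtsv(rt, sprintf("rasa_%s.tsv", st))
      results$strata[[st]]$rasa <- rt
    }
    if (config$compute_energy) {
      cc1 <- as.character(config$cutoffs[1L])
      zero <- matrix(0, length(AA3), 4, dimnames = list(AA3, NUCLEOTIDES))
      agg <- list(dot_s = zero, dot_n = zero, nd_s = zero, nd_n = zero)
      for (x in cx) {
        em <- x$energy[[cc1]]
        if (is.null(em)) next
        agg$dot_s <- agg$dot_s + em$dot * em$dot_n
        agg$dot_n <- agg$dot_n + em$dot_n
        agg$nd_s <- agg$nd_s + em$nondot * em$nondot_n
        agg$nd_n <- agg$nd_n + em$nondot_n
      }
      emean <- function(s, n) round_half_up(ifelse(n > 0, s / pmax(n, 1), 0), 2)
      etab <- data.frame(resid = AA3,
                         emean(agg$dot_s, agg$dot_n),
                         emean(agg$nd_s, agg$nd_n))
      names(etab) <- c("resid", paste0("dot_", NUCLEOTIDES),
                       paste0("nondot_", NUCLEOTIDES))
      wtsv(etab, sprintf("energy_%s.tsv", st))
      results$strata[[st]]$energy <- etab
    }
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(results)
}

.analyse_complex <- function(row, config) {
  free <- read_structure(row$free_pdb)
  bound <- read_structure(row$bound_pdb)
  pair <- structure_pair(free, bound)
  dot <- find_dot_residues(pair)
  regions <- segment_regions(dot, bound, min_length = config$min_region)
  dot_in_regions <- unlist(regions$residues)
  if (is.null(dot_in_regions)) dot_in_regions <- character(0)

  ## protein secondary structure: DSSP output if supplied, else the
  ## dihedral fallback over every protein chain
  ss <- if (!is.null(row$dssp) && !is.na(row$dssp) && nzchar(row$dssp)) {
    read_dssp(row$dssp)
  } else {
    pch <- names(bound$chain_type)[bound$chain_type == "protein"]
    do.call(c, lapply(pch, function(ch) assign_secondary_structure(bound, ch)))
  }

  nt_classes <- NULL
  if (!is.null(row$rna_ss) && !is.na(row$rna_ss) && nzchar(row$rna_ss)) {
    lines <- readLines(row$rna_ss, warn = FALSE)
    rss <- parse_dotbracket(lines[1L], lines[2L])
    rch <- names(bound$chain_type)[bound$chain_type == "rna"][1L]
    nt_classes <- annotate_rna(bound, rch, rss)
  }

  eparams <- energy_params(path = config$params_path,
                           dielectric = config$dielectric,
                           distance_dependent = config$distance_dependent)

  contacts <- list(); counts <- list(); ssx <- list(); rnx <- list()
  energy <- list()
  for (cc in as.character(config$cutoffs)) {
    ct <- find_contacts(bound, as.numeric(cc), dot_residues = dot_in_regions)
    contacts[[cc]] <- ct
    counts[[cc]] <- count_table(bound, dot_in_regions, ct)
    ssx[[cc]] <- protein_ss_crosstab(dot_in_regions, ct, ss)
    rnx[[cc]] <- if (!is.null(nt_classes)) {
      rna_ss_crosstab(ct, nt_classes, dot_in_regions)
    }
    if (config$compute_energy && cc == as.character(config$cutoffs[1L])) {
      energy[[cc]] <- energy_matrix(bound, ct, dot_in_regions, eparams,
                                    shell = config$shell, strict = FALSE)
    }
  }

  rasa <- NULL
  if (config$compute_sasa) {
    pch <- names(bound$chain_type)[bound$chain_type == "protein"]
    pat <- bound$atoms[bound$atoms$chain %in% pch, ]
    rasa <- relative_sasa(compute_sasa(pat))
  }

  list(dot = dot_in_regions, regions = regions, contacts = contacts,
       counts = counts, ss_crosstab = ssx, rna_crosstab = rnx,
       energy = energy, rasa = rasa)
}
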