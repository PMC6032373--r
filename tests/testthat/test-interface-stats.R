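fake_counts <- function(N_ip, N_id, N_ib, N_ibd, N_p = sum(N_ip)) {
  aa <- data.frame(resid = AA3, N_ip = N_ip, N_id = N_id, N_ib = N_ib,
                   N_ibd = N_ibd, stringsAsFactors = FALSE)
  nt <- data.frame(nt = NUCLEOTIDES, N_prot = 0L, N_idt = 0L)
  structure(list(aa = aa, nt = nt, N_p = N_p), class = "count_table")
}

test_that("binding frequency in DOT regions follows N_ibd / N_id", {
  cnt <- fake_counts(N_ip = rep(50, 20), N_id = c(7, 12, 0, rep(10, 17)),
                     N_ib = rep(20, 20), N_ibd = c(0, 3, 0, rep(5, 17)))
  f <- freq_binding_in_dot(cnt)
  expect_equal(unname(f["ALA"]), 0)
  expect_equal(unname(f["ARG"]), 0.25)
  expect_true(is.na(f["ASN"]))  # undefined, not zero
})

test_that("share of binders in DOT follows N_ibd / N_ib and stays in [0,1]", {
  cnt <- fake_counts(N_ip = rep(50, 20), N_id = rep(10, 20),
                     N_ib = c(10, 10, 0, rep(10, 17)),
                     N_ibd = c(10, 2, 0, rep(4, 17)))
  f <- freq_dot_among_binders(cnt)
  expect_equal(unname(f["ALA"]), 1)
  expect_equal(unname(f["ARG"]), 0.2)
  expect_true(is.na(f["ASN"]))
  expect_true(all(f[!is.na(f)] >= 0 & f[!is.na(f)] <= 1))
})

test_that("propensity normalises DOT-binding frequency by composition", {
  N_ip <- rep(50, 20)
  cnt <- fake_counts(N_ip = N_ip, N_id = rep(10, 20), N_ib = rep(10, 20),
                     N_ibd = c(4, 0, rep(2, 18)), N_p = 1000)
  p <- propensity(cnt)
  expect_equal(unname(p["ALA"]), (4 / 10) / (50 / 1000))  # = 8.0
  expect_equal(unname(p["ARG"]), 0)
  # null case: identical composition, uniform binding probability
  null <- fake_counts(N_ip = rep(50, 20), N_id = rep(20, 20),
                      N_ib = rep(5, 20), N_ibd = rep(1, 20),
                      N_p = 1000)
  expect_equal(unname(propensity(null)), rep(1, 20))
})

test_that("relative percentages reproduce the published worked examples", {
  expect_equal(relative_percentage(22, 145), 15.2)
  expect_equal(relative_percentage(66, 742), 8.9)
  expect_equal(relative_percentage(18, 137), 13.1)
  expect_equal(relative_percentage(26, 131), 19.8)
  expect_equal(relative_percentage(32, 157), 20.4)
  expect_equal(relative_percentage(20, 109), 18.3)
  expect_equal(relative_percentage(43, 189, digits = 2), 22.75)
  expect_equal(relative_percentage(0, 100), 0)
  expect_true(is.na(relative_percentage(5, 0)))
})

test_that("depletion p-value is the exact binomial lower tail", {
  expect_equal(depletion_test(0, 0.027, 96), (1 - 0.027)^96,
               tolerance = 1e-14)
  expect_equal(depletion_test(96, 0.027, 96), 1.0)
  expect_error(depletion_test(0, 0, 96), "between 0 and 1")
  expect_error(depletion_test(0, 1, 96), "between 0 and 1")
})

test_that("bootstrap SE is zero for identical complexes and reproducible", {
  cnt <- fake_counts(N_ip = rep(50, 20), N_id = rep(10, 20),
                     N_ib = rep(10, 20), N_ibd = rep(2, 20))
  tabs <- replicate(10, cnt, simplify = FALSE)
  bs <- bootstrap_stat(tabs, function(x) propensity(pool_counts(x)),
                       n_samples = 100, seed = 7)
  expect_equal(unname(bs$se), rep(0, 20))
  bs2 <- bootstrap_stat(tabs, function(x) propensity(pool_counts(x)),
                        n_samples = 100, seed = 7)
  expect_identical(bs$se, bs2$se)
})

test_that("bootstrap SE of a mean approaches the closed form", {
  set.seed(31)
  vals <- rnorm(20)
  tabs <- as.list(vals)
  bs <- bootstrap_stat(tabs, function(x) mean(unlist(x)),
                       n_samples = 1000, seed = 5)
  closed <- sd(vals) / sqrt(20)
  expect_lt(abs(bs$se - closed) / closed, 0.15)
})

test_that("contact matrix normalises to 1 and matches a direct tally", {
  ct <- data.frame(
    protein_key = paste0("A|", 1:10, "|"),
    resid = "ARG", nt_key = "R|1|", nt = "G",
    min_distance = 3, in_dot = FALSE, stringsAsFactors = FALSE)
  m <- aa_nt_contact_matrix(ct)
  expect_equal(m["ARG", "G"], 1)
  expect_equal(sum(m), 1)
  expect_equal(sum(aa_nt_contact_matrix(ct[0, ])), 0)

  set.seed(8)
  ct2 <- data.frame(
    protein_key = sprintf("A|%d|", 1:50),
    resid = sample(AA3, 50, replace = TRUE),
    nt_key = sprintf("R|%d|", sample(1:6, 50, replace = TRUE)),
    nt = sample(NUCLEOTIDES, 50, replace = TRUE),
    min_distance = 3, in_dot = FALSE, stringsAsFactors = FALSE)
  m2 <- aa_nt_contact_matrix(ct2)
  expect_equal(sum(m2), 1)
  for (k in 1:5) {
    i <- sample(AA3, 1); j <- sample(NUCLEOTIDES, 1)
    expect_equal(m2[i, j], sum(ct2$resid == i & ct2$nt == j) / 50)
  }
})

test_that("protein SS cross-tab reports per-class binding percentages", {
  dot <- sprintf("A|%d|", 1:20)
  ss <- factor(c(rep("helix", 8), rep("sheet", 5), rep("other", 7)),
               levels = c("helix", "sheet", "other"))
  names(ss) <- dot
  ct <- data.frame(protein_key = dot[c(1, 2, 9, 10, 11, 14)])
  tab <- protein_ss_crosstab(dot, ct, ss)
  expect_equal(tab$N_d, c(8L, 5L, 7L))
  expect_equal(tab$N_idt, c(2L, 3L, 1L))
  expect_equal(tab$relative_binding_pct,
               c(relative_percentage(2, 8), relative_percentage(3, 5),
                 relative_percentage(1, 7)))
  empty <- protein_ss_crosstab(character(0), ct[0, , drop = FALSE], ss)
  expect_equal(sum(empty$N_d), 0L)
})

test_that("RNA SS cross-tab counts distinct nucleotides per class", {
  # 6 nucleotides: 1-2 unpaired, 3-4 paired, 5-6 pseudoknot
  cls <- factor(rep(c("unpaired", "basepaired", "pseudoknot"), each = 2),
                levels = c("unpaired", "basepaired", "pseudoknot"))
  names(cls) <- sprintf("R|%d|", 1:6)
  nts <- c("A", "C", "G", "U", "G", "C")
  ct <- data.frame(
    protein_key = c("A|1|", "A|2|", "A|2|", "A|3|", "A|9|"),
    resid = "ARG",
    nt_key = sprintf("R|%d|", c(1, 1, 3, 5, 4)),
    nt = nts[c(1, 1, 3, 5, 4)],
    min_distance = 3, stringsAsFactors = FALSE)
  dot <- c("A|1|", "A|2|")
  tab <- rna_ss_crosstab(ct, cls, dot)
  # DOT contacts touch nucleotides 1 (unpaired A) and 3 (paired G)
  expect_equal(tab$N_idt[tab$nt == "A" & tab$ss == "unpaired"], 1L)
  expect_equal(tab$N_idt[tab$nt == "G" & tab$ss == "basepaired"], 1L)
  # all contacts touch nucleotides 1, 3, 4, 5
  expect_equal(tab$N_prot[tab$nt == "All" & tab$ss == "basepaired"], 2L)
  expect_equal(tab$N_prot[tab$nt == "All" & tab$ss == "pseudoknot"], 1L)
  # zero-count combinations are retained as explicit rows
  expect_true(all(c("A", "C", "G", "U", "All") %in% tab$nt))
  expect_equal(nrow(tab), 15L)
  expect_equal(tab$relative_contact_pct[tab$nt == "U"], c(0, 0, 0))
  # unannotated contacted nucleotide is an error naming the nucleotide
  ct_bad <- rbind(ct, data.frame(protein_key = "A|4|", resid = "ARG",
                                 nt_key = "R|9|", nt = "A", min_distance = 3))
  expect_error(rna_ss_crosstab(ct_bad, cls, dot), "R\\|9\\|")
})

test_that("count tables from structures satisfy their invariants", {
  sp <- fixture_spec(
    n_protein = 25, n_rna = 4,
    missing_free = data.frame(start = 8, length = 6),
    contact_plan = data.frame(resno = c(10, 20), nt = c(1, 2),
                              distance = c(3.0, 3.2)),
    seed = 11)
  pair <- generate_pair(sp)
  bound <- read_structure(pair$bound)
  spr <- structure_pair(read_structure(pair$free), bound)
  dot <- find_dot_residues(spr)
  ct <- find_contacts(bound, 3.5, dot)
  cnt <- count_table(bound, dot, ct)
  with(cnt$aa, {
    expect_true(all(N_ibd <= pmin(N_id, N_ib)))
    expect_true(all(N_ib <= N_ip))
    expect_true(all(N_ip <= cnt$N_p))
  })
  expect_equal(cnt$N_p, 25)
  expect_equal(sum(cnt$aa$N_id), 6)
  # summed DOT-binding counts equal the distinct DOT interface residues
  expect_equal(sum(cnt$aa$N_ibd),
               length(unique(ct$protein_key[ct$protein_key %in% dot])))
  # pooling two complexes doubles every count
  pooled <- pool_counts(list(cnt, cnt))
  expect_equal(pooled$aa$N_ip, 2 * cnt$aa$N_ip)
  expect_equal(pooled$N_p, 2 * cnt$N_p)
  expect_equal(pooled$nt$N_prot, 2 * cnt$nt$N_prot)
})
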