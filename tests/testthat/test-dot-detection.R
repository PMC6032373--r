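make_pair <- function(...) {
  pair <- generate_pair(fixture_spec(...))
  free <- read_structure(pair$free)
  bound <- read_structure(pair$bound)
  list(sp = structure_pair(free, bound), bound = bound, truth = pair$truth)
}

test_that("mapping: identical numbering gives the identity correspondence", {
  p <- make_pair(n_protein = 12, n_rna = 0, seed = 1)
  m <- p$sp$mapping
  expect_equal(m$free_key, m$bound_key)
  expect_equal(nrow(m), 12L)
})

test_that("mapping: numbering offset is recovered by alignment", {
  p <- make_pair(n_protein = 20, n_rna = 0, bound_offset = 100, seed = 2)
  m <- p$sp$mapping
  expect_equal(nrow(m), 20L)
  expect_equal(split_residue_key(m$bound_key)$resno,
               split_residue_key(m$free_key)$resno + 100L)
  # mapped residues carry identical residue names
  expect_true(all(m$resid %in% AA3))
})

test_that("mapping: unrelated sequences are rejected", {
  a <- read_structure(generate_pair(fixture_spec(
    n_protein = 15, n_rna = 0, sequence = rep(c("ALA", "GLY", "SER"), 5),
    seed = 1))$bound)
  b <- read_structure(generate_pair(fixture_spec(
    n_protein = 15, n_rna = 0, sequence = rep(c("TRP", "PHE", "LYS"), 5),
    bound_offset = 100, seed = 1))$bound)
  expect_error(build_mapping(a, b), "not the same protein")
})

test_that("DOT residues are free-missing and bound-ordered", {
  # no free disorder -> no DOT
  p0 <- make_pair(n_protein = 10, n_rna = 0, seed = 3)
  expect_length(find_dot_residues(p0$sp), 0L)

  # free missing 10-14, bound fully ordered
  p1 <- make_pair(n_protein = 20, n_rna = 0,
                  missing_free = data.frame(start = 10, length = 5), seed = 3)
  expect_equal(find_dot_residues(p1$sp), residue_key("A", 10:14))

  # residue 12 also missing in bound is excluded
  p2 <- make_pair(n_protein = 20, n_rna = 0,
                  missing_free = data.frame(start = 10, length = 5),
                  missing_bound = data.frame(start = 12, length = 1), seed = 3)
  dot <- find_dot_residues(p2$sp)
  expect_equal(dot, residue_key("A", c(10, 11, 13, 14)))

  # invariants: DOT within free missing, disjoint from bound missing,
  # all DOT residues carry atoms in the bound structure
  expect_true(all(dot %in% p2$sp$mapping$bound_key[
    p2$sp$mapping$free_key %in% p2$sp$free$missing$key]))
  expect_length(intersect(dot, p2$bound$missing$key), 0L)
  expect_true(all(dot %in% p2$bound$atoms$key))
})

test_that("segmentation keeps maximal runs of length >= 3", {
  p <- make_pair(n_protein = 20, n_rna = 0,
                 missing_free = data.frame(start = 10, length = 5),
                 missing_bound = data.frame(start = 12, length = 1), seed = 3)
  # runs 10-11 and 13-14: both too short
  expect_equal(nrow(segment_regions(find_dot_residues(p$sp), p$bound)), 0L)

  p5 <- make_pair(n_protein = 20, n_rna = 0,
                  missing_free = data.frame(start = 10, length = 5), seed = 3)
  reg <- segment_regions(find_dot_residues(p5$sp), p5$bound)
  expect_equal(reg$length, 5L)
  expect_equal(c(reg$start, reg$end), c("10", "14"))

  # two regions, one crossing the >50 length bin
  p2 <- make_pair(n_protein = 70, n_rna = 0,
                  missing_free = data.frame(start = c(1, 7),
                                            length = c(3, 54)), seed = 4)
  reg2 <- segment_regions(find_dot_residues(p2$sp), p2$bound)
  expect_equal(reg2$length, c(3L, 54L))
})

test_that("unlisted numbering gaps break continuity", {
  # residues 1-10 and 41-50; nothing recorded for 11-40
  pair <- generate_pair(fixture_spec(
    n_protein = 20, n_rna = 0,
    missing_free = data.frame(start = 9, length = 4), seed = 5))
  bound <- read_structure(pair$bound)
  free <- read_structure(pair$free)
  renumber <- function(s) {
    sel <- s$atoms$resno > 10
    s$atoms$resno[sel] <- s$atoms$resno[sel] + 30L
    s$atoms$key <- residue_key(s$atoms$chain, s$atoms$resno, s$atoms$icode)
    sel <- s$missing$resno > 10
    s$missing$resno[sel] <- s$missing$resno[sel] + 30L
    s$missing$key <- residue_key(s$missing$chain, s$missing$resno, s$missing$icode)
    s
  }
  bound <- renumber(bound)
  free <- renumber(free)
  sp <- structure_pair(free, bound)
  dot <- find_dot_residues(sp)
  expect_equal(dot, residue_key("A", c(9, 10, 41, 42)))
  # the 10 -> 41 jump splits the run; both halves are < 3 residues
  expect_equal(nrow(segment_regions(dot, bound)), 0L)
})

test_that("insertion-coded residues count as consecutive", {
  pair <- generate_pair(fixture_spec(
    n_protein = 12, n_rna = 0,
    missing_free = data.frame(start = 5, length = 3), seed = 6))
  bound <- read_structure(pair$bound)
  free <- read_structure(pair$free)
  # renumber so the chain reads 1-5, 5A, 6-11 (residue 6 becomes 5A)
  relabel <- function(s) {
    for (f in c("atoms", "missing")) {
      ins <- s[[f]]$resno == 6
      shift <- s[[f]]$resno >= 7
      s[[f]]$resno[ins] <- 5L
      s[[f]]$icode[ins] <- "A"
      s[[f]]$resno[shift] <- s[[f]]$resno[shift] - 1L
      s[[f]]$key <- residue_key(s[[f]]$chain, s[[f]]$resno, s[[f]]$icode)
    }
    s
  }
  bound <- relabel(bound)
  free <- relabel(free)
  sp <- structure_pair(free, bound)
  reg <- segment_regions(find_dot_residues(sp), bound)
  expect_equal(reg$length, 3L)
  expect_equal(reg$residues[[1]], c("A|5|", "A|5|A", "A|6|"))
})

test_that("segmentation agrees with a brute-force scan on random patterns", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 40L
    miss <- sort(sample.int(n, sample(0:15, 1)))
    runs <- if (length(miss)) {
      grp <- cumsum(c(1, diff(miss) != 1))
      data.frame(start = vapply(split(miss, grp), min, 0L),
                 length = vapply(split(miss, grp), length, 0L))
    } else NULL
    pair <- generate_pair(fixture_spec(n_protein = n, n_rna = 0,
                                       missing_free = runs, seed = seed))
    bound <- read_structure(pair$bound)
    sp <- structure_pair(read_structure(pair$free), bound)
    reg <- segment_regions(find_dot_residues(sp), bound)
    expect_equal(sort(reg$length), sort(oracle_regions(miss)))
  }
})

test_that("region summaries bin lengths and count regions per complex", {
  fake <- function(lens) {
    data.frame(chain = rep("A", length(lens)),
               start = rep("1", length(lens)),
               end = rep("2", length(lens)),
               length = as.integer(lens))
  }
  s <- region_summary(list(fake(c(3, 5, 10)), fake(c(12, 55)),
                           fake(integer(0))))
  expect_equal(unname(s$length_bins),
               c(3L, 1L, 0L, 1L))  # 3-10: {3,5,10}; 11-20: {12}; >50: {55}
  expect_equal(as.integer(s$n_regions[c("0", "2", "3")]), c(1L, 1L, 1L))

  many <- c(replicate(9, fake(3), simplify = FALSE),
            list(fake(rep(3, 4))))
  expect_equal(region_summary(many)$frac_lt3, 90)
})
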