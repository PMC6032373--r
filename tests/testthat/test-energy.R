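toy_params <- function(dielectric = 1, distance_dependent = FALSE) {
  energy_params(table = data.frame(
    atom_type = c("X1", "X2", "Q+", "Q-"),
    rstar = c(1.5, 2.0, 1.8, 1.8),
    epsstar = c(0.20, 0.45, 0.0, 0.0),
    q = c(0, 0, 1, -1)), dielectric = dielectric,
    distance_dependent = distance_dependent)
}

toy_res <- function(types, x, key = "A|1|", resid = "GLY") {
  data.frame(key = key, resid = resid, elety = types, elesy = "C",
             x = x, y = 0, z = 0, stringsAsFactors = FALSE)
}

test_that("LJ minimum identity: E(R*) = -eps*, decaying to zero", {
  eps <- sqrt(0.20 * 0.45)
  rstar <- 1.5 + 2.0
  expect_equal(lj_term(eps, rstar, rstar), -eps, tolerance = 1e-13)
  expect_lt(abs(lj_term(eps, rstar, 10 * rstar)), 1e-4 * eps)
  # local minimum: nudging r either way raises the energy
  expect_gt(lj_term(eps, rstar, rstar + 0.1), -eps)
  expect_gt(lj_term(eps, rstar, rstar - 0.1), -eps)
  expect_error(lj_term(eps, rstar, 0), "positive")
})

test_that("LJ crosses zero at R* 2^(-1/6), located by numeric scan", {
  eps <- 0.3; rstar <- 3.4
  r0 <- rstar * 2^(-1 / 6)
  expect_equal(lj_term(eps, rstar, r0), 0, tolerance = 1e-12)
  # bracket the sign change on a grid around the root
  grid <- seq(r0 - 0.2, r0 + 0.2, by = 0.004)
  e <- lj_term(eps, rstar, grid)
  expect_true(all(e[grid < r0 - 1e-9] > 0))
  expect_true(all(e[grid > r0 + 1e-9] < 0))
})

test_that("Coulomb term follows 332.0637 q1 q2 / (eps r)", {
  expect_equal(coulomb_term(1, 1, 3.32), 332.0637 / 3.32)
  expect_equal(coulomb_term(0, 1, 2.5), 0)
  expect_equal(coulomb_term(1, -1, 4, dielectric = 2),
               coulomb_term(1, -1, 4) / 2)
  # distance-dependent screening divides by r twice
  expect_equal(coulomb_term(1, 1, 5, distance_dependent = TRUE),
               332.0637 / 25)
  expect_error(coulomb_term(1, 1, 0), "positive")
})

test_that("residue pair energy reduces to lj_term for neutral single atoms", {
  p <- toy_params()
  a <- toy_res("X1", 0)
  b <- toy_res("X2", 3.5, key = "R|1|")
  expect_equal(residue_pair_energy(a, b, p), -sqrt(0.20 * 0.45),
               tolerance = 1e-12)
  # beyond the evaluation shell the energy is exactly zero
  expect_equal(residue_pair_energy(a, toy_res("X2", 50, key = "R|1|"), p), 0)
  # symmetry
  expect_equal(residue_pair_energy(a, b, p), residue_pair_energy(b, a, p))
})

test_that("multi-atom pair energy equals the brute-force double loop", {
  set.seed(21)
  p <- toy_params(dielectric = 2)
  mk <- function(n, key, offset) {
    data.frame(key = key, resid = "GLY",
               elety = sample(c("X1", "X2", "Q+", "Q-"), n, replace = TRUE),
               elesy = "C",
               x = runif(n, 0, 4) + offset, y = runif(n, 0, 4),
               z = runif(n, 0, 4), stringsAsFactors = FALSE)
  }
  a <- mk(15, "A|1|", 0)
  b <- mk(15, "R|1|", 4)
  got <- residue_pair_energy(a, b, p, shell = 10)
  # independent evaluation, atom pair by atom pair
  look <- function(t) p$table[t, ]
  want <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(b[j, c("x", "y", "z")]))^2))
      if (r > 10) next
      pi_ <- look(a$elety[i]); pj <- look(b$elety[j])
      epsij <- sqrt(pi_$epsstar * pj$epsstar)
      rij <- pi_$rstar + pj$rstar
      want <- want + epsij * ((rij / r)^12 - 2 * (rij / r)^6) +
        332.0637 * pi_$q * pj$q / (2 * r)
    }
  }
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("energy is invariant under rigid rotation of the pair", {
  p <- toy_params()
  a <- toy_res(c("X1", "Q+"), c(0, 1.2))
  b <- toy_res(c("X2", "Q-"), c(4, 5.1), key = "R|1|")
  e0 <- residue_pair_energy(a, b, p)
  th <- 0.7
  rot <- function(df) {
    x <- df$x * cos(th) - df$y * sin(th)
    df$y <- df$x * sin(th) + df$y * cos(th)
    df$x <- x
    df$z <- df$z + 3
    df
  }
  expect_equal(residue_pair_energy(rot(a), rot(b), p), e0, tolerance = 1e-9)
})

test_that("atoms without parameters error in strict mode, zero otherwise", {
  p <- toy_params()
  a <- toy_res("ZZ", 0)
  b <- toy_res("X2", 3.5, key = "R|1|")
  expect_error(residue_pair_energy(a, b, p), "ZZ")
  expect_warning(e <- residue_pair_energy(a, b, p, strict = FALSE), "ZZ")
  expect_equal(e, 0)
})

test_that("energy matrix stratifies DOT and non-DOT means per cell", {
  p <- toy_params()
  atoms <- rbind(
    toy_res("X1", 0, key = "A|1|", resid = "ARG"),
    toy_res("X1", 20, key = "A|2|", resid = "ARG"),
    toy_res("X2", 3.5, key = "R|1|", resid = "G"),
    toy_res("X2", 23.5, key = "R|2|", resid = "G"))
  atoms$chain <- substr(atoms$key, 1, 1)
  atoms$resno <- as.integer(sub(".*\\|(\\d+)\\|.*", "\\1", atoms$key))
  atoms$icode <- ""
  atoms$hydrogen <- FALSE
  s <- structure(list(atoms = atoms, missing = data.frame(key = character()),
                      chain_type = c(A = "protein", R = "rna")),
                 class = "dot_structure")
  ct <- find_contacts(s, 3.5, dot_residues = "A|1|")
  em <- energy_matrix(s, ct, "A|1|", p)
  e_ref <- -sqrt(0.20 * 0.45)
  expect_equal(em$dot["ARG", "G"], e_ref, tolerance = 1e-9)
  expect_equal(em$nondot["ARG", "G"], e_ref, tolerance = 1e-9)
  expect_equal(em$dot_n["ARG", "G"], 1)
  expect_equal(sum(em$dot_n) + sum(em$nondot_n), nrow(ct))
  # empty cells are zero with zero counts
  expect_equal(em$dot["TRP", "U"], 0)
  expect_equal(em$dot_n["TRP", "U"], 0)
})
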