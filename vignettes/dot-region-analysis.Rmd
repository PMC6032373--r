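---
title: "Detecting and characterising disorder-to-order transitions at protein-RNA interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising disorder-to-order transitions at protein-RNA interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotrna)
```

## The model

Many RNA-binding proteins carry intrinsically disordered regions that
fold only when the RNA partner is bound. When both crystal forms exist,
the evidence is purely observational: residues present in the construct
but unresolved in the free crystal appear in the PDB header's
REMARK 465 block, while the same residues carry coordinates in the
complex. `dotrna` operationalises this as:

* a **DOT residue** is missing (REMARK 465) in the free structure and
  ordered (has atoms) in the bound complex, under a residue
  correspondence requiring at least 99 % sequence identity;
* a **DOT region** is a maximal run of at least three consecutive DOT
  residues within one chain.

Both definitions are conservative by construction. Residues that are
mobile but still modelled (high B-factors, alternate conformations) are
not counted — only a complete absence of coordinates in the free form
qualifies. Consecutive means adjacent in author numbering: an
insertion-coded pair (52, 52A) is consecutive, while a bare numbering
jump (30 → 41) with no intervening REMARK 465 entries breaks a run,
because nothing in the file says those residues are adjacent in
sequence.

Around the detection step the package computes the interface
statistics that characterise how DOT regions recognise RNA: per-type
binding frequencies and propensities, bootstrap standard errors,
secondary-structure cross-tabulations on both sides of the interface,
relative solvent accessibility, and pairwise interaction energies.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| contact cutoffs | 3.5 and 6.0 | Å | the two heavy-atom cutoffs conventional in the protein–RNA interface literature; both are always computed so trends can be compared across them |
| minimum region length | 3 | residues | shorter runs are indistinguishable from crystallographic noise in missing-residue records |
| bootstrap replicates | 1000 | samples | complexes (not residues) are resampled with replacement, sample size equal to the number of complexes, because complexes are the independent units |
| SASA probe radius | 1.4 | Å | water probe |
| SASA sphere points | 960 | points | doubling to 1920 changes totals by < 0.5 % on the test fixtures |
| energy evaluation shell | 10 | Å | both the 12-6 and the screened 1/r term are negligible beyond it at interface scale; summation over a whole ribosome would add noise, not signal |
| dielectric | 1.0 (option: ε = r) | — | vacuum Coulomb by default; the distance-dependent option is the common implicit-solvent approximation |
| region-length bins | 3–10, 11–20, 21–50, >50 | residues | configurable via `length_breaks` |

Contact detection uses heavy atoms only (most crystal structures lack
hydrogens) and a closed interval: a pair exactly at the cutoff is a
contact. The boundary rule has to be fixed somewhere for
reproducibility; the closed form was chosen so that a fixture placed
exactly at 3.5 Å tests positive.

The propensity statistic is

$$\mathrm{propensity}(i) \;=\; \frac{N_{ibd}/N_{id}}{N_{ip}/N_p},$$

the DOT-binding frequency of type *i* normalised by the type's share of
the protein. It equals 1 when a type's DOT residues bind at a rate equal
to the type's background frequency — the null against which the
synthetic recovery tests are built (see below). Types absent from DOT
regions are reported as `NA`, never 0: "no opportunity" and "never
binds" are different statements.

## Energy model

Residue–nucleotide interaction energy is the sum over inter-residue
atom pairs of a 12-6 Lennard-Jones term in A/B form
($A_{ij}=\varepsilon^*_{ij}{R^*_{ij}}^{12}$,
$B_{ij}=2\varepsilon^*_{ij}{R^*_{ij}}^{6}$, so the minimum is exactly
$-\varepsilon^*_{ij}$ at $r=R^*_{ij}$) plus Coulomb
($332.0637\,q_iq_j/\varepsilon r$ kcal/mol). Combination rules are the
AMBER conventions: radii add, well depths combine by geometric mean.

The parameter table (`inst/extdata/energy_params.tsv`) is a
configuration artifact, not a constant of the method: it ships
representative AMBER-style values for the backbone and nucleotide
heavy-atom types used by the fixtures, keyed by atom name with an
element fallback, and is meant to be replaced wholesale when a
different force field is wanted. Atoms without Lennard-Jones parameters
are an error in strict mode and a warned-about zero otherwise
(`strict = FALSE`, the pipeline default, so a single odd terminal atom
does not abort a complex).

## Solvent accessibility

SASA is Shrake–Rupley: each heavy atom's solvent-expanded sphere
(van der Waals radius + probe) is sampled with a deterministic
golden-angle spiral; a point is accessible if outside every neighbour's
expanded sphere. Determinism was preferred over random sampling so that
identical inputs give identical outputs without seed plumbing. The
spiral is not mirror-symmetric, so two geometrically equivalent atoms
agree only to sampling resolution (≈ 0.3 % at 960 points) — the tests
assert symmetry at 1 %.

Relative accessibility divides by the residue type's maximum in an
extended Ala-X-Ala tripeptide (Tien et al. 2013 theoretical maxima,
shipped as data) and is reported in percent; values above 100 are
legitimate for extreme conformations. The per-type summary compares
mean RASA of DOT residues against all residues of the protein
component; computing on the protein component alone (RNA removed) is
the default, since including the RNA would conflate burial-by-folding
with burial-by-binding — the complex-wide alternative can be had by
passing the full structure.

## What the synthetic generator emulates — and what it does not

`generate_pair()` builds free/bound PDB pairs with ideal-geometry
backbones (helix φ = −57°, ψ = −47°; strand φ = −120°, ψ = 120°),
reduced atom sets (N, CA, C, O, CB; RNA P, C1′, N9/N1), controlled
REMARK 465 runs, and nucleotides placed so the minimum heavy-atom
distance to a target residue matches a requested value within 0.05 Å
(the placement search errors out when a neighbouring residue would
shadow the target). Ground truth — expected DOT regions and the exact
contact sets at both cutoffs, tallied by an exhaustive atom-pair scan —
travels with each fixture.

What passing these tests shows: the bookkeeping (parsing, mapping,
segmentation, contact detection, counting) is exact, and the statistics
recover planted parameters. What it does not show: behaviour on real
crystallographic pathologies (chain breaks mislabelled as disorder,
ambiguous alternate conformations, modified residues without MODRES
records beyond the mapped cases) or the biological validity of any
particular cutoff. Fixtures have no side chains, so side-chain-mediated
contacts are out of reach of the synthetic tests by design.

`generate_count_scenario()` works at the count level rather than
building coordinates: each simulated complex draws residue types and
binding indicators so that the expected propensity of type *i* equals
the requested target exactly (a DOT residue of type *i* binds with
probability target × composition fraction). The defaults — 200
complexes of 2400 residues with 1200 in DOT regions — were chosen once
for statistical power: the recovery contract asserts every null type
within ±0.15 of 1.0, which needs roughly 10⁴ DOT residues per type;
real proteins have far fewer DOT residues per complex, which is exactly
why the statistic is pooled over a dataset before interpretation.

## Numerical choices and degenerate inputs

* Alternate locations: highest occupancy wins, ties go to the first
  record in file order.
* Residues listed in REMARK 465 that also carry atoms are an error —
  the two sources must be consistent for DOT calls to mean anything.
* A nucleotide contacting both a DOT and a non-DOT residue counts once
  per column in the nucleotide tables (distinct-nucleotide convention).
* Table percentages are rounded half-up to the table's printed
  precision; `round()`'s round-half-even would disagree on exact .5
  boundaries.
* Bootstrap and generators save and restore the global RNG state, so
  library calls do not perturb a caller's random sequence.
* Empty sets propagate as empty tables or `NA`, not zeros: zero regions
  in a complex is data, an undefined ratio is not.
* The pipeline isolates failures per complex (skip + log) and aborts
  only when every complex fails; run logs carry no timestamps so a
  rerun with the same manifest and seed is byte-identical.

## Problem sizes used by the test-suite

The suites run synthetic studies sized to exercise every code path
while staying desk-scale: 100 random complexes (50 residues / 10
nucleotides) for contact-oracle equivalence, 100 generated free/bound
pairs for exact DOT recovery, 200 count-level complexes with 1000
bootstrap replicates for propensity recovery, and three-complex
manifests for end-to-end determinism.

## Known limitations

* Disorder visible only as elevated B-factors or partial occupancy is
  not detected; coordinates present means ordered.
* The dihedral fallback secondary-structure assigner is intended for
  the ideal-geometry fixtures; real structures should come with DSSP
  output (`read_dssp()`), since the hydrogen-bond based algorithm it
  approximates is the field standard.
* First NMR model only; mmCIF is not parsed; DNA chains and ligands are
  ignored.
* The energy scorer ranks pairings; it is not a minimiser and carries
  no entropic or solvation terms beyond the optional ε = r screening.
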