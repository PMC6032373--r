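# dotrna

Analysis of disorder-to-order transition (DOT) regions at protein–RNA
interfaces.

Intrinsically disordered regions of RNA-binding proteins often fold only
upon binding their RNA partner. When the same protein has been
crystallised both free and in complex with RNA, that transition leaves a
fingerprint in the PDB files: residues listed as *missing* (REMARK 465)
in the free structure but resolved in the complex. `dotrna` detects
these regions and characterises how they recognise RNA — who binds,
from which secondary structure, how exposed they are, and how favourable
the amino-acid/nucleotide pairings are energetically.

The package is aimed at structural bioinformaticians studying
disorder-mediated nucleic-acid recognition, and at anyone who needs a
tested, deterministic implementation of the underlying primitives
(missing-residue bookkeeping, interface contacts, relative solvent
accessibility, pairwise interaction energies) with a synthetic-structure
generator for validation.

## What it computes

**DOT regions.** A residue is a DOT residue when it is missing in the
free protein and ordered in the bound complex; a DOT region is a maximal
run of ≥ 3 consecutive DOT residues (author numbering; insertion-coded
residues count as consecutive, unlisted numbering gaps break a run).

**Interface statistics.** A residue–nucleotide pair is in contact when
its minimum heavy-atom distance is ≤ 3.5 Å (or 6 Å). With per-type
counts N<sub>ibd</sub> (type *i* binding within DOT regions),
N<sub>id</sub> (type *i* in DOT regions), N<sub>ib</sub> (type *i*
binding anywhere), N<sub>ip</sub> (type *i* in the protein) and
N<sub>p</sub> (all residues):

- binding frequency in DOT regions: N<sub>ibd</sub> / N<sub>id</sub>
- share of binders that are in DOT: N<sub>ibd</sub> / N<sub>ib</sub>
- propensity: (N<sub>ibd</sub> / N<sub>id</sub>) / (N<sub>ip</sub> / N<sub>p</sub>)

Standard errors come from bootstrap resampling of whole complexes
(1000 replicates by default); depletion of a residue type at the
interface is scored with the exact binomial lower tail. Cross-tabs
relate contacts to protein secondary structure (DSSP letters or a
dihedral fallback) and RNA pairing state (dot-bracket with pseudoknots).

**Accessibility and energy.** Per-residue solvent accessibility uses
Shrake–Rupley sampling (960-point deterministic sphere, 1.4 Å probe),
expressed relative to Ala-X-Ala extended maxima. Interaction energies
are the 12-6 Lennard-Jones plus Coulomb sum over inter-residue atom
pairs,

E = Σ [ A<sub>ij</sub>/r<sup>12</sup> − B<sub>ij</sub>/r<sup>6</sup> + q<sub>i</sub>q<sub>j</sub>/(ε r) ],
A<sub>ij</sub> = ε\*<sub>ij</sub>(R\*<sub>ij</sub>)<sup>12</sup>,
B<sub>ij</sub> = 2ε\*<sub>ij</sub>(R\*<sub>ij</sub>)<sup>6</sup>,

with AMBER-style R\*, ε\* and partial charges from an editable
parameter table.

## Worked example

Everything is testable without downloads: the synthetic generator
builds free/bound PDB pairs with known ground truth.

```r
library(dotrna)

spec <- fixture_spec(
  n_protein = 30, n_rna = 4,
  missing_free = data.frame(start = 12, length = 6),   # disordered when free
  contact_plan = data.frame(resno = 14, nt = 2, distance = 3.2),
  seed = 42)
pair <- generate_pair(spec)

bound <- read_structure(pair$bound)
pr    <- structure_pair(read_structure(pair$free), bound)
dot   <- find_dot_residues(pr)
segment_regions(dot, bound)[, c("chain", "start", "end", "length")]
#>   chain start end length
#> 1     A    12  17      6

contacts <- find_contacts(bound, 3.5, dot_residues = dot)
contacts
#>   protein_key resid nt_key nt min_distance in_dot
#> 1       A|14|   GLU   R|2|  C     3.199976   TRUE
```

The six residues planted as missing-when-free come back as one DOT
region (12–17), and the nucleotide placed 3.2 Å from residue 14 is the
single 3.5 Å contact, flagged as a DOT interface residue. Counts and
statistics follow directly:

```r
cnt <- count_table(bound, dot, contacts)
propensity(cnt)[["GLU"]]
#> [1] 15
```

GLU binds from a DOT region (1 of 1 DOT glutamate) while making up only
2 of 30 residues, hence the propensity (1/1)/(2/30) = 15. On published
count tables the same helpers reproduce the printed percentages, e.g.
`relative_percentage(22, 145)` → `15.2`, and
`depletion_test(0, 0.027, 96)` → `0.0722` — the probability that a
residue type expected at 2.7 % of a 96-residue interface is never seen.

`run_pipeline(manifest, run_config(), outdir)` runs the whole analysis
over a TSV manifest of structure pairs and writes the report tables
(regions, frequencies with bootstrap SEs, contact matrices,
secondary-structure cross-tabs, RASA and energy tables) plus a run log.

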