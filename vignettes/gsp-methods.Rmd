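---
title: "Methods: graph-based structural pattern search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-based structural pattern search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsp4r)
```

## The pattern model and its semantics

A graph-based structural pattern is a labeled property graph over two kinds
of entities. Amino nodes are either specific (a 3-letter residue name) or
wildcards; a wildcard may carry a polarity class or an explicit allowed set
of residue codes. A pattern may contain at most one ligand node, specific
(3-letter hetero code) or wildcard; multi-ligand patterns are out of scope.
Three edge kinds constrain an assignment:

* **distance** (undirected): the minimum atom-pair distance between the two
  assigned entities must lie in `[min, max]`, with the global envelope
  0.5–7.0 Å. The lower bound excludes physically impossible overlaps; the
  upper bound is the interaction cutoff (below).
* **next** (directed): the second residue immediately follows the first in
  the chain. This is deliberately *adjacency*, a gap of exactly zero — a
  separate gap edge with range `(1, *)` expresses "one or more residues
  between".
* **gap** (directed): with `g` the number of residues strictly between the
  endpoints, `min ≤ g ≤ max` with `min ≥ 1` and `max = *` for unbounded.

A hit is an injective assignment of amino nodes to residues satisfying
everything. Injectivity is a semantic choice the model needs to make: if
two CYS nodes could bind the same cysteine, a symmetric two-node pattern
would count each unordered pair once, twice *and* degenerately, and the
arithmetic of mirror solutions (an order-free k-identical-node pattern
yields k! hits per satisfying set) would not hold. When a structure carries
several copies of the ligand compound, each copy is a separate candidate
and hits binding different copies are distinct — the tool counts
occurrences, not binding sites.

Polarity classes use the standard textbook partition of the twenty
residues: non-polar {GLY, ALA, VAL, LEU, ILE, PRO, PHE, MET, TRP}, polar
uncharged {SER, THR, CYS, TYR, ASN, GLN}, positively charged {LYS, ARG,
HIS}, negatively charged {ASP, GLU}. Residues outside the twenty (modified
residues kept in the polymer) have standard name `undefined` and belong to
no class, so a polarity-restricted wildcard never matches them while an
unrestricted wildcard does.

## Pre-processing of coordinate files

`parse_pdb_file()` reduces a PDB entry to one chain — the one with the most
amino acids, ties broken to the lexicographically smallest chain identifier
so parsing is deterministic. Only the first NMR model is used. For
alternate locations the first-listed conformer of each atom is kept. All
atoms present in the file enter the distance computation; deposited
structures rarely include hydrogens, so in practice distances are between
heavy atoms. Waters (HOH/DOD/WAT) are never ligands. Hetero groups that are
really polymer residues (MSE and similar) are treated as residues with
standard name `undefined` (MSE maps to MET); the remaining hetero groups on
the selected chain become ligand candidates.

Residues are renumbered 1…n in order of appearance, ignoring author
numbering and insertion codes. This makes gap arithmetic well defined on
exactly the entities the matcher sees, and it is the numbering the
provenance ids encode (`1B38_A_1_4` = atom 4 of residue 1 of chain A of
1B38).

The contact table stores every residue pair and ligand–residue pair whose
minimum atom-pair distance is at most the cutoff, default **7.0 Å** —
distances beyond that are taken to mean no interaction. Residue pairs are
stored once per unordered pair (lower index first); the matcher and the
SQL compiler both treat distance edges symmetrically, the compiler by
probing both stored orientations. A centroid-plus-radius bound prunes
pairs that cannot fall within the cutoff before the exact cross-pair
minimum is computed; this is an exact optimization, not an approximation.

## Two backends, one semantics

The in-memory matcher is the reference: candidate filtering per node, then
backtracking over nodes in ascending candidate-count order with edge
checks as soon as both endpoints are placed. It exists to be obviously
correct, and it is itself tested against blind exhaustive enumeration over
all injective assignments.

The SQL backend mirrors the relational layout a production deployment
would use: `protein`, `standard_amino` (21 rows), `amino`, `ligand`, two
atom tables, the two distance tables, `next_amino_amino` and
`protein_cath`, with codes and sequence indexes denormalized into the
distance tables and twelve secondary indexes. The compiler emits one
sub-expression per node–edge–node structure — a join against the
appropriate distance or adjacency table, or pure sequence-index arithmetic
for gap edges — and conjoins them with node predicates, same-protein
conditions and pairwise `<>` conditions for injectivity. Gap edges are
compiled as arithmetic on `seq_index` rather than by walking the adjacency
table so that a gap of `x(35,50)` costs the same as a gap of `x(2)`. Only
one of the fifteen node–edge–node transformation templates has a published
reference form; the others follow from the enumerated combinations and are
pinned down behaviourally by the backend-equivalence property (several
hundred randomized structure/pattern pairs per test run must return
bit-identical hit sets).

SQLite was chosen as the embedded engine: the schema and the generated SQL
stay inside the common subset, so a client–server backend (e.g.
PostgreSQL) remains a drop-in deployment detail rather than a design
change.

## Linear notation import

`parse_prosite()` accepts dash-separated 1-letter residue codes, bracket
alternations (`[LIVMFYWC]`, imported as a wildcard with an allowed set)
and gap terms `x`, `x(n)`, `x(n,m)`, with literal `x(n)`/`x(*)` meaning an
unbounded gap of at least one residue. Adjacent residue letters become
next-edges; consecutive gap terms accumulate. Leading and trailing gap
terms constrain nothing under these semantics and are dropped with a
warning. With a ligand code supplied, every amino node receives a
default-range (0.5–7.0 Å) distance edge to the ligand node — the idiom for
turning a sequence motif into a binding-site pattern. Rendering back to
text (`format_prosite()`) is exact for single-chain patterns, which keeps
the import honest under round-trip tests.

## The synthetic generator and what it does (not) show

`generate_structure()` emulates the inputs the ingester expects: a
single-chain structure whose residues sit on a jittered self-avoiding walk
with ~3.8 Å consecutive anchor spacing (the Cα–Cα distance of a trans
peptide bond) and 1–5 atoms within 2 Å of each anchor. When a binding-site
pattern is planted, each instance receives its own ligand copy placed far
from the chain and from other instances; the instance's residues take the
pattern's identities, and one atom of each is placed at a distance drawn
uniformly from `[min + 0.1, max − 0.1]` of its distance edge — the 0.1 Å
interior margin guarantees that coordinate round-trips through the PDB
format's three decimals (±5·10⁻⁴ Å) can never flip a hit across a range
boundary. Decoy suppression is geometric, not probabilistic: every
non-planted residue stays beyond the 7.0 Å cutoff from every ligand, and
decoy identities are drawn from codes that no pattern node can match. The
returned ground truth therefore is exact by construction, including mirror
assignments within an instance, which are enumerated by predicate-filtered
backtracking.

Planted patterns are restricted to the binding-site shape (amino nodes on
a single gap/next chain, one distance edge each to the single ligand, no
fully unconstrained wildcard) because outside that shape decoys cannot be
excluded by identity and ground truth would no longer be constructive.
Randomized patterns in the equivalence tests are not so restricted.

What passing these tests shows: the two backends implement the same
semantics, that semantics equals exhaustive enumeration, and planted
signal is recovered exactly with clean negative controls. What they do not
show: behaviour on real crystallographic pathologies (occupancy
disorder, chain breaks, alternate conformer geometry beyond first-listed,
symmetry-related contacts) or the hit counts of any particular public PDB
snapshot, which depend on the snapshot.

## Facets

Classification keyword grouping stems each classification string to its
uppercased leading token before any `/` or `,`, with empty values grouped
as `UNKNOWN` — the visible grouping logic of deposited classification
strings, chosen over text mining because classifications are too
inconsistent to reward more machinery. CATH grouping counts each hit at
all four hierarchy levels (a protein annotated 3.30.160.60 counts under 3,
3.30, 3.30.160 and 3.30.160.60) with a `No value` bucket for unannotated
proteins; annotations arrive as a user-supplied two-column file, never
fetched. Mean distances per group are arithmetic and unweighted across
hits. All facet tables are recomputable from the exported JSON alone,
which the tests verify.

## Problem sizes and numerical choices

The test suite works at desk scale by design: equivalence properties run
on 200 randomized structure/pattern pairs (chains ≤ 25 residues, ≤ 2
ligand copies, patterns ≤ 5 nodes mixing all edge kinds), plant-and-recover
on 50+ seeded specs with 0–5 instances on 70-residue chains, contact
correctness on 100 random structures, and the six zinc-finger class
patterns on 100-residue corpora. Distances are compared exactly between
backends (both store IEEE doubles; SQLite REAL round-trips them); test
tolerances of 1e-9 absorb only the unit-vector normalization error of the
generator. Chain-selection ties, alternate locations and NMR models are
resolved by the deterministic rules above, so every operation is
reproducible from a seed.

## Known limitations

Single-chain analysis only — inter-chain binding sites and
crystal-symmetry neighbours are invisible. mmCIF input is not parsed. At
most one ligand node per pattern. No approximate or geometry-superposition
matching: a pattern either matches exactly or not at all. Keyword
stemming is an approximation of curated keyword grouping, and full-PDB
summaries are snapshot-dependent by nature.
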