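---
title: "Multiple structure alignment with structmsa: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple structure alignment with structmsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmsa)
```

## The problem

Homologous protein families often diverge in sequence while conserving
three-dimensional structure. For machine learning on such families one wants a
residue-residue correspondence across many structures — a multiple *structure*
alignment — with high coverage: long gap-free blocks whose columns carry
feature values for every member. `structmsa` builds such alignments from
alpha-carbon geometry alone and extracts per-residue structural features
indexed by the alignment columns.

## The pairwise model

Aligning two structures by coordinate distance presupposes that they are
already superposed, while superposing them presupposes an alignment. The
package breaks this circularity with three cheap candidate superpositions:

1. **Secondary structure**: the two code strings (H/E/C, assigned internally
   from backbone hydrogen bonds) are aligned by affine-gap dynamic
   programming with score +1 for equal codes, -1 for unequal, 0 when either
   is unassigned, and gap penalties (1, 0); the aligned residue pairs feed a
   Kabsch fit.
2. **Distance signals, first anchor**: every overlapping 30-residue stretch
   is summarized by the distances of its alpha carbons to the stretch's
   first residue. These signals are rigid-motion invariant, so two
   arbitrarily oriented structures can be compared directly. The two segment
   lists are aligned by dynamic time warping (the same DP engine with zero
   gap penalties — leniency is wanted while the orientation is still
   unknown), scoring a segment pair by the median of
   `exp(-(d_i - d_j)^2 / 10)` over its positions. The anchor alpha carbons
   of aligned segment pairs feed a Kabsch fit.
3. **Distance signals, last anchor**: the same with distances measured to
   the last residue of each stretch.

Each candidate transform is applied to the first structure, a dense score
matrix `exp(-gamma * d^2)` over alpha-carbon pairs is built, and an
affine-gap global alignment (gap open 1, gap extend 0.01) is computed. The
alignment score is the *sum of pair similarities over aligned pairs*; the
best candidate wins, and the winner is refined by one round of Kabsch on its
aligned pairs followed by re-alignment (`refine_iterations` exposes more
rounds, stopping when the score improves by less than 1e-6). Ties between
candidates (within 1e-9) resolve in the order signal/first, signal/last,
secondary, so output is deterministic.

`gamma = 0.03` (1/angstrom^2) puts the similarity at about 0.62 for residues
4 angstrom apart — the customary structural-equivalence cutoff — and below
0.15 by 8 angstrom, encoding the belief that residues beyond 8 angstrom are
unlikely to be equivalent.

```{r gamma}
score_coords(c(0, 0, 0), c(4, 0, 0))   # ~0.62 at 4 angstrom
score_coords(c(0, 0, 0), c(8, 0, 0))   # ~0.15 at 8 angstrom
```

## Progressive alignment and the consensus feedback

For more than two structures, all pairs are aligned, each pair's score is
divided by its number of aligned pairs (a length-normalized similarity in
[0, 1]), and a guide tree is built on the distance `1 - similarity`.
"Maximum linkage" agglomeration is used: the distance from a merged node to
anything else is the maximum over its members, with ties broken by
lexicographic node id so the merge order is reproducible. Each merge aligns
two *nodes* — stacks of already-aligned structures collapsed to per-column
averaged coordinates, a secondary-structure row, and a **consensus row**.

The consensus row is the feedback mechanism. At a leaf it equals the
consensus weight `cw` (default 1) everywhere; after each merge it is the
number of residues aligned at the column times `cw`. Before two nodes are
aligned, each node's consensus is multiplied by half the number of structures
in the *other* node, and the resulting value is concatenated to the 3-D
coordinates as a fourth component entering only the Gaussian score (the
geometric steps — segment signals and Kabsch — always operate on plain 3-D
points, since a consensus count is not a coordinate). Columns with equal
consensus in both nodes contribute nothing to the score exponent and keep
scoring highly; columns where one node has a well-populated core and the
other a gap-riddled fringe score lower. The net effect is that fully aligned
core blocks resist late gap insertion, which is precisely the failure mode
of naive progressive alignment on conserved families. Setting
`consensus_weight = 0` switches the mechanism off.

Merging is bookkept as: coordinates averaged (unweighted between the two
children) at doubly occupied columns and copied from the occupied child at
gap columns; the secondary code of the first child where both are occupied;
counts summed; member rows extended with the new gaps so that every
structure's row always reads out its full residue index sequence.

## Quality metrics

Four metrics summarize an alignment: the count and ratio of gap-less
columns; the equivalence score against a reference alignment (the percentage
of gap-less test columns whose residue-index tuple occurs as a column of the
reference); and, after superposing every structure onto the longest one
using the gap-less columns, the mean pairwise RMSD and the mean
count/fraction of residue pairs within 4 angstrom ("structurally
equivalent"). The common-reference superposition — rather than per-pair
refitting — is deliberate: it scores the alignment as a single rigid
ensemble. A per-pair mode can be had by calling `kabsch()` per pair, but the
packaged metrics follow the common-reference definition.

## Structural features

Per residue, `extract_features()` assembles: Gaussian and anisotropic
network model square fluctuations (Kirchhoff/Hessian eigenmodes; defaults
10 and 15 angstrom cutoffs with unit spring constants — the conventional
values — and 50 low-frequency modes; with all modes the result equals the
pseudo-inverse diagonal, which the tests verify); backbone phi/psi, the
alpha virtual torsion (CA i-1..i+2), the kappa bend angle (between the
CA(i-2)->CA(i) and CA(i)->CA(i+2) virtual bonds), tco (cosine between
consecutive C=O bonds); best hydrogen-bond energies as donor and as
acceptor from the Kabsch-Sander electrostatic model
`E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332` kcal/mol; solvent
accessibility by Shrake-Rupley sampling; and residue depth as the mean
distance of a residue's atoms to a sampled solvent-accessible surface.
Atom-level features (accessibility, depth) are emitted as alpha-carbon,
beta-carbon and residue-mean columns, with the alpha carbon standing in for
glycine's missing beta carbon. `aligned_feature_matrix()` scatters the
tables into alignment columns with `NA` exactly at gaps;
`drop_gap_columns()` reproduces the usual dense-matrix preprocessing for
learners.

Two surface-sampling details are worth knowing. Sampling uses a
deterministic golden-spiral point set, and coordinates are first rotated
into a principal-axes frame with a fixed sign convention, so accessibility
and depth are invariant under rigid motion of the input up to eigen-solver
precision. Accuracy is bounded by the number of sample points
(`sasa_points`, `sphere_points`), which the tests keep modest (48-128) and
applications may raise.

## Secondary structure without an external binary

Rather than shelling out to DSSP, the package reimplements the hydrogen-bond
energy above with bonds at E < -0.5 kcal/mol: `H` for residues covered by
two consecutive i -> i+4 turns, `E` for members of the standard parallel or
antiparallel bridge patterns, `C` otherwise, `-` where the backbone is
incomplete. The amide hydrogen is rebuilt at 1 angstrom from N along the
previous residue's O -> C direction, and donors across chain breaks
(C(i-1)-N(i) > 2.5 angstrom) are skipped. The alphabet is collapsed to three
states because the alignment score only tests code equality — a finer
alphabet could only lower similarity scores, never change their structure.
`read_pdb()` accepts precomputed codes via `sec_codes` for users who prefer
external DSSP output.

## Synthetic fixtures: what they do and do not emulate

`make_structure()` grows ideal backbones (helix phi/psi -57/-47, strand
-139/135, seeded random coil torsions with clash-rejection resampling) from
standard internal coordinates, yielding full N/CA/C/O/CB atoms, real
i -> i+4 hydrogen bonds in helices, and 3.8 angstrom CA steps. The loop
generator draws torsions rather than placing CA points directly: the trans
peptide makes the CA trace a ~3.8 angstrom self-avoiding walk anyway, and a
complete backbone is required for torsion and hydrogen-bond features.
`perturb()` models structural divergence as i.i.d. Gaussian atom
displacement (expected CA RMSD `noise_sd * sqrt(3)`), and `random_rigid()`
draws uniform rotations and translations in a 100-angstrom box. The family
used throughout the tests is a 60-residue helix-loop-strand-loop-helix
topology with noise between 0.3 and 2.5 angstrom.

These fixtures exercise every code path, but they are not real proteins:
noise is isotropic and residue-independent (no hinge or loop flexibility),
side chains beyond the beta carbon do not exist, and deletion variants are
made by excising residues from a shared backbone. Passing tests therefore
demonstrate algorithmic correctness (oracle agreement, invariances, gap
localization, consensus behavior), not benchmark-level accuracy on
experimental structures — the metrics module exists precisely so that users
can score alignments of real data, including against curated reference
alignments read from aligned FASTA.

Pairwise alignments of a structure with itself or a rigid copy recover the
identity correspondence with score equal to the residue count; the suite
checks this for the 60-residue fixture at sizes 2-8, problem sizes chosen to
exercise multi-level guide trees while keeping the full suite fast.

## Numerical choices and degenerate inputs

* DP gap convention: a run of L gaps costs `open + (L - 1) * extend`;
  terminal gaps are penalized like internal ones. The intended use is
  full-length homologous chains, where true global alignment is the honest
  objective; the brute-force enumeration oracle in the tests shares the
  convention.
* DP tie-breaks prefer match over a gap consuming the first structure's
  index over a gap consuming the second's, making tracebacks deterministic.
* Kabsch applies the standard determinant correction, so degenerate (planar
  or collinear) inputs still yield a proper rotation; fewer than 3 point
  pairs is an error.
* Structures shorter than the 30-residue segment length: `make_segments()`
  itself refuses (a 20-residue chain has no 30-residue stretch), but the
  pairwise driver shrinks the segment length to `max(10, floor(N/2))` so
  short chains remain alignable; `segment_length` is exposed for manual
  control.
* A coarse strategy that fails (too few segments, no positive-scoring
  secondary pairs — e.g. all-coil vs all-helix) is skipped; only if all
  three fail does the pairwise alignment error.
* Elastic network models: near-zero eigenvalues are those below `1e-8 *
  max|lambda|`; more than one (GNM) or six (ANM) zero modes aborts with a
  message naming the disconnected components rather than returning
  fluctuations of a broken contact graph.
* Half-counts in the consensus multiplication use exact `n/2` for odd
  structure counts.
* The all-vs-all pairwise stage is computed serially; its result is a pure
  function of the inputs, so a parallel implementation would have to be
  bit-identical.

## Open choices made here

The linkage family behind the guide tree and the exact refinement schedule
are genuinely open design points. Complete linkage was chosen over
average/single linkage because it delays merges involving any divergent
member, which empirically protects core columns; one refinement round is the
default because the score plateaus after it on the fixture families (the
early-stopping rule makes extra rounds harmless). Coordinate averaging
between children is unweighted; weighting by stack size would bias
intermediate nodes towards large subfamilies and is intentionally not done.

## Limitations

Flexible (hinged) superposition is out of scope — a single rigid transform
per pairwise step is assumed. Only the first model of multi-model PDB files
is read, hetero atoms and mmCIF are not handled, and sequence similarity
contributes nothing to the score by design. Runtime grows as the square of
both the number of structures and their length; the
`scaling_benchmark_groups()` generator exists to measure this on synthetic
families of configurable size, and its timings are informational only.
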