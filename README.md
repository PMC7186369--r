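# structmsa

Multiple protein structure alignment and aligned structural feature
extraction for homologous, sequence-divergent protein families — the setting
where sequence aligners fail but geometry still identifies equivalent
residues, and where machine learning on residue features needs long gap-free
alignment blocks.

## The method

**Pairwise alignment.** Two structures are first coarsely superposed by the
best of three strategies: alignment of secondary-structure code strings
(match +1, mismatch −1, unassigned 0; gap penalties σ=1, ε=0), or dynamic
time warping of rotation-invariant *distance signals* — each overlapping
30-residue stretch represented by the distances of its alpha carbons to the
stretch's first (or last) residue, segment pairs scored by

    ScoreP(i,j) = median_d exp(−(P_i,d − P_j,d)² / 10)

with zero gap penalties, followed by a Kabsch fit on the anchor residues of
aligned segments. The superposed alpha carbons are then aligned globally
with affine gap costs (σ=1, ε=0.01) under a Gaussian coordinate similarity

    ScoreC(i,j) = exp(−γ ‖α_i − α_j‖²),  γ = 0.03 Å⁻²

which evaluates to ≈0.6 at the customary 4 Å equivalence cutoff and near 0
by 8 Å. The alignment score is the sum of ScoreC over aligned pairs, and the
winning alignment is refined by one re-superposition/re-alignment round.

**Multiple alignment.** All pairs are aligned; each score is divided by its
number of aligned pairs and the resulting similarity drives a
maximum-linkage guide tree. Progressive merges operate on *nodes* (stacks
collapsed to averaged coordinates) carrying a **consensus row** — the count
of residues aligned at each column times the consensus weight `cw` (default
1). Before each merge the consensus is scaled by half the other node's size
and concatenated to the coordinates as a fourth component of ScoreC, so
columns that are well aligned in both nodes keep scoring highly and core
blocks resist gap insertion as the alignment grows.

**Features and metrics.** Per residue the package computes GNM/ANM elastic
network fluctuations, phi/psi/alpha/kappa/tco angles, Kabsch–Sander
hydrogen-bond energies, Shrake–Rupley solvent accessibility and sampled
residue depth, scattered into alignment columns with explicit missing values
at gaps. Alignment quality is reported as gap-less positions, equivalence
against a reference alignment, and mean pairwise RMSD / structurally
equivalent residues (within 4 Å) after superposing everything onto the
longest structure.

Everything is testable offline: a fixture module grows ideal
helix/strand/loop backbones with full N/CA/C/O/CB atoms, Gaussian coordinate
noise and random rigid motions.

## Worked example

```r
library(structmsa)

# a synthetic family: one 60-residue helix-loop-strand-loop-helix backbone,
# three noisy rigidly-moved copies, one of them with a 6-residue deletion
base <- make_structure(fixture_spec(
  list(c("helix", 20), c("loop", 8), c("strand", 12), c("loop", 6),
       c("helix", 14)), seed = 7, id = "member0"))
fam <- c(list(base), lapply(1:3, function(i) {
  st <- random_rigid(perturb(base, 0.5, 100 + i), 200 + i)
  st$id <- paste0("member", i)
  st
}))
fam[[4]] <- subset_residues(fam[[4]], setdiff(1:60, 25:30))
fam[[4]]$id <- "member3"

msa <- multiple_align(fam)
msa
#> <MultipleAlignment: 4 structures, 60 columns, 54 gap-less>

alignment_quality(msa, fam)
#> <AlignmentQuality>
#>   gapless_count             54
#>   gapless_ratio             0.9
#>   equivalence_score         NA
#>   mean_pairwise_rmsd        0.9521448
#>   mean_equivalent_count     57
#>   mean_equivalent_fraction  1
```

The 6 deleted residues come back as exactly 6 contiguous gap columns (60
columns, 54 gap-less); the noisy copies superpose to ~0.95 Å mean pairwise
RMSD with every aligned pair within 4 Å. Feature matrices follow the same
alignment:

```r
feats <- lapply(fam, extract_features)
names(feats) <- vapply(fam, `[[`, character(1), "id")
fm <- aligned_feature_matrix(msa, feats)
fm
#> <FeatureMatrix: 4 structures x 60 columns x 13 features>
write_feature_tsv(drop_gap_columns(fm), "features.tsv")
```

A thin command-line wrapper ships in `inst/cli/structmsa`
(`structmsa align --pdbs a.pdb,b.pdb --out aln.fasta`, `structmsa fixtures`).

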