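---
title: "Quantifying metal-locked conformational dynamics of a homodimeric metallosensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metal-locked conformational dynamics of a homodimeric metallosensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mntrdyn)
```

## The scientific problem

MntR, the manganese-sensing transcription factor of *Bacillus subtilis*, is a
homodimer of 142-residue chains, each built from an N-terminal DNA-binding
domain (DBD), a linker helix, and a C-terminal dimerization domain. Mn²⁺
binding at two sites per monomer raises the protein's DNA affinity. The
mechanistic picture this package is built to quantify is *conformational
selection*: the metal-free protein wanders over a broad set of relative
DBD orientations and only occasionally visits the DNA-binding-competent one,
while metal binding narrows the ensemble around that competent orientation.
Under this picture the informative observable is not any single structure
but the *distribution* of a geometric descriptor over an ensemble of frames.

The package implements four descriptors, the clustering and PCA machinery
used to characterise ensemble breadth, ensemble-comparison statistics, and a
synthetic-ensemble generator with prescribed descriptor distributions.

## Descriptors

All descriptors are evaluated per frame on a `trajectory` (a shared atom
table plus one coordinate row per frame) and carry units and the sampling
interval.

- **DBH dihedral** χ: the signed torsion over the backbone carbonyl carbons
  of residues 47 and 36 of chain A and 47 and 36 of chain B, in that order
  (continuous dimer numbering 47, 36, 189, 178 — chain B residues are offset
  by chain A's length of 142). It measures the relative *orientation* of the
  two DNA-binding helices, which distance-based measures miss. "Backbone C"
  is read as the carbonyl carbon (PDB name `C`), not Cα: the descriptor
  definitions in this field name Cα explicitly when they mean it. The atom
  is user-overridable (`atom = "CA"`).
- **Hinge angle** θ: the vertex angle at C(75) between C(64) and C(86),
  quantifying the bend of the linker helix. It is reported per chain or, by
  default, as the per-frame mean of the two chains: published values for
  this system are single numbers per state without stated chain handling, so
  the symmetric mean is the default and both per-chain variants remain
  available.
- **Lys41 Cα distance**: the inter-chain Cα–Cα distance of residue 41, a
  classic activation measure that is deliberately included because it fails
  to separate the states (its distributions overlap almost completely).
- **Site-2 gap**: the minimum distance between the Asp8 carboxylate oxygens
  (OD1/OD2) and the Glu99 carboxylate oxygens (OE1/OE2) of one chain — the
  gap bridged by the second metal ion or by the engineered D8C–E99C
  disulfide. Only residue identities are fixed by convention; the nearest
  carboxylate-oxygen pair is the chemically meaningful choice. On models
  without side chains the Cα–Cα distance is used and the series is flagged
  (`attr(x, "fallback")`).

Signed torsions use the IUPAC convention (clockwise positive viewed from
p2 towards p3) and are reported signed; note that the torsion is invariant
under reversing the four points and flips sign only under mirror reflection.
Summaries keep the sign rather than folding it.

## Superposition, clustering, PCA

`kabsch()` is the closed-form SVD solution for the least-squares rigid
superposition, with the standard determinant correction that excludes
reflections. `pairwise_rmsd_matrix()` superposes every frame pair
independently on the chosen selection and uses the singular-value identity
for the minimised squared deviation, so no per-pair coordinates are
materialised beyond the centred frames.

`gromos_cluster()` implements the Daura neighbour-count algorithm: the frame
with the most neighbours within the cutoff (closed ball, distance ≤ cutoff)
becomes a centroid, the cluster is removed, and the step repeats. Ties on
the neighbour count are broken by the lowest frame index, which makes
results deterministic. Cluster sizes are non-increasing in discovery order
(the maximal neighbour count cannot grow as frames are removed). One
property this greedy scheme does **not** have is monotonicity of the cluster
count in the cutoff: enlarging the cutoff changes which frame wins the
neighbour count, and the altered removal order can split the remainder into
*more* clusters. Roughly a fifth of small random distance matrices show such
local increases, and an independently coded literal-loop implementation
reproduces them exactly, so this is a fact about the algorithm rather than
an implementation artefact.

PCA follows the essential-dynamics recipe: frames (typically Cα atoms of
chains stripped of their first 3 and last 7 residues) are superposed onto an
iteratively refined mean structure — fit, average, refit, until the mean
moves less than 10⁻⁶ Å RMS — and the sample covariance (divisor n−1) of the
3N Cartesian coordinates is eigendecomposed. Superposing to the iterative
mean rather than an arbitrary reference frame removes reference bias from
the covariance; the fixed point is unique up to one global rotation, which
affects no eigenvalue, projection or loading. Factor loadings use the
correlation-style definition — eigenvector element × √eigenvalue ÷
coordinate SD, which equals the correlation between the coordinate and the
component's projection series — aggregated per residue as the Euclidean norm
over x, y, z. Zero-variance coordinates get loading 0 and raise a flag.

## Ensemble comparison

`summarize_series()` reports mean, sample SD (n−1), extrema and quartiles
(linear-interpolation convention, `quantile` type 7).
`compare_ensembles()` adds the difference of means (first minus second), the
SD ratio, and an *overlap fraction*: the fraction of the first ensemble's
values inside the second's Tukey fences [q1 − 1.5·IQR, q3 + 1.5·IQR].
Ensemble overlap is usually described verbally; the Tukey-fence containment
makes it a single computable number with boxplot semantics. No hypothesis
testing is attempted: MD descriptor series are autocorrelated, so naive
p-values would be meaningless, and the ensembles are summarised as
mean ± SD exactly as the field reports them.

## The synthetic generator

Raw multi-hundred-nanosecond trajectories of this system are not publicly
deposited, so the package ships a generator that emulates *descriptor-level*
ensemble behaviour on a coarse model. `make_template()` builds a
C2-symmetric two-chain backbone (N, CA, C per residue; 142 residues per
chain): a serpentine DBD block (residues 1–63) containing the DNA-binding
helix as a straight helical segment (36–50), a linker helix (64–86) bent to
about 170° at residue 75, and a serpentine dimerization core (87–142).
Chain B is the exact C2 image of chain A.

`generate_ensemble()` draws per-frame descriptor targets from Gaussians —
optionally AR(1)-correlated across frames — and poses the template exactly:

1. **Hinge**: the linker segment below the vertex (residues 64–74) rotates
   about the axis normal to the C64–C75–C86 plane through C75, closing or
   opening the angle to the drawn target exactly.
2. **Dihedral**: the two DBH blocks (residues 36–50) rotate about the
   torsion axis C(36ᴬ)→C(47ᴮ), half the correction per chain. Rotation about
   the torsion axis changes the torsion by exactly the rotation angle, and
   both on-axis atoms stay fixed.
3. **Lys41 distance**: the DBH blocks translate along the same axis,
   symmetrically, by the root of the quadratic that sets the Cα separation.
   Translation along the torsion axis leaves the torsion unchanged and
   touches no hinge atom.

Because each step moves the smallest atom set that defines its descriptor
and later steps are invariant to earlier ones, the three descriptor channels
are orthogonal by construction and every drawn target is met to machine
precision before noise. Isotropic Gaussian jitter (default SD 0.15 Å, a
modest crystallographic-quality positional uncertainty) is then added to
every atom; it perturbs the dihedral by ≈0.9° SD, the hinge by ≈0.35° and
the Lys41 distance by ≈0.2 Å, all zero-mean to first order, so preset means
and SDs are recovered within sampling error. Infeasible targets (e.g. a
Lys41 separation unreachable along the axis) raise a generation error naming
the frame. Identical parameters and seed give bitwise-identical output.

Deliberate simplifications, and hence what passing tests do *not* show about
real data: the pose unit for the dihedral is the DNA-binding helix rather
than the whole DBD, and the hinge moves only the linker, so the generator
reproduces descriptor *distributions* but not the correlated domain motion,
side-chain packing, solvent effects or backbone connectivity of a real
trajectory. Its overall Cα dispersion is consequently smaller than that of
real simulations: at the pipeline's default 1.8 Å clustering cutoff the
synthetic ensembles often collapse into one or two clusters, and the
variance-to-cluster-count ordering between states is exercised in the tests
both at 1.8 Å (as ≥) and, strictly, at a cutoff matched to the synthetic
dispersion (≈1 Å). Published trajectory-scale numbers for this system —
absolute cluster counts per state, or an 86/8/3 % PCA variance split —
depend on the underlying simulations and cannot be reproduced from
synthetic ensembles; the package instead tests their qualitative signatures
(state separation along PC1 by more than two pooled SDs, heaviest PC1
loadings inside the DBH residue range, wider states never yielding fewer
clusters).

### Preset parameters

| state | dihedral (°) | hinge (°) | Lys41 (Å) | provenance |
|---|---|---|---|---|
| `apo` | 64.6 ± 12.5 | 170.3 ± 4.1 | 37.8 ± 2.8 | reported |
| `mn` | 36.5 ± 7.3 | 169.5 ± 3.7 | 37.2 ± 1.9 | reported |
| `zn` | 70 ± 16 (assumed) | 173.1 ± 3.5 | 37.8 ± 2.8 (assumed) | mixed |
| `mutant` | 38 ± 8 (assumed) | 169.5 ± 3.7 (assumed) | 37.2 ± 1.9 (assumed) | assumed |

"Reported" marks published measurements for the corresponding MntR state;
"assumed" marks package-chosen convenience defaults for quantities published
only as figures: the Zn²⁺-bound dihedral is set wider than apo (the
Zn²⁺-bound helices fluctuate even more than the metal-free ones) and the
D8C–E99C disulfide mutant is set Mn-like (its dihedral behaviour tracks the
Mn²⁺-bound state). Each `synthetic_params` object records this in its
`provenance` field; assumed values are excluded from quantitative
recovery targets. The AR(1) coefficient defaults to 0 (exchangeable frames)
because no autocorrelation value is published; setting `ar1 > 0` emulates
the sluggish frame-to-frame memory of real MD when needed.

## Pipeline defaults

`run_config()` fixes the analysis conventions: terminal stripping of 3 head
and 7 tail residues per chain (flexible termini add noise to clustering and
PCA), gromos cutoff 1.8 Å, clustering from 20 ns, PCA on the 200–500 ns
window of merged ensembles, carbonyl-carbon descriptor atoms, 100 ps per
frame. Every deviation from these defaults is warned about and recorded in
the provenance JSON written next to each command's outputs.

Numbering note: residue 1 of a model chain is the first *modelled* residue;
constructs whose N-terminal methionine is absent are handled by the
numbering of the input file and never renumbered. Chains are paired
alphabetically by chain identifier unless overridden.

## Numerical choices and degenerate inputs

- Angles at coincident points and torsions over collinear triples raise
  degeneracy errors rather than returning NaN.
- `kabsch()` requires ≥3 non-collinear points; the smallest-singular-value
  sign flip handles the reflection branch.
- Stripping semantics: `strip_head`/`strip_tail` drop residues counted along
  each chain's residue order; because the counts refer to the intact chain
  termini, a trajectory records applied selections and re-applying the
  identical selection is a no-op.
- PDB output uses the fixed 8.3 coordinate field (round-trips preserve
  coordinates to 5·10⁻⁴ Å; descriptor series to ≈0.01° / 10⁻³ Å);
  unrepresentable coordinates raise an overflow error. Single-frame writes
  use the single-model dialect (no MODEL records).
- Eigenvalues are clamped at zero against numerical noise; variance
  fractions of a zero-variance ensemble are reported as zeros and flagged.

## Problem sizes

The test suite and the acceptance script use 3000-frame ensembles for
descriptor-recovery statistics (mean recovery is checked within four
standard errors of the configured SD), 40–60-frame ensembles for clustering
and PCA properties, and ≤12-frame instances for exhaustive oracle
comparisons — sizes at which every property is sharply testable on one CPU.

## Known limitations

- The generator emulates descriptor distributions, not physics; see above.
- Crystal-structure comparisons (`crystal_rmsd()`) require user-supplied PDB
  files; the package does not redistribute Protein Data Bank entries.
- mmCIF, binary trajectory formats (DCD/XTC), assembly expansion and
  mass-weighted superposition are out of scope; inputs are whole molecules
  in multi-model PDB form.
- gromos cluster counts are not monotone in the cutoff (see above); cutoff
  choice remains a user decision.
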