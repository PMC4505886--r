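---
title: "Quantifying Valpha/Vbeta interdomain geometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Valpha/Vbeta interdomain geometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdomgeom)
```

# The problem

An alpha-beta T-cell receptor binds its peptide-MHC ligand through two
paired immunoglobulin-like variable domains, Valpha and Vbeta. The two
domains do not associate at a single fixed angle: across receptors (and,
for one receptor, between its bound and unbound states) the Vbeta domain is
rotated relative to Valpha by small but systematic amounts. `vdomgeom`
turns that qualitative observation into numbers: a single rotation per
structure, a distance between any two such rotations, a statistically
supported clustering of the resulting geometry space, and a search for the
common pivot point about which the rotations occur.

The same machinery applies to any pair of rigid domains related by
framework-conserved superposition — the TCR is the motivating system, not a
restriction.

# The model

## Unified frames via conserved frameworks

Each variable domain consists of a structurally conserved beta-sheet core
(the framework) and hypervariable loops (the CDRs). Only the framework is
comparable across receptors, so all superpositions use framework C-alpha
atoms exclusively:

1. **Loop/turn removal.** `remove_loops_and_turns()` masks residues by a
   geometric extension criterion on the C-alpha trace: a residue is kept
   when the span across a +/-2-residue window is at least 2.75 Å per
   backbone step (extended chain advances ~3.3 Å per residue, helices
   ~1.5 Å, turns less). We chose a trace-geometric detector over a
   hydrogen-bond-based secondary-structure assignment because variable
   domains are routinely deposited without hydrogens and occasionally as
   C-alpha-only models; the detector needs nothing but the trace. The
   final anchor subset is data-derived anyway (next step), so the mask
   only needs to be a reasonable starting point.
2. **Iterative anchor refinement.** `derive_framework_subset()` starts
   from the masked positions shared by every domain in the ensemble and
   alternates (a) least-squares superposition of every domain onto the
   current anchors of the reference with (b) dropping of all anchors whose
   RMS fluctuation about the ensemble-mean position exceeds `dev_cutoff`
   (default 1.0 Å), one batch per iteration, largest deviations first,
   until the set is stable. Convergence is declared only by set stability;
   the variance of the per-domain superposition RMSDs is reported as a
   diagnostic (`rmsd_variance`, with a documented "low" threshold of
   0.05 Å²) rather than used as a stopping rule, because a deviating anchor
   can hold the RMSD variance low while still biasing the frame. The
   procedure is idempotent: rerunning on a converged subset changes
   nothing. If fewer than three non-collinear anchors survive, a
   convergence error carrying the last subset is raised — two unrelated
   point clouds have no common core and should fail loudly.
3. **Superposition.** Residue correspondence is by position label (author
   numbering with insertion codes); matched C-alpha pairs are superposed by
   the closed-form least-squares rotation (Kabsch, SVD with reflection
   correction). One high-resolution structure is the global reference;
   every complex is aligned on its *alpha* domain
   (`align_complex_on_alpha()`), carrying alpha, beta and any context
   chains with the same rigid transform.

## Cuboids and Euler angles

After alpha-alignment, all geometric variation is concentrated in the beta
domain. `build_reference_cuboid()` attaches a box to the reference beta
domain: axes are the principal axes of the anchor C-alphas, extents cover
all atoms. Eigenvectors carry a sign ambiguity, so the first two axes are
oriented to have positive dot products with the reference axes of the same
rank and the third is their cross product (proper, right-handed,
deterministic). For every other structure, the rigid transform mapping the
reference beta anchors onto that structure's beta anchors
(`beta_pose()`) carries the cuboid along; its rotation part *is* the
structure's interdomain geometry.

The rotation is reported as xyz-order Euler angles
(`euler_xyz_from_rotation()`). "xyz order" is ambiguous in the wild, so
the package fixes it precisely: intrinsic rotations about x, then y, then
z, i.e. the matrix product `Rz(theta) Ry(psi) Rx(phi)`; test vectors are
in the unit tests ((0, 90, 0) carries e_z onto e_x). At gimbal lock
(|psi| = 90°) only phi + theta is determined; the convention phi := 0 is
applied and recomposition still reproduces the input rotation. Observed
interdomain angles are far from 90°, so the convention never matters in
practice, but it keeps the decomposition total. Angles are degrees
externally, radians internally.

The distance between two geometries is the Euler-angle distance (EAD): the
Euclidean norm of the componentwise differences, each difference wrapped to
(-180, 180]. Wrapping preserves the metric axioms (symmetry, identity,
triangle inequality — property-tested on 10^4 random triples) and is
inert for the small angles the method measures. The EAD is computed on
degrees; this matches the scale on which results are reported.

## Clustering with multiscale bootstrap support

Structures with several biological units (BUs) are first collapsed by
componentwise angle averaging (`average_bu()`; means are taken after
wrapping differences to the first record, which coincides with the
arithmetic mean at within-crystal spreads). The EAD matrix is clustered
with Ward's minimum-variance linkage via `stats::hclust(method =
"ward.D2")` — the Lance-Williams update on squared dissimilarities, which
is the correct Ward formulation for a Euclidean metric such as the EAD.
Merge heights are monotone and ties resolve deterministically to the
lowest-index pair.

Cluster significance uses a multiscale bootstrap (`bootstrap_support()`):
resampling at ten scale factors r in 0.5..1.4 of the sample size, counting
for each original dendrogram node how often its clade recurs in replicate
trees, and combining the scale-wise frequencies into an
approximately-unbiased (au) value by a weighted least-squares fit of
`qnorm(1 - bp)` against `v*sigma + c/sigma` with `sigma = sqrt(n/n')`,
giving `au = 1 - pnorm(v - c)`. The reported bp is the clade frequency at
the scale closest to 1. Nodes with all-hit (or all-miss) frequencies
short-circuit to au = 1 (or 0) since the fit is degenerate there.

What to resample is a genuine design choice: the classical scheme
resamples feature dimensions, but a geometry record has only three
components (phi, psi, theta), which is statistically degenerate. The
default therefore resamples *structures* (observations): a node counts as
recovered in a replicate when its sampled members form a clade in the
replicate tree, and only replicates in which the node's sampled membership
is a non-trivial proper subset are informative. The classical
feature-dimension scheme remains available (`resample = "components"`)
for comparison, and neither mode is claimed to be anything other than this
package's interpretation.

`cut_significant_clusters()` turns support into a partition: maximal
non-root nodes with au >= 0.95 become clusters, uncovered leaves become
singletons. The root is excluded because the full set is a trivially
recurring clade. Note a structural property of this rule: a node joining
two genuinely distinct clusters can itself be stable under resampling when
one pairing is clearly preferred, in which case the supernode rather than
its children would be maximal. With several well-separated clusters at
comparable mutual distances the pairing is unstable and supernode support
collapses, which is what the planted-truth tests exercise.

Defaults: 1000 replicates per scale for interactive use (the tests use
200–500; support values for well-separated clusters saturate far below
that), au threshold 0.95, seed mandatory and embedded in all outputs.

## The center of rotation

If all beta poses are rotations about a common pivot, that pivot is the
one point whose position is invariant across the ensemble. The search
makes this operational: a cubic grid (`fit_grid()`) is centered on the
reference beta cuboid, axes parallel to the reference frame, indexed
x-fastest and identically for every structure; each structure's pose
carries the grid along (`transform_grid_points()`); and for every grid
index the *variance of the pairwise distances* between equivalent points
is computed (`variance_field()`). The variance is taken over all n^2
ordered structure pairs including the zero self-pairs, with squared
deviations from the pair mean and 1/(n^2 - 1) normalisation — the printed
double-sum form of the defining expression, whose deviation term we read
as squared (as a variance requires); a flag (`exclude_self = TRUE`)
removes the self-pairs for sensitivity analysis, which shifts the values
but not the argmin on planted data. The CoR is the argmin
(`locate_cor()`), ties to the lowest index; an ensemble without rotational
diversity (field numerically zero) has no CoR and errors out. With
self-pairs included the field vanishes only where all structures agree
exactly, so a common fixed point is the unique zero.

Identifiability caveat: if every pose rotates about (nearly) the same
axis, the invariant set is that whole axis, and the argmin is determined
only up to a flat valley. The synthetic defaults plant three cluster
centers with distinct rotation axes for exactly this reason.

The full-resolution grid of the method (edge 32 Å, spacing 0.1 Å, i.e.
321^3 = 33,076,161 points) is prohibitive to scan exhaustively against all
structure pairs, so the default strategy is coarse-to-fine: a 1.0 Å pass
over the full extent, then a 0.1 Å pass in a 3 Å box around the coarse
minimum. With commensurate spacings the fine lattice is a sub-lattice of
the exhaustive one, and the tests verify that coarse-to-fine and
exhaustive scans return the same point on enumerable instances. An
`"exhaustive"` strategy with memory-bounded chunking is provided for
cluster-scale runs.

Around the located CoR, `cor_environment()` lists residues by
closest-atom distance and `detect_interchain_hbonds()` reports
donor-acceptor heavy-atom pairs across the chains within 3.5 Å. The
cutoff is heavy-atom only, with no angular term, because crystal
structures of this class lack hydrogens; residues whose polar side-chain
atoms are unresolved are flagged rather than silently skipped. In real
receptors the CoR sits at a conserved interchain glutamine-glutamine
hydrogen-bond pair; the corresponding framework position is position 44 in
the IMGT unique numbering of both chains, and `frequency_at_position()`
tabulates its residue inventory from any aligned FASTA of V-segment
sequences (alignment construction is out of scope — aligners are external
tools and their versions drift; the package consumes the alignment and a
column-position mapping).

# The synthetic generator: what it emulates, what it does not

`planted_ensemble()` is first-class, tested code, not a test fixture
dump. It emulates the statistical structure of a receptor ensemble:

- two pseudo-immunoglobulin domains (eight extended strands in two sheets,
  compact connecting loops, ~105 residues) with a designated framework and
  a glutamine donor/acceptor pair;
- a planted beta pose per structure: cluster center angles plus
  independent per-component Gaussian jitter, rotated about a common pivot
  in the interdomain interface;
- optional isotropic coordinate noise and a random global rigid motion per
  structure so that alignment is always exercised.

Defaults were fixed once as the baseline study conditions: 24 structures,
3 clusters at mutual EAD 20° (mutually equidistant centers — the pairing
instability this induces is what makes supernodes insignificant, mirroring
ensembles with several comparably distant geometry clusters), jitter SD
0.5° (small against the 2-10° between-type differences the method
resolves), pivot at (15, -2, 2.5) Å in the interface and inside the search
grid, zero coordinate noise, and the jitter is per component so that
expected EADs are analytically computable. Sizes used by the test suite
and acceptance script (9-24 structures, 2-3 clusters, 200-500 bootstrap
replicates per scale, coarse-to-fine at 0.1 Å) were chosen as the smallest
ensembles on which the planted truth is still uniquely identifiable.

What passing tests on these ensembles shows: the geometry extraction,
metric, clustering, significance machinery and pivot search are correct
against planted ground truth, to stated numerical tolerances, including
under arbitrary global motions of the inputs. What it does not show:
robustness to the things real crystallography adds — framework plasticity
beyond isotropic noise, missing residues and alternate conformations in
awkward places, BU-to-BU heterogeneity within one crystal, and
biological-unit annotation errors. Reproduction of published values on the
deposited structure set is therefore kept as a separate acceptance layer
that runs when the coordinate files are locally available, with tolerances
(±0.5° on pairwise EADs) that absorb the documented substitution of
closed-form least-squares superposition for the original
distance-matrix-alignment tool and the unpublished final anchor subset.

# Numerical choices, degenerate inputs, limitations

- **Altlocs**: highest summed occupancy wins, ties to the alphabetically
  first identifier — deterministic and standard.
- **Insertion codes** are preserved in position labels; internal indexing
  is ordinal within the extracted domain.
- **Rotation validation**: orthonormality and det +1 to 1e-9 on
  construction; Euler decomposition validates to 1e-6 by default.
- **Collinearity**: templates and cuboids reject rank-deficient anchor
  sets (relative eigenvalue threshold 1e-10).
- **Ties**: Ward merges and CoR argmins break to the lowest index;
  anchor drops are batched per iteration, largest first.
- **Known limitations**: residue correspondence is label-based, so
  cross-structure use on real data requires consistently numbered domains
  (e.g. a renumbered manifest) — no structural alignment fallback is
  attempted; the bootstrap's observation-resampling interpretation is this
  package's choice; translation components of the beta pose are computed
  but deliberately not analysed (the rotation dominates the phenomenon
  this method targets); and the shipped 85-entry dataset catalog lists
  identifiers, states and species but not per-BU chain assignments, which
  must be completed against locally obtained coordinate files.

# A worked synthetic run

```{r example}
ens <- planted_ensemble(synthetic_spec(n_structures = 9, n_clusters = 3,
                                       seed = 2))
pipe <- tcr_geometry_pipeline(c(list(ens$reference), ens$complexes),
                              reference_id = "REF0")
pipe

head(pipe$records[, c("pdb_id", "phi", "psi", "theta")], 4)

cl <- run_cluster(pipe$records[pipe$records$pdb_id != "REF0", ],
                  n_replicas = 400, seed = 5)
cl$assignment

res <- run_cor(pipe, spacing = 0.1, extent = 32)
res$cor
ens$pivot
```
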