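---
title: "Methods: contact quantification, diffusion condensation and C-PHATE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact quantification, diffusion condensation and C-PHATE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactome)
```

This vignette is the package's own account of its models and numerical
choices: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and where the design was genuinely open.

## 1. Contact quantification

Segmented vEM data arrive as ordered stacks of 2-D integer label images
with physical calibration (`pixel_size` in nm/px, `z_spacing` in nm). A
`label_volume` optionally carries an inclusive slice `region`, reflecting
the practice of standardizing the analyzed neuropil region across datasets
(cell bodies removed, fixed posterior boundary) so that contact quantities
are comparable.

**Directed contact counts.** Contact between neurons A and B on a slice is
quantified by expanding A's region isotropically by the threshold distance
and counting the pixels of B it covers (and symmetrically B into A).
"Expansion" is Euclidean dilation: a pixel belongs to the expanded region
iff its center lies within `distance_px` of some pixel center of the
region. An alternative reading of outline expansion — homothetic scaling
about the region centroid — was considered and rejected: dilation is what
a distance-threshold definition of adjacency implies, it is
shape-congruent for convex regions, and it is independent of an arbitrary
center. Directed counts are summed over in-region slices; the symmetric
adjacency entry is the arithmetic mean of the two directions (both
directions are kept on the contact records). Counts are verified exactly
against an exhaustive pixel-pair oracle in the tests.

**Units.** Thresholds are stored both in nm and px; conversion is
round-half-up (`threshold_spec(45, 4.5)` is 10 px). Half-up rather than
R's round-half-even, so a 10.5 px threshold becomes 11, matching the
convention that the threshold is "at least this distance".

**Contact areas.** The area of a contact is the sum over slices of the
overlap-outline length times `z_spacing`. The outline length is measured
by boundary-segment counting: the number of exposed pixel edges
(4-neighborhood, image border exposed) times `pixel_size`. This estimator
is exact for axis-aligned rectangles and slightly overestimates diagonal
boundaries (up to a factor of about 1.41 for a 45-degree staircase); it was
chosen because it is deterministic, resolution-consistent and reproducible,
and because the slice-outline-times-spacing area convention is inherently a
first-order estimate in the first place.

**Threshold calibration.** To compare datasets that differ in resolution
and membrane-calling convention, the threshold is calibrated per dataset:
directly contacting pairs are defined as those with nonzero contact at the
45 nm reference expansion; for each candidate distance the mean penetration
depth — the maximum of `(candidate_px − distance_to_expander) × pixel_size`
over covered partner pixels, averaged over ordered contacting pairs — is
measured, and the smallest candidate reaching the 30 nm target overlap is
selected. The 45 nm / 30 nm defaults are the reference protocol values for
manually segmented data.

## 2. Diffusion condensation

Initial coordinates are the adjacency profiles: row i of the adjacency
matrix is neuron i's vector of contact quantities with every other neuron.
Clustering therefore groups neurons whose *patterns* of contact are
similar, not merely neurons that touch each other. Raw values are used
without log or rank transformation; preprocessing is deliberately the
caller's choice.

Each iteration computes a Gaussian affinity at bandwidth σ among current
centers, row-normalizes to the diffusion operator `P = D⁻¹A`, smooths
(`Y = PX`), and merges centers by connected components of the graph with
edges at Euclidean distance < ε, replacing each component by the unweighted
mean of its members.

**The merge threshold ε** is computed once, after the first diffusion step,
as the maximum coordinate-wise range of `Y` divided by 10 000, and is then
fixed. The coordinate-range formulation and the max-pairwise-Chebyshev
formulation are identical (per coordinate, the range *is* the largest
pairwise difference); the equivalence is asserted in the tests. The 10 000
divisor makes ε a small fraction of the data's spatial extent, so merging
only fires once diffusion has actually collapsed a neighborhood.

**The bandwidth schedule** is the one genuinely open design choice.
σ starts at the smallest nonzero pairwise distance among the initial
profiles and is multiplied by 1.1 after any iteration that produces no
merge; it is never shrunk. The rationale: a small initial σ makes the first
diffusion steps strictly local, so tightly-knit groups collapse below ε
first, and σ inflates only when condensation stalls, progressively
coarsening the process — a time-inhomogeneous schedule in the spirit of the
condensation literature. The obvious alternative — recomputing σ as the
median pairwise distance each iteration — was implemented and measured: on
planted 4-block benchmarks the median distance reflects the between-block
scale, diffusion mixes blocks before within-block condensation completes,
and block recovery collapses (2/20 instances versus 100/100 for the growth
schedule at factor 1.1; a sweep over growth factors 1.05–1.5 showed 1.05
and 1.1 both at 100/100 with 1.1 converging faster). `adaptive_sigma()`
exposes both the `"min"` and `"median"` statistics; `run_condensation()`
uses min-initialization with growth 1.1 by default (`sigma_growth` in
`condensation_params()`).

**Merging is transitive** (connected components of the ε-proximity graph),
not pairwise-sequential: a pairwise rule would depend on scan order,
breaking permutation equivariance. New centers are unweighted means of the
merged centers, so a large cluster and a singleton merge to their midpoint
rather than the mass-weighted center; this matches the center-update
formula of the condensation recursion and keeps the dynamics independent of
cluster history.

**Modularity** is always evaluated on the fixed iteration-0 adjacency
graph, never on the evolving coarse graph. Scores at different iterations
are then directly comparable, which is what makes "the iteration with the
highest modularity" a meaningful selection rule. Evaluating on the coarse
graph would conflate partition quality with the changing null model of a
shrinking graph. The implementation is verified against an independent
double-loop evaluation (1e-12) and igraph's weighted modularity (1e-9).

The trace records the initial singleton state as iteration 0, then one
entry per diffuse-and-condense pass; `select_strata()` takes the earliest
maximum-modularity iteration (ties broken early, favoring the finer
partition). `max_iterations` defaults to 1000; reaching it returns a
non-converged trace with a machine-parsable warning rather than failing.

## 3. C-PHATE

The connectivity matrix has one node per (iteration, cluster) pair across
the whole trace. Three constructions were open and are resolved as follows:

- **Per-iteration cluster affinities** are block sums of the original
  adjacency over cluster members. Aggregation conserves total edge weight
  and makes the kernel of a merged cluster the natural coarse-graining of
  its members' contacts.
- **Lag-2 blocks** use the composed product `P_{t,t+1} P_{t+1,t+2}`. For
  nested (merge-only) partitions this equals directly tabulated two-step
  movements, so the choice is notational rather than numerical.
- **Iterations without merges still contribute nodes** (their transition
  blocks are identity): every iteration of the condensation movie is
  represented. `collapse_duplicates = TRUE` drops consecutive duplicate
  partitions for compact plots.

Lag weights default to (100, 30) and the embedding diffusion time to 50
with seed 1 — the standard parameter set for these plots; the strong lag-1
weight is what strings each cluster's trajectory into a continuous path
toward the center.

**The embedding backend** is pluggable behind the `cphate_embed()`
contract (3-D, finite, identical output for identical input and seed). The
default backend is a compact potential-distance embedding of the
PHATE family: row-normalize the connectivity to a Markov operator, raise it
to the diffusion time by repeated squaring, take `−log` of the diffused
transition probabilities (with a 1e-12 floor against exact zeros), and
apply classical MDS to the pairwise potential distances. It is fully
deterministic, so seed-determinism holds trivially; the seed is still
consumed so stochastic backends are drop-in replacements. This backend does
not reproduce full PHATE (no adaptive alpha-decay kernel, no metric-MDS
refinement), and coordinates are not expected to match any other
implementation's — only the structural properties are contracted:
within-block singletons embed closer than cross-block ones (verified on
planted fixtures, separation ratios 15–120x), and cluster trajectories
converge toward the final all-neuron node.

## 4. Meshing

Isosurfaces are extracted by **marching tetrahedra**: each grid cube is
split into six tetrahedra around a body diagonal, and with binary voxel
values the level-0.5 iso-vertices fall exactly on midpoints of edges
between inside and outside voxel centers. The decomposition induces
matching face diagonals on neighboring cubes, so the surface is watertight
by construction; the volume is zero-padded so surfaces close at the
boundary. Vertices are scaled anisotropically by
`(pixel_size, pixel_size, z_spacing)`. No smoothing is applied anywhere —
meshes are a pure function of mask and calibration, and re-extraction is
bitwise identical. For an axis-aligned cuboid the flat faces land exactly
on the half-voxel bounding planes and only the chamfered edges deviate, so
measured areas sit within ~1.2% of the analytic value for a
30 x 24 x 20-voxel cuboid (the 5% contract holds with margin from ~10
voxels per edge).

Downsampling (the performance reduction applied to whole-neuron and
nerve-ring-shell meshes) is an integer x-y block reduction applied to masks
before triangulation, with a reduced pixel counted foreground if any
constituent pixel is — preserving thin neurites at the cost of slight
dilation. Default is 1 (off).

Contact patches are isosurfaces over stacked per-slice overlap masks; an
empty or untriangulatable overlap returns `NULL` with a warning, since a
missing reciprocal patch is a recorded outcome of real pipelines, not an
error. Synapse glyphs are blocks (presynaptic), octahedrally subdivided
spheres (postsynaptic) and 6-spike octahedral stars (electrical) — the
star's exact geometry is a package convention, as only the shape family is
standard — centered at the annotated coordinate and scaled by
`base_size_nm` times the per-annotation factor. Alignment across specimens
is vertex-wise `scale * (rotation %*% v)` with orthonormality checked to
1e-6.

OBJ input/output uses `v`/`f` records with 1-based indices; coordinates are
written at 9 significant digits, so round-trips preserve vertices to
better than 1e-6 relative.

## 5. Synthetic data: what it does and does not show

`make_tube_phantom()` builds disk-cross-section tubes with exact analytic
ground truth for every pixel, which is what allows *exact* oracle
equivalence tests of the contact counts. `make_planted_adjacency()` draws
within-block weights from N(100, 10) and between-block weights from
N(1, 1) (negatives clipped to zero), with 4 blocks of 10 as the default
recovery benchmark — block structure with a clean scale separation, sized
like the strata of a small neuropil. `make_point_cloud()` provides Gaussian
blobs for testing the condensation primitives on raw coordinates.

These generators deliberately do **not** emulate realistic neurite
morphology, EM noise, segmentation errors, heavy-tailed contact-size
distributions, or partial-volume effects. Passing tests therefore
demonstrate algorithmic correctness (counts match definitions, hierarchies
are nested, planted structure at a 100:1 weight contrast is recovered),
not robustness to the messiness of real segmentations; on real data the
stratum count and membership depend on contact-profile quality and the
bandwidth schedule, and borderline neurons can legitimately move between
strata across datasets.

## 6. Degenerate inputs, tolerances, problem sizes

- Empty masks: `expand_region` returns the mask unchanged with a warning;
  volumes with no nonzero labels are errors.
- All-identical rows at ε computation are an error (degenerate input);
  all-zero pairwise distances at bandwidth selection fall back to the last
  positive bandwidth.
- Zero affinity row sums (isolated clusters with no contacts) are errors
  naming the row, both in the diffusion operator and the C-PHATE kernel.
- Adjacency CSV input: relative asymmetry above 1e-6 is an error; below,
  the matrix is symmetrized by the mean with a logged notice. Columns are
  realigned to rows by label, never by position.
- Stochastic matrices are validated to row sums within 1e-9.

Test and acceptance runs use 40-neuron planted matrices (20 instances for
recovery), two-tube phantoms of 26 x 40 px with 2–3 slices against the
exhaustive pixel oracle, and a 30 x 24 x 20-voxel cuboid for mesh accuracy:
sizes chosen so that exact brute-force oracles (which are quadratic or
worse) remain the comparison standard while exercising every code path; the
full suite completes in well under a minute.

## 7. Known limitations

- The bandwidth schedule is a documented package choice; other condensation
  implementations will produce different iteration-by-iteration traces
  (though similarly structured hierarchies).
- The shared-pixel definition counts partner pixels covered by the
  expansion; a pixel-pair-within-distance definition would differ on thin
  (<= 2 px) structures.
- The contact outline estimator overestimates diagonal perimeters (above).
- The default embedding backend is PHATE-family, not PHATE: coordinates are
  not comparable across backends, only the topology of the trajectories.
- XLSX adjacency input is not supported; convert to CSV.
- Labels above 65535 cannot be stored in the 16-bit image formats used for
  label stacks.
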