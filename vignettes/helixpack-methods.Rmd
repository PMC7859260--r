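---
title: "Methods: quantifying transmembrane helix self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transmembrane helix self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixpack)
```

## The analysis problem

Coarse-grained (Martini-level) self-assembly simulations of 36
transmembrane (TM) helices in a lipid patch produce microseconds of
trajectory in which helices form and break dimers, trimers and higher
oligomers. `helixpack` turns such trajectories — and multi-model NMR
ensembles treated as pseudo-trajectories, one frame per model — into
quantitative assembly descriptors. Every representation is built on one
primitive: the ordered backbone (BB) bead trace of each helix, one bead
per residue, coordinates in nm. For NMR ensembles the CA atom stands in
for the BB bead; the Martini BB bead sits at the backbone centre of mass,
within ~0.07 nm of the CA, negligible at the 0.5–1.5 nm scales analysed
here.

Two assumptions run through the whole chain:

* **The membrane normal is Z.** Orientation vectors and radial maps live
  in the XY plane. Helices tilted more than 80° away from Z have no
  meaningful in-plane frame and are flagged invalid (skipped and counted)
  rather than contributing garbage.
* **Orthorhombic periodic boxes.** All distances use the minimum-image
  convention; NMR-derived frames carry no box and are treated as
  non-periodic.

## Contact matrices

A contact is an inter-helix residue pair whose BB beads lie at distance
less than or equal to the cut-off (the boundary is inclusive). Counts are
accumulated over both orderings of every helix pair, so the matrix is
symmetric by construction and raw totals are twice the unordered count —
the double sum over helices does not specify an ordering convention, and
the normalized matrix (each entry divided by the maximum) is identical
either way. Defaults follow the two-interface logic of the TNFR systems:
0.5 nm resolves tight dimeric interfaces, 0.8 nm the looser trimeric
ones. At CG resolution 0.4 nm lies inside the bead exclusion radius and
detects nothing; beyond ~1 nm specificity is lost. The implementation is a
dense vectorized accumulation; at the study scale (36 helices × ~35
residues ≈ 1260 beads per frame) this is a ~12 MB boolean problem per
frame and needs no spatial indexing. Its correctness contract is exact
agreement with an explicit O(H²N²) brute-force loop, which the test suite
enforces on bundles up to 6 × 30 residues, periodic and non-periodic, at
both cut-offs.

## Body-fixed frames and radial maps

The reference point of a helix is the centroid of its interface residue
triplet, `C_i = (r_{i−1} + r_i + r_{i+1})/3`. Widening to two residues per
side moves the centroid by ~0.1 nm on an ideal helix (the two estimates
sit on opposite sides of the axis) — below the bead scale and without
consequence for any 1.5 nm criterion, so the triplet default stands. The
in-plane orientation is the bisection vector of the two bonds leaving the
central bead, `v = (r_{i−1} − r_i) + (r_{i+1} − r_i)`, projected on XY and
normalized; on a regular helix it points from the surface residue inward
toward the axis, which fixes the sign convention. A projected norm below
10⁻³ nm (beads collinear in Z) invalidates the frame.

Interface residues per system (author numbering): S258/I259/L260 for p75,
L181/L182/P183 for Fas, V218/T219/V220 for DR5, with G217 as the
alternative centre for the DR5 dimer interface
(`default_center_residue()`).

Neighbour centroids, expressed in each reference helix's frame (origin at
the centroid, +X along the orientation vector) and accumulated every
100 ns (each tick maps to the nearest stored frame at or after it), form
the radial cloud. The density map is a fixed-bandwidth Gaussian kernel
density on a regular grid (default bandwidth 0.1 nm, step 0.05 nm, extent
±3 nm), scaled to integrate to the number of points on the grid; the
bandwidth is a display parameter only — every census quantity is computed
from the raw points, so no result depends on the estimator.

## Census: distance plus relative orientation

For an ordered helix pair the descriptor is (distance, α, β): the XY
minimum-image centroid distance, the angular position of the neighbour in
the reference frame, and the counterclockwise in-plane angle β from the
reference orientation vector to the neighbour's. β is the symmetry
fingerprint: exactly 180° for the protomers of a C2 dimer and exactly
120°/240° for adjacent protomers of a C3 trimer, independent of the
assembly's global pose. β is kept signed (mod 360) so that 120° and 240°
remain distinguishable.

Census criteria (defaults in parentheses):

* **first orbit / d_max (1.5 nm)** — the innermost ring of the radial
  map, where direct-contact partners sit;
* **β tolerance (25°)** — chosen so the 120/180/240 windows cannot
  overlap (gaps of 60° > 2 × 25°), making the C2 and C3 categories
  disjoint with no tie-breaking;
* **closed trimer** — a 3-cycle of C3-compatible pairs whose signed betas
  taken around the cycle sum to 0 mod 360° within 3 × 25°. The cyclic
  consistency test is this package's operational definition of "trimer";
  an ideal trimer gives 120° × 3 = 360° exactly, while a spurious
  3-clique of mixed orientations fails it.

Association records convert the per-frame census into lifetimes: an
interval opens when a member set (pair or triple) first satisfies its
criterion and closes when it fails for more than `gap_tolerance`
consecutive strides (default 0, strict — no interval bridging is assumed),
each qualifying stride contributing `dt` of association time. First-orbit
spots are isolated by density-based clustering (DBSCAN with eps 0.25 nm,
minimum cluster size max(5, 1% of in-orbit points)); cluster parameters
are config knobs and validation relies on planted ground truth, never on
parameter-sensitive absolute counts. The Markov transition matrix counts,
for every ordered pair, its cluster-label transitions between consecutive
strides; rows with no outgoing counts are flagged rather than normalized.

## Structure comparison

Superposition is the least-squares Kabsch algorithm (SVD with determinant
correction). Oligomer-against-oligomer RMSD minimizes over all chain
correspondences — exhaustive search, at most 6! = 720 permutations at the
assembly sizes handled. The Cn symmetry axis is placed through the
assembly centroid along the Z-dominant principal direction of the bead
cloud; per-protomer azimuth gaps against 360/n measure the symmetry
deviation. R/T/A RMSD expresses each per-bead deviation in the local
orthonormal cylindrical basis about that axis (radial out from the axis,
tangential, axial along it), so the Pythagorean identity
R² + T² + A² = RMSD² holds to rounding; beads on the axis are excluded
and counted. Comparisons are made at CG bead level directly — no
backmapping to all-atom structures — so absolute RMSD values are not
comparable to all-atom alignment figures.

## Membrane diagnostics

Area per lipid is the projected form `2·box_x·box_y / N_lipids`, without
protein-area correction: with 36 helices in a 625 nm² patch the protein
bias is a few percent, and the projected form is the simplest defensible
estimator when the true protein cross-section is not tracked. Thickness is
the separation of the two leaflet head-bead mean z positions (leaflets
split at the overall mean z) — robust at small patch sizes, where density
profile peaks are noisy. Convergence is declared at the earliest time from
which `k` consecutive window means (default 3 windows) agree pairwise
within a relative tolerance (default 2%); this windowed criterion is an
operational reconstruction — the choice of metric is not standardized —
and supports the practice of analysing self-assembly only after the
membrane has settled (from 3 μs onward in the reference systems).

## What the synthetic generator does and does not emulate

`generate_trajectory()` realizes the reference system geometry: 36
helices on an even grid in a 25 × 25 × 10 nm box (spacing box/√36 ≈
4.17 nm), each randomly oriented about Z, with planted C2 / C3 /
dimer-of-trimer assemblies at well-separated grid cells, independent
per-frame rigid-body Gaussian jitter, bounded uniform orientation noise,
and optional per-assembly on/off schedules (scheduled-off members are
displaced 1.25 nm radially apart, far enough to break every census
criterion while staying clear of neighbouring cells). Helix geometry is
the canonical α-helix parameterization (rise 0.15 nm/residue, twist
100°/residue, helical radius 0.23 nm). The output is a deterministic
function of the spec and seed.

What it is **not**: an MD surrogate. There are no energetics, no lipid or
water degrees of freedom, no diffusion, no assembly kinetics — jitter is
temporally uncorrelated. Passing the planted-recovery tests therefore
demonstrates that the *analysis chain* is correct (geometry, criteria,
bookkeeping, invariances), not that any simulation result is reproduced.
Absolute oligomer counts and microsecond association times from real CG
runs are expressly out of reach at desk scale and are never asserted.

## Numerical and design choices

* Coordinates in nm internally; PDB Å converted on read/write; TRR times
  stored in ps (converted to ns on load).
* Contact boundary inclusive (`≤ d_cut`); degenerate all-zero matrices
  normalize to themselves with a warning flag.
* Frames without a box (NMR) default to 25 × 25 × 10 nm and are flagged
  non-periodic; minimum-image wrapping is skipped for them.
* Under periodic boundaries, global rotations are exact symmetries of the
  analysis only when they map the box to itself (multiples of 90° for the
  square patch); the invariance tests use 90° + translation on periodic
  frames and arbitrary rotations on non-periodic ones.
* Default analysis window: all loaded frames. For production runs the
  settled window (3000 ns to end) is passed explicitly; NMR pseudo
  trajectories are analysed whole.
* `contact_matrix` requires equal residue counts across helices (one
  peptide variant per matrix), as the residue-pair indexing is
  sequence-local.
* Test and acceptance problem sizes: brute-force contact oracles on ≤ 6
  helices × 30 residues × 2 frames; planted-recovery on 36 helices × 200
  frames (jitter σ 0.05 nm, orientation noise 10°, recovery ≥ 95% with
  zero false trimers); all other properties on comparably small fixtures.
  These sizes exercise every code path at full study geometry while
  keeping the suite fast.

## Known limitations

* XTC trajectories are not read (the lossy xdr3dfcoord codec is not
  implemented); use TRR or multi-frame GRO.
* Double-precision TRR files are rejected (CG production output is single
  precision).
* No side-chain beads: all criteria operate on BB beads, as the contact
  and radial definitions require.
* The asymmetric third helix of a forming trimer (a 3-clique failing
  cyclic consistency) is not classified further — only flagged by its
  absence from the closed-trimer list.
* No kinetic modelling: the Markov matrix is a descriptive summary at the
  analysis stride, not an estimated MSM with lag-time selection.
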