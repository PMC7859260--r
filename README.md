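# helixpack

Analysis of transmembrane-helix self-assembly in coarse-grained (CG)
membrane simulations.

Single-pass transmembrane (TM) helices of TNF-receptor superfamily members
(p75/TNFR16, Fas/CD95, DR5/TNFRSF10B) self-associate in the membrane into
dimers, trimers and dimers of trimers, and the oligomeric state of the TM
region is part of the receptors' signalling mechanism. Micro-second Martini
CG simulations of 36-helix membrane patches sample these assemblies, but
deciding *which* helices form *which* oligomer, with what interface,
symmetry and lifetime, requires an unbiased analysis chain. `helixpack`
implements that chain for anyone running CG self-assembly simulations of
TM helix bundles (or analysing multi-model NMR ensembles as pseudo
trajectories):

* **Contact matrices.** For every ordered helix pair (H, K ≠ H) and residue
  pair (i, j), `NC_ij = Σ_T Σ_H Σ_{K≠H} C_ij^{HK}` counts frames in which
  the backbone (BB) beads of residues i and j lie within a cut-off
  (inclusive, minimum-image): `C_ij^{HK} = 1` iff `‖r_i^K − r_j^H‖ ≤ d_cut`.
  Two cut-offs (0.5 and 0.8 nm) resolve the tighter dimeric and looser
  trimeric interfaces; 0.4 nm detects nothing at CG resolution and 1 nm
  loses specificity. Matrices are normalized to the most frequent contact,
  `NC_ij / max(NC_ij)`.
* **Radial density maps.** Each helix gets a body-fixed frame: origin at
  the centroid of the reference residue triplet,
  `C_i = (r_{i−1} + r_i + r_{i+1})/3`, and X-axis along the in-plane
  bisection (orientation) vector `v = (r_{i−1} − r_i) + (r_{i+1} − r_i)`.
  Neighbour centroids accumulated in this frame over time (default every
  100 ns) give the radial map whose first orbit (< 1.5 nm) holds the
  direct-contact partners.
* **Oligomer census.** A neighbour at distance ≤ 1.5 nm with relative
  orientation β ≈ 180° is a C2 dimer partner; β ≈ 120°/240° is
  C3-compatible; a 3-cycle of C3-compatible pairs whose betas close the
  cycle (Σβ ≡ 0 mod 360°) is a closed trimer. Per-pair/per-triple
  association intervals, accumulated and longest lifetimes, first-orbit
  spot clustering (density-based) and a Markov transition matrix over the
  spots summarize the assembly dynamics.
* **Structure comparison.** Kabsch superposition onto NMR references
  (over all chain correspondences for oligomers), ensemble averaging of
  multi-model PDB files, Cn symmetry-axis fitting, and decomposition of
  the deviation into radial/tangential/axial (R/T/A) RMSD components
  about the symmetry axis.
* **Membrane diagnostics.** Projected area per lipid
  (`2·box_x·box_y / N_lipids`), head-bead bilayer thickness, and the
  windowed convergence check used to justify analysing from 3 μs onward.
* **Synthetic generator.** Deterministic, ground-truth-labelled 36-helix
  bundle trajectories (planted C2/C3/dimer-of-trimer assemblies,
  rigid-body jitter, orientation noise, on/off schedules) that validate
  every step of the chain without a CG engine.

File formats: multi-model PDB (read via `bio3d`, written natively), GRO
(single and multi-frame) and single-precision TRR. All coordinates are
handled in nm.

## Worked example

Plant one C2 dimer (axis distance 1.4 nm) and one C3 trimer in a 36-helix
patch with realistic jitter, then run the census and clustering:

```r
library(helixpack)

spec <- synthetic_spec(
  planted = list(list(type = "C2", pair_distance = 1.4), list(type = "C3")),
  jitter_sigma = 0.05, orientation_noise = 10,
  n_frames = 50, dt_ns = 100, seed = 42)
sim <- generate_trajectory(spec)

cen <- oligomer_census(sim$trajectory, center_residue = 15, stride_ns = 100)
cen
#> Oligomer census over 50 frames (dt 100 ns; d_max 1.5 nm, beta_tol 25 deg)
#>   mean per frame: 0.64 C2 pairs, 3.00 C3-compatible pairs, 1.00 closed trimers

cl <- radial_cloud(sim$trajectory, center_residue = 15, stride_ns = 100)
cluster_spots(cl, eps = 0.12)
#> First-orbit spot clusters (< 1.5 nm, eps 0.12 nm): 3 clusters, 62637 points outside
#>   label   n     x     y alpha mean_distance beta_mode
#> 1     1  64 1.087 0.888 39.25          1.41       180
#> 2     2 150 1.051 0.129  7.02          1.07       120
#> 3     3 149 0.412 0.976 67.13          1.07       240
```

The trimer is recovered in every frame (3 C3-compatible pairs closing into
1 trimer). Its two first-orbit spots sit 1.07 nm from the reference helix
with β concentrated at 120° and 240° — the C3 fingerprint. The planted
dimer sits at 1.41 nm with β ≈ 180°, and because its distance rides the
1.5 nm orbit boundary under jitter it is only counted in 64 % of frames;
the association records show the resulting intermittency:

```r
association_records(cen, "c2")
#> Association records (c2): 1 member sets over 2 helices
#>   accumulated 3200.0 ns, mean interval 213.3 ns, longest 600.0 ns

markov_transitions(cl, cluster_spots(cl, eps = 0.12))
#> Markov transition matrix over radial clusters (4 states)
#>         spot1 spot2 spot3 outside
#> spot1   0.548     0 0.000   0.452
#> spot2   0.000     1 0.000   0.000
#> spot3   0.000     0 0.993   0.007
#> outside 0.000     0 0.000   1.000
```

The stable trimer spots have self-transition probabilities near 1, the
flickering dimer spot much lower — the qualitative Markov signature of
stable oligomer clusters.

Real trajectories load the same way via
`load_cg_trajectory("system.gro", "traj.trr", helix_grouping = ...)`, NMR
ensembles via `load_multimodel_structure("2mic.pdb", ...)`, and the
peptide constructs (sequences, author numbering, interface reference
residues) come from `peptide_registry()` / `default_center_residue()`.

A command-line front end is installed with the package
(`exec/helixpack`):

```sh
Rscript exec/helixpack census --config run.yaml --outdir out/
```

writing CSV/JSON results plus a manifest with parameters, seed and output
checksums.

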