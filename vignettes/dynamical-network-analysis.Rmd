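---
title: "Methods: dynamical networks, rigidity, and conservation in lattice-like assemblies"
author: "dynacomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamical networks, rigidity, and conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters and why
their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the numerical and design choices made where the
method left room.

## The problem

Microtubule walls are sheets of protofilaments: rows of alternating
alpha/beta-tubulin monomers coupled strongly along each protofilament
(longitudinally, with intra-dimer contacts tighter than inter-dimer ones)
and more weakly between protofilaments (laterally). Most lateral
interfaces are homotypic ("B-type"); at the seam the lattice is offset
and the lateral contact is heterotypic ("A-type") and weaker. How
mechanical perturbations propagate through such a wall — and how the seam
reroutes them — is naturally phrased as a network question over a
molecular-dynamics ensemble: which residues and residue–residue contacts
carry the correlated motion?

`dynacomm` implements that analysis chain for any multi-chain assembly:
conformational stability checks (RMSD, RMSF, frame clustering), contact
and interaction profiling between subunit groups, a correlation-weighted
dynamical network with centrality-based pathway extraction, per-residue
rigidity (force constants), and sequence conservation, orchestrated by a
single pipeline over one or more systems.

## The dynamical network

**Nodes.** One node per residue: the C-alpha for amino acids, a
configurable representative atom for ligands (default: the beta-phosphorus
of GTP/GDP). Chains that were position-restrained during the simulation
carry no physical fluctuation information, so they are excluded from the
network (`select_nodes(exclude_chains = ...)`). Whether nucleotide
ligands should be nodes is a genuinely open choice; the default includes
them, and `include_ligands = FALSE` drops them.

**Edges (contact gating).** An edge joins residues i and j when any
heavy-atom pair of the two residues is within `contact_cutoff` (default
0.45 nm) in at least `contact_fraction` (default 0.75) of the frames.
Covalently adjacent residues (i, i±1 within a chain) never form edges:
their backbone correlation is trivially high and would otherwise dominate
every path. Both gates are config keys; the defaults are the conventional
choices of residue-level network analysis rather than values the method
itself prescribes.

**Weights (generalized correlation).** Pearson correlations of
displacement vectors miss nonlinear and orthogonal-direction coupling.
Instead each edge carries the mutual-information-based generalized
correlation
$$ w_{ij} = \sqrt{1 - e^{-2 I_{ij} / 3}} \in [0, 1], $$
where \(I_{ij}\) is the mutual information between the two 3D displacement
series (dimensionality 3 gives the factor 3). \(I\) is estimated with the
Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator (KSG-1,
Chebyshev norms, compiled in C++; `knn_k` default 5). For jointly Gaussian
series with per-axis correlation \(\rho\),
\(I = -\tfrac32 \ln(1-\rho^2)\), so \(w = \rho\) exactly — which is what
makes the estimator testable against Gaussian synthetic data: at 5000
frames the recovery error stays within ±0.05 across
\(\rho \in \{0, 0.4, 0.8\}\), and an estimator floor of ~0.05–0.1 for
truly independent series is expected and tested. Displacements are
mean-centered per node; a deterministic jitter of relative magnitude
1e-8, seeded from the network seed, breaks exact distance ties (the
estimator is rank-based, so sub-tolerance jitter does not move the
estimate). Zero-variance (restrained) series would make the estimator
meaningless; they are defined as correlation 0 with a warning. At least
100 frames are required.

**Degree and betweenness.** Weighted degree \(dg_i = \sum_j A_{ij} w_{ij}\)
measures local influence. For pathways, the optimal ("communication-wise
shortest") path between two nodes is the one that maximizes the *product*
of edge correlations, computed as the minimum of additive edge lengths
\(-\log w_{ij}\). A "sum of correlations" reading of optimality is
ill-posed — adding edges to a path can only raise the sum, so the
maximum-sum path is typically the longest — whereas the product
convention is the standard one for correlation-weighted residue networks;
the package adopts it. Betweenness counts optimal paths:
\(\sigma(s,t)\) optimal paths per unordered pair, \(\sigma(s,t|i)\) of
them through node i (or edge e), accumulated with Brandes' algorithm on
a tie-tolerant shortest-path DAG (relative tolerance 1e-9 on path
lengths, so float noise neither splits nor merges genuine ties). Raw sums
are normalized to [0, 1] by \(2/((n-1)(n-2))\) for nodes and
\(2/(n(n-1))\) for edges. (The printed form of the normalization in the
method literature divides by C while defining C as the standard
multiplicative factor; multiplying is the reading that lands in [0, 1]
and is what the package does.) Edges with weight 0 have infinite length
and are excluded from path finding; disconnected pairs contribute
nothing, with each component handled per se. Correctness is anchored by
an exhaustive simple-path-enumeration oracle: on random weighted graphs
of up to 6 nodes, node and edge betweenness agree with enumeration to
1e-12.

**Thresholding.** Ranked edge-betweenness curves are heavy-tailed; the
interesting edges sit above the knee. The knee is the point of maximum
perpendicular distance from the chord joining the first and last points
of the rank-vs-value curve; across systems, the *lowest* per-system knee
value is the shared threshold, so the same bar applies everywhere. An
exactly linear curve has no knee; the function warns and returns the last
value. `top_edges()` reports the above-threshold edges with chain-
interface annotations and per-chain betweenness distributions.

## Contacts and interactions

`contact_frequency()` reports, per residue pair across two disjoint
groups, the fraction of frames with any heavy-atom pair within the cutoff
(0.45 nm default), plus per-residue marginals (contact with *any* partner
residue). `contact_difference()` subtracts marginals between systems
(absent residues count 0), the standard seam-localization map.

`classify_interactions()` types non-covalent interactions geometrically,
frame by frame:

* salt bridge — charged-group centroid distance ≤ 0.55 nm between
  {Lys-NZ, Arg-NE/NH1/NH2, His ring N if `his_protonated`} and
  {Asp-OD1/OD2, Glu-OE1/OE2, nucleotide phosphate oxygens};
* hydrogen bond — donor–acceptor heavy-atom distance ≤ 0.35 nm, and the
  D–H...A angle ≥ 130° whenever the topology contains hydrogens
  (distance-only otherwise, flagged in the output — synthetic and
  coarse-grained inputs lack hydrogens);
* hydrophobic — apolar-carbon pair distance ≤ 0.40 nm over per-residue
  apolar atom tables.

These thresholds follow common interaction-profiler conventions; the
reference analyses delegate to an external profiler whose exact criteria
are not printed, so all four are config keys and the defaults are
documented conventions, not asserted equivalences. Residues outside the
chemistry tables are skipped with a warning. `stable_interactions()`
keeps interactions whose mean frequency across systems is **strictly**
greater than 0.75 (mean 0.75 is excluded; a pair absent from a system
counts 0 there).

## Conformation

RMSD series superpose each frame onto the reference (frame 1) over the
same selection before measuring. Frame clustering builds the pairwise
superposed-RMSD matrix and cuts an agglomerative tree at 0.15 nm, the
conventional cutoff at which a structurally stable trajectory yields one
cluster. The linkage criterion is not dictated by the method; average
linkage is the default (least cutoff-sensitive of the common choices),
with single/complete as options. The pairwise matrix is O(F²), so a
configurable stride subsamples frames, and a `max_frames` guard (default
2000) refuses pathological sizes rather than thrashing.

## Rigidity (force constants)

For residue i, \(d_i(t)\) is the mean distance to all other included
nodes at frame t, and
$$ k_i = \frac{3 k_B T}{\langle (d_i - \langle d_i \rangle)^2 \rangle} $$
with \(k_B = 0.0083144621\) kJ mol⁻¹ K⁻¹ and T defaulting to 300 K
(config key — rigidity scales linearly in T, so reported values always
state it). Whether sequence neighbours should be excluded from the mean
varies between variants of the method; the default excludes none and
`exclude_window` exposes the choice. Residues with zero distance variance
(fully static inputs) are flagged NA rather than infinite. Multi-system
profiles report mean and min–max envelope per residue, the standard
presentation. Two properties pin the implementation: exact agreement with
the closed form on a fixed-variance series (0.1%), and invariance under
global rotation/translation (distances are internal coordinates).

A note on validating the estimator against a harmonic well: a probe
sampled from the Boltzmann distribution of an isotropic well of stiffness
k has per-axis variance \(k_B T / k\). Any mean-of-distances observable
is 1-Lipschitz in the probe position, so its variance can never exceed
the largest per-axis variance (Gaussian Poincaré inequality); with a
tight, distant anchor cluster the bound is attained,
\(\mathrm{var}(d) = k_B T / k\), and the estimator reads exactly
\(3k\). `gen_harmonic_ensemble()` therefore records
`k_estimator_expected = 3 k_design` in its ground truth, and the recovery
tests assert agreement with that oracle-derived value (within 10% at
50,000 frames) — the estimator's convention factor of 3 presumes the
probed coordinate captures all three degrees of freedom, which a single
distance cannot.

## Conservation

Columns of a FASTA alignment are mapped to six stereochemical classes
(aliphatic AVLIMC, aromatic FWYH, polar STNQ, basic KR, acidic DE,
special GP); the Shannon entropy of the class composition, normalized by
\(\ln 6\), gives NE ∈ [0, 1] with 0 = perfectly conserved class and 1 =
uniform over all classes. Gaps are excluded from the counts rather than
treated as a seventh class (the within-class substitution invariance —
replacing every L by V changes nothing — is the point of the
stereochemical grouping and is tested as such); columns with more than
50% gaps are flagged unreliable, and ambiguity codes (B/Z/X) are dropped
with a warning. `annotate_structure()` writes NE×100 into B-factors
(PDB's two-decimal field makes the round trip exact to 0.01) with a
sentinel (-1) for unmapped or sequence-mismatching residues.
`rigid_set_conservation()` compares the median NE of the rigid set
(\(k_i\) above the profile median) with the overall median, per chain.

## Synthetic ground truth

The generators exist so that every downstream stage has an analytic
target; they trade physical realism for exactness.

**Sheets.** `sheet_spec()` describes a grid: `n_rows` protofilament
analogs, each a row of `n_cols` monomer blocks alternating alpha/beta, one
chain per block, `beads_per_monomer` single-residue beads per block
(default 5: center plus four in-plane arms). Blocks move as rigid units —
per-axis Gaussian displacements with standard deviation
`fluctuation_sigma` (default 0.02 nm) — plus independent per-bead jitter
of sigma/10, so residue-level and block-level correlations agree to 1%.
The designed block–block correlation is the maximal product of couplings
along lattice paths (`coupling_long` 0.85 along rows, `coupling_lat` 0.7
between rows, `coupling_seam` at the seam column), an AR(1)-like decay
with lattice distance. The implied matrix is checked for positive
semi-definiteness (eigenvalue tolerance 1e-10) and rejected otherwise;
sampling goes through an eigendecomposition square root. Two consequences
are worth internalizing:

* the *realized* correlation of the seam pair is the maximum over paths,
  not the raw `coupling_seam` — a weakly coupled pair that shares strong
  neighbours co-moves through them (~0.51 for the defaults). Tests
  compare against `GroundTruth$correlation`, not the input couplings;
* geometry carries the other half of the seam phenotype: facing beads of
  adjacent blocks sit `contact_gap_nm` = 0.30 nm apart (inside the 0.45
  nm cutoff in every frame at the default fluctuation scale), while the
  seam interface is widened to `seam_gap_nm` = 0.50 nm, outside the
  cutoff, so its contact frequency collapses (analytically
  \(\Phi((0.45 - 0.50)/s_{rel}) \approx 0.03\)) and it fails the 75%
  network gate. That is the A-type analog: fewer lateral contacts, not
  merely weaker correlation. A seam whose contact *survives* the gate
  necessarily becomes a high-betweenness bridge — its correlation cannot
  drop below the around-path product, so the direct crossing always wins —
  which is why the generator realizes seam weakness geometrically.
  `GroundTruth$contact_pairs` records per-interface gap, analytic
  expected contact frequency, and the resulting expected edge set, so
  end-to-end tests compare the network against the design's own
  prediction.

Restrained blocks (`restrained_blocks`, the corner-anchor analog) have
exactly zero displacement and jitter and are meant to be excluded from
network analysis like their real counterparts.

**Other generators.** `gen_correlated_ensemble()` draws per-axis
multivariate Gaussian displacement series with an arbitrary PSD
correlation matrix (beads 2 nm apart, so no spurious contacts);
`gen_harmonic_ensemble()` is described above; `gen_two_state_ensemble()`
jitters tightly (sigma 0.02 nm) about two conformations separated by a
per-bead internal displacement (not a rigid-body move), recording the
frame-to-state assignment; `gen_toy_msa()` samples alignment columns
from explicit per-column letter distributions (gap fraction included).
All generators are deterministic in their seed, down to the written
files.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: no solvent or force-field physics, no periodic
boundaries, no anharmonic or multi-basin dynamics inside a state, no
side-chain chemistry beyond the residue-name tables (sheet beads are
C-alpha-only, so interaction typing on sheets is vacuous by design), no
sequence co-evolution, and rigid blocks rather than internally flexible
monomers. The synthetic results validate the estimators and the plumbing,
not the biology.

## Numerical choices and degenerate inputs

* Internal units are nm everywhere; PDB/DCD I/O converts to/from
  Angstrom. Residue numbering in reports follows the PDB (1-based).
  Frames and atoms are indexed 1-based, R-style.
* Path-length ties: relative tolerance 1e-9; PSD checks: eigenvalue
  tolerance 1e-10; KSG tie-breaking jitter: 1e-8 relative, seeded.
* Alignment uses a two-pass fit (frames onto frame 1, then onto the
  resulting mean) by default; collinear fit selections are rejected.
  For the drift-free synthetic sheets the pipeline examples disable
  alignment: least-squares superposition of a fully positively
  correlated lattice removes the common displacement mode and shrinks
  pairwise correlations well below the design (0.7 lateral measures
  ~0.27 aligned vs ~0.65 unaligned). With real trajectories, where
  rigid-body diffusion dwarfs internal motion, alignment is essential
  and the measured correlations are by definition post-alignment ones.
* Equilibration is cut in frames per replica (`equil_frames`), since
  converting a time cut requires the output cadence; the CLI/config
  layer leaves that conversion to the user.
* Degenerate cases have defined behaviour rather than NaNs: empty
  networks error with the gate parameters, zero-variance correlation is
  0 with a warning, zero-variance rigidity is NA, all-gap columns are
  flagged, linear knee curves warn and return the last value.

## Problem sizes

The test-suite and acceptance runs use sizes chosen to make sampling
error visibly smaller than the tolerances while keeping a laptop-scale
footprint: 5000 frames for correlation recovery (estimator s.e. ~0.01),
50,000 frames for force-constant recovery (variance s.e. ~0.6%), 100
random graphs of ≤ 6 nodes for the betweenness oracle, 500-frame 2 x 6
sheets (60 residues, ~87 edges) for the end-to-end seam analysis, and
160-frame two-state ensembles for clustering. Pairwise-RMSD clustering in
the pipeline uses a stride of 10.

## Known limitations

* Trajectory input is DCD-only (plus PDB topologies); the DCD writer is
  single-precision CHARMM format without unit cells, and no
  periodic-boundary unwrapping is performed.
* The KSG estimator is O(F²) per edge; for very long trajectories,
  subsample frames before `build_network()`.
* Interaction typing depends on standard residue/atom naming; exotic
  protonation states beyond the His flag are not modelled.
* Knee detection assumes a single dominant corner in the ranked curve;
  multi-scale curves yield the global corner only.
* Sequence weighting (redundancy correction) in conservation scoring is
  not implemented; highly redundant alignments overweight their majority
  clade.
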