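# dynacomm

Trajectory-based analysis of **mechanical communication in lattice-like
protein assemblies**, built around the tubulin-sheet problem: how do
mechanical vibrations propagate through a wall of laterally and
longitudinally coupled subunits, and what changes at a seam-like (A-type)
lateral interface compared with the regular (B-type) one?

The package is aimed at structural-bioinformatics users who have molecular
dynamics trajectories of a multi-chain assembly (topology as PDB, replicas
as DCD) and want, from one configuration file or a handful of function
calls:

* **Dynamical networks** — residues as nodes; an edge joins residues i, j
  when they are in heavy-atom contact (cutoff 0.45 nm) in at least 75% of
  frames; each edge is weighted by the *generalized correlation
  coefficient*
  `w_ij = sqrt(1 - exp(-2 I_ij / 3))`, with the mutual information `I_ij`
  of the two 3D displacement series estimated by a Kraskov k-nearest-
  neighbour estimator. For jointly Gaussian motions with per-axis
  correlation `rho`, `w_ij = rho` exactly.
* **Communication pathways** — weighted degree `dg_i = sum_j A_ij w_ij`;
  node and edge betweenness over optimal paths that maximize the product
  of edge correlations (additive edge lengths `-log w_ij`), normalized by
  `2/((n-1)(n-2))` (nodes) and `2/(n(n-1))` (edges); knee-point
  thresholding of the ranked edge-betweenness curve, with the lowest knee
  across systems as the shared cutoff.
* **Contacts & interactions** — residue-pair contact frequencies,
  geometric typing of salt bridges / hydrogen bonds / hydrophobic
  contacts, a strict `mean frequency > 0.75` stability filter across
  systems, and per-residue contact-difference maps between systems.
* **Rigidity** — per-residue force constants
  `k_i = 3 k_B T / var(d_i)`, where `d_i(t)` is residue i's mean distance
  to all other residues, plus the comparison of the rigid set
  (`k_i > median k`) with evolutionary conservation.
* **Conservation** — normalized stereochemically sensitive Shannon
  entropy per MSA column (six classes: AVLIMC / FWYH / STNQ / KR / DE /
  GP), `NE = H / ln 6` in [0, 1], mapped onto structure B-factors.
* **Synthetic ground truth** — generators for correlated Gaussian
  ensembles, harmonic-well probes, two-conformation ensembles, toy MSAs,
  and full tubulin-like sheets (grids of rigid monomer blocks with
  stronger longitudinal than lateral coupling, optional weak seam column,
  restrained corners) whose correlation structure and contact geometry
  are known analytically, so every stage of the pipeline is testable
  without external data.

## Worked example

Generate a 2 x 6 tubulin-like sheet with a weak lateral column (coupling
0.2 vs 0.7, the A-type/seam analog), build its dynamical network, and
extract the top communication edges:

```r
library(dynacomm)

spec  <- sheet_spec(n_rows = 2, n_cols = 6, coupling_lat = 0.7,
                    coupling_seam = 0.2, seam_col = 3,
                    n_frames = 500, seed = 1)
sheet <- gen_toy_sheet(spec)
sheet$system
#> MolecularSystem: 60 atoms, 12 chains, 500 frames, 1 replica(s)

nodes <- select_nodes(sheet$system)
net   <- build_network(sheet$system, nodes)
net
#> DynamicalNetwork: 60 nodes, 87 edges ( contact cutoff 0.45 nm, fraction >= 0.75 )
#>   edge weights: min 0.648  median 0.952  max 0.955

rep <- betweenness_centrality(net)
kn  <- knee_threshold(sort(rep$edge_betweenness$betweenness,
                           decreasing = TRUE))
round(kn, 4)
#> [1] 0.0475
top <- top_edges(net, rep, kn)
head(top$edges[, c("chain_i", "resid_i", "chain_j", "resid_j",
                   "weight", "betweenness", "cross_chain")])
#>    chain_i resid_i chain_j resid_j    weight betweenness cross_chain
#> 70       J       2       J       5 0.9530439   0.3000000       FALSE
#> 72       J       2       K       3 0.8036307   0.2994350        TRUE
#> 64       I       2       J       3 0.7789284   0.2949153        TRUE
#> 57       H       2       I       3 0.7984566   0.2740113        TRUE
#> 62       I       2       I       5 0.9541152   0.2728814       FALSE
#> 71       J       3       J       5 0.9531030   0.2706215       FALSE
```

Chains A–F are the first protofilament row, G–L the second; the seam
column (chains C and I) contributes **no** lateral edge — its widened,
weakly coupled interface fails the 75% contact gate — and the
top-betweenness lateral edges (e.g. J2–K3, I2–J3) sit away from the weak
column, while edge weights separate the strong intra-block couplings
(~0.95) from inter-block ones (~0.65–0.85). Comparing this sheet against
a uniform one with `contact_difference()` localizes the contact loss
(about -0.99 in marginal frequency) to the two seam residues.

The same analyses run end-to-end from a YAML config:

```sh
inst/cli/dynacomm simulate --seed 7 --seam-col 3 --out sheets/
inst/cli/dynacomm run-all --config config.yaml --out results/
```

or from R via `run_pipeline(load_config("config.yaml"))`, which writes
CSV/GraphML/JSON tables (RMSD, clusters, contacts, interactions, network,
centralities, knee threshold, top edges, force constants, conservation)
plus a manifest with parameter echo and output hashes.

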