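# Synthetic systems with known statistical structure: correlated Gaussian
# ensembles, harmonic-well probes, two-state ensembles, tubulin-sheet-like
# bead lattices, and toy MSAs. Every generator records its design as ground
# truth so downstream analyses can be validated without external data.

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(seed))
  expr
}

chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("too many chains for single-character ids")
  pool[seq_len(n)]
}

check_correlation_matrix <- function(C, tol = 1e-10) {
  if (!isSymmetric(unname(C), tol = 1e-12)) stop("correlation matrix is not symmetric")
  if (any(abs(diag(C) - 1) > 1e-12)) stop("correlation matrix diagonal is not 1")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  }
  invisible(ev)
}

# sample n_frames draws of an N-dim Gaussian with correlation C (unit sd)
sample_mvn <- function(C, n_frames) {
  ev <- eigen(C, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(C))
  matrix(stats::rnorm(n_frames * nrow(C)), n_frames) %*% t(L)
}

#' Correlated Gaussian displacement ensemble
#'
#' N single-bead residues whose per-axis displacement series are
#' multivariate normal with the given correlation matrix (axes
#' independent); the ground truth for validating the generalized
#' correlation estimator. Beads sit 2 nm apart so no spurious contacts
#' arise.
#'
#' @param correlation_matrix symmetric, unit-diagonal, positive
#'   semi-definite N x N matrix.
#' @param n_frames number of frames.
#' @param seed RNG seed (same spec + seed = identical coordinates).
#' @param sigma per-axis displacement standard deviation in nm.
#' @return a `MolecularSystem` with attribute `design` (the correlation
#'   matrix).
#' @export
gen_correlated_ensemble <- function(correlation_matrix, n_frames, seed,
                                    sigma = 0.1) {
  C <- as.matrix(correlation_matrix)
  check_correlation_matrix(C)
  n <- nrow(C)
  atoms <- data.frame(
    eleno = seq_len(n), elety = "CA", resid = seq_len(n),
    resname = "ALA", chain = "A", element = "C",
    stringsAsFactors = FALSE
  )
  base <- cbind(2 * (seq_len(n) - 1), 0, 0)
  xyz <- with_seed(seed, {
    out <- matrix(0, n_frames, 3L * n)
    for (ax in 1:3) {
      disp <- sample_mvn(C, n_frames) * sigma
      out[, seq(ax, 3L * n, by = 3L)] <-
        sweep(disp, 2L, base[, ax], `+`)
    }
    out
  })
  sys <- molecular_system(atoms, xyz)
  attr(sys, "design") <- C
  sys
}

#' Harmonic-well probe ensemble
#'
#' One probe bead sampled from the isotropic Boltzmann distribution of a
#' harmonic well of stiffness `force_constant` (per-axis coordinate
#' variance `kB * temperature / force_constant`), in front of a fixed,
#' tightly clustered cloud of distant anchor beads. Ground truth for the
#' force-constant estimator: with this far-cluster anchor geometry the
#' variance of the probe's mean distance to the anchors equals its
#' per-axis variance, so the `3 kB T / var` estimator is expected to read
#' `3 * force_constant` (recorded as `k_estimator_expected`).
#'
#' @param force_constant well stiffness in kJ mol-1 nm-2 (> 0).
#' @param temperature in K (> 0).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param n_anchors anchor bead count.
#' @param anchor_distance distance from probe to the anchor cluster (nm).
#' @param anchor_spread anchor cluster radius (nm).
#' @return a `MolecularSystem` (probe = chain P, anchors = chain X) with
#'   attribute `truth`: `k_design`, `axis_variance`,
#'   `k_estimator_expected`.
#' @export
gen_harmonic_ensemble <- function(force_constant, temperature, n_frames,
                                  seed, n_anchors = 24L,
                                  anchor_distance = 4, anchor_spread = 0.2) {
  if (force_constant <= 0) stop("force_constant must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  axis_var <- kB * temperature / force_constant
  n <- n_anchors + 1L
  atoms <- data.frame(
    eleno = seq_len(n), elety = "CA",
    resid = c(1L, seq_len(n_anchors)),
    resname = "ALA",
    chain = c("P", rep("X", n_anchors)),
    element = "C", stringsAsFactors = FALSE
  )
  xyz <- with_seed(seed, {
    anchors <- cbind(anchor_distance, 0, 0)[rep(1L, n_anchors), ] +
      matrix(stats::rnorm(3L * n_anchors, 0, anchor_spread), n_anchors)
    probe <- matrix(stats::rnorm(3L * n_frames, 0, sqrt(axis_var)),
                    n_frames)
    out <- matrix(rep(as.vector(t(anchors)), each = n_frames),
                  n_frames)
    cbind(probe, out)
  })
  sys <- molecular_system(atoms, xyz)
  attr(sys, "truth") <- list(k_design = force_constant,
                             axis_variance = axis_var,
                             k_estimator_expected = 3 * force_constant)
  sys
}

#' Two-conformation ensemble
#'
#' Frames fluctuate tightly about conformation A for the first half and
#' about conformation B - A shifted by `displacement` in internal
#' coordinates (per-bead directions, not a rigid-body move) - for the
#' second. Ground truth for conformational clustering.
#'
#' @param displacement internal displacement between the states (nm, >= 0).
#' @param n_frames_per_state frames per state.
#' @param seed RNG seed.
#' @param sigma within-state jitter sd (nm), much smaller than
#'   `displacement`.
#' @param n_beads bead count.
#' @return a `MolecularSystem` with attribute `state` (per-frame label
#'   1/2).
#' @export
gen_two_state_ensemble <- function(displacement, n_frames_per_state = 100L,
                                   seed = 1L, sigma = 0.02, n_beads = 10L) {
  if (displacement < 0) stop("displacement must be >= 0")
  atoms <- data.frame(
    eleno = seq_len(n_beads), elety = "CA", resid = seq_len(n_beads),
    resname = "ALA", chain = "A", element = "C",
    stringsAsFactors = FALSE
  )
  nf <- 2L * n_frames_per_state
  xyz <- with_seed(seed, {
    base <- matrix(stats::runif(3L * n_beads, 0, 2), n_beads)
    dir <- matrix(stats::rnorm(3L * n_beads), n_beads)
    dir <- dir / sqrt(rowSums(dir^2))
    shift <- dir * displacement
    shift <- sweep(shift, 2L, colMeans(shift)) # no net translation
    stateB <- base + shift
    out <- matrix(0, nf, 3L * n_beads)
    for (f in seq_len(nf)) {
      ref <- if (f <= n_frames_per_state) base else stateB
      out[f, ] <- as.vector(t(ref + matrix(stats::rnorm(3L * n_beads, 0,
                                                        sigma), n_beads)))
    }
    out
  })
  sys <- molecular_system(atoms, xyz)
  attr(sys, "state") <- rep(1:2, each = n_frames_per_state)
  sys
}

#' Specification of a synthetic tubulin-like sheet
#'
#' A grid of rigid monomer blocks: `n_rows` protofilament analogs, each a
#' row of `n_cols` monomers (alternating alpha/beta along the row, so
#' column pairs (1,2), (3,4), ... are the intra-dimer analogs).
#' Longitudinal coupling acts along a row between adjacent columns;
#' lateral coupling acts between rows at the same column (the B-type
#' analog). An optional seam column gets `coupling_seam` on its lateral
#' pair(s) instead - the A-type analog - together with a slightly wider
#' lateral gap, so the seam is both dynamically and geometrically weaker.
#' Block-block correlations decay with lattice distance as the maximal
#' product of couplings along lattice paths; the implied correlation
#' matrix must be positive semi-definite or the spec is rejected.
#'
#' @param n_rows protofilament analogs (grid rows).
#' @param n_cols monomers along each protofilament (grid columns).
#' @param beads_per_monomer 1-7 beads per block: center, then +x, -x, +y,
#'   -y, +z, -z arms (5 gives full in-plane contacts).
#' @param lattice_spacing block-center spacing in nm.
#' @param coupling_long,coupling_lat,coupling_seam displacement
#'   correlations in \[0, 1)\ for longitudinal, lateral, and seam lateral
#'   couplings.
#' @param seam_col optional column index whose lateral pair(s) form the
#'   seam.
#' @param restrained_blocks list of `c(row, col)` whose beads have exactly
#'   zero fluctuation (position-restrained corner analogs).
#' @param fluctuation_sigma per-axis block displacement sd (nm).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param contact_gap_nm gap between facing beads of adjacent blocks (nm).
#' @param seam_gap_nm widened gap at the seam lateral interface (nm).
#' @return a validated `SheetSpec` list.
#' @export
sheet_spec <- function(n_rows = 2L, n_cols = 6L, beads_per_monomer = 5L,
                       lattice_spacing = 0.9, coupling_long = 0.85,
                       coupling_lat = 0.7, coupling_seam = 0.2,
                       seam_col = NULL, restrained_blocks = list(),
                       fluctuation_sigma = 0.02, n_frames = 600L,
                       seed = 1L, contact_gap_nm = 0.30,
                       seam_gap_nm = 0.50) {
  for (cc in c(coupling_long, coupling_lat, coupling_seam)) {
    if (cc < 0 || cc >= 1) stop("couplings must lie in [0, 1)")
  }
  if (beads_per_monomer < 1L || beads_per_monomer > 7L) {
    stop("beads_per_monomer must be in 1..7")
  }
  if (!is.null(seam_col) && (seam_col < 1L || seam_col > n_cols)) {
    stop("seam_col outside grid")
  }
  for (rb in restrained_blocks) {
    if (rb[1] < 1L || rb[1] > n_rows || rb[2] < 1L || rb[2] > n_cols) {
      stop("restrained block outside grid")
    }
  }
  if (2 * ((lattice_spacing - contact_gap_nm) / 2) >= lattice_spacing) {
    stop("contact gap must be positive")
  }
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               beads_per_monomer = as.integer(beads_per_monomer),
               lattice_spacing = lattice_spacing,
               coupling_long = coupling_long, coupling_lat = coupling_lat,
               coupling_seam = coupling_seam,
               seam_col = if (is.null(seam_col)) NULL else as.integer(seam_col),
               restrained_blocks = restrained_blocks,
               fluctuation_sigma = fluctuation_sigma,
               n_frames = as.integer(n_frames), seed = as.integer(seed),
               contact_gap_nm = contact_gap_nm, seam_gap_nm = seam_gap_nm)
  class(spec) <- "SheetSpec"
  # validate the implied correlation matrix up front
  sheet_correlation(spec)
  spec
}

# designed block-block correlation: maximal product of couplings over
# lattice paths (computed as -log shortest paths on the coupling graph)
sheet_correlation <- function(spec) {
  nb <- spec$n_rows * spec$n_cols
  bid <- function(r, c) (r - 1L) * spec$n_cols + c
  D <- matrix(Inf, nb, nb)
  diag(D) <- 0
  set_edge <- function(a, b, w) {
    if (w <= 0) return()
    D[a, b] <<- -log(w); D[b, a] <<- -log(w)
  }
  for (r in seq_len(spec$n_rows)) {
    for (c in seq_len(spec$n_cols)) {
      if (c < spec$n_cols) set_edge(bid(r, c), bid(r, c + 1L),
                                    spec$coupling_long)
      if (r < spec$n_rows) {
        w <- if (!is.null(spec$seam_col) && c == spec$seam_col) {
          spec$coupling_seam
        } else spec$coupling_lat
        set_edge(bid(r, c), bid(r + 1L, c), w)
      }
    }
  }
  # Floyd-Warshall
  for (k in seq_len(nb)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  C <- exp(-D)
  diag(C) <- 1
  check_correlation_matrix(C)
  C
}

bead_offsets <- function(arm, bpm) {
  pos <- rbind(c(0, 0, 0),
               c(arm, 0, 0), c(-arm, 0, 0),
               c(0, arm, 0), c(0, -arm, 0),
               c(0, 0, arm), c(0, 0, -arm))
  pos[seq_len(bpm), , drop = FALSE]
}

#' Generate a synthetic tubulin-like sheet trajectory
#'
#' Builds the block lattice of a [sheet_spec()]: one chain per monomer
#' block (`beads_per_monomer` single-atom residues each), rigid per-block
#' displacements drawn from the designed correlation matrix (per-axis
#' multivariate Gaussian, sd `fluctuation_sigma`), small independent
#' per-bead jitter (sigma/10) so residue- and block-level correlations
#' agree, restrained blocks exactly frozen, and facing beads of adjacent
#' blocks within contact distance (wider gap at the seam).
#'
#' @param spec a `SheetSpec`.
#' @return list with `system` (a `MolecularSystem`) and `truth` (a
#'   `GroundTruth` list: block table, designed correlation matrix with
#'   chain dimnames, expected contact pairs with weak-interface flags, and
#'   the seam location).
#' @export
gen_toy_sheet <- function(spec) {
  stopifnot(inherits(spec, "SheetSpec"))
  nr <- spec$n_rows; nc <- spec$n_cols; bpm <- spec$beads_per_monomer
  s <- spec$lattice_spacing
  arm <- (s - spec$contact_gap_nm) / 2
  nb <- nr * nc
  chains <- chain_ids(nb)
  bid <- function(r, c) (r - 1L) * nc + c
  restrained <- rep(FALSE, nb)
  for (rb in spec$restrained_blocks) restrained[bid(rb[1], rb[2])] <- TRUE
  blocks <- data.frame(
    block = seq_len(nb),
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    chain = chains,
    monomer = ifelse(rep(seq_len(nc), times = nr) %% 2L == 1L,
                     "alpha", "beta"),
    restrained = restrained,
    stringsAsFactors = FALSE
  )
  C <- sheet_correlation(spec)
  dimnames(C) <- list(chains, chains)

  # static base coordinates, with the seam gap widened
  base <- matrix(0, nb * bpm, 3L)
  atoms <- vector("list", nb)
  seam_pull <- (spec$seam_gap_nm - spec$contact_gap_nm) / 2
  for (b in seq_len(nb)) {
    r <- blocks$row[b]; c <- blocks$col[b]
    center <- c((c - 1L) * s, (r - 1L) * s, 0)
    off <- bead_offsets(arm, bpm)
    if (!is.null(spec$seam_col) && c == spec$seam_col && bpm >= 5L) {
      # pull back the lateral arms that face across the seam
      if (r < nr) off[4L, 2L] <- off[4L, 2L] - seam_pull  # +y arm
      if (r > 1L) off[5L, 2L] <- off[5L, 2L] + seam_pull  # -y arm
    }
    idx <- ((b - 1L) * bpm + 1L):(b * bpm)
    base[idx, ] <- sweep(off, 2L, center, `+`)
    atoms[[b]] <- data.frame(
      eleno = idx, elety = "CA", resid = seq_len(bpm),
      resname = if (blocks$monomer[b] == "alpha") "ALA" else "GLY",
      chain = chains[b], element = "C", stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, atoms)

  free <- which(!restrained)
  nf <- spec$n_frames
  sigma <- spec$fluctuation_sigma
  xyz <- with_seed(spec$seed, {
    disp <- array(0, dim = c(nf, nb, 3L))
    if (length(free) > 0L) {
      Cf <- C[free, free, drop = FALSE]
      for (ax in 1:3) disp[, free, ax] <- sample_mvn(Cf, nf) * sigma
    }
    out <- matrix(0, nf, 3L * nb * bpm)
    for (b in seq_len(nb)) {
      idx <- ((b - 1L) * bpm + 1L):(b * bpm)
      for (ax in 1:3) {
        cols <- 3L * (idx - 1L) + ax
        jit <- if (restrained[b]) 0 else
          matrix(stats::rnorm(nf * bpm, 0, sigma / 10), nf)
        out[, cols] <- rep(base[idx, ax], each = nf) + disp[, b, ax] + jit
      }
    }
    out
  })
  system <- molecular_system(atoms, xyz)

  # expected contacts: adjacent blocks within lattice spacing, with the
  # analytic contact frequency at the reference 0.45 nm cutoff. The facing
  # bead distance is gap + relative displacement along the interface axis
  # (restrained blocks do not move), so the frequency is the Gaussian tail
  # probability of staying inside the cutoff.
  ref_cutoff <- 0.45
  expected_freq <- function(a, b, gap) {
    va <- if (restrained[a]) 0 else sigma^2
    vb <- if (restrained[b]) 0 else sigma^2
    cov_ab <- if (restrained[a] || restrained[b]) 0 else C[a, b] * sigma^2
    s2 <- va + vb - 2 * cov_ab + 2 * (sigma / 10)^2
    if (s2 <= 0) return(as.numeric(gap <= ref_cutoff))
    stats::pnorm((ref_cutoff - gap) / sqrt(s2))
  }
  pairs <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) {
      a <- bid(r, c); b <- bid(r, c + 1L)
      pairs[[length(pairs) + 1L]] <- data.frame(
        chain_a = chains[a], chain_b = chains[b],
        type = "longitudinal", weak = FALSE, gap_nm = spec$contact_gap_nm,
        expected_frequency = expected_freq(a, b, spec$contact_gap_nm),
        stringsAsFactors = FALSE)
    }
    if (r < nr) {
      a <- bid(r, c); b <- bid(r + 1L, c)
      weak <- !is.null(spec$seam_col) && c == spec$seam_col
      gap <- if (weak && bpm >= 5L) spec$seam_gap_nm else spec$contact_gap_nm
      pairs[[length(pairs) + 1L]] <- data.frame(
        chain_a = chains[a], chain_b = chains[b],
        type = "lateral", weak = weak, gap_nm = gap,
        expected_frequency = expected_freq(a, b, gap),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  pairs$expected_edge <- pairs$expected_frequency >= 0.75
  truth <- list(blocks = blocks, correlation = C,
                contact_pairs = pairs,
                seam_col = spec$seam_col, spec = spec)
  class(truth) <- "GroundTruth"
  list(system = system, truth = truth)
}

#' Write a generated sheet to disk
#'
#' PDB topology + DCD trajectory + JSON ground-truth sidecar.
#'
#' @param sheet result of [gen_toy_sheet()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return named character vector of the paths written.
#' @export
write_sheet <- function(sheet, dir, name = "sheet") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  dcd <- file.path(dir, paste0(name, ".dcd"))
  js <- file.path(dir, paste0(name, "_truth.json"))
  write_system(sheet$system, pdb, dcd)
  truth <- sheet$truth
  jsonlite::write_json(
    list(blocks = truth$blocks,
         correlation = truth$correlation,
         contact_pairs = truth$contact_pairs,
         seam_col = truth$seam_col,
         spec = truth$spec[setdiff(names(truth$spec), "restrained_blocks")],
         restrained_blocks = truth$spec$restrained_blocks),
    js, auto_unbox = TRUE, digits = NA
  )
  c(pdb = pdb, dcd = dcd, truth = js)
}

#' Specification of a synthetic MSA
#'
#' @param n_sequences number of aligned sequences.
#' @param column_profiles list (one element per column) of named
#'   probability vectors over amino-acid letters plus optionally the gap
#'   character "-"; each must sum to 1, with gap fraction < 1.
#' @param seed RNG seed.
#' @return a validated `MSASpec` list.
#' @export
msa_spec <- function(n_sequences, column_profiles, seed = 1L) {
  for (p in column_profiles) {
    if (abs(sum(p) - 1) > 1e-8) stop("column profile does not sum to 1")
    gp <- if ("-" %in% names(p)) p[["-"]] else 0
    if (gp < 0 || gp >= 1) stop("gap fraction must lie in [0, 1)")
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 column_profiles = column_profiles,
                 seed = as.integer(seed)),
            class = "MSASpec")
}

#' Generate a toy MSA with controlled column composition
#'
#' Samples each column independently from its target distribution; the
#' realized composition converges to the design as the number of sequences
#' grows.
#'
#' @param spec an `MSASpec`.
#' @return an `MSA` object (see [read_msa()]).
#' @export
gen_toy_msa <- function(spec) {
  stopifnot(inherits(spec, "MSASpec"))
  ncols <- length(spec$column_profiles)
  ali <- with_seed(spec$seed, {
    m <- matrix("-", spec$n_sequences, ncols)
    for (j in seq_len(ncols)) {
      p <- spec$column_profiles[[j]]
      m[, j] <- sample(names(p), spec$n_sequences, replace = TRUE,
                       prob = as.numeric(p))
    }
    m
  })
  ids <- sprintf("seq%04d", seq_len(spec$n_sequences))
  rownames(ali) <- ids
  msa_object(ali, ids, reference = 1L)
}

#' Write an MSA to FASTA
#' @param msa an `MSA`.
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  bio3d::write.fasta(seqs = msa$ali, ids = msa$ids, file = path)
  invisible(path)
}
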