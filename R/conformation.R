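#' RMSD time series against a reference frame
#'
#' Root-mean-squared deviation of the selected atoms from their coordinates
#' in the reference frame, after least-squares superposition onto that frame
#' over the same selection.
#'
#' @param system a `MolecularSystem`.
#' @param atoms atom indices defining the selection (default: all atoms).
#' @param reference reference frame index (default 1, the initial
#'   coordinates).
#' @param fit superpose each frame onto the reference before measuring
#'   (default TRUE)?
#' @return an `RmsdSeries` data.frame with columns `frame`, `rmsd` (nm).
#' @export
rmsd_series <- function(system, atoms = NULL, reference = 1L, fit = TRUE) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(system))
  if (length(atoms) == 0L) stop("selection is empty")
  cols <- xyz_cols(atoms)
  r <- bio3d::rmsd(system$xyz[reference, cols],
                   system$xyz[, cols, drop = FALSE], fit = fit)
  out <- data.frame(frame = seq_len(n_frames(system)), rmsd = as.numeric(r))
  attr(out, "selection") <- atoms
  attr(out, "reference") <- reference
  class(out) <- c("RmsdSeries", "data.frame")
  out
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each node atom about its time-mean
#' position. Frames must already be aligned (see [align_frames()]); an RMSF
#' over unaligned frames mixes internal motion with rigid-body drift.
#'
#' @param system a `MolecularSystem` with >= 2 frames.
#' @param nodes a `NodeSelection` (one atom per residue).
#' @return data.frame `chain`, `resid`, `resname`, `rmsf` (nm).
#' @export
rmsf_profile <- function(system, nodes) {
  if (n_frames(system) < 2L) stop("RMSF needs at least 2 frames")
  rmsf <- vapply(nodes$atom_index, function(ai) {
    xyz <- atom_coords(system, ai)
    dev <- sweep(xyz, 2L, colMeans(xyz))
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1L))
  data.frame(chain = nodes$chain, resid = nodes$resid,
             resname = nodes$resname, rmsf = rmsf,
             stringsAsFactors = FALSE)
}

#' Pairwise frame-frame RMSD matrix
#'
#' Symmetric matrix of RMSDs between every pair of (optionally strided)
#' frames, with per-pair least-squares superposition over the selection.
#'
#' @inheritParams rmsd_series
#' @param stride keep every `stride`-th frame.
#' @param max_frames guard against the O(F^2) memory/time cost; exceeding it
#'   is an error (raise `stride` instead).
#' @return list with `d` (matrix) and `frames` (original frame indices).
#' @export
pairwise_rmsd <- function(system, atoms = NULL, stride = 1L,
                          max_frames = 2000L) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(system))
  frames <- seq(1L, n_frames(system), by = as.integer(stride))
  nf <- length(frames)
  if (nf > max_frames) {
    stop("pairwise RMSD over ", nf, " frames exceeds max_frames = ",
         max_frames, "; increase the stride")
  }
  cols <- xyz_cols(atoms)
  x <- system$xyz[frames, cols, drop = FALSE]
  d <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    ri <- bio3d::rmsd(x[i, ], x[(i + 1L):nf, , drop = FALSE], fit = TRUE)
    d[i, (i + 1L):nf] <- ri
    d[(i + 1L):nf, i] <- ri
  }
  list(d = d, frames = frames)
}

#' Cluster trajectory frames by linkage on pairwise RMSD
#'
#' Agglomerative (hierarchical) clustering of frames with the pairwise
#' superposed RMSD as metric, cut at a fixed height. With the conventional
#' 0.15 nm cutoff a structurally stable trajectory yields a single cluster;
#' distinct conformational states separate.
#'
#' @inheritParams pairwise_rmsd
#' @param cutoff tree cut height in nm (default 0.15).
#' @param linkage agglomeration criterion: "average" (default), "single",
#'   or "complete".
#' @return a `ClusterAssignment` data.frame (`frame`, `cluster`) with labels
#'   contiguous from 1 in order of first appearance; attributes `cutoff`,
#'   `linkage`, `sizes`.
#' @export
cluster_frames <- function(system, atoms = NULL, cutoff = 0.15,
                           linkage = c("average", "single", "complete"),
                           stride = 1L, max_frames = 2000L) {
  linkage <- match.arg(linkage)
  if (n_frames(system) < 2L) stop("clustering needs at least 2 frames")
  pr <- pairwise_rmsd(system, atoms = atoms, stride = stride,
                      max_frames = max_frames)
  hc <- stats::hclust(stats::as.dist(pr$d), method = linkage)
  raw <- stats::cutree(hc, h = cutoff)
  # relabel contiguously from 1 in order of first appearance
  lab <- match(raw, unique(raw))
  out <- data.frame(frame = pr$frames, cluster = lab)
  attr(out, "cutoff") <- cutoff
  attr(out, "linkage") <- linkage
  attr(out, "sizes") <- as.integer(table(lab))
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("ClusterAssignment:", length(sizes), "cluster(s) at cutoff",
      attr(x, "cutoff"), "nm (", attr(x, "linkage"), "linkage )\n")
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
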