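#' Molecular system container
#'
#' A `MolecularSystem` bundles a static topology (atoms, residues, chains)
#' with an ordered set of coordinate frames and the replica boundaries of the
#' trajectory. Coordinates are stored internally in nanometres in the
#' bio3d-style flat layout (one row per frame, columns `x1,y1,z1,x2,...`).
#'
#' @param atoms data.frame with columns `eleno` (atom serial), `elety`
#'   (atom name), `resid` (residue number), `resname`, `chain`, `element`.
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`, in nm.
#' @param replicas list of integer vectors `c(start, end)` (1-based,
#'   inclusive) partitioning the frames into replicas; defaults to a single
#'   replica spanning all frames.
#' @return an object of class `MolecularSystem`.
#' @export
molecular_system <- function(atoms, xyz, replicas = NULL) {
  req <- c("eleno", "elety", "resid", "resname", "chain", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("coordinate width (", ncol(xyz), ") does not match 3 * n_atoms (",
         3L * nrow(atoms), ")")
  }
  if (nrow(xyz) < 1L) stop("system has zero frames")
  if (is.null(replicas)) replicas <- list(c(1L, nrow(xyz)))
  covered <- unlist(lapply(replicas, function(r) seq.int(r[1], r[2])))
  if (!identical(as.integer(covered), seq_len(nrow(xyz)))) {
    stop("replica boundaries do not partition the frames in order")
  }
  # residue numbers must be unique within a chain
  rk <- unique(atoms[, c("chain", "resid", "resname")])
  if (anyDuplicated(rk[, c("chain", "resid")])) {
    stop("duplicated residue id within a chain")
  }
  structure(
    list(atoms = atoms, xyz = xyz,
         replicas = lapply(replicas, function(r) as.integer(r))),
    class = "MolecularSystem"
  )
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat("MolecularSystem:", n_atoms(x), "atoms,",
      length(unique(x$atoms$chain)), "chains,",
      n_frames(x), "frames,",
      length(x$replicas), "replica(s)\n")
  invisible(x)
}

#' @export
summary.MolecularSystem <- function(object, ...) {
  per_chain <- table(object$atoms$chain)
  cat("MolecularSystem\n")
  cat("  atoms   :", n_atoms(object), "\n")
  cat("  residues:", nrow(unique(object$atoms[, c("chain", "resid")])), "\n")
  cat("  chains  :", paste(names(per_chain), collapse = " "), "\n")
  cat("  frames  :", n_frames(object), "in", length(object$replicas),
      "replica(s)\n")
  invisible(object)
}

#' Number of frames in a system
#' @param system a `MolecularSystem`.
#' @return integer frame count.
#' @export
n_frames <- function(system) nrow(system$xyz)

#' Number of atoms in a system
#' @param system a `MolecularSystem`.
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

# column indices into the flat xyz layout for a set of atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

# frames x 3 coordinate matrix of one atom
atom_coords <- function(system, atom_idx) {
  system$xyz[, xyz_cols(atom_idx), drop = FALSE]
}

# residue-level key "chain:resid"
res_key <- function(chain, resid) paste(chain, resid, sep = ":")

#' Subset the frames of a system
#' @param system a `MolecularSystem`.
#' @param frames integer frame indices (1-based) to keep, in order.
#' @param replicas optional replacement replica boundaries for the result.
#' @return a `MolecularSystem` with the selected frames.
#' @export
subset_frames <- function(system, frames, replicas = NULL) {
  if (any(frames < 1L | frames > n_frames(system))) stop("frame index out of range")
  molecular_system(system$atoms, system$xyz[frames, , drop = FALSE],
                   replicas = replicas)
}
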