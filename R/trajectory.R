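#' Select one network node per residue
#'
#' Picks a representative atom per residue: the C-alpha for amino acids and a
#' configurable atom for ligand residues (e.g. the phosphorus of GTP/GDP).
#' Chains under position restraint during the simulation are excluded, as are
#' ligands when `include_ligands = FALSE`. Node ordering is a pure function
#' of the topology: (chain, residue number).
#'
#' @param system a `MolecularSystem`.
#' @param exclude_chains character vector of chain ids to drop.
#' @param ligand_atoms named character vector mapping residue name to the
#'   representative atom name for non-amino-acid residues.
#' @param rep_atom representative atom name for amino acids (default "CA").
#' @param include_ligands keep residues named in `ligand_atoms`?
#' @return a `NodeSelection` data.frame with one row per node: `node`,
#'   `atom_index`, `chain`, `resid`, `resname`, `elety`.
#' @export
select_nodes <- function(system, exclude_chains = character(),
                         ligand_atoms = c(GTP = "PB", GDP = "PB"),
                         rep_atom = "CA", include_ligands = TRUE) {
  a <- system$atoms
  have <- unique(a$chain)
  bad <- setdiff(exclude_chains, have)
  if (length(bad) > 0L) {
    stop("excluded chain(s) not present in system: ", paste(bad, collapse = ", "))
  }
  a$atom_index <- seq_len(nrow(a))
  a <- a[!(a$chain %in% exclude_chains), , drop = FALSE]
  res <- unique(a[, c("chain", "resid", "resname")])
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  rows <- vector("list", nrow(res))
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    sub <- a[a$chain == res$chain[i] & a$resid == res$resid[i], , drop = FALSE]
    rn <- res$resname[i]
    if (rn %in% names(ligand_atoms)) {
      if (!include_ligands) next
      want <- ligand_atoms[[rn]]
    } else {
      want <- rep_atom
    }
    hit <- which(trimws(sub$elety) == want)
    if (length(hit) == 0L) {
      stop("residue ", rn, " ", res$resid[i], " (chain ", res$chain[i],
           ") lacks representative atom ", want)
    }
    keep[i] <- TRUE
    rows[[i]] <- data.frame(
      atom_index = sub$atom_index[hit[1L]], chain = res$chain[i],
      resid = res$resid[i], resname = rn, elety = want,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[keep])
  out <- cbind(node = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("NodeSelection", "data.frame")
  out
}

#' @export
print.NodeSelection <- function(x, ...) {
  cat("NodeSelection:", nrow(x), "nodes over",
      length(unique(x$chain)), "chains\n")
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Concatenate the equilibrated portion of each replica
#'
#' Drops the first `equil_frames` frames of every replica (the
#' pre-equilibrium transient) and concatenates what remains, the standard
#' pre-processing step before correlation, contact, and rigidity analyses.
#'
#' @param system a `MolecularSystem` with replica boundaries.
#' @param equil_frames number of frames to discard at the start of each
#'   replica (0 keeps everything).
#' @return a `MolecularSystem` holding only equilibrated frames, with
#'   updated replica boundaries.
#' @export
concat_equilibrated <- function(system, equil_frames) {
  equil_frames <- as.integer(equil_frames)
  if (equil_frames < 0L) stop("equil_frames must be >= 0")
  keep <- integer()
  replicas <- list()
  at <- 0L
  for (r in system$replicas) {
    len <- r[2] - r[1] + 1L
    if (equil_frames >= len) {
      stop("equilibration cut (", equil_frames,
           ") is not shorter than replica length (", len, ")")
    }
    idx <- seq.int(r[1] + equil_frames, r[2])
    keep <- c(keep, idx)
    replicas[[length(replicas) + 1L]] <- c(at + 1L, at + length(idx))
    at <- at + length(idx)
  }
  subset_frames(system, keep, replicas = replicas)
}

# Kabsch optimal rotation: returns frame coords (n x 3) superposed onto ref
kabsch_fit <- function(mob, ref, fit_idx) {
  mr <- mob[fit_idx, , drop = FALSE]
  rr <- ref[fit_idx, , drop = FALSE]
  cm <- colMeans(mr); cr <- colMeans(rr)
  H <- crossprod(sweep(mr, 2L, cm), sweep(rr, 2L, cr))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mob, 2L, cm) %*% t(U), 2L, cr, `+`)
}

#' Least-squares superpose all frames onto a reference
#'
#' Removes rigid-body translation/rotation so that downstream correlations,
#' fluctuations, and force constants reflect internal motion only. By
#' default a two-pass procedure is used: frames are first fitted onto frame
#' 1, then re-fitted onto the resulting mean structure.
#'
#' @param system a `MolecularSystem`.
#' @param fit_atoms atom indices used for the superposition (default: all).
#' @param reference `"mean"` for the two-pass mean-structure fit, or a frame
#'   index to fit directly onto that frame.
#' @return a `MolecularSystem` with aligned coordinates.
#' @export
align_frames <- function(system, fit_atoms = NULL, reference = "mean") {
  if (is.null(fit_atoms)) fit_atoms <- seq_len(n_atoms(system))
  if (length(fit_atoms) == 0L) stop("fit selection is empty")
  if (length(fit_atoms) < 3L) stop("fit selection needs >= 3 atoms")
  nf <- n_frames(system); na <- n_atoms(system)
  as_frames <- function(xyz) {
    lapply(seq_len(nrow(xyz)), function(f) {
      matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    })
  }
  frames <- as_frames(system$xyz)
  # degenerate (collinear) selections have a rank-deficient coordinate spread
  spread <- svd(sweep(frames[[1L]][fit_atoms, , drop = FALSE], 2L,
                      colMeans(frames[[1L]][fit_atoms, , drop = FALSE])))$d
  if (sum(spread > 1e-8) < 2L) stop("degenerate (collinear) fit selection")
  fit_all <- function(frames, ref) {
    lapply(frames, kabsch_fit, ref = ref, fit_idx = fit_atoms)
  }
  if (identical(reference, "mean")) {
    pass1 <- fit_all(frames, frames[[1L]])
    ref <- Reduce(`+`, pass1) / length(pass1)
    fitted <- fit_all(pass1, ref)
  } else {
    ref_i <- as.integer(reference)
    if (ref_i < 1L || ref_i > nf) stop("reference frame out of range")
    fitted <- fit_all(frames, frames[[ref_i]])
  }
  xyz <- t(vapply(fitted, function(m) as.vector(t(m)), numeric(3L * na)))
  molecular_system(system$atoms, xyz, replicas = system$replicas)
}
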