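#' Select the atoms of a residue group
#'
#' Builds the atom table for a group of residues (e.g. one subunit or one
#' side of an interface), optionally restricted to heavy atoms.
#'
#' @param system a `MolecularSystem`.
#' @param chains chain ids to include (NULL = all).
#' @param resids residue numbers to include (NULL = all in the chains).
#' @param heavy_only drop hydrogens (default TRUE)?
#' @return data.frame of atoms with an `atom_index` column.
#' @export
residue_group <- function(system, chains = NULL, resids = NULL,
                          heavy_only = TRUE) {
  a <- system$atoms
  a$atom_index <- seq_len(nrow(a))
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (!is.null(resids)) a <- a[a$resid %in% resids, , drop = FALSE]
  if (heavy_only) a <- a[toupper(trimws(a$element)) != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("residue group is empty")
  a
}

# per-frame squared distances between two atom sets -> na x nb matrix
frame_dist2 <- function(xa, xb) {
  outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
}

# frame f of a frames x atoms x 3 array, kept as an atoms x 3 matrix
frame_slice <- function(arr, f) {
  matrix(arr[f, , ], ncol = 3L)
}

# frames x natoms x 3 coordinate array for a group
group_coords <- function(system, group) {
  nf <- n_frames(system)
  na <- nrow(group)
  arr <- array(0, dim = c(nf, na, 3L))
  for (k in seq_len(na)) {
    arr[, k, ] <- atom_coords(system, group$atom_index[k])
  }
  arr
}

#' Contact frequency between two residue groups
#'
#' For every residue pair (a in A, b in B), the fraction of frames in which
#' any heavy-atom pair of the two residues lies within the distance cutoff.
#' The per-residue marginal (fraction of frames in contact with *any*
#' partner residue) is attached as the `marginals` attribute.
#'
#' @param system a `MolecularSystem`.
#' @param group_a,group_b atom tables from [residue_group()]; must be
#'   residue-disjoint.
#' @param cutoff heavy-atom distance cutoff in nm (default 0.45).
#' @return a `ContactTable` data.frame: `chain_i`, `resid_i`, `resname_i`,
#'   `chain_j`, `resid_j`, `resname_j`, `frequency`.
#' @export
contact_frequency <- function(system, group_a, group_b, cutoff = 0.45) {
  if (nrow(group_a) == 0L || nrow(group_b) == 0L) stop("empty group")
  ka <- res_key(group_a$chain, group_a$resid)
  kb <- res_key(group_b$chain, group_b$resid)
  if (length(intersect(unique(ka), unique(kb))) > 0L) {
    stop("groups must be residue-disjoint")
  }
  resa <- unique(group_a[, c("chain", "resid", "resname")])
  resb <- unique(group_b[, c("chain", "resid", "resname")])
  ia <- match(ka, res_key(resa$chain, resa$resid))
  ib <- match(kb, res_key(resb$chain, resb$resid))
  nra <- nrow(resa); nrb <- nrow(resb)
  pair_of <- outer(ia, ib, function(i, j) (i - 1L) * nrb + j)
  nf <- n_frames(system)
  ca <- group_coords(system, group_a)
  cb <- group_coords(system, group_b)
  cut2 <- cutoff^2
  pair_counts <- integer(nra * nrb)
  marg_a <- integer(nra); marg_b <- integer(nrb)
  for (f in seq_len(nf)) {
    d2 <- frame_dist2(frame_slice(ca, f), frame_slice(cb, f))
    hit <- which(d2 <= cut2)
    if (length(hit) == 0L) next
    pairs <- unique(pair_of[hit])
    pair_counts[pairs] <- pair_counts[pairs] + 1L
    ra <- unique((pairs - 1L) %/% nrb + 1L)
    rb <- unique((pairs - 1L) %% nrb + 1L)
    marg_a[ra] <- marg_a[ra] + 1L
    marg_b[rb] <- marg_b[rb] + 1L
  }
  grid <- expand.grid(j = seq_len(nrb), i = seq_len(nra))
  out <- data.frame(
    chain_i = resa$chain[grid$i], resid_i = resa$resid[grid$i],
    resname_i = resa$resname[grid$i],
    chain_j = resb$chain[grid$j], resid_j = resb$resid[grid$j],
    resname_j = resb$resname[grid$j],
    frequency = pair_counts[(grid$i - 1L) * nrb + grid$j] / nf,
    stringsAsFactors = FALSE
  )
  marg <- rbind(
    data.frame(side = "A", chain = resa$chain, resid = resa$resid,
               resname = resa$resname, frequency = marg_a / nf,
               stringsAsFactors = FALSE),
    data.frame(side = "B", chain = resb$chain, resid = resb$resid,
               resname = resb$resname, frequency = marg_b / nf,
               stringsAsFactors = FALSE)
  )
  attr(out, "marginals") <- marg
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  class(out) <- c("ContactTable", "data.frame")
  out
}

#' @export
print.ContactTable <- function(x, ...) {
  nz <- sum(x$frequency > 0)
  cat("ContactTable:", nrow(x), "residue pairs (", nz,
      "in contact ) at cutoff", attr(x, "cutoff"), "nm over",
      attr(x, "n_frames"), "frames\n")
  invisible(x)
}

#' Per-residue contact-frequency difference map
#'
#' Signed difference (`x - ref`) of the per-residue marginal contact
#' frequencies of two contact tables, the standard way to localize where an
#' interface (e.g. a seam) gains or loses contacts relative to a reference
#' system. Residues absent from one table count as frequency 0.
#'
#' @param table_x,table_ref `ContactTable` objects sharing residue labels.
#' @return data.frame `side`, `chain`, `resid`, `resname`, `diff` in
#'   \[-1, 1\].
#' @export
contact_difference <- function(table_x, table_ref) {
  mx <- attr(table_x, "marginals")
  mr <- attr(table_ref, "marginals")
  if (is.null(mx) || is.null(mr)) stop("inputs must be ContactTable objects")
  key <- function(m) paste(m$side, m$chain, m$resid, sep = ":")
  all_keys <- union(key(mx), key(mr))
  fx <- mx$frequency[match(all_keys, key(mx))]
  fr <- mr$frequency[match(all_keys, key(mr))]
  fx[is.na(fx)] <- 0; fr[is.na(fr)] <- 0
  meta <- rbind(mx[, c("side", "chain", "resid", "resname")],
                mr[, c("side", "chain", "resid", "resname")])
  meta <- meta[match(all_keys, key(meta)), , drop = FALSE]
  out <- cbind(meta, diff = fx - fr)
  rownames(out) <- NULL
  out
}
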