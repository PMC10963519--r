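#' Boltzmann constant in kJ mol-1 K-1
#' @export
kB <- 0.0083144621

#' Mean-distance time series of one residue
#'
#' `d_i(t)`: the mean, over all other included nodes j, of the node-node
#' distance at frame t. The variance of this series measures how rigidly
#' residue i sits inside the assembly.
#'
#' @param system a `MolecularSystem`.
#' @param nodes a `NodeSelection`.
#' @param target node index (row of `nodes`) of the residue i.
#' @param exclude_window drop nodes within this many sequence positions of
#'   the target on the same chain (0 = none).
#' @return numeric vector, one mean distance (nm) per frame.
#' @export
mean_distance_series <- function(system, nodes, target, exclude_window = 0L) {
  if (nrow(nodes) < 2L) stop("need at least 2 nodes")
  if (n_frames(system) < 2L) stop("need at least 2 frames")
  others <- setdiff(seq_len(nrow(nodes)), target)
  if (exclude_window > 0L) {
    same <- nodes$chain[others] == nodes$chain[target]
    near <- abs(nodes$resid[others] - nodes$resid[target]) <= exclude_window
    others <- others[!(same & near)]
  }
  if (length(others) == 0L) stop("no partner nodes left after exclusion")
  xi <- atom_coords(system, nodes$atom_index[target])
  acc <- 0
  for (j in others) {
    xj <- atom_coords(system, nodes$atom_index[j])
    acc <- acc + sqrt(rowSums((xi - xj)^2))
  }
  acc / length(others)
}

#' Per-residue force-constant (rigidity) profile
#'
#' For each node i, `k_i = 3 k_B T / var(d_i)` where `d_i(t)` is the mean
#' distance of node i to all other nodes (see [mean_distance_series()]).
#' Large `k_i` marks residues that hold their position relative to the rest
#' of the assembly - the mechanically rigid core. Residues with zero
#' distance variance (e.g. under position restraints) are flagged `NA`.
#'
#' When a list of systems is supplied, per-system profiles are computed on
#' shared residue labels and summarized as mean with a min-max envelope.
#'
#' @param system a `MolecularSystem`, or a list of them (replicas/systems).
#' @param nodes a `NodeSelection` (valid for every system supplied).
#' @param temperature simulation temperature in K (default 300).
#' @param exclude_window see [mean_distance_series()].
#' @return a `ForceConstantProfile` data.frame: `chain`, `resid`,
#'   `resname`, `k` (single system) or `k_mean`, `k_min`, `k_max`
#'   (several), in kJ mol-1 nm-2; attribute `temperature`.
#' @export
force_constant_profile <- function(system, nodes, temperature = 300,
                                   exclude_window = 0L) {
  if (temperature <= 0) stop("temperature must be positive")
  one <- function(sys) {
    vapply(seq_len(nrow(nodes)), function(i) {
      d <- mean_distance_series(sys, nodes, i, exclude_window)
      v <- stats::var(d)
      if (v <= 0) return(NA_real_)
      3 * kB * temperature / v
    }, numeric(1L))
  }
  base <- data.frame(chain = nodes$chain, resid = nodes$resid,
                     resname = nodes$resname, stringsAsFactors = FALSE)
  if (inherits(system, "MolecularSystem")) {
    out <- cbind(base, k = one(system))
  } else {
    ks <- vapply(system, one, numeric(nrow(nodes)))
    out <- cbind(base,
                 k_mean = rowMeans(ks),
                 k_min = apply(ks, 1L, min),
                 k_max = apply(ks, 1L, max))
  }
  attr(out, "temperature") <- temperature
  class(out) <- c("ForceConstantProfile", "data.frame")
  out
}

#' @export
print.ForceConstantProfile <- function(x, ...) {
  kcol <- if ("k" %in% names(x)) x$k else x$k_mean
  cat("ForceConstantProfile:", nrow(x), "residues at T =",
      attr(x, "temperature"), "K\n")
  cat("  k (kJ mol-1 nm-2): median", round(stats::median(kcol, na.rm = TRUE), 1),
      " max", round(max(kcol, na.rm = TRUE), 1), "\n")
  if (anyNA(kcol)) cat("  flagged (zero-variance):", sum(is.na(kcol)), "\n")
  invisible(x)
}

#' Plot a force-constant profile
#'
#' Profile along the residue index; with multi-system profiles the mean is
#' drawn as a line inside the min-max envelope.
#'
#' @param x a `ForceConstantProfile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ForceConstantProfile <- function(x, ...) {
  idx <- seq_len(nrow(x))
  if ("k" %in% names(x)) {
    graphics::plot(idx, x$k, type = "l", xlab = "residue",
                   ylab = "k (kJ mol-1 nm-2)", ...)
  } else {
    graphics::plot(idx, x$k_mean, type = "n", xlab = "residue",
                   ylab = "k (kJ mol-1 nm-2)",
                   ylim = range(c(x$k_min, x$k_max), na.rm = TRUE), ...)
    ok <- stats::complete.cases(x$k_min, x$k_max)
    graphics::polygon(c(idx[ok], rev(idx[ok])),
                      c(x$k_min[ok], rev(x$k_max[ok])),
                      col = "grey85", border = NA)
    graphics::lines(idx, x$k_mean)
  }
  invisible(x)
}

#' Write a PDB coloured by force constant
#'
#' B-factor column set to `k_i` (capped at 999.99 by format width) for
#' visual inspection of the rigid core.
#'
#' @param profile a single-system `ForceConstantProfile`.
#' @param system the matching `MolecularSystem`.
#' @param file output PDB path.
#' @return invisibly, `file`.
#' @export
write_rigidity_pdb <- function(profile, system, file) {
  kcol <- if ("k" %in% names(profile)) profile$k else profile$k_mean
  key <- res_key(profile$chain, profile$resid)
  b <- kcol[match(res_key(system$atoms$chain, system$atoms$resid), key)]
  b[is.na(b)] <- -1
  a <- system$atoms
  bio3d::write.pdb(file = file, xyz = system$xyz[1L, ] * 10,
                   type = rep("ATOM", nrow(a)), eleno = a$eleno,
                   elety = a$elety, resid = a$resname, chain = a$chain,
                   resno = a$resid, elesy = a$element,
                   o = rep(1, nrow(a)), b = pmin(b, 999.99))
  invisible(file)
}

#' Conservation of the mechanically rigid residue set
#'
#' Defines the rigid set as the residues whose force constant exceeds the
#' median of the profile, and compares the median normalized entropy (NE)
#' inside that set with the overall median NE, per chain. A rigid-set
#' median below the overall median means rigid residues are preferentially
#' conserved.
#'
#' @param profile a `ForceConstantProfile`.
#' @param ne numeric vector of per-residue NE values aligned with the rows
#'   of `profile` (map MSA columns to residues first; see
#'   [stereochemical_entropy_profile()]).
#' @return data.frame per chain: `chain`, `n_rigid`, `median_ne_rigid`,
#'   `median_ne_all`.
#' @export
rigid_set_conservation <- function(profile, ne) {
  if (length(ne) != nrow(profile)) {
    stop("NE vector length does not match the profile")
  }
  kcol <- if ("k" %in% names(profile)) profile$k else profile$k_mean
  out <- lapply(split(seq_len(nrow(profile)), profile$chain), function(idx) {
    k <- kcol[idx]
    med_k <- stats::median(k, na.rm = TRUE)
    rigid <- idx[!is.na(k) & k > med_k]
    data.frame(chain = profile$chain[idx[1L]],
               n_rigid = length(rigid),
               median_ne_rigid = stats::median(ne[rigid], na.rm = TRUE),
               median_ne_all = stats::median(ne[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
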