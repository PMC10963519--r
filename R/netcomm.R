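#' Generalized correlation coefficient of two displacement series
#'
#' Mutual-information-based correlation in \[0, 1\] between the 3D
#' displacement series of two residues, capturing linear and nonlinear
#' coupling alike. The mutual information I is estimated with the
#' Kraskov k-nearest-neighbour estimator on the displacement vectors and
#' mapped to a correlation scale by
#' `r = sqrt(1 - exp(-2 I / 3))`,
#' which for jointly Gaussian series with per-axis correlation rho returns
#' rho exactly (since then `I = -(3/2) log(1 - rho^2)`).
#'
#' @param series_i,series_j numeric matrices, frames x 3, of displacements
#'   (positions are mean-centered internally).
#' @param k number of nearest neighbours for the estimator (default 5).
#' @param jitter_seed seed for the deterministic sub-tolerance jitter that
#'   breaks distance ties in the estimator.
#' @param min_frames minimum series length (default 100).
#' @return scalar in \[0, 1\]; zero-variance series return 0 with a warning.
#' @export
generalized_correlation <- function(series_i, series_j, k = 5L,
                                    jitter_seed = 1L, min_frames = 100L) {
  series_i <- as.matrix(series_i); series_j <- as.matrix(series_j)
  nf <- nrow(series_i)
  if (nrow(series_j) != nf) stop("series length mismatch")
  if (nf < min_frames) {
    stop("too few frames (", nf, ") for the mutual-information estimator; ",
         "need >= ", min_frames)
  }
  si <- stats::sd(as.vector(series_i)); sj <- stats::sd(as.vector(series_j))
  if (si == 0 || sj == 0) {
    warning("zero-variance series: generalized correlation defined as 0")
    return(0)
  }
  series_i <- sweep(series_i, 2L, colMeans(series_i))
  series_j <- sweep(series_j, 2L, colMeans(series_j))
  # deterministic tie-breaking jitter, orders of magnitude below the signal
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(as.integer(jitter_seed))
  series_i <- series_i + matrix(stats::rnorm(length(series_i), 0, si * 1e-8),
                                nrow = nf)
  series_j <- series_j + matrix(stats::rnorm(length(series_j), 0, sj * 1e-8),
                                nrow = nf)
  I <- ksg_mi_cpp(series_i, series_j, as.integer(k))
  r <- sqrt(max(0, 1 - exp(-2 * max(I, 0) / 3)))
  min(max(r, 0), 1)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Build the contact-gated, correlation-weighted dynamical network
#'
#' Residue-level network: one node per residue (from a [select_nodes()]
#' selection); an edge joins residues i, j iff they are in heavy-atom
#' contact (any atom pair within `contact_cutoff`) in at least
#' `contact_fraction` of the frames and are neither the same residue nor
#' covalent (i, i+-1) neighbours within a chain. Each edge carries the
#' generalized correlation coefficient of the two node-atom displacement
#' series as weight.
#'
#' @param system an aligned, equilibrated `MolecularSystem`.
#' @param nodes a `NodeSelection`.
#' @param contact_cutoff heavy-atom contact cutoff in nm (default 0.45).
#' @param contact_fraction minimum fraction of frames in contact
#'   (default 0.75).
#' @param k nearest-neighbour count of the mutual-information estimator.
#' @param seed seed for the estimator's tie-breaking jitter.
#' @return a `DynamicalNetwork`: list with `nodes`, `adjacency` (0/1
#'   matrix), `weights` (generalized correlations), `contact_fraction`
#'   matrix, and the gating parameters.
#' @export
build_network <- function(system, nodes, contact_cutoff = 0.45,
                          contact_fraction = 0.75, k = 5L, seed = 1L) {
  n <- nrow(nodes)
  nf <- n_frames(system)
  # residue-residue contact fractions over the node residues (heavy atoms)
  heavy <- residue_group(system)
  heavy$key <- res_key(heavy$chain, heavy$resid)
  node_key <- res_key(nodes$chain, nodes$resid)
  heavy <- heavy[heavy$key %in% node_key, , drop = FALSE]
  ridx <- match(heavy$key, node_key)
  coords <- group_coords(system, heavy)
  cut2 <- contact_cutoff^2
  counts <- matrix(0L, n, n)
  for (f in seq_len(nf)) {
    d2 <- frame_dist2(frame_slice(coords, f), frame_slice(coords, f))
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    hit <- hit[ridx[hit[, 1L]] < ridx[hit[, 2L]], , drop = FALSE]
    if (nrow(hit) == 0L) next
    pairs <- unique(cbind(ridx[hit[, 1L]], ridx[hit[, 2L]]))
    counts[pairs] <- counts[pairs] + 1L
  }
  cfrac <- counts / nf
  cfrac <- cfrac + t(cfrac)
  adjacency <- (cfrac >= contact_fraction) * 1L
  # exclude covalently adjacent residues within a chain
  same_chain <- outer(nodes$chain, nodes$chain, `==`)
  adj_res <- abs(outer(nodes$resid, nodes$resid, `-`)) == 1L
  adjacency[same_chain & adj_res] <- 0L
  diag(adjacency) <- 0L
  if (sum(adjacency) == 0L) {
    stop("empty network: no residue pair passes the contact gate (cutoff ",
         contact_cutoff, " nm, fraction ", contact_fraction, ")")
  }
  # displacement series of the node atoms
  disp <- lapply(nodes$atom_index, function(ai) {
    x <- atom_coords(system, ai)
    sweep(x, 2L, colMeans(x))
  })
  weights <- matrix(0, n, n)
  ut <- which(upper.tri(adjacency) & adjacency == 1L, arr.ind = TRUE)
  for (e in seq_len(nrow(ut))) {
    i <- ut[e, 1L]; j <- ut[e, 2L]
    w <- generalized_correlation(disp[[i]], disp[[j]], k = k,
                                 jitter_seed = seed + i * 131L + j)
    weights[i, j] <- w; weights[j, i] <- w
  }
  rn <- paste0(nodes$chain, ":", nodes$resid)
  dimnames(adjacency) <- dimnames(weights) <- dimnames(cfrac) <- list(rn, rn)
  structure(list(nodes = nodes, adjacency = adjacency, weights = weights,
                 contact_fraction = cfrac,
                 params = list(contact_cutoff = contact_cutoff,
                               contact_fraction = contact_fraction,
                               k = k, seed = seed)),
            class = "DynamicalNetwork")
}

#' @export
print.DynamicalNetwork <- function(x, ...) {
  ne <- sum(x$adjacency) / 2
  cat("DynamicalNetwork:", nrow(x$nodes), "nodes,", ne, "edges",
      "( contact cutoff", x$params$contact_cutoff, "nm, fraction >=",
      x$params$contact_fraction, ")\n")
  if (ne > 0) {
    w <- x$weights[upper.tri(x$weights) & x$adjacency == 1L]
    cat("  edge weights: min", round(min(w), 3), " median",
        round(stats::median(w), 3), " max", round(max(w), 3), "\n")
  }
  invisible(x)
}

#' Edge list of a dynamical network
#' @param network a `DynamicalNetwork`.
#' @return data.frame `i`, `j` (node indices, i < j), node labels, `weight`.
#' @export
network_edges <- function(network) {
  ut <- which(upper.tri(network$adjacency) & network$adjacency == 1L,
              arr.ind = TRUE)
  nd <- network$nodes
  data.frame(
    i = ut[, 1L], j = ut[, 2L],
    chain_i = nd$chain[ut[, 1L]], resid_i = nd$resid[ut[, 1L]],
    chain_j = nd$chain[ut[, 2L]], resid_j = nd$resid[ut[, 2L]],
    weight = network$weights[ut],
    stringsAsFactors = FALSE
  )
}

#' Weighted degree centrality
#'
#' `dg_i = sum_j A_ij w_ij`: the sum of the generalized correlations on a
#' node's edges, a measure of local influence.
#'
#' @param network a `DynamicalNetwork`.
#' @return data.frame `node`, `chain`, `resid`, `degree`.
#' @export
degree_centrality <- function(network) {
  dg <- rowSums(network$adjacency * network$weights)
  data.frame(node = network$nodes$node, chain = network$nodes$chain,
             resid = network$nodes$resid, degree = as.numeric(dg))
}

#' Convert to an igraph graph
#' @param network a `DynamicalNetwork`.
#' @return an undirected weighted `igraph` object.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_adjacency_matrix(
    network$adjacency * network$weights,
    mode = "undirected", weighted = TRUE, diag = FALSE
  )
  igraph::V(g)$chain <- network$nodes$chain
  igraph::V(g)$resid <- network$nodes$resid
  g
}

#' Export a network as GraphML
#' @param network a `DynamicalNetwork`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_graphml <- function(network, file) {
  igraph::write_graph(as_igraph(network), file, format = "graphml")
  invisible(file)
}
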