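# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; nothing is read from disk.

# A bare MolecularSystem from a frames x atoms x 3 coordinate array.
make_system <- function(coords, chain = NULL, resname = "ALA",
                        elety = "CA", element = "C", resid = NULL,
                        replicas = NULL) {
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(1L, dim(coords)))
  }
  na <- dim(coords)[2L]
  if (is.null(chain)) chain <- rep("A", na)
  if (is.null(resid)) {
    resid <- stats::ave(seq_len(na), chain, FUN = seq_along)
  }
  atoms <- data.frame(
    eleno = seq_len(na),
    elety = rep_len(elety, na),
    resid = resid,
    resname = rep_len(resname, na),
    chain = rep_len(chain, na),
    element = rep_len(element, na),
    stringsAsFactors = FALSE
  )
  nf <- dim(coords)[1L]
  xyz <- matrix(0, nf, 3L * na)
  for (a in seq_len(na)) xyz[, xyz_idx(a)] <- coords[, a, ]
  molecular_system(atoms, xyz, replicas = replicas)
}

xyz_idx <- function(a) (3L * a - 2L):(3L * a)

# A static system from an atoms data.frame and one coordinate matrix,
# replicated over n frames (used by the interaction-typing tests).
make_static_system <- function(atoms, coords, n_frames = 10L) {
  xyz <- matrix(rep(as.vector(t(coords)), each = n_frames), n_frames)
  molecular_system(atoms, xyz)
}

atom_row <- function(eleno, elety, resid, resname, chain,
                     element = substr(elety, 1, 1)) {
  data.frame(eleno = eleno, elety = elety, resid = resid,
             resname = resname, chain = chain, element = element,
             stringsAsFactors = FALSE)
}

# ---- independent betweenness oracle: exhaustive simple-path enumeration --

oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  node_raw <- numeric(n)
  edge_raw <- matrix(0, n, n)
  len <- function(path) {
    sum(-log(W[cbind(path[-length(path)], path[-1L])]))
  }
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (v in which(W[u, ] > 0)) {
        if (!(v %in% path)) walk(c(path, v))
      }
    }
    walk(s)
    out
  }
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, len, numeric(1L))
      best <- min(lens)
      opt <- paths[lens <= best + tol * max(1, abs(best))]
      sig <- length(opt)
      for (p in opt) {
        inner <- setdiff(p, c(s, t))
        node_raw[inner] <- node_raw[inner] + 1 / sig
        for (e in seq_len(length(p) - 1L)) {
          lo <- min(p[e], p[e + 1L]); hi <- max(p[e], p[e + 1L])
          edge_raw[lo, hi] <- edge_raw[lo, hi] + 1 / sig
        }
      }
    }
  }
  list(node = node_raw * 2 / ((n - 1) * (n - 2)),
       edge = edge_raw * 2 / (n * (n - 1)))
}

# random connected weighted graph on n nodes (spanning tree + extra edges)
random_weighted_graph <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1L, 1L)
    W[u, v] <- W[v, u] <- runif(1, 0.1, 0.95)
  }
  extra <- which(upper.tri(W) & W == 0)
  if (length(extra) > 0L) {
    add <- extra[runif(length(extra)) < 0.4]
    W[add] <- runif(length(add), 0.1, 0.95)
    W <- pmax(W, t(W))
  }
  W
}

run_betweenness <- function(W) {
  betweenness_centrality(list(weights = W))
}

# dense matrices from a CentralityReport, for oracle comparison
report_as_matrices <- function(report, n) {
  node <- numeric(n)
  node[report$node_betweenness$node] <- report$node_betweenness$betweenness
  edge <- matrix(0, n, n)
  eb <- report$edge_betweenness
  edge[cbind(eb$i, eb$j)] <- eb$betweenness
  list(node = node, edge = edge)
}

# sample per-axis Pearson correlation between two beads of a system
axis_correlations <- function(system, a, b) {
  xa <- system$xyz[, xyz_idx(a)]
  xb <- system$xyz[, xyz_idx(b)]
  vapply(1:3, function(ax) stats::cor(xa[, ax], xb[, ax]), numeric(1L))
}
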