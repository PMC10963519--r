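# Optimal communication paths and betweenness centrality.
#
# The optimal (communication-wise shortest) path between two nodes is the
# one maximizing the PRODUCT of the edge correlations, computed as the
# minimum-length path under additive edge lengths -log(w_ij). Path-length
# ties are resolved with a relative tolerance so that float noise does not
# split genuinely degenerate optima.

.path_tol <- 1e-9

#' Node and edge betweenness centrality of a dynamical network
#'
#' Counts, for every unordered node pair (s, t), the optimal paths
#' sigma(s, t) (maximal product of edge correlations, i.e. minimal summed
#' -log weight) and the share sigma(s, t | i) passing through node i (or
#' edge e). Raw sums are normalized to \[0, 1\] with
#' `2 / ((n - 1)(n - 2))` for nodes and `2 / (n(n - 1))` for edges,
#' n being the node count. Disconnected pairs contribute nothing; each
#' connected component is handled on its own. Zero-weight edges have
#' infinite length and are excluded from path finding.
#'
#' @param network a `DynamicalNetwork`, or a list with `weights` (symmetric
#'   matrix of edge weights in (0, 1\]; 0 = no edge) for direct use on toy
#'   graphs.
#' @return a `CentralityReport`: list with `node_betweenness` (data.frame),
#'   `edge_betweenness` (data.frame), `degree`, `n`, and the normalization
#'   factors.
#' @export
betweenness_centrality <- function(network) {
  W <- if (inherits(network, "DynamicalNetwork")) {
    network$adjacency * network$weights
  } else {
    as.matrix(network$weights)
  }
  n <- nrow(W)
  if (n < 2L) stop("network needs at least 2 nodes")
  if (any(W < 0)) stop("negative edge weights")
  dropped <- 0L
  # adjacency lists with -log lengths; w == 0 edges are non-edges
  nbrs <- vector("list", n)
  lens <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(W[i, ] > 0)
    js <- js[js != i]
    nbrs[[i]] <- js
    lens[[i]] <- -log(W[i, js])
  }
  node_raw <- numeric(n)
  edge_raw <- matrix(0, n, n)
  for (s in seq_len(n)) {
    # phase 1: plain Dijkstra for the final distances
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- NA_integer_; best <- Inf
      for (v in seq_len(n)) {
        if (!done[v] && dist[v] < best) { best <- dist[v]; u <- v }
      }
      if (is.na(u)) break
      done[u] <- TRUE
      js <- nbrs[[u]]; ls <- lens[[u]]
      for (e in seq_along(js)) {
        v <- js[e]
        alt <- dist[u] + ls[e]
        if (alt < dist[v]) dist[v] <- alt
      }
    }
    # phase 2: tolerance-tied shortest-path DAG, sigma counts, dependencies
    reach <- which(is.finite(dist))
    ord <- reach[order(dist[reach])]
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    for (v in ord) {
      if (v == s) next
      js <- nbrs[[v]]; ls <- lens[[v]]
      for (e in seq_along(js)) {
        u <- js[e]
        if (!is.finite(dist[u])) next
        tol <- .path_tol * max(1, abs(dist[v]))
        if (abs(dist[u] + ls[e] - dist[v]) <= tol &&
            dist[v] - dist[u] > tol) {
          preds[[v]] <- c(preds[[v]], u)
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(ord)) {
      for (u in preds[[v]]) {
        c_uv <- sigma[u] / sigma[v] * (1 + delta[v])
        delta[u] <- delta[u] + c_uv
        lo <- min(u, v); hi <- max(u, v)
        edge_raw[lo, hi] <- edge_raw[lo, hi] + c_uv
      }
      if (v != s) node_raw[v] <- node_raw[v] + delta[v]
    }
  }
  # every unordered pair was counted from both endpoints
  node_raw <- node_raw / 2
  edge_raw <- edge_raw / 2
  node_norm <- 2 / ((n - 1) * (n - 2))
  edge_norm <- 2 / (n * (n - 1))
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(
    i = ut[, 1L], j = ut[, 2L], weight = W[ut],
    betweenness = edge_raw[ut] * edge_norm,
    raw = edge_raw[ut]
  )
  nodes_df <- data.frame(
    node = seq_len(n),
    betweenness = node_raw * node_norm,
    raw = node_raw
  )
  if (inherits(network, "DynamicalNetwork")) {
    nd <- network$nodes
    nodes_df$chain <- nd$chain; nodes_df$resid <- nd$resid
    edges$chain_i <- nd$chain[edges$i]; edges$resid_i <- nd$resid[edges$i]
    edges$chain_j <- nd$chain[edges$j]; edges$resid_j <- nd$resid[edges$j]
  }
  structure(list(node_betweenness = nodes_df,
                 edge_betweenness = edges[order(-edges$betweenness), ],
                 n = n,
                 node_normalization = node_norm,
                 edge_normalization = edge_norm),
            class = "CentralityReport")
}

#' @export
print.CentralityReport <- function(x, ...) {
  cat("CentralityReport:", x$n, "nodes,", nrow(x$edge_betweenness),
      "edges\n")
  cat("  top edge betweenness:",
      paste(round(utils::head(x$edge_betweenness$betweenness, 3L), 4L),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot the ranked edge-betweenness curve
#' @param x a `CentralityReport`.
#' @param knee optional knee value to mark with a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.CentralityReport <- function(x, knee = NULL, ...) {
  v <- sort(x$edge_betweenness$betweenness, decreasing = TRUE)
  graphics::plot(seq_along(v), v, type = "b", pch = 16, cex = 0.6,
                 xlab = "edge rank", ylab = "edge betweenness", ...)
  if (!is.null(knee)) graphics::abline(h = knee, lty = 2)
  invisible(x)
}

#' Knee of a ranked betweenness curve
#'
#' Finds the knee (elbow) of a descending ranked-value curve as the point
#' of maximum perpendicular distance from the chord joining its first and
#' last points, and returns the value attained there. Given several curves
#' (one per system), the minimum of the per-curve knee values is the shared
#' threshold.
#'
#' @param ranked_values a descending numeric vector, or a list of such
#'   vectors (one per system).
#' @return for a single curve, the betweenness value at the knee; for a
#'   list, a list with per-system `knees` and the shared `threshold`
#'   (their minimum).
#' @export
knee_threshold <- function(ranked_values) {
  if (is.list(ranked_values)) {
    knees <- vapply(ranked_values, knee_threshold, numeric(1L))
    return(list(knees = knees, threshold = min(knees)))
  }
  v <- as.numeric(ranked_values)
  m <- length(v)
  if (m < 3L) stop("knee detection needs at least 3 points")
  if (is.unsorted(rev(v))) v <- sort(v, decreasing = TRUE)
  x <- seq_len(m)
  # perpendicular distance of each point from the first-to-last chord
  x1 <- x[1L]; y1 <- v[1L]; x2 <- x[m]; y2 <- v[m]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * x - (x2 - x1) * v + x2 * y1 - y2 * x1) / denom
  if (max(d) < 1e-12 * max(1, abs(y1))) {
    warning("ranked curve is linear; no knee, returning the last value")
    return(v[m])
  }
  v[which.max(d)]
}

#' Top-betweenness edges above a threshold, with interface annotation
#'
#' Returns the edges whose betweenness exceeds the threshold, annotated by
#' whether they cross a chain-chain interface (and which), plus a per-chain
#' aggregation of node and edge betweenness suitable for box plots.
#'
#' @param network a `DynamicalNetwork`.
#' @param report the matching `CentralityReport`.
#' @param threshold betweenness threshold (e.g. from [knee_threshold()]).
#' @param interface_map optional function `(chain_i, chain_j) -> label`
#'   naming the interface an inter-chain edge crosses.
#' @return list with `edges` (the filtered, annotated table), `node_dist`
#'   and `edge_dist` (per-chain betweenness distributions).
#' @export
top_edges <- function(network, report, threshold, interface_map = NULL) {
  eb <- report$edge_betweenness
  keep <- eb[eb$betweenness > threshold, , drop = FALSE]
  nd <- network$nodes
  if (nrow(keep) > 0L) {
    keep$cross_chain <- keep$chain_i != keep$chain_j
    keep$interface <- NA_character_
    if (!is.null(interface_map)) {
      cc <- which(keep$cross_chain)
      keep$interface[cc] <- vapply(cc, function(r) {
        interface_map(keep$chain_i[r], keep$chain_j[r])
      }, character(1L))
    }
  }
  nb <- report$node_betweenness
  node_dist <- split(nb$betweenness, nd$chain[nb$node])
  ch_e <- paste(pmin(eb$chain_i, eb$chain_j), pmax(eb$chain_i, eb$chain_j),
                sep = "-")
  edge_dist <- split(eb$betweenness, ch_e)
  list(edges = keep, node_dist = node_dist, edge_dist = edge_dist)
}
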