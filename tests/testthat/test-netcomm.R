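test_that("generalized correlation has the right limits", {
  s <- gen_correlated_ensemble(diag(2), 5000, seed = 23)
  xi <- s$xyz[, 1:3]
  xj <- s$xyz[, 4:6]
  # independent series stay near 0
  expect_lt(generalized_correlation(xi, xj), 0.1)
  # identical series saturate toward 1
  expect_gt(generalized_correlation(xi, xi), 0.95)
  # zero-variance series are defined as 0 with a warning
  expect_warning(
    r0 <- generalized_correlation(matrix(0, 200, 3), xj[1:200, ]),
    "zero-variance")
  expect_identical(r0, 0)
  expect_error(generalized_correlation(xi[1:50, ], xj[1:50, ]), "too few")
})

test_that("generalized correlation recovers Gaussian per-axis correlations", {
  # analytic identity for Gaussians: I = -(3/2) log(1 - rho^2) => r = rho
  for (rho in c(0.4, 0.8)) {
    C <- matrix(c(1, rho, rho, 1), 2)
    s <- gen_correlated_ensemble(C, 5000, seed = 100 + round(10 * rho))
    r <- generalized_correlation(s$xyz[, 1:3], s$xyz[, 4:6])
    expect_lt(abs(r - rho), 0.05)
  }
})

test_that("network construction matches the sheet ground truth", {
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 300,
                                 seed = 24))
  sys <- sh$system
  nodes <- select_nodes(sys)
  net <- build_network(sys, nodes)
  ed <- network_edges(net)
  inter <- ed[ed$chain_i != ed$chain_j, ]
  got <- unique(paste(pmin(inter$chain_i, inter$chain_j),
                      pmax(inter$chain_i, inter$chain_j)))
  cp <- sh$truth$contact_pairs
  want <- paste(pmin(cp$chain_a, cp$chain_b), pmax(cp$chain_a, cp$chain_b))
  expect_setequal(got, want[cp$expected_edge])
  # covalently adjacent residues never form edges
  same_chain <- ed$chain_i == ed$chain_j
  expect_true(all(abs(ed$resid_i - ed$resid_j)[same_chain] != 1L))
  # stronger designed couplings carry larger weights (rank agreement)
  C <- sh$truth$correlation
  inter$design <- mapply(function(a, b) C[a, b], inter$chain_i,
                         inter$chain_j)
  agg <- stats::aggregate(cbind(weight, design) ~ chain_i + chain_j,
                          inter, max)
  expect_gt(stats::cor(agg$weight, agg$design, method = "spearman"), 0.6)
  # weights and adjacency are symmetric by construction
  expect_identical(net$weights, t(net$weights))
  expect_identical(net$adjacency, t(net$adjacency))
})

test_that("restrained chains are excluded from the network", {
  corners <- list(c(1, 1), c(2, 3))
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 150,
                                 restrained_blocks = corners, seed = 25))
  frozen <- sh$truth$blocks$chain[sh$truth$blocks$restrained]
  nodes <- select_nodes(sh$system, exclude_chains = frozen)
  net <- build_network(sh$system, nodes)
  expect_false(any(frozen %in% net$nodes$chain))
  ed <- network_edges(net)
  expect_false(any(ed$chain_i %in% frozen | ed$chain_j %in% frozen))
})

test_that("degree centrality follows the weighted-sum definition", {
  tri <- list(weights = matrix(c(0, 0.5, 0.5,
                                 0.5, 0, 0.5,
                                 0.5, 0.5, 0), 3))
  net <- structure(list(
    nodes = data.frame(node = 1:3, chain = "A", resid = 1:3),
    adjacency = (tri$weights > 0) * 1L, weights = tri$weights),
    class = "DynamicalNetwork")
  expect_equal(degree_centrality(net)$degree, c(1, 1, 1))
  single <- matrix(0, 3, 3); single[1, 2] <- single[2, 1] <- 0.7
  net$weights <- single; net$adjacency <- (single > 0) * 1L
  expect_equal(degree_centrality(net)$degree, c(0.7, 0.7, 0))
  # random graph vs independent row-sum oracle
  W <- random_weighted_graph(10, seed = 77)
  net$nodes <- data.frame(node = 1:10, chain = "A", resid = 1:10)
  net$weights <- W; net$adjacency <- (W > 0) * 1L
  expect_equal(degree_centrality(net)$degree, unname(rowSums(W)))
})

test_that("betweenness matches analytic three-node cases", {
  # path A-B-C with equal weights: all traffic transits B
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 0.5
  path[2, 3] <- path[3, 2] <- 0.5
  rep <- run_betweenness(path)
  b <- rep$node_betweenness$betweenness
  expect_equal(b, c(0, 1, 0))
  eb <- rep$edge_betweenness
  expect_equal(sort(eb$betweenness), c(2 / 3, 2 / 3))
  # complete graph, equal weights < 1: direct edges always win
  k3 <- matrix(0.5, 3, 3); diag(k3) <- 0
  rep3 <- run_betweenness(k3)
  expect_equal(rep3$node_betweenness$betweenness, c(0, 0, 0))
  expect_equal(rep3$edge_betweenness$betweenness, rep(1 / 3, 3))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  for (seed in 1:25) {
    n <- sample(3:6, 1)
    W <- random_weighted_graph(n, seed = 1000 + seed)
    got <- report_as_matrices(run_betweenness(W), n)
    want <- oracle_betweenness(W)
    expect_equal(got$node, want$node, tolerance = 1e-12)
    expect_equal(got$edge, want$edge, tolerance = 1e-12)
  }
})

test_that("betweenness handles degenerate ties by counting all optima", {
  # 4-cycle with equal weights: two tied paths between opposite corners
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5; W[1, 4] <- W[4, 1] <- 0.5
  rep <- run_betweenness(W)
  # each node transits half of exactly one opposite pair: raw 0.5,
  # normalized by 2/((4-1)(4-2)) = 1/3
  expect_equal(rep$node_betweenness$betweenness, rep(0.5 / 3, 4))
  want <- oracle_betweenness(W)
  got <- report_as_matrices(rep, 4)
  expect_equal(got$node, want$node, tolerance = 1e-12)
  expect_equal(got$edge, want$edge, tolerance = 1e-12)
})

test_that("betweenness is invariant under uniform weight scaling on trees", {
  # on a tree every pair has a unique path, so -log shifts cancel exactly
  set.seed(31)
  n <- 7
  W <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    W[u, v] <- W[v, u] <- runif(1, 0.2, 0.9)
  }
  base <- report_as_matrices(run_betweenness(W), n)
  for (c in c(0.3, 0.7, 1)) {
    scaled <- report_as_matrices(run_betweenness(W * c), n)
    expect_equal(scaled$node, base$node, tolerance = 1e-12)
    expect_equal(scaled$edge, base$edge, tolerance = 1e-12)
  }
})

test_that("knee thresholding finds the corner of ranked curves", {
  # oracle: hand max-distance-to-chord computation over the L-curve
  curve <- c(10, 9.5, 9, 1, 0.9, 0.8)
  x <- seq_along(curve)
  d <- abs((curve[6] - curve[1]) * x - (6 - 1) * curve +
             6 * curve[1] - curve[6] * 1)
  expect_identical(which.max(d), 4L)
  expect_identical(knee_threshold(curve), curve[which.max(d)])
  # strictly linear curve: warning, last value
  expect_warning(lin <- knee_threshold(seq(10, 1, length.out = 6)),
                 "linear")
  expect_identical(lin, 1)
  # multi-system: the lowest knee is the shared threshold
  multi <- knee_threshold(list(c(10, 9, 5, 1, 0.9, 0.8) + 0,
                               c(8, 7, 3, 0.5, 0.4, 0.3),
                               c(9, 8, 4, 0.7, 0.6, 0.5)))
  expect_identical(multi$threshold, min(multi$knees))
  expect_error(knee_threshold(c(1, 2)), "at least 3")
})

test_that("top-edge filtering respects the threshold and annotations", {
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 2, n_frames = 150,
                                 seed = 26))
  nodes <- select_nodes(sh$system)
  net <- build_network(sh$system, nodes)
  rep <- betweenness_centrality(net)
  above_max <- top_edges(net, rep, max(rep$edge_betweenness$betweenness))
  expect_identical(nrow(above_max$edges), 0L)
  all_edges <- top_edges(net, rep, -1)
  expect_identical(nrow(all_edges$edges), nrow(rep$edge_betweenness))
  expect_true(all(c("cross_chain", "interface") %in%
                    names(all_edges$edges)))
  # per-chain distributions cover every chain
  expect_setequal(names(all_edges$node_dist), unique(nodes$chain))
})
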