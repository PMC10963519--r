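test_that("correlated ensembles realize their designed correlations", {
  # independence: identity matrix
  s0 <- gen_correlated_ensemble(diag(4), n_frames = 5000, seed = 11)
  for (a in 1:3) {
    for (b in (a + 1):4) {
      expect_true(all(abs(axis_correlations(s0, a, b)) < 0.05))
    }
  }
  # designed pairwise correlation 0.8
  C <- matrix(c(1, 0.8, 0.8, 1), 2)
  s <- gen_correlated_ensemble(C, n_frames = 5000, seed = 12)
  expect_true(all(abs(axis_correlations(s, 1, 2) - 0.8) < 0.05))
})

test_that("correlated ensembles are deterministic and reject bad matrices", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  s1 <- gen_correlated_ensemble(C, 50, seed = 7)
  s2 <- gen_correlated_ensemble(C, 50, seed = 7)
  expect_identical(s1$xyz, s2$xyz)
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(gen_correlated_ensemble(bad, 10, 1), "positive semi-definite")
  notsym <- matrix(c(1, 0.2, 0.5, 1), 2)
  expect_error(gen_correlated_ensemble(notsym, 10, 1), "symmetric")
})

test_that("harmonic probes sample the Boltzmann variance of the well", {
  s <- gen_harmonic_ensemble(748.3, 300, n_frames = 50000, seed = 3)
  probe <- s$xyz[, 1:3]
  target <- kB * 300 / 748.3
  for (ax in 1:3) {
    expect_lt(abs(stats::var(probe[, ax]) / target - 1), 0.05)
  }
  # doubling k halves the variance
  s2 <- gen_harmonic_ensemble(2 * 748.3, 300, n_frames = 50000, seed = 4)
  ratio <- stats::var(s2$xyz[, 1]) / stats::var(probe[, 1])
  expect_lt(abs(ratio - 0.5), 0.05)
  # reproducibility and validation
  expect_identical(gen_harmonic_ensemble(100, 300, 20, seed = 9)$xyz,
                   gen_harmonic_ensemble(100, 300, 20, seed = 9)$xyz)
  expect_error(gen_harmonic_ensemble(-1, 300, 10, 1), "positive")
  expect_error(gen_harmonic_ensemble(100, 0, 10, 1), "positive")
})

test_that("toy sheets realize their contact geometry", {
  # no seam: adjacent blocks always in contact, non-adjacent never
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 200,
                                 seed = 21))
  sys <- sh$system
  tr <- sh$truth
  cutoff <- 0.45
  chains <- tr$blocks$chain
  # brute-force distance check over all frames and block pairs
  min_dist <- function(ca, cb) {
    ia <- which(sys$atoms$chain == ca)
    ib <- which(sys$atoms$chain == cb)
    m <- Inf
    for (f in seq_len(n_frames(sys))) {
      xa <- matrix(sys$xyz[f, as.vector(rbind(3 * ia - 2, 3 * ia - 1, 3 * ia))],
                   ncol = 3, byrow = TRUE)
      xb <- matrix(sys$xyz[f, as.vector(rbind(3 * ib - 2, 3 * ib - 1, 3 * ib))],
                   ncol = 3, byrow = TRUE)
      m <- min(m, sqrt(min(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                             2 * tcrossprod(xa, xb))))
    }
    m
  }
  max_facing <- function(ca, cb) {
    ia <- which(sys$atoms$chain == ca)
    ib <- which(sys$atoms$chain == cb)
    mx <- 0
    for (f in seq_len(n_frames(sys))) {
      xa <- matrix(sys$xyz[f, as.vector(rbind(3 * ia - 2, 3 * ia - 1, 3 * ia))],
                   ncol = 3, byrow = TRUE)
      xb <- matrix(sys$xyz[f, as.vector(rbind(3 * ib - 2, 3 * ib - 1, 3 * ib))],
                   ncol = 3, byrow = TRUE)
      mx <- max(mx, sqrt(min(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                               2 * tcrossprod(xa, xb))))
    }
    mx
  }
  adj <- paste(tr$contact_pairs$chain_a, tr$contact_pairs$chain_b)
  for (a in seq_along(chains)) {
    for (b in seq_along(chains)) {
      if (a >= b) next
      key <- paste(chains[a], chains[b])
      key2 <- paste(chains[b], chains[a])
      if (key %in% adj || key2 %in% adj) {
        expect_lt(max_facing(chains[a], chains[b]), cutoff)
      } else {
        expect_gt(min_dist(chains[a], chains[b]), cutoff)
      }
    }
  }
})

test_that("seam sheets mark exactly one weak lateral interface", {
  sh <- gen_toy_sheet(sheet_spec(coupling_lat = 0.7, coupling_seam = 0.2,
                                 seam_col = 3, n_frames = 50, seed = 5))
  cp <- sh$truth$contact_pairs
  expect_identical(sum(cp$weak), 1L)
  expect_identical(cp$type[cp$weak], "lateral")
  # the weak interface is expected to fail the default contact gate
  expect_false(cp$expected_edge[cp$weak])
  expect_true(all(cp$expected_edge[!cp$weak]))
  expect_error(sheet_spec(seam_col = 9), "seam_col")
})

test_that("restrained blocks are exactly frozen", {
  corners <- list(c(1, 1), c(1, 4), c(2, 1), c(2, 4))
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 4, n_frames = 60,
                                 restrained_blocks = corners, seed = 8))
  blocks <- sh$truth$blocks
  frozen <- blocks$chain[blocks$restrained]
  expect_length(frozen, 4L)
  for (ch in frozen) {
    ia <- which(sh$system$atoms$chain == ch)
    for (a in ia) {
      xyz <- sh$system$xyz[, (3 * a - 2):(3 * a)]
      expect_identical(max(apply(xyz, 2, stats::var)), 0)
    }
  }
  expect_error(sheet_spec(restrained_blocks = list(c(5, 1))), "outside")
})

test_that("sheet generation is file-level deterministic", {
  spec <- sheet_spec(n_rows = 2, n_cols = 3, n_frames = 30, seed = 42,
                     seam_col = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sheet(gen_toy_sheet(spec), d1)
  p2 <- write_sheet(gen_toy_sheet(spec), d2)
  for (k in c("pdb", "dcd", "truth")) {
    expect_identical(unname(tools::md5sum(p1[k])),
                     unname(tools::md5sum(p2[k])))
  }
})

test_that("two-state ensembles record their state assignment", {
  s <- gen_two_state_ensemble(0.5, n_frames_per_state = 40, seed = 2)
  st <- attr(s, "state")
  expect_identical(st, rep(1:2, each = 40))
  # within-state spread is tiny compared with the between-state shift
  mean_a <- colMeans(s$xyz[st == 1, ])
  mean_b <- colMeans(s$xyz[st == 2, ])
  shift <- sqrt(mean((mean_a - mean_b)^2) * 3)
  expect_gt(shift, 0.2)
  s0 <- gen_two_state_ensemble(0, n_frames_per_state = 40, seed = 2)
  mean_a0 <- colMeans(s0$xyz[1:40, ])
  mean_b0 <- colMeans(s0$xyz[41:80, ])
  expect_lt(sqrt(mean((mean_a0 - mean_b0)^2)), 0.02)
})

test_that("toy MSAs realize their column profiles", {
  classes <- c("A", "F", "S", "K", "D", "G")
  prof_uniform <- stats::setNames(rep(1 / 6, 6), classes)
  spec <- msa_spec(600, list(
    c(A = 1.0),
    prof_uniform,
    c(A = 0.8, "-" = 0.2)
  ), seed = 31)
  msa <- gen_toy_msa(spec)
  expect_identical(dim(msa$ali), c(600L, 3L))
  expect_true(all(msa$ali[, 1] == "A"))
  counts <- table(factor(msa$ali[, 2], levels = classes))
  expect_true(all(abs(counts - 100) < 40))
  expect_lt(abs(mean(msa$ali[, 3] == "-") - 0.2), 0.05)
  # determinism through the FASTA writer
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(gen_toy_msa(spec), f1)
  write_msa(gen_toy_msa(spec), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(msa_spec(10, list(c(A = 0.5))), "sum to 1")
  expect_error(msa_spec(10, list(c("-" = 1))), "gap fraction")
})
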