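test_that("contact frequencies equal designed frame fractions", {
  # two single-atom residues: inside the cutoff in 60 of 100 frames
  nf <- 100
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 1] <- ifelse(seq_len(nf) <= 60, 0.3, 1.0)
  sys <- make_system(coords, chain = c("A", "B"))
  ga <- residue_group(sys, chains = "A")
  gb <- residue_group(sys, chains = "B")
  ct <- contact_frequency(sys, ga, gb, cutoff = 0.45)
  expect_identical(ct$frequency, 0.6)
  marg <- attr(ct, "marginals")
  expect_identical(marg$frequency, c(0.6, 0.6))
  expect_error(contact_frequency(sys, ga, ga, cutoff = 0.45), "disjoint")
})

test_that("sheet contacts are 1 for adjacent and 0 for distant blocks", {
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 80,
                                 seed = 15))
  sys <- sh$system
  blocks <- sh$truth$blocks
  ga <- residue_group(sys, chains = blocks$chain[blocks$row == 1])
  gb <- residue_group(sys, chains = blocks$chain[blocks$row == 2])
  ct <- contact_frequency(sys, ga, gb, cutoff = 0.45)
  lat <- ct[ct$chain_i == "A" & ct$chain_j == "D", ]
  expect_identical(max(lat$frequency), 1)       # facing beads always touch
  far <- ct[ct$chain_i == "A" & ct$chain_j == "F", ]
  expect_identical(max(far$frequency), 0)       # diagonal blocks never do
})

test_that("contact frequency is monotone in the cutoff and frame-permutation invariant", {
  set.seed(16)
  nf <- 40
  coords <- array(rnorm(nf * 4 * 3, 0, 0.2), c(nf, 4, 3))
  coords[, 2, 1] <- coords[, 2, 1] + 0.4
  coords[, 3, 2] <- coords[, 3, 2] + 0.6
  coords[, 4, 1] <- coords[, 4, 1] + 1.0
  sys <- make_system(coords, chain = c("A", "A", "B", "B"))
  ga <- residue_group(sys, chains = "A")
  gb <- residue_group(sys, chains = "B")
  cuts <- c(0.2, 0.4, 0.6, 0.9)
  freqs <- vapply(cuts, function(h) {
    contact_frequency(sys, ga, gb, cutoff = h)$frequency
  }, numeric(4))
  for (p in 1:4) expect_true(all(diff(freqs[p, ]) >= 0))
  perm <- sample(nf)
  sys_p <- subset_frames(sys, perm)
  ct1 <- contact_frequency(sys, ga, gb, cutoff = 0.5)
  ct2 <- contact_frequency(sys_p, ga, gb, cutoff = 0.5)
  expect_identical(ct1$frequency, ct2$frequency)
})

test_that("salt bridges are detected from charged-group centroids", {
  # Lys NZ at 0.4 nm from the Asp carboxylate centroid, all frames
  atoms <- rbind(
    atom_row(1, "CA", 1, "LYS", "A"),
    atom_row(2, "NZ", 1, "LYS", "A", element = "N"),
    atom_row(3, "CA", 1, "ASP", "B"),
    atom_row(4, "OD1", 1, "ASP", "B", element = "O"),
    atom_row(5, "OD2", 1, "ASP", "B", element = "O")
  )
  coords <- rbind(
    c(-0.5, 0, 0), c(0, 0, 0),
    c(0.9, 0, 0), c(0.4, 0.05, 0), c(0.4, -0.05, 0)
  )
  sys <- make_static_system(atoms, coords, n_frames = 20)
  ga <- residue_group(sys, chains = "A")
  gb <- residue_group(sys, chains = "B")
  recs <- classify_interactions(sys, ga, gb)
  sb <- recs[recs$type == "salt_bridge", ]
  expect_identical(nrow(sb), 1L)
  expect_identical(sb$frequency, 1)
  # subset property: a salt-bridge pair is also a contact at 0.55 nm
  ct <- contact_frequency(sys, ga, gb, cutoff = 0.55)
  pair <- ct[ct$resname_i == "LYS" & ct$resname_j == "ASP", ]
  expect_gt(max(pair$frequency), 0)
})

test_that("hydrogen bonds respect the distance and angle criteria", {
  mk <- function(angle_deg) {
    # donor N-H ... O acceptor with a controlled D-H...A angle
    h <- c(0.1, 0, 0)
    d <- c(0, 0, 0)
    th <- angle_deg * pi / 180
    a <- h + 0.2 * c(cos(pi - th), sin(pi - th), 0)
    atoms <- rbind(
      atom_row(1, "N", 1, "SER", "A", element = "N"),
      atom_row(2, "H", 1, "SER", "A", element = "H"),
      atom_row(3, "O", 1, "GLY", "B", element = "O")
    )
    make_static_system(atoms, rbind(d, h, a), n_frames = 5)
  }
  sys_good <- mk(170)
  ga <- residue_group(sys_good, chains = "A", heavy_only = FALSE)
  gb <- residue_group(sys_good, chains = "B", heavy_only = FALSE)
  recs <- classify_interactions(sys_good, ga, gb)
  expect_true("hydrogen_bond" %in% recs$type)
  sys_bad <- mk(100)
  recs_bad <- classify_interactions(sys_bad,
                                    residue_group(sys_bad, chains = "A",
                                                  heavy_only = FALSE),
                                    residue_group(sys_bad, chains = "B",
                                                  heavy_only = FALSE))
  expect_false("hydrogen_bond" %in% recs_bad$type)
  # without hydrogens the classifier degrades to distance-only
  sys_noh <- make_static_system(
    rbind(atom_row(1, "N", 1, "SER", "A", element = "N"),
          atom_row(2, "O", 1, "GLY", "B", element = "O")),
    rbind(c(0, 0, 0), c(0.3, 0, 0)), n_frames = 5)
  recs_noh <- classify_interactions(
    sys_noh, residue_group(sys_noh, chains = "A"),
    residue_group(sys_noh, chains = "B"))
  expect_true("hydrogen_bond" %in% recs_noh$type)
  expect_false(attr(recs_noh, "hydrogens_used"))
})

test_that("hydrophobic contacts count their designed frame fraction", {
  atoms <- rbind(
    atom_row(1, "CB", 1, "ALA", "A"),
    atom_row(2, "CB", 1, "VAL", "B")
  )
  nf <- 30
  coords <- array(0, c(nf, 2, 3))
  coords[, 2, 1] <- ifelse(seq_len(nf) <= 15, 0.39, 0.8)
  sys <- molecular_system(atoms, {
    xyz <- matrix(0, nf, 6)
    xyz[, 4] <- coords[, 2, 1]
    xyz
  })
  recs <- classify_interactions(sys, residue_group(sys, chains = "A"),
                                residue_group(sys, chains = "B"))
  hp <- recs[recs$type == "hydrophobic", ]
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$frequency, 0.5)
  # unknown residue names are skipped with a warning
  atoms_unk <- rbind(atom_row(1, "CB", 1, "ALA", "A"),
                     atom_row(2, "XX", 1, "FOO", "B", element = "C"))
  sys_unk <- make_static_system(atoms_unk, rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_warning(classify_interactions(
    sys_unk, residue_group(sys_unk, chains = "A"),
    residue_group(sys_unk, chains = "B")), "unknown")
})

test_that("the stability filter applies a strict 0.75 threshold", {
  rec <- function(freq) {
    data.frame(type = "salt_bridge", chain_i = "A", resid_i = 1L,
               resname_i = "LYS", atom_i = "NZ", chain_j = "B",
               resid_j = 2L, resname_j = "ASP", atom_j = "OD1+OD2",
               frequency = freq, interface = NA_character_,
               stringsAsFactors = FALSE)
  }
  # mean 0.8 -> kept
  kept <- stable_interactions(list(rec(0.9), rec(0.8), rec(0.7)))
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$mean_frequency, 0.8)
  # mean exactly 0.75 -> excluded (strictly greater than)
  out <- stable_interactions(list(rec(0.75), rec(0.75), rec(0.75)))
  expect_identical(nrow(out), 0L)
  # present in one of three systems at 1.0 -> mean 1/3 -> excluded
  empty <- rec(1)[0, ]
  out2 <- stable_interactions(list(rec(1), empty, empty))
  expect_identical(nrow(out2), 0L)
})

test_that("contact-difference maps are antisymmetric and localized", {
  sh <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 60,
                                 seed = 17))
  sys <- sh$system
  blocks <- sh$truth$blocks
  ga <- residue_group(sys, chains = blocks$chain[blocks$row == 1])
  gb <- residue_group(sys, chains = blocks$chain[blocks$row == 2])
  ct <- contact_frequency(sys, ga, gb)
  zero <- contact_difference(ct, ct)
  expect_true(all(zero$diff == 0))
  # antisymmetry against a perturbed table
  sh2 <- gen_toy_sheet(sheet_spec(n_rows = 2, n_cols = 3, n_frames = 60,
                                  seed = 17, seam_col = 2))
  sys2 <- sh2$system
  ct2 <- contact_frequency(sys2, residue_group(sys2, chains = unique(ga$chain)),
                           residue_group(sys2, chains = unique(gb$chain)))
  d12 <- contact_difference(ct2, ct)
  d21 <- contact_difference(ct, ct2)
  expect_equal(d12$diff, -d21$diff)
  # the loss of contacts localizes to the seam-column blocks (B and E)
  seam_chains <- blocks$chain[blocks$col == 2]
  strong_loss <- d12[d12$diff < -0.5, ]
  expect_gt(nrow(strong_loss), 0L)
  expect_true(all(strong_loss$chain %in% seam_chains))
})
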