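# Residue chemistry tables used by the geometric interaction classifier.
# Heavy-atom names follow PDB v3 conventions for the 20 standard residues.

.aa_standard <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.positive_atoms <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2") # only if protonated (config flag)
)

.negative_atoms <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

.hb_donors <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG"
)

.hb_acceptors <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

.apolar_atoms <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG", "CD"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
  HIS = "CB", THR = "CG2", CYS = "CB"
)

#' Geometric criteria for non-covalent interaction typing
#'
#' Distance/angle thresholds of the classifier, following common
#' interaction-profiler conventions. All values are configurable.
#'
#' @param hbond_dist_nm donor-acceptor heavy-atom cutoff (nm).
#' @param hbond_angle_deg minimum D-H...A angle (degrees), used only when
#'   the topology contains hydrogens.
#' @param saltbridge_dist_nm charged-group centroid cutoff (nm).
#' @param hydrophobic_dist_nm apolar-carbon pair cutoff (nm).
#' @param his_protonated treat histidine as positively charged?
#' @return a list of class `interaction_geometry`.
#' @export
interaction_geometry <- function(hbond_dist_nm = 0.35,
                                 hbond_angle_deg = 130,
                                 saltbridge_dist_nm = 0.55,
                                 hydrophobic_dist_nm = 0.40,
                                 his_protonated = FALSE) {
  structure(list(hbond_dist_nm = hbond_dist_nm,
                 hbond_angle_deg = hbond_angle_deg,
                 saltbridge_dist_nm = saltbridge_dist_nm,
                 hydrophobic_dist_nm = hydrophobic_dist_nm,
                 his_protonated = his_protonated),
            class = "interaction_geometry")
}

# atoms of one kind for a residue subset; ligand phosphates count as acidic
pick_atoms <- function(group, table, kind, his_protonated = FALSE) {
  sel <- logical(nrow(group))
  ety <- trimws(group$elety)
  for (i in seq_len(nrow(group))) {
    rn <- group$resname[i]
    if (kind == "donor" || kind == "acceptor") {
      tab <- if (kind == "donor") .hb_donors else .hb_acceptors
      if (ety[i] %in% tab$backbone && rn %in% .aa_standard) sel[i] <- TRUE
      if (!is.null(tab[[rn]]) && ety[i] %in% tab[[rn]]) sel[i] <- TRUE
      if (rn == "HIS" && kind == "donor" && !his_protonated) {
        # neutral His: keep both ring nitrogens as possible donors anyway
      }
    } else if (kind == "positive") {
      if (rn == "HIS" && !his_protonated) next
      if (!is.null(.positive_atoms[[rn]]) && ety[i] %in% .positive_atoms[[rn]]) {
        sel[i] <- TRUE
      }
    } else if (kind == "negative") {
      if (!is.null(.negative_atoms[[rn]]) && ety[i] %in% .negative_atoms[[rn]]) {
        sel[i] <- TRUE
      }
      # nucleotide phosphate oxygens (GTP/GDP and relatives)
      if (!(rn %in% .aa_standard) && grepl("^O[0-9]?[ABG]$|^OP[0-9]", ety[i])) {
        sel[i] <- TRUE
      }
    } else if (kind == "apolar") {
      if (!is.null(.apolar_atoms[[rn]]) && ety[i] %in% .apolar_atoms[[rn]]) {
        sel[i] <- TRUE
      }
    }
  }
  group[sel, , drop = FALSE]
}

# charged-group centroids: one row per (residue, sign)
charge_centroids <- function(system, group, sign, his_protonated) {
  atoms <- pick_atoms(group, NULL, if (sign > 0) "positive" else "negative",
                      his_protonated)
  if (nrow(atoms) == 0L) return(NULL)
  split_idx <- split(seq_len(nrow(atoms)), res_key(atoms$chain, atoms$resid))
  lapply(split_idx, function(idx) {
    sub <- atoms[idx, , drop = FALSE]
    coords <- 0
    for (ai in sub$atom_index) coords <- coords + atom_coords(system, ai)
    list(chain = sub$chain[1L], resid = sub$resid[1L],
         resname = sub$resname[1L],
         atoms = paste(trimws(sub$elety), collapse = "+"),
         xyz = coords / nrow(sub))
  })
}

record_key <- function(type, ci, ri, cj, rj) {
  a <- paste(ci, ri, sep = ":"); b <- paste(cj, rj, sep = ":")
  swap <- a > b
  paste(type, ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

# detect pairs within cutoff per frame between two per-frame coordinate sets
pairwise_freq <- function(xa_list, xb_list, nf, cutoff) {
  # xa_list/xb_list: lists of frames x 3 matrices (one per entity)
  na <- length(xa_list); nb <- length(xb_list)
  counts <- matrix(0L, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d2 <- rowSums((xa_list[[i]] - xb_list[[j]])^2)
      counts[i, j] <- sum(d2 <= cutoff^2)
    }
  }
  counts / nf
}

#' Classify non-covalent interactions between two residue groups
#'
#' Frame-by-frame geometric detection of salt bridges (charged-group
#' centroid distance), hydrogen bonds (donor-acceptor heavy-atom distance,
#' plus the D-H...A angle when the topology has hydrogens), and hydrophobic
#' contacts (apolar-carbon pair distance), aggregated to per-residue-pair
#' frequencies. Residues with names outside the chemistry tables are
#' skipped with a warning.
#'
#' @param system a `MolecularSystem`.
#' @param group_a,group_b atom tables from [residue_group()] (pass
#'   `heavy_only = FALSE` if the topology has hydrogens and you want the
#'   angle criterion).
#' @param geometry an [interaction_geometry()] configuration.
#' @param interface optional label stored with every record (e.g.
#'   "intra-dimer", "lateral-left").
#' @return data.frame of `InteractionRecord` rows: `type`, `chain_i`,
#'   `resid_i`, `resname_i`, `atom_i`, `chain_j`, `resid_j`, `resname_j`,
#'   `atom_j`, `frequency`, `interface`. Attribute `hydrogens_used` records
#'   whether the angle criterion was applied.
#' @export
classify_interactions <- function(system, group_a, group_b,
                                  geometry = interaction_geometry(),
                                  interface = NA_character_) {
  known <- c(.aa_standard, "GTP", "GDP", "ATP", "ADP")
  for (g in list(group_a, group_b)) {
    unk <- setdiff(unique(g$resname), known)
    if (length(unk) > 0L) {
      warning("skipping residues with unknown chemistry: ",
              paste(unk, collapse = ", "))
    }
  }
  group_a <- group_a[group_a$resname %in% known, , drop = FALSE]
  group_b <- group_b[group_b$resname %in% known, , drop = FALSE]
  nf <- n_frames(system)
  has_h <- any(toupper(trimws(system$atoms$element)) == "H")
  records <- list()
  add <- function(type, ea, eb, freq) {
    if (freq <= 0) return()
    k <- record_key(type, ea$chain, ea$resid, eb$chain, eb$resid)
    if (!is.null(records[[k]]) && records[[k]]$frequency >= freq) return()
    records[[k]] <<- data.frame(
      type = type, chain_i = ea$chain, resid_i = ea$resid,
      resname_i = ea$resname, atom_i = ea$atoms,
      chain_j = eb$chain, resid_j = eb$resid, resname_j = eb$resname,
      atom_j = eb$atoms, frequency = freq, interface = interface,
      stringsAsFactors = FALSE
    )
  }

  # --- salt bridges: opposite-charge centroid pairs ---------------------
  for (dir in 1:2) {
    pos <- charge_centroids(system, if (dir == 1) group_a else group_b, +1,
                            geometry$his_protonated)
    neg <- charge_centroids(system, if (dir == 1) group_b else group_a, -1,
                            geometry$his_protonated)
    if (is.null(pos) || is.null(neg)) next
    for (p in pos) for (q in neg) {
      d2 <- rowSums((p$xyz - q$xyz)^2)
      freq <- sum(d2 <= geometry$saltbridge_dist_nm^2) / nf
      if (dir == 1) add("salt_bridge", p, q, freq) else add("salt_bridge", q, p, freq)
    }
  }

  # --- hydrogen bonds: donor-acceptor heavy atoms (+ angle if H present) --
  hb_pair_freq <- function(don_group, acc_group, swap) {
    don <- pick_atoms(don_group, NULL, "donor", geometry$his_protonated)
    acc <- pick_atoms(acc_group, NULL, "acceptor", geometry$his_protonated)
    if (nrow(don) == 0L || nrow(acc) == 0L) return()
    for (i in seq_len(nrow(don))) {
      dxyz <- atom_coords(system, don$atom_index[i])
      hxyz <- if (has_h) donor_hydrogens(system, don[i, ]) else NULL
      for (j in seq_len(nrow(acc))) {
        axyz <- atom_coords(system, acc$atom_index[j])
        ok <- rowSums((dxyz - axyz)^2) <= geometry$hbond_dist_nm^2
        if (!is.null(hxyz) && length(hxyz) > 0L) {
          ang_ok <- rep(FALSE, nf)
          for (h in hxyz) {
            v1 <- dxyz - h; v2 <- axyz - h
            cosang <- rowSums(v1 * v2) /
              (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
            ang_ok <- ang_ok |
              (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >=
                 geometry$hbond_angle_deg)
          }
          ok <- ok & ang_ok
        }
        freq <- sum(ok) / nf
        ea <- list(chain = don$chain[i], resid = don$resid[i],
                   resname = don$resname[i], atoms = trimws(don$elety[i]))
        eb <- list(chain = acc$chain[j], resid = acc$resid[j],
                   resname = acc$resname[j], atoms = trimws(acc$elety[j]))
        if (swap) add("hydrogen_bond", eb, ea, freq) else add("hydrogen_bond", ea, eb, freq)
      }
    }
  }
  hb_pair_freq(group_a, group_b, swap = FALSE)
  hb_pair_freq(group_b, group_a, swap = TRUE)

  # --- hydrophobic: apolar carbon pairs ---------------------------------
  apa <- pick_atoms(group_a, NULL, "apolar")
  apb <- pick_atoms(group_b, NULL, "apolar")
  if (nrow(apa) > 0L && nrow(apb) > 0L) {
    for (i in seq_len(nrow(apa))) {
      xi <- atom_coords(system, apa$atom_index[i])
      for (j in seq_len(nrow(apb))) {
        xj <- atom_coords(system, apb$atom_index[j])
        freq <- sum(rowSums((xi - xj)^2) <=
                      geometry$hydrophobic_dist_nm^2) / nf
        add("hydrophobic",
            list(chain = apa$chain[i], resid = apa$resid[i],
                 resname = apa$resname[i], atoms = trimws(apa$elety[i])),
            list(chain = apb$chain[j], resid = apb$resid[j],
                 resname = apb$resname[j], atoms = trimws(apb$elety[j])),
            freq)
      }
    }
  }

  out <- if (length(records) > 0L) do.call(rbind, records) else
    data.frame(type = character(), chain_i = character(),
               resid_i = integer(), resname_i = character(),
               atom_i = character(), chain_j = character(),
               resid_j = integer(), resname_j = character(),
               atom_j = character(), frequency = numeric(),
               interface = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "hydrogens_used") <- has_h
  out
}

# hydrogens covalently bound to a donor: same residue, within 0.125 nm
donor_hydrogens <- function(system, donor_row) {
  a <- system$atoms
  idx <- which(a$chain == donor_row$chain & a$resid == donor_row$resid &
                 toupper(trimws(a$element)) == "H")
  if (length(idx) == 0L) return(list())
  dxyz <- atom_coords(system, donor_row$atom_index)
  out <- list()
  for (ai in idx) {
    hxyz <- atom_coords(system, ai)
    if (mean(sqrt(rowSums((hxyz - dxyz)^2))) <= 0.125) {
      out[[length(out) + 1L]] <- hxyz
    }
  }
  out
}

#' Filter interactions stable across systems
#'
#' Keeps interactions whose mean frequency across the supplied systems is
#' strictly greater than the threshold (default 0.75). An interaction
#' missing from a system counts as frequency 0 there.
#'
#' @param records_per_system list of interaction tables from
#'   [classify_interactions()], one per system.
#' @param threshold strict lower bound on the mean frequency.
#' @return data.frame of stable interactions with per-system frequencies
#'   (`freq_1`, `freq_2`, ...) and `mean_frequency`.
#' @export
stable_interactions <- function(records_per_system, threshold = 0.75) {
  ns <- length(records_per_system)
  if (ns == 0L) stop("no systems supplied")
  keys <- lapply(records_per_system, function(r) {
    record_key(r$type, r$chain_i, r$resid_i, r$chain_j, r$resid_j)
  })
  all_keys <- unique(unlist(keys))
  if (length(all_keys) == 0L) {
    return(data.frame(type = character(), mean_frequency = numeric()))
  }
  freq <- matrix(0, length(all_keys), ns,
                 dimnames = list(all_keys, paste0("freq_", seq_len(ns))))
  meta <- NULL
  for (s in seq_len(ns)) {
    r <- records_per_system[[s]]
    if (nrow(r) == 0L) next
    freq[match(keys[[s]], all_keys), s] <- r$frequency
    m <- r[, c("type", "chain_i", "resid_i", "resname_i", "atom_i",
               "chain_j", "resid_j", "resname_j", "atom_j")]
    rownames(m) <- keys[[s]]
    meta <- if (is.null(meta)) m else rbind(meta, m[setdiff(keys[[s]], rownames(meta)), , drop = FALSE])
  }
  mean_f <- rowMeans(freq)
  keep <- mean_f > threshold
  out <- cbind(meta[all_keys[keep], , drop = FALSE],
               as.data.frame(freq[keep, , drop = FALSE]),
               mean_frequency = mean_f[keep])
  rownames(out) <- NULL
  out
}
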