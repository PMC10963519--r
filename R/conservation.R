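# Stereochemical classes used by the conservation score: substitutions
# within a class are considered conservative, so a column mixing L and V is
# as conserved as an invariant one.
.stereo_classes <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y", "H"),
  polar     = c("S", "T", "N", "Q"),
  basic     = c("K", "R"),
  acidic    = c("D", "E"),
  special   = c("G", "P")
)

#' Read a multiple sequence alignment from FASTA
#'
#' Enforces equal sequence lengths, normalizes to upper case, and builds
#' the column -> residue-position map of a chosen reference sequence
#' (skipping its gap columns).
#'
#' @param path FASTA alignment file.
#' @param reference index or name of the reference sequence (default 1).
#' @return an `MSA` object: list with `ali` (character matrix, sequences x
#'   columns), `ids`, `reference`, and `ref_map` (for each reference
#'   residue position, its alignment column).
#' @export
read_msa <- function(path, reference = 1L) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  # reject ragged alignments up front (the reader would silently pad them)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no sequences in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lens <- vapply(seq_along(starts), function(i) {
    if (starts[i] + 1L > ends[i]) return(0L)
    sum(nchar(gsub("\\s", "", lines[(starts[i] + 1L):ends[i]])))
  }, integer(1L))
  if (any(lens == 0L)) stop("empty sequence in ", path)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(lens), collapse = ", "))
  }
  fa <- bio3d::read.fasta(path)
  ali <- toupper(fa$ali)
  if (nrow(ali) == 0L || ncol(ali) == 0L) stop("empty alignment")
  msa_object(ali, rownames(ali), reference)
}

msa_object <- function(ali, ids, reference = 1L) {
  if (is.character(reference)) reference <- match(reference, ids)
  ref_row <- ali[reference, ]
  ref_map <- which(!(ref_row %in% c("-", ".")))
  structure(list(ali = ali, ids = ids, reference = reference,
                 ref_map = ref_map),
            class = "MSA")
}

#' @export
print.MSA <- function(x, ...) {
  cat("MSA:", nrow(x$ali), "sequences x", ncol(x$ali), "columns;",
      "reference", x$ids[x$reference], "with", length(x$ref_map),
      "residues\n")
  invisible(x)
}

#' Normalized stereochemically sensitive Shannon entropy per column
#'
#' Maps residues to six stereochemical classes (aliphatic AVLIMC, aromatic
#' FWYH, polar STNQ, basic KR, acidic DE, special GP), computes the Shannon
#' entropy `H = -sum p_c ln p_c` of the class composition of each column
#' (gaps excluded from the counts), and normalizes by `ln 6` so NE lies in
#' \[0, 1\]: 0 = fully conserved class, 1 = uniform over all six classes.
#' Ambiguity codes (B, Z, X) are excluded with a warning. Columns with a
#' gap fraction above `max_gap` (or entirely gapped) are flagged
#' unreliable.
#'
#' @param msa an `MSA` from [read_msa()].
#' @param max_gap gap-fraction threshold above which a column is flagged
#'   (default 0.5).
#' @return a `ConservationProfile` data.frame: `column`,
#'   `reference_position` (NA where the reference has a gap), `ne`,
#'   `gap_fraction`, `flagged`; attribute `class_counts` (6 x columns).
#' @export
stereochemical_entropy_profile <- function(msa, max_gap = 0.5) {
  ali <- msa$ali
  ncol_ali <- ncol(ali)
  class_of <- character(0)
  for (cl in names(.stereo_classes)) {
    class_of[.stereo_classes[[cl]]] <- cl
  }
  cls_names <- names(.stereo_classes)
  counts <- matrix(0L, length(cls_names), ncol_ali,
                   dimnames = list(cls_names, NULL))
  ne <- numeric(ncol_ali)
  gap_frac <- numeric(ncol_ali)
  ambiguous_seen <- FALSE
  for (j in seq_len(ncol_ali)) {
    col <- ali[, j]
    gaps <- col %in% c("-", ".")
    gap_frac[j] <- mean(gaps)
    col <- col[!gaps]
    amb <- col %in% c("B", "Z", "X")
    if (any(amb)) ambiguous_seen <- TRUE
    col <- col[!amb]
    cls <- class_of[col]
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0L) {
      ne[j] <- NA_real_
      next
    }
    tab <- table(factor(cls, levels = cls_names))
    counts[, j] <- as.integer(tab)
    p <- tab[tab > 0] / sum(tab)
    ne[j] <- -sum(p * log(p)) / log(6)
  }
  if (ambiguous_seen) {
    warning("ambiguity codes (B/Z/X) excluded from class counts")
  }
  ref_pos <- rep(NA_integer_, ncol_ali)
  ref_pos[msa$ref_map] <- seq_along(msa$ref_map)
  out <- data.frame(column = seq_len(ncol_ali),
                    reference_position = ref_pos,
                    ne = ne, gap_fraction = gap_frac,
                    flagged = is.na(ne) | gap_frac > max_gap)
  attr(out, "class_counts") <- counts
  attr(out, "reference_letters") <- unname(ali[msa$reference, msa$ref_map])
  class(out) <- c("ConservationProfile", "data.frame")
  out
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat("ConservationProfile:", nrow(x), "columns; median NE",
      round(stats::median(x$ne, na.rm = TRUE), 3), ";",
      sum(x$flagged), "flagged\n")
  invisible(x)
}

# three-letter -> one-letter residue codes via bio3d
aa_one <- function(resname) {
  suppressWarnings(bio3d::aa321(resname))
}

#' Map conservation onto structure residues
#'
#' Walks each mapped chain in residue order, pairs its residues with the
#' reference-sequence positions of the profile, verifies the amino-acid
#' identity, and returns per-residue NE. Mismatching or unmapped residues
#' get the sentinel value and are counted.
#'
#' @param profile a `ConservationProfile`.
#' @param system a `MolecularSystem`.
#' @param chains chains whose sequence follows the profile's reference
#'   sequence (each chain is aligned from its first residue).
#' @param sentinel value for unmapped/mismatched residues (default -1).
#' @return data.frame `chain`, `resid`, `resname`, `ne`, `matched`;
#'   attribute `n_mismatch`.
#' @export
map_conservation <- function(profile, system, chains, sentinel = -1) {
  ref_cols <- profile$column[!is.na(profile$reference_position)]
  ref_ne <- profile$ne[ref_cols]
  # reference letters from the class-count provenance are not stored;
  # identity check uses the alignment letters kept on the profile if any
  ref_letters <- attr(profile, "reference_letters")
  rows <- list()
  n_mismatch <- 0L
  for (ch in chains) {
    res <- unique(system$atoms[system$atoms$chain == ch,
                               c("chain", "resid", "resname")])
    res <- res[order(res$resid), , drop = FALSE]
    for (i in seq_len(nrow(res))) {
      if (i <= length(ref_ne)) {
        ok <- TRUE
        if (!is.null(ref_letters)) {
          ok <- identical(aa_one(res$resname[i]), ref_letters[i])
        }
        val <- if (ok) ref_ne[i] else sentinel
        if (!ok) n_mismatch <- n_mismatch + 1L
      } else {
        val <- sentinel
        n_mismatch <- n_mismatch + 1L
        ok <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resid = res$resid[i], resname = res$resname[i],
        ne = val, matched = ok, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_mismatch") <- n_mismatch
  out
}

#' Write a PDB coloured by conservation
#'
#' Per-residue B-factor set to `NE * 100` (PDB B-factor precision is two
#' decimals, so NE round-trips to 0.01 resolution when divided back by
#' 100). Unmapped residues carry the sentinel.
#'
#' @param profile a `ConservationProfile`.
#' @param system a `MolecularSystem`.
#' @param chains chains mapped to the profile's reference sequence.
#' @param file output PDB path.
#' @param sentinel B-factor for unmapped residues (default -1).
#' @return invisibly, the per-residue mapping used (see
#'   [map_conservation()]).
#' @export
annotate_structure <- function(profile, system, chains, file,
                               sentinel = -1) {
  mapping <- map_conservation(profile, system, chains, sentinel = sentinel)
  key <- res_key(mapping$chain, mapping$resid)
  b <- mapping$ne[match(res_key(system$atoms$chain, system$atoms$resid), key)]
  b <- ifelse(is.na(b) | b == sentinel, sentinel, b * 100)
  a <- system$atoms
  bio3d::write.pdb(file = file, xyz = system$xyz[1L, ] * 10,
                   type = rep("ATOM", nrow(a)), eleno = a$eleno,
                   elety = a$elety, resid = a$resname, chain = a$chain,
                   resno = a$resid, elesy = a$element,
                   o = rep(1, nrow(a)), b = b)
  invisible(mapping)
}
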