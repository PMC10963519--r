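#' Write a system to PDB (+ optional DCD trajectory)
#'
#' The PDB holds the topology and the first frame as reference coordinates;
#' the DCD holds every frame. Internal coordinates are nm; both files are
#' written in Angstrom, the convention of the formats.
#'
#' @param system a `MolecularSystem`.
#' @param pdb_file output PDB path.
#' @param dcd_file optional output DCD path (CHARMM-format, 32-bit).
#' @return invisibly, the paths written.
#' @export
write_system <- function(system, pdb_file, dcd_file = NULL) {
  a <- system$atoms
  bio3d::write.pdb(
    file = pdb_file,
    xyz = system$xyz[1L, ] * 10,
    type = rep("ATOM", nrow(a)),
    eleno = a$eleno,
    elety = a$elety,
    resid = a$resname,
    chain = a$chain,
    resno = a$resid,
    elesy = a$element,
    o = rep(1, nrow(a)),
    b = rep(0, nrow(a))
  )
  if (!is.null(dcd_file)) write_dcd(system$xyz * 10, dcd_file)
  invisible(c(pdb = pdb_file, dcd = dcd_file))
}

#' Write a coordinate matrix as a CHARMM-format DCD trajectory
#'
#' Minimal single-precision CHARMM DCD writer (no unit cell). Coordinates
#' are taken as given (callers pass Angstrom, the format convention).
#'
#' @param xyz numeric matrix, frames x (3 * n_atoms).
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_dcd <- function(xyz, file) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  natom <- ncol(xyz) / 3L
  if (natom != floor(natom)) stop("xyz width is not a multiple of 3")
  nframes <- nrow(xyz)
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  # header record: 'CORD' + 20 control integers (CHARMM version flag = 24)
  wi(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wi(nframes); wi(1L); wi(1L); wi(nframes)
  wi(rep(0L, 5L))
  wf(1.0)                       # DELTA as float32 in the CHARMM convention
  wi(rep(0L, 9L))               # crystal flag 0, unused fields
  wi(24L)                       # version
  wi(84L)
  # title record
  title <- sprintf("%-80s", "synthetic trajectory written by dynacomm")
  wi(4L + 80L)
  wi(1L)
  writeChar(substr(title, 1L, 80L), con, nchars = 80L, eos = NULL)
  wi(4L + 80L)
  # atom-count record
  wi(4L); wi(natom); wi(4L)
  # frames: one record per axis
  ix <- seq(1L, 3L * natom, by = 3L)
  reclen <- 4L * natom
  for (f in seq_len(nframes)) {
    row <- xyz[f, ]
    wi(reclen); wf(row[ix]); wi(reclen)
    wi(reclen); wf(row[ix + 1L]); wi(reclen)
    wi(reclen); wf(row[ix + 2L]); wi(reclen)
  }
  invisible(file)
}

#' Load a topology plus one or more trajectory replicas
#'
#' Reads a PDB topology and DCD trajectory replicas, records replica
#' boundaries, and returns coordinates in nm. All replicas must match the
#' topology atom count.
#'
#' @param topology PDB file path.
#' @param trajectories character vector of DCD paths, one per replica; if
#'   empty, the PDB coordinates become a single one-frame trajectory.
#' @return a `MolecularSystem`.
#' @export
load_system <- function(topology, trajectories = character()) {
  if (!file.exists(topology)) stop("topology not found: ", topology)
  pdb <- bio3d::read.pdb(topology)
  a <- pdb$atom
  atoms <- data.frame(
    eleno = a$eleno, elety = a$elety, resid = a$resno,
    resname = a$resid, chain = a$chain, element = a$elesy,
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$element) | atoms$element == "")) {
    atoms$element <- substr(trimws(atoms$elety), 1L, 1L)
  }
  natom <- nrow(atoms)
  if (length(trajectories) == 0L) {
    return(molecular_system(atoms, matrix(pdb$xyz / 10, nrow = 1L)))
  }
  frames <- list()
  replicas <- list()
  at <- 0L
  for (tr in trajectories) {
    if (!file.exists(tr)) stop("trajectory not found: ", tr)
    ext <- tolower(tools::file_ext(tr))
    if (ext != "dcd") stop("unsupported trajectory format: .", ext,
                           " (only DCD is supported)")
    x <- bio3d::read.dcd(tr, verbose = FALSE)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != 3L * natom) {
      stop("atom-count mismatch: topology has ", natom, " atoms but ", tr,
           " has ", ncol(x) / 3, " atoms per frame")
    }
    if (nrow(x) == 0L) stop("trajectory has zero frames: ", tr)
    frames[[length(frames) + 1L]] <- x / 10
    replicas[[length(replicas) + 1L]] <- c(at + 1L, at + nrow(x))
    at <- at + nrow(x)
  }
  molecular_system(atoms, do.call(rbind, frames), replicas = replicas)
}
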