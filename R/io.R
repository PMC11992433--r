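# Structure/trajectory readers and writers. PDB files carry Angstrom
# coordinates; everything in memory is nm. XYZ trajectory files carry
# Angstrom with atom labels "chain:resno:resid:elety" so chain information
# round-trips.

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `helix_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "helix_trajectory"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("REMARK   6 DT %g PS", traj$dt), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %d", f), con)
    writeLines(pdb_atom_lines(traj$atoms, frame_coords(traj, f) * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' @param traj A `helix_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "helix_trajectory"))
  a <- traj$atoms
  labels <- paste(a$chain, a$resno, a$resid, a$elety, sep = ":")
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f) * 10
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("frame %d dt %g ps", f, traj$dt), con)
    writeLines(sprintf("%s %12.6f %12.6f %12.6f", labels,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
  invisible(path)
}

# validate ATOM/HETATM records so format errors name the offending line
check_pdb_atom_lines <- function(lines) {
  at <- grep("^(ATOM  |HETATM)", lines)
  for (i in at) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("format error at line ", i, ": ATOM record too short",
           call. = FALSE)
    coords <- suppressWarnings(as.numeric(
      c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("format error at line ", i, ": unparseable coordinates",
           call. = FALSE)
  }
  invisible(length(at))
}

#' Read a structure or trajectory file
#'
#' Accepts single- or multi-model PDB and XYZ files (as written by
#' [write_trajectory_pdb()] / [write_trajectory_xyz()] / [write_model()]).
#' Coordinates are converted from Angstrom to nm. A single-model PDB still
#' returns a one-frame `helix_trajectory`.
#'
#' @param path Input file.
#' @param dt Frame spacing in ps; for PDB/XYZ files written by this package
#'   the value recorded in the file takes precedence.
#' @param chains Optional chain subset to keep.
#' @return A `helix_trajectory`.
#' @export
read_structure <- function(path, dt = 100, chains = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^[0-9]+\\s*$", first)) {
    traj <- read_structure_xyz(path, dt = dt)
  } else {
    lines <- readLines(path)
    check_pdb_atom_lines(lines)
    rem <- grep("^REMARK   6 DT ", lines, value = TRUE)
    if (length(rem))
      dt <- as.numeric(sub("^REMARK   6 DT ([0-9.eE+-]+) PS.*$", "\\1",
                           rem[1L]))
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    atoms <- data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                        resid = pdb$atom$resid, elety = pdb$atom$elety,
                        stringsAsFactors = FALSE)
    xyz <- matrix(as.numeric(pdb$xyz), nrow = nrow(pdb$xyz)) / 10
    traj <- helix_trajectory(xyz, atoms, dt = dt)
  }
  if (!is.null(chains)) {
    keep <- select_atoms(traj, chain = chains)
    if (!length(keep))
      stop("selection error: no atoms in chain(s) ",
           paste(chains, collapse = ","), call. = FALSE)
    traj <- helix_trajectory(traj$xyz[, xyz_cols(keep), drop = FALSE],
                             traj$atoms[keep, ], dt = traj$dt,
                             metadata = traj$metadata)
  }
  traj
}

read_structure_xyz <- function(path, dt = 100) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); atoms <- NULL
  while (i <= length(lines)) {
    if (!grepl("^[0-9]+\\s*$", lines[i]))
      stop("format error at line ", i, ": expected atom count", call. = FALSE)
    n <- as.integer(lines[i])
    comment <- lines[i + 1L]
    m <- regmatches(comment, regexec("dt ([0-9.eE+-]+) ps", comment))[[1L]]
    if (length(m) == 2L) dt <- as.numeric(m[2L])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) != 4L)
    if (length(bad))
      stop("format error at line ", i + 1L + bad[1L],
           ": expected 'label x y z'", call. = FALSE)
    tab <- do.call(rbind, parts)
    co <- suppressWarnings(apply(tab[, 2:4, drop = FALSE], 2L, as.numeric))
    if (anyNA(co)) {
      bad_row <- which(apply(is.na(co), 1L, any))[1L]
      stop("format error at line ", i + 1L + bad_row,
           ": unparseable coordinates", call. = FALSE)
    }
    if (is.null(atoms)) {
      lab <- strsplit(tab[, 1L], ":")
      full <- all(lengths(lab) == 4L)
      atoms <- data.frame(
        chain = if (full) vapply(lab, `[[`, "", 1L) else "A",
        resno = if (full) as.integer(vapply(lab, `[[`, "", 2L))
        else seq_len(n),
        resid = if (full) vapply(lab, `[[`, "", 3L) else "UNK",
        elety = if (full) vapply(lab, `[[`, "", 4L) else tab[, 1L],
        stringsAsFactors = FALSE)
    }
    frames[[length(frames) + 1L]] <- as.vector(t(co)) / 10
    i <- i + 2L + n
  }
  helix_trajectory(do.call(rbind, frames), atoms, dt = dt)
}
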