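# Idealized collagen triple-helix model building: 39-residue chain windows,
# analytic superhelix coordinates, and the 2^3 wild-type/mutant trimer
# register combinations. Internal length unit is nm; PDB files are Angstrom.

#' Default geometric parameters of the idealized collagen superhelix
#'
#' An analytic stand-in for a crystallographic collagen peptide template:
#' a right-handed superhelix of three chains related by a 120 degree phase
#' and a one-residue axial stagger.
#'
#' @param rise Axial rise per residue along the superhelix axis (nm).
#'   0.286 nm is the canonical collagen value.
#' @param radius Radial offset of each chain's C-alpha trace from the common
#'   axis (nm).
#' @param supertwist Superhelical rotation per residue (radians); positive is
#'   right-handed. The default corresponds to roughly one supercoil turn per
#'   30 residues (10 triplets).
#' @param stagger Inter-chain stagger in residues (chain B trails A by this
#'   amount, C trails B).
#' @param bulge Radial out-bulge amplitude (nm) applied to inserted residues
#'   of an untrimmed mutant chain.
#' @return A list of class `helix_params`.
#' @export
helix_params <- function(rise = 0.286, radius = 0.28,
                         supertwist = 2 * pi / 30, stagger = 1,
                         bulge = 0.15) {
  if (rise <= 0 || radius <= 0)
    stop("parameter error: rise and radius must be positive", call. = FALSE)
  structure(list(rise = rise, radius = radius, supertwist = supertwist,
                 stagger = stagger, bulge = bulge), class = "helix_params")
}

#' Construct a chain specification for one trimer strand
#'
#' Validates the Gly-Xaa-Yaa registry of a window that starts on a Gly
#' position and applies the standard collagen hydroxylation rule: every Pro
#' at a Yaa position is marked hydroxyproline (one-letter `"O"`), Pro at Xaa
#' stays Pro.
#'
#' @param sequence Window sequence (character scalar or residue vector);
#'   length must be a multiple of 3 and position 1 must be Gly-frame.
#' @param label One of `"A"`, `"B"`, `"C"` (leading/middle/trailing).
#' @param is_mutant Logical flag.
#' @param insert_range Optional integer length-2 vector: window positions of
#'   an untrimmed inserted run (used for bulge placement).
#' @param hydroxylate Apply the Yaa-proline hydroxylation rule (default TRUE).
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(sequence, label = "A", is_mutant = FALSE,
                       insert_range = NULL, hydroxylate = TRUE) {
  res <- as_residue_vector(sequence)
  n <- length(res)
  if (n %% 3L != 0L)
    stop("phase error: window length ", n, " is not a multiple of 3",
         call. = FALSE)
  gly_idx <- seq.int(1L, n, by = 3L)
  if (!all(res[gly_idx] == "G"))
    stop("phase error: window does not have Gly at every registry position",
         call. = FALSE)
  if (hydroxylate) {
    yaa_idx <- seq.int(3L, n, by = 3L)
    res[yaa_idx][res[yaa_idx] == "P"] <- "O"
  }
  structure(list(sequence = paste(res, collapse = ""), label = label,
                 is_mutant = is_mutant, n_residues = n,
                 n_triplets = n %/% 3L,
                 hyp_positions = which(res == "O"),
                 insert_range = insert_range),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec %s%s> %s (%d triplets, %d Hyp)\n", x$label,
              if (x$is_mutant) " mutant" else "", x$sequence, x$n_triplets,
              length(x$hyp_positions)))
  invisible(x)
}

#' Extract an in-frame chain window centered on a duplication locus
#'
#' Selects a `window_len`-residue slice of the chain whose first residue is
#' a Gly of the registry frame and whose center is as close as possible to
#' the duplication locus (the midpoint of the duplicated run for the
#' wild-type window; the midpoint of the tandem repeat for the mutant
#' window). With `mode = "trimmed"` (default) the mutant window keeps the
#' same length as the wild-type one, flanks trimmed symmetrically; with
#' `mode = "extended"` the mutant window keeps its full flanks and is
#' `window_len + length_aa` residues long, the inserted copy tracked in
#' `insert_range`.
#'
#' @param protein_seq Reference protein sequence (scalar or residue vector).
#' @param dup A `protein_dup`, or `NULL` for an unmodified reference slice
#'   centered mid-sequence.
#' @param window_len Window length in residues (multiple of 3; default 39,
#'   i.e. 13 triplets).
#' @param registry Optional `helix_registry`; defaults to a frame starting
#'   at position 1.
#' @param mutant Return the mutant window (requires `dup`)?
#' @param mode `"trimmed"` or `"extended"` mutant window semantics.
#' @param label,hydroxylate Passed to [chain_spec()].
#' @return A `chain_spec`. The window start (reference or mutant coordinate)
#'   is available as attribute `"window_start"`.
#' @export
extract_window <- function(protein_seq, dup = NULL, window_len = 39L,
                           registry = NULL, mutant = FALSE,
                           mode = c("trimmed", "extended"),
                           label = "A", hydroxylate = TRUE) {
  mode <- match.arg(mode)
  res <- as_residue_vector(protein_seq)
  window_len <- as.integer(window_len)
  if (window_len %% 3L != 0L)
    stop("phase error: window_len must be a multiple of 3", call. = FALSE)
  if (is.null(registry))
    registry <- triple_helix_registry(1L, length(res) %/% 3L)
  if (mutant && is.null(dup))
    stop("mutant window requested without a duplication", call. = FALSE)

  if (is.null(dup)) {
    center <- (length(res) + 1) / 2
  } else {
    if (dup$ins_after < registry$domain_start ||
        dup$ins_after > registry$domain_end)
      stop("duplication outside the registry span", call. = FALSE)
    center <- if (dup$is_tandem) (dup$aa_start + dup$aa_end) / 2
    else dup$ins_after + 0.5
  }
  len <- window_len
  seq_use <- res
  is_mut <- FALSE
  insert_range <- NULL
  if (mutant) {
    if (dup$length_aa %% 3L != 0L)
      stop("phase error: duplication length breaks the triplet frame",
           call. = FALSE)
    run <- strsplit(dup$aa_seq, "")[[1L]]
    seq_use <- append(res, run, after = dup$ins_after)
    # the repeat region spans run + inserted copy in mutant coordinates
    center <- dup$ins_after + (1 - dup$length_aa) / 2 + dup$length_aa
    if (dup$is_tandem)
      center <- (dup$aa_start + dup$aa_end + dup$length_aa) / 2
    if (mode == "extended") len <- window_len + dup$length_aa
    is_mut <- TRUE
  }
  # candidate in-frame starts (Gly positions of the registry frame)
  starts <- seq.int(registry$domain_start, length(seq_use) - len + 1L, by = 3L)
  starts <- starts[starts >= 1L]
  if (!length(starts))
    stop("sequence too short for a ", len, "-residue in-frame window",
         call. = FALSE)
  s <- starts[which.min(abs(starts + (len - 1) / 2 - center))]
  if (mutant && (s > dup$ins_after + 1L - dup$length_aa ||
                 s + len - 1L < dup$ins_after + dup$length_aa))
    stop("duplication does not fit inside the window", call. = FALSE)
  if (mutant)
    insert_range <- c(dup$ins_after + 1L - s + 1L,
                      dup$ins_after + dup$length_aa - s + 1L)
  out <- chain_spec(seq_use[s:(s + len - 1L)], label = label,
                    is_mutant = is_mut,
                    insert_range = if (mutant && mode == "extended")
                      insert_range,
                    hydroxylate = hydroxylate)
  attr(out, "window_start") <- s
  out
}

# three-letter residue names for the PDB writer
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL", O = "HYP")

#' Idealized superhelix coordinates for one chain
#'
#' Places a minimal backbone + C-beta representation (N, CA, C, O, CB, and a
#' schematic hydroxyl OD1 for hydroxyproline) of the chain on a right-handed
#' superhelix: residue axial index `u = i - 1 - register_index * stagger`,
#' axial position `rise * u`, azimuth `supertwist * u + 2*pi/3 *
#' register_index`. Successive register indices therefore trail by one
#' residue and wind 120 degrees apart, C-termini falling within the
#' template's stagger envelope. Deterministic for fixed parameters.
#'
#' For a chain with an `insert_range` (untrimmed mutant), the inserted
#' residues are interpolated along the axial gap left by the wild-type frame
#' and pushed radially outward by the `bulge` amplitude, a simple stand-in
#' geometry handed to downstream refinement.
#'
#' @param chain A `chain_spec`.
#' @param register_index 0 (leading, A), 1 (middle, B) or 2 (trailing, C).
#' @param params A [helix_params()] list.
#' @return A list with `atoms` (data.frame: `chain`, `resno`, `resid`,
#'   `elety`) and `coords` (matrix, nm).
#' @export
ideal_helix_coordinates <- function(chain, register_index = 0L,
                                    params = helix_params()) {
  stopifnot(inherits(chain, "chain_spec"), register_index %in% 0:2)
  res <- strsplit(chain$sequence, "")[[1L]]
  n <- length(res)
  k <- as.integer(register_index)
  u <- seq_len(n) - 1 - k * params$stagger
  r_off <- rep(params$radius, n)
  if (!is.null(chain$insert_range)) {
    ir <- chain$insert_range
    m <- ir[2L] - ir[1L] + 1L
    # residues after the insertion recover the wild-type axial frame
    u[seq_len(n) > ir[2L]] <- u[seq_len(n) > ir[2L]] - m
    j <- seq_len(m)
    u[ir[1L]:ir[2L]] <- (ir[1L] - 2 - k * params$stagger) + j / (m + 1)
    r_off[ir[1L]:ir[2L]] <- params$radius +
      params$bulge * sin(pi * j / (m + 1))
  }
  theta <- params$supertwist * u + 2 * pi * k / 3
  z <- params$rise * u
  rad <- cbind(cos(theta), sin(theta), 0)       # outward unit vector
  tang <- cbind(-sin(theta), cos(theta), 0)
  axis <- matrix(c(0, 0, 1), n, 3L, byrow = TRUE)
  ca <- r_off * rad + z * axis

  atoms <- list(); coords <- list()
  add <- function(i, elety, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = chain$label, resno = i, resid = unname(AA3[res[i]]),
      elety = elety, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  for (i in seq_len(n)) {
    add(i, "N",  ca[i, ] - 0.123 * axis[i, ] - 0.05 * rad[i, ])
    add(i, "CA", ca[i, ])
    add(i, "C",  ca[i, ] + 0.123 * axis[i, ] - 0.05 * rad[i, ])
    add(i, "O",  ca[i, ] + 0.123 * axis[i, ] - 0.17 * rad[i, ] +
          0.05 * tang[i, ])
    if (res[i] != "G")
      add(i, "CB", ca[i, ] + 0.153 * rad[i, ])
    if (res[i] == "O")
      add(i, "OD1", ca[i, ] + 0.25 * rad[i, ] + 0.08 * tang[i, ])
  }
  list(atoms = do.call(rbind, atoms), coords = do.call(rbind, coords))
}

#' Assemble a trimer model from three chain specifications
#'
#' @param chains List of three `chain_spec` objects in register order
#'   (leading A, middle B, trailing C); labels are overwritten to A/B/C.
#' @param params A [helix_params()] list.
#' @param id Model identifier; default encodes the wt/mut composition as a
#'   three-letter code such as `"WMW"`.
#' @return An object of class `trimer_model` with `atoms`, `coords` (nm),
#'   `chains`, `id`.
#' @export
build_trimer <- function(chains, params = helix_params(), id = NULL) {
  stopifnot(length(chains) == 3L,
            all(vapply(chains, inherits, logical(1L), "chain_spec")))
  labs <- c("A", "B", "C")
  parts <- lapply(1:3, function(k) {
    ch <- chains[[k]]; ch$label <- labs[k]
    ideal_helix_coordinates(ch, register_index = k - 1L, params = params)
  })
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  coords <- do.call(rbind, lapply(parts, `[[`, "coords"))
  if (is.null(id))
    id <- paste(vapply(chains, function(ch)
      if (isTRUE(ch$is_mutant)) "M" else "W", character(1L)), collapse = "")
  for (k in 1:3) chains[[k]]$label <- labs[k]
  structure(list(atoms = atoms, coords = coords, chains = chains,
                 id = id, params = params), class = "trimer_model")
}

#' @export
print.trimer_model <- function(x, ...) {
  cat(sprintf("<trimer_model %s> chains %s, %d atoms\n", x$id,
              paste(vapply(x$chains, function(ch)
                sprintf("%s(%d)", ch$label, ch$n_residues), character(1L)),
                collapse = "/"),
              nrow(x$atoms)))
  invisible(x)
}

#' Enumerate all wild-type/mutant trimer register combinations
#'
#' Assigns each of the three register positions (A leading, B middle, C
#' trailing) either the wild-type or the mutant chain, giving the
#' 2^3 = 8 models: one all-wild-type, three single-mutant, three
#' double-mutant, one all-mutant. All chains are C-terminally aligned by
#' construction of the register stagger.
#'
#' @param wt,mut `chain_spec` objects for the wild-type and mutant windows.
#' @param params A [helix_params()] list.
#' @return A named list of 8 `trimer_model` objects; names are the
#'   three-letter W/M composition codes ordered as binary codes
#'   `WWW, WWM, WMW, ..., MMM`.
#' @export
enumerate_trimers <- function(wt, mut, params = helix_params()) {
  stopifnot(inherits(wt, "chain_spec"), inherits(mut, "chain_spec"))
  codes <- 0:7
  models <- lapply(codes, function(code) {
    pick <- function(bit) if (bitwAnd(code, bit) > 0L) mut else wt
    build_trimer(list(pick(4L), pick(2L), pick(1L)), params = params)
  })
  names(models) <- vapply(models, `[[`, character(1L), "id")
  models
}

#' Write a trimer model as a PDB file
#'
#' Chains A/B/C get separate chain identifiers, residues are 1-based and
#' coordinates are converted from nm to Angstrom. A REMARK line records the
#' wild-type/mutant chain composition so that model files are
#' self-describing.
#'
#' @param model A `trimer_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trimer_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("REMARK   6 COMPOSITION %s", model$id), con)
  writeLines(pdb_atom_lines(model$atoms, model$coords * 10), con)
  writeLines("END", con)
  invisible(path)
}

# format ATOM records (coordinates already in Angstrom)
pdb_atom_lines <- function(atoms, xyz_ang) {
  elety <- ifelse(nchar(atoms$elety) < 4L,
                  sprintf(" %-3s", atoms$elety), atoms$elety)
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          seq_len(nrow(atoms)), elety, atoms$resid, atoms$chain,
          atoms$resno, xyz_ang[, 1], xyz_ang[, 2], xyz_ang[, 3])
}

#' Read a trimer model written by [write_model()]
#'
#' @param path PDB file path.
#' @return A list with `atoms` (chain/resno/resid/elety), `coords` (nm) and
#'   `composition` (the REMARK code, or `NA`).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  comp <- NA_character_
  rem <- grep("^REMARK   6 COMPOSITION", readLines(path, n = 5L),
              value = TRUE)
  if (length(rem)) comp <- sub("^REMARK   6 COMPOSITION ", "", rem[1L])
  list(atoms = data.frame(chain = pdb$atom$chain, resno = pdb$atom$resno,
                          resid = pdb$atom$resid, elety = pdb$atom$elety,
                          stringsAsFactors = FALSE),
       coords = cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10,
       composition = comp)
}
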