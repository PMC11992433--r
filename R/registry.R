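# The Gly-Xaa-Yaa triplet frame over a collagen chain, position-class
# bookkeeping, collagenase cleavage-site scanning and distances.

# Imino residues: proline and hydroxyproline. Hydroxyproline is carried as
# the one-letter code "O" in sequences annotated with hydroxylation marks;
# plain "P" is accepted where hydroxylation is unknown.
IMINO <- c("P", "O")

#' Define a Gly-Xaa-Yaa triple-helix registry
#'
#' The registry fixes the triplet frame over a collagen chain: residue
#' `domain_start` is the Gly of the first triplet, and every residue at an
#' offset divisible by 3 from it is a Gly position.
#'
#' @param domain_start Protein coordinate (1-based) of the first Gly.
#' @param n_triplets Number of complete Gly-Xaa-Yaa triplets covered. The
#'   full-length collagen alpha-1(III) triple-helical domain has 343.
#' @return An object of class `helix_registry`.
#' @export
triple_helix_registry <- function(domain_start, n_triplets) {
  domain_start <- as.integer(domain_start); n_triplets <- as.integer(n_triplets)
  stopifnot(domain_start >= 1L, n_triplets >= 1L)
  structure(list(domain_start = domain_start, n_triplets = n_triplets,
                 domain_end = domain_start + 3L * n_triplets - 1L),
            class = "helix_registry")
}

#' @export
print.helix_registry <- function(x, ...) {
  cat(sprintf("<helix_registry> %d triplets, residues %d-%d\n",
              x$n_triplets, x$domain_start, x$domain_end))
  invisible(x)
}

#' Position class (Gly/Xaa/Yaa) of protein positions under a registry
#'
#' @param registry A `helix_registry`.
#' @param pos Integer vector of protein positions within the registry span.
#' @return Character vector in `c("Gly", "Xaa", "Yaa")`.
#' @export
position_class <- function(registry, pos) {
  stopifnot(inherits(registry, "helix_registry"))
  if (any(pos < registry$domain_start | pos > registry$domain_end))
    stop("position outside the registry span", call. = FALSE)
  c("Gly", "Xaa", "Yaa")[(pos - registry$domain_start) %% 3L + 1L]
}

#' Does an in-frame duplication preserve the Gly-every-third registry?
#'
#' The duplicated run is (by HGVS normalization) inserted immediately after
#' `dup$aa_end`. Registry is preserved iff the run length is a multiple of 3
#' and every run residue that lands on a Gly position of the frame is Gly;
#' residues downstream shift by a multiple of 3 and keep their class.
#'
#' @param registry A `helix_registry`.
#' @param dup A `protein_dup`.
#' @return `TRUE` or `FALSE`.
#' @export
registry_check <- function(registry, dup) {
  stopifnot(inherits(registry, "helix_registry"), inherits(dup, "protein_dup"))
  run_start <- if (dup$is_tandem) dup$aa_start else dup$ins_after
  if (run_start < registry$domain_start ||
      dup$ins_after > registry$domain_end)
    stop("range error: duplication outside the registry span", call. = FALSE)
  if (dup$length_aa %% 3L != 0L) return(FALSE)
  run <- strsplit(dup$aa_seq, "")[[1L]]
  ins_pos <- dup$ins_after + seq_len(dup$length_aa)  # inserted copy positions
  gly_slots <- (ins_pos - registry$domain_start) %% 3L == 0L
  all(run[gly_slots] == "G")
}

#' Per-class occurrence statistics of a residue type
#'
#' Counts occurrences of one residue type at Gly, Xaa and Yaa positions over
#' the registry span and reports the percentage of occurrences per class.
#' In the collagen alpha-1(III) chain most Ile and Leu sit at Xaa, where
#' they form the Gly-Ile/Leu-Yaa triplets recognized by collagenases.
#'
#' @param sequence Character scalar (one-letter residues) or character
#'   vector; position 1 of the sequence is protein position 1.
#' @param registry A `helix_registry` whose span the sequence must cover.
#' @param residue Single one-letter amino-acid code (e.g. `"L"`).
#' @return A data.frame with columns `class`, `count`, `percent` (percent of
#'   this residue's occurrences in each class; sums to 100 when the residue
#'   occurs at all).
#' @export
xaa_yaa_stats <- function(sequence, registry, residue) {
  stopifnot(inherits(registry, "helix_registry"))
  res <- as_residue_vector(sequence)
  if (length(residue) != 1L || !grepl("^[A-Z]$", residue <- toupper(residue)))
    stop("invalid residue code: must be a single letter", call. = FALSE)
  if (length(res) < registry$domain_end)
    stop("sequence does not cover the registry span", call. = FALSE)
  span <- registry$domain_start:registry$domain_end
  cls <- position_class(registry, span)
  hit <- res[span] == residue
  count <- vapply(c("Gly", "Xaa", "Yaa"),
                  function(k) sum(hit & cls == k), integer(1L))
  total <- sum(count)
  data.frame(class = c("Gly", "Xaa", "Yaa"), count = as.integer(count),
             percent = if (total > 0) 100 * count / total else rep(NA_real_, 3L),
             row.names = NULL)
}

#' Scan for candidate collagenase cleavage sites
#'
#' A candidate is any registry triplet starting Gly-Ile or Gly-Leu (the
#' scissile bond lies between the Gly and the Ile/Leu). The canonical MMP-1
#' site of the alpha-1(III) chain is distinguished by its context: the two
#' triplets upstream each contain at least one imino residue (Pro/Hyp) while
#' the two triplets downstream contain none. Candidates lacking full
#' two-triplet context on either side have that flag set to `FALSE`.
#'
#' @param sequence Character scalar or residue vector covering the registry.
#' @param registry A `helix_registry`.
#' @return A data.frame of class `cleavage_sites` with columns `site_start`
#'   (protein position of the scissile Gly), `partner` (`"I"` or `"L"`),
#'   `upstream_ok`, `downstream_ok`, `is_true_site`.
#' @export
scan_cleavage_sites <- function(sequence, registry) {
  stopifnot(inherits(registry, "helix_registry"))
  res <- as_residue_vector(sequence)
  if (length(res) < registry$domain_end)
    stop("sequence does not cover the registry span", call. = FALSE)
  gly_pos <- seq.int(registry$domain_start, registry$domain_end, by = 3L)
  cand <- gly_pos[res[gly_pos] == "G" & gly_pos + 1L <= registry$domain_end &
                    res[gly_pos + 1L] %in% c("I", "L")]
  has_imino <- function(p) any(res[c(p + 1L, p + 2L)] %in% IMINO)  # Xaa/Yaa of triplet at Gly p
  up_ok <- vapply(cand, function(g) {
    g - 6L >= registry$domain_start && has_imino(g - 6L) && has_imino(g - 3L)
  }, logical(1L))
  down_ok <- vapply(cand, function(g) {
    g + 8L <= registry$domain_end && !has_imino(g + 3L) && !has_imino(g + 6L)
  }, logical(1L))
  out <- data.frame(site_start = as.integer(cand),
                    partner = res[cand + 1L],
                    upstream_ok = up_ok, downstream_ok = down_ok,
                    is_true_site = up_ok & down_ok, row.names = NULL)
  class(out) <- c("cleavage_sites", "data.frame")
  out
}

#' Signed residue distance from a cleavage site to a duplication
#'
#' Counted from the first residue after the scissile bond (the Ile/Leu) to
#' the first duplicated residue; downstream is positive. A duplication
#' starting immediately after the scissile bond has distance 0.
#'
#' @param dup A `protein_dup`.
#' @param site_start Protein position of the scissile-bond Gly (scalar), or
#'   a one-row subset of a [scan_cleavage_sites()] result.
#' @return Integer residue count.
#' @export
distance_to_cleavage <- function(dup, site_start) {
  stopifnot(inherits(dup, "protein_dup"))
  if (is.data.frame(site_start)) {
    stopifnot(nrow(site_start) == 1L)
    site_start <- site_start$site_start
  }
  first_dup <- if (dup$is_tandem) dup$aa_start else dup$ins_after + 1L
  as.integer(first_dup - (site_start + 1L))
}

#' Annotate a set of duplication variants against a coding sequence
#'
#' Convenience wrapper producing the tabular report: one row per HGVS
#' descriptor with nucleotide/protein lengths, duplicated run, registry
#' preservation and (when a cleavage site is found) the distance to the
#' nearest true cleavage site.
#'
#' @param hgvs Character vector of HGVS duplication descriptors.
#' @param cds Coding sequence (character scalar).
#' @param registry A `helix_registry` (optional; registry columns are `NA`
#'   without it).
#' @param file Optional path: when given, the table is written as TSV.
#' @return A data.frame with columns `hgvs`, `dup_length_nt`, `dup_length_aa`,
#'   `dup_seq`, `aa_start`, `aa_end`, `registry_preserved`,
#'   `distance_to_cleavage`.
#' @export
annotate_variants <- function(hgvs, cds, registry = NULL, file = NULL) {
  rows <- lapply(hgvs, function(h) {
    v <- parse_dup(h)
    p <- project_to_protein(v, cds)
    reg_ok <- NA; dist <- NA_integer_
    if (!is.null(registry)) {
      reg_ok <- registry_check(registry, p)
      sites <- scan_cleavage_sites(cds_to_protein(cds), registry)
      true_sites <- sites$site_start[sites$is_true_site]
      if (length(true_sites)) {
        d <- vapply(true_sites, function(s) distance_to_cleavage(p, s),
                    integer(1L))
        dist <- d[which.min(abs(d))]
      }
    }
    data.frame(hgvs = h, dup_length_nt = v$length_nt,
               dup_length_aa = p$length_aa, dup_seq = p$aa_seq,
               aa_start = p$aa_start, aa_end = p$aa_end,
               registry_preserved = reg_ok, distance_to_cleavage = dist)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

# translate a CDS string to its one-letter protein vector
cds_to_protein <- function(cds) {
  cds <- toupper(gsub("\\s", "", paste(cds, collapse = "")))
  translate_nt(strsplit(cds, "")[[1L]])
}

# accept "GLAGPA" or c("G","L",...) and return an uppercase residue vector
as_residue_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  toupper(sequence)
}

#' Read the first sequence from a FASTA file
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Character scalar, the sequence in upper case.
#' @export
read_fasta_seq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          seqonly = TRUE)
  toupper(s[[1L]])
}
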