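# HGVS-style duplication parsing and protein projection for collagen chains.
# Coordinates are 1-based inclusive throughout (cDNA and protein), matching
# the HGVS convention.

#' Parse an HGVS-style cDNA duplication descriptor
#'
#' Accepts descriptors of the form `<transcript>:c.<start>_<end>dup` with an
#' optional trailing duplicated nucleotide run (separated by `-` or given
#' directly), e.g. `"NM_000090.3:c.2868_2885dup"` or
#' `"NM_000090.3:c.2868_2885dupGGGTCTTGCAGGACCACC"`.
#'
#' @param hgvs_text Character scalar, the descriptor.
#' @return An object of class `coding_variant` with fields `transcript_id`,
#'   `cdna_start`, `cdna_end`, `length_nt`, `in_frame` and (possibly `NA`)
#'   `dup_nt`, the declared duplicated sequence kept for validation.
#' @examples
#' parse_dup("NM_000090.3:c.2868_2885dup")
#' @export
parse_dup <- function(hgvs_text) {
  stopifnot(is.character(hgvs_text), length(hgvs_text) == 1L)
  txt <- trimws(hgvs_text)
  # tolerate the unicode hyphen sometimes used between "dup" and the run
  txt <- gsub("‐|‑|‒|–", "-", txt)
  pat <- "^([A-Za-z0-9_.()-]+):c\\.([0-9]+)_([0-9]+)dup-?([ACGTacgt]*)$"
  if (!grepl(pat, txt)) {
    bad <- if (!grepl(":", txt)) txt else sub("^[^:]*:", "", txt)
    stop("malformed HGVS duplication descriptor: '", bad, "'", call. = FALSE)
  }
  m <- regmatches(txt, regexec(pat, txt))[[1L]]
  start <- as.integer(m[3L]); end <- as.integer(m[4L])
  if (start > end)
    stop("coordinate error: cdna_start (", start, ") > cdna_end (", end, ")",
         call. = FALSE)
  dup_nt <- toupper(m[5L])
  if (!nzchar(dup_nt)) dup_nt <- NA_character_
  len <- end - start + 1L
  if (!is.na(dup_nt) && nchar(dup_nt) != len)
    stop("declared duplicated sequence length (", nchar(dup_nt),
         ") does not match coordinates (", len, " nt)", call. = FALSE)
  structure(
    list(transcript_id = m[2L], cdna_start = start, cdna_end = end,
         length_nt = len, in_frame = (len %% 3L == 0L), dup_nt = dup_nt),
    class = "coding_variant")
}

#' @export
print.coding_variant <- function(x, ...) {
  cat(sprintf("<coding_variant> %s:c.%d_%ddup  (%d nt, %s)\n",
              x$transcript_id, x$cdna_start, x$cdna_end, x$length_nt,
              if (x$in_frame) "in-frame" else "out-of-frame"))
  invisible(x)
}

#' Project an in-frame cDNA duplication onto protein coordinates
#'
#' Builds the mutant coding sequence, translates both alleles, locates the
#' inserted amino-acid run and normalizes it to the 3'-most (most C-terminal)
#' equivalent position, the HGVS convention under which e.g. an 18-nt
#' duplication is named p.(Leu958_Gly963dup).
#'
#' When the duplicated nucleotides are not codon-aligned the junction
#' codons are hybrids and the protein-level change may be a plain insertion
#' rather than a clean tandem amino-acid duplication; this is reported via
#' `is_tandem` (and `aa_start`/`aa_end` are `NA` in that case, HGVS would
#' name it `ins`).
#'
#' @param variant A `coding_variant` from [parse_dup()].
#' @param cds Character scalar: the coding nucleotide sequence (5'->3',
#'   length divisible by 3).
#' @return An object of class `protein_dup` with fields `aa_start`, `aa_end`
#'   (1-based inclusive protein coordinates of the duplicated run on the
#'   reference protein; `NA` for non-tandem insertions), `ins_after` (the
#'   reference residue after which the run is inserted), `aa_seq`
#'   (one-letter inserted run), `length_aa` and `is_tandem`.
#' @export
project_to_protein <- function(variant, cds) {
  stopifnot(inherits(variant, "coding_variant"))
  cds <- toupper(gsub("\\s", "", paste(cds, collapse = "")))
  if (nchar(cds) %% 3L != 0L)
    stop("cds length (", nchar(cds), ") is not divisible by 3", call. = FALSE)
  if (variant$cdna_end > nchar(cds))
    stop("range error: variant end ", variant$cdna_end,
         " beyond cds length ", nchar(cds), call. = FALSE)
  if (!variant$in_frame)
    stop("frame error: duplication length ", variant$length_nt,
         " is not a multiple of 3", call. = FALSE)
  nt <- strsplit(cds, "")[[1L]]
  dup_run <- nt[variant$cdna_start:variant$cdna_end]
  if (!is.na(variant$dup_nt) &&
      paste(dup_run, collapse = "") != variant$dup_nt)
    stop("declared duplicated sequence does not match the cds at c.",
         variant$cdna_start, "_", variant$cdna_end, call. = FALSE)

  mut <- append(nt, dup_run, after = variant$cdna_end)
  wt_aa  <- translate_nt(nt)
  mut_aa <- translate_nt(mut)
  k <- length(mut_aa) - length(wt_aa)
  if (k * 3L != variant$length_nt)  # in-frame dup can never hit this
    stop("internal error: protein insertion length mismatch", call. = FALSE)

  # first protein position where the alleles differ
  d <- 1L
  while (d <= length(wt_aa) && wt_aa[d] == mut_aa[d]) d <- d + 1L
  # shift the insertion point to its 3'-most equivalent representation
  while (d + k <= length(mut_aa) && mut_aa[d] == mut_aa[d + k]) d <- d + 1L
  ins <- mut_aa[d:(d + k - 1L)]
  tandem <- d - k >= 1L && identical(ins, wt_aa[(d - k):(d - 1L)])
  protein_dup(aa_start = if (tandem) d - k else NA_integer_,
              aa_end = if (tandem) d - 1L else NA_integer_,
              aa_seq = paste(ins, collapse = ""),
              ins_after = d - 1L, is_tandem = tandem)
}

#' Construct a protein-level duplication/insertion record
#'
#' @param aa_start,aa_end 1-based inclusive reference coordinates of the
#'   duplicated run (`NA` for a non-tandem insertion).
#' @param aa_seq One-letter sequence of the inserted run.
#' @param ins_after Reference residue after which the run is inserted;
#'   defaults to `aa_end` (the tandem convention).
#' @param is_tandem Is the run a clean tandem duplication of the reference?
#' @return An object of class `protein_dup`.
#' @export
protein_dup <- function(aa_start, aa_end, aa_seq, ins_after = aa_end,
                        is_tandem = TRUE) {
  k <- nchar(aa_seq)
  if (is_tandem && (is.na(aa_start) || aa_end - aa_start + 1L != k))
    stop("aa coordinates do not match the run length", call. = FALSE)
  structure(
    list(aa_start = as.integer(aa_start), aa_end = as.integer(aa_end),
         aa_seq = aa_seq, ins_after = as.integer(ins_after),
         length_aa = as.integer(k), is_tandem = isTRUE(is_tandem)),
    class = "protein_dup")
}

#' @export
print.protein_dup <- function(x, ...) {
  if (x$is_tandem)
    cat(sprintf("<protein_dup> p.%d_%ddup %s (%d aa)\n",
                x$aa_start, x$aa_end, x$aa_seq, x$length_aa))
  else
    cat(sprintf("<protein_dup> p.%d_%dins%s (%d aa, not a clean tandem)\n",
                x$ins_after, x$ins_after + 1L, x$aa_seq, x$length_aa))
  invisible(x)
}

# translate a nucleotide character vector with the standard code
translate_nt <- function(nt) {
  aa <- seqinr::translate(nt)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  aa
}
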