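## Six-frame translation scanning of nucleotide contigs.
##
## Draft genome assemblies are scanned by translating every contig in all six
## reading frames, splitting the translations at stop codons, and retaining
## peptide segments long enough to be informative for profile-HMM search.
## Coordinates are 0-based, half-open, and always reported on the forward
## strand with an explicit strand field.

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D")

#' Reverse complement of a nucleotide string
#'
#' @param nuc A nucleotide string (IUPAC alphabet, case-insensitive).
#' @return The reverse complement, upper-cased. `N` maps to `N`; the function
#'   is an involution.
#' @export
#' @examples
#' reverse_complement("ATG")  # "CAT"
reverse_complement <- function(nuc) {
  stopifnot(is.character(nuc), length(nuc) == 1L)
  if (nchar(nuc) == 0L) return(nuc)
  nuc <- toupper(nuc)
  bad <- regexpr(sprintf("[^%s]", paste(names(IUPAC_COMPLEMENT), collapse = "")), nuc)
  if (bad > 0L) {
    abort(sprintf("invalid nucleotide character '%s' at position %d",
                  substr(nuc, bad, bad), bad))
  }
  from <- paste(names(IUPAC_COMPLEMENT), collapse = "")
  to <- paste(unname(IUPAC_COMPLEMENT), collapse = "")
  paste(rev(split_chars(chartr(from, to, nuc))), collapse = "")
}

#' Translate a nucleotide sequence in a given reading frame
#'
#' Standard genetic code (translation table 1). Negative frames translate the
#' reverse complement with the same offset rule. The trailing partial codon is
#' dropped; codons containing `N` (or any ambiguity code) translate to `X`;
#' stop codons appear as `*`.
#'
#' @param nuc Nucleotide string (IUPAC, case-insensitive).
#' @param frame Signed reading frame in `c(1, 2, 3, -1, -2, -3)`.
#' @return Amino-acid string, possibly empty if the effective sequence is
#'   shorter than one codon.
#' @export
#' @examples
#' translate("ATGAAATAG", 1)  # "MK*"
#' translate("CAT", -1)       # "M"
translate <- function(nuc, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  nuc <- toupper(nuc)
  bad <- regexpr(sprintf("[^%s]", paste(names(IUPAC_COMPLEMENT), collapse = "")), nuc)
  if (bad > 0L) {
    abort(sprintf("invalid nucleotide character '%s' at position %d",
                  substr(nuc, bad, bad), bad))
  }
  if (frame < 0L) nuc <- reverse_complement(nuc)
  offset <- abs(frame) - 1L
  n <- nchar(nuc) - offset
  if (n < 3L) return("")
  n_codons <- n %/% 3L
  starts <- offset + 3L * seq_len(n_codons) - 2L
  codons <- substring(nuc, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split six-frame translations of contigs into stop-free peptide segments
#'
#' Every contig is translated in all six frames; each translation is split at
#' stop codons and segments of at least `min_len` residues are returned with
#' coordinates that map each segment back to the forward strand of its contig
#' (0-based, half-open). Re-extracting the nucleotide span of a segment and
#' re-translating it in frame +1 (after reverse complementing for minus-strand
#' segments) reproduces `aa_seq` exactly.
#'
#' @param contigs Data frame with columns `id`, `seq`, and optionally
#'   `species`.
#' @param min_len Minimum segment length in residues (default 20; shorter
#'   matches carry too little information for profile search).
#' @return A tibble with columns `contig_id`, `species`, `frame`, `strand`,
#'   `nuc_start`, `nuc_end`, `aa_seq`.
#' @export
six_frame_segments <- function(contigs, min_len = 20L) {
  stopifnot(min_len >= 1L, all(c("id", "seq") %in% names(contigs)))
  species <- if ("species" %in% names(contigs)) contigs$species else rep(NA_character_, nrow(contigs))
  out <- vector("list", nrow(contigs) * 6L)
  n_out <- 0L
  for (i in seq_len(nrow(contigs))) {
    cs <- normalize_nuc(contigs$seq[i], what = contigs$id[i])
    L <- nchar(cs)
    if (L < 3L) next
    for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      aa <- translate(cs, frame)
      if (nchar(aa) == 0L) next
      runs <- gregexpr("[^*]+", aa)[[1]]
      if (runs[1] == -1L) next
      len <- attr(runs, "match.length")
      keep <- len >= min_len
      if (!any(keep)) next
      c1 <- as.integer(runs[keep]) - 1L       # 0-based first codon index
      c2 <- c1 + len[keep] - 1L               # 0-based last codon index
      offset <- abs(frame) - 1L
      if (frame > 0L) {
        nuc_start <- offset + 3L * c1
        nuc_end <- offset + 3L * (c2 + 1L)
        strand <- "+"
      } else {
        nuc_start <- L - (offset + 3L * (c2 + 1L))
        nuc_end <- L - (offset + 3L * c1)
        strand <- "-"
      }
      n_out <- n_out + 1L
      out[[n_out]] <- tibble(
        contig_id = contigs$id[i],
        species = species[i],
        frame = frame,
        strand = strand,
        nuc_start = nuc_start,
        nuc_end = nuc_end,
        aa_seq = substring(aa, c1 + 1L, c2 + 1L)
      )
    }
  }
  if (n_out == 0L) {
    return(tibble(contig_id = character(), species = character(),
                  frame = integer(), strand = character(),
                  nuc_start = integer(), nuc_end = integer(),
                  aa_seq = character()))
  }
  dplyr::bind_rows(out[seq_len(n_out)])
}

#' Extract the nucleotide span encoding a peptide segment
#'
#' Inverse of the coordinate mapping in [six_frame_segments()]: returns the
#' forward-strand span, reverse complemented for minus-strand segments, so
#' that `translate(result, 1)` reproduces the segment's peptide.
#'
#' @param contig_seq Contig nucleotide string.
#' @param nuc_start,nuc_end 0-based half-open coordinates on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string in the segment's reading orientation.
#' @export
segment_nucleotides <- function(contig_seq, nuc_start, nuc_end, strand) {
  s <- substr(contig_seq, nuc_start + 1L, nuc_end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Write peptide segments as a BED-like 6-column TSV
#'
#' Columns: contig, start, end, strand, frame, peptide (0-based half-open).
#'
#' @param segments Tibble from [six_frame_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  out <- segments[, c("contig_id", "nuc_start", "nuc_end", "strand", "frame", "aa_seq")]
  names(out) <- c("contig", "start", "end", "strand", "frame", "peptide")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
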