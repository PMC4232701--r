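## Internal helpers shared across modules.

## Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## log(sum(exp(x))) with max factoring; -Inf-safe.
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## Validate and normalize a nucleotide string to upper-case {A,C,G,T,N}.
normalize_nuc <- function(nuc, what = "sequence") {
  nuc <- toupper(nuc)
  bad <- regexpr("[^ACGTN]", nuc)
  if (bad > 0L) {
    abort(sprintf("invalid nucleotide character '%s' at position %d in %s",
                  substr(nuc, bad, bad), bad, what))
  }
  nuc
}

## Map an amino-acid string to 0-based integer codes; X / ambiguity -> -1.
aa_encode <- function(aa_seq) {
  chars <- split_chars(toupper(aa_seq))
  idx <- match(chars, AMINO_ACIDS)
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a tibble
#' with one row per record, so results feed directly into the tidy pipeline.
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  tibble(id = ids, seq = unname(as.character(x)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A data frame with columns `id` and `seq`.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
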