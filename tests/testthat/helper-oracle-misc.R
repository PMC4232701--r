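# Independent oracles for translation and parsimony, plus small fixtures.

# Per-codon lookup translation using Biostrings' genetic code table directly
# (no frame logic shared with the package).
oracle_translate <- function(nuc, frame) {
  nuc <- toupper(nuc)
  if (frame < 0) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    nuc <- paste(rev(comp[strsplit(nuc, "")[[1]]]), collapse = "")
  }
  off <- abs(frame) - 1
  chars <- strsplit(nuc, "")[[1]]
  chars <- chars[(off + 1):length(chars)]
  n_codon <- length(chars) %/% 3
  if (n_codon == 0) return("")
  out <- character(n_codon)
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(n_codon)) {
    codon <- paste(chars[(3 * i - 2):(3 * i)], collapse = "")
    out[i] <- if (grepl("N", codon)) "X" else unname(gc[codon])
  }
  paste(out, collapse = "")
}

# Brute-force Fitch parsimony: enumerate every assignment of {0,1} to the
# internal nodes and count state changes over edges; return the minimum.
oracle_fitch_score <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_state <- as.integer(tree$tip.label %in% present_tips)
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    internal <- as.integer(intToBits(mask))[seq_len(nnode)]
    states <- c(tip_state, internal)
    changes <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Exhaustive bipartition check: a set is monophyletic on an unrooted tree iff
# removing some edge splits the tips into (set | complement).
oracle_monophyletic <- function(tree, taxa) {
  ut <- ape::unroot(tree)
  target <- sort(taxa)
  ntip <- length(ut$tip.label)
  for (j in seq_len(nrow(ut$edge))) {
    g <- ut
    child <- ut$edge[j, 2]
    tips_below <- if (child <= ntip) {
      ut$tip.label[child]
    } else {
      ape::extract.clade(ut, child)$tip.label
    }
    other <- setdiff(ut$tip.label, tips_below)
    if (identical(sort(tips_below), target) || identical(sort(other), target)) {
      return(TRUE)
    }
  }
  FALSE
}

random_ungapped_alignment <- function(n_rows, n_cols, seed, gap_frac = 0) {
  set.seed(seed)
  rows <- vapply(seq_len(n_rows), function(i) {
    ch <- sample(famscan:::AMINO_ACIDS, n_cols, replace = TRUE)
    if (gap_frac > 0) {
      gaps <- which(runif(n_cols) < gap_frac)
      ch[gaps] <- "-"
    }
    paste(ch, collapse = "")
  }, character(1))
  tibble::tibble(id = paste0("r", seq_len(n_rows)), seq = rows)
}
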