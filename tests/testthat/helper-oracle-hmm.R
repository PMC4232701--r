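# Independent brute-force oracles for profile-HMM scoring.
#
# enumerate_paths() sums (or maximizes) over every legal local-alignment path
# by explicit recursion: entry at any match state and any target start
# position, transitions through match/insert/delete states, exit from any
# match state (or a trailing delete chain ending at D_M). It shares no code
# with the package's dynamic-programming kernels.

# All probabilities in odds units against the background; returns a list of
# per-path log-odds values (natural log) so the caller can sum or max.
enumerate_path_logodds <- function(hmm, seq) {
  M <- hmm$M
  L <- nchar(seq)
  a <- match(strsplit(toupper(seq), "")[[1]], famscan:::AMINO_ACIDS)
  q <- unname(hmm$background)
  modds <- function(k, ai) if (is.na(ai)) 0 else log(hmm$match_emit[k, ai]) - log(q[ai])
  iodds <- function(ai) if (is.na(ai)) 0 else log(hmm$insert_emit[ai]) - log(q[ai])
  tr <- hmm$transitions
  entry <- 2 * (M - seq_len(M) + 1) / (M * (M + 1))
  eps <- 1 / (M - seq_len(M) + 1)
  lp <- log(L / (L + 2))
  out <- new.env()
  out$vals <- numeric(0)
  emit_path <- function(v) out$vals <- c(out$vals, v)

  # acc: log-odds accumulated; pos: index of last consumed residue
  from_match <- function(k, pos, acc) {
    emit_path(acc + log(eps[k]))               # exit from M_k
    if (k < M) {
      stay <- log(1 - eps[k])
      if (pos < L) {
        from_state("M", k + 1, pos + 1,
                   acc + stay + log(tr$MM[k]) + modds(k + 1, a[pos + 1]) - lp)
        from_state("I", k, pos + 1,
                   acc + stay + log(tr$MI[k]) + iodds(a[pos + 1]) - lp)
      }
      from_state("D", k + 1, pos, acc + stay + log(tr$MD[k]))
    }
  }
  from_insert <- function(k, pos, acc) {
    if (pos < L) {
      from_state("M", k + 1, pos + 1,
                 acc + log(tr$IM[k]) + modds(k + 1, a[pos + 1]) - lp)
      from_state("I", k, pos + 1,
                 acc + log(tr$II[k]) + iodds(a[pos + 1]) - lp)
    }
  }
  from_delete <- function(k, pos, acc) {
    if (k == M) {
      emit_path(acc)                           # D_M -> E with probability 1
      return(invisible(NULL))
    }
    if (pos < L) {
      from_state("M", k + 1, pos + 1,
                 acc + log(tr$DM[k]) + modds(k + 1, a[pos + 1]) - lp)
    }
    from_state("D", k + 1, pos, acc + log(tr$DD[k]))
  }
  from_state <- function(type, k, pos, acc) {
    if (!is.finite(acc)) return(invisible(NULL))
    switch(type,
           M = from_match(k, pos, acc),
           I = from_insert(k, pos, acc),
           D = from_delete(k, pos, acc))
  }
  for (s in seq_len(L)) {
    for (k in seq_len(M)) {
      from_state("M", k, s, log(entry[k]) + modds(k, a[s]) - lp)
    }
  }
  out$vals + log(2 / (L + 2))
}

oracle_forward_ln <- function(hmm, seq) {
  v <- enumerate_path_logodds(hmm, seq)
  m <- max(v)
  m + log(sum(exp(v - m)))
}

oracle_viterbi_ln <- function(hmm, seq) {
  max(enumerate_path_logodds(hmm, seq))
}

# Random small profile for oracle comparisons (valid normalized parameters).
random_small_hmm <- function(M = 3L, seed = 1L) {
  set.seed(seed)
  q <- unname(famscan:::BACKGROUND_FREQS)
  me <- matrix(0, M, 20, dimnames = list(NULL, famscan:::AMINO_ACIDS))
  for (k in seq_len(M)) {
    x <- rgamma(20, 0.8)
    me[k, ] <- x / sum(x)
  }
  rdir3 <- function() { x <- rgamma(3, 2); x / sum(x) }
  rdir2 <- function() { x <- rgamma(2, 2); x / sum(x) }
  n1 <- max(M - 1L, 0L)
  tr <- list(MM = numeric(n1), MI = numeric(n1), MD = numeric(n1),
             IM = numeric(n1), II = numeric(n1),
             DM = numeric(n1), DD = numeric(n1))
  for (k in seq_len(n1)) {
    t3 <- rdir3(); t2 <- rdir2(); td <- rdir2()
    tr$MM[k] <- t3[1]; tr$MI[k] <- t3[2]; tr$MD[k] <- t3[3]
    tr$IM[k] <- t2[1]; tr$II[k] <- t2[2]
    tr$DM[k] <- td[1]; tr$DD[k] <- td[2]
  }
  structure(list(name = "rand", subfamily = NA_character_,
                 region = NA_character_, M = M, match_emit = me,
                 insert_emit = stats::setNames(q, famscan:::AMINO_ACIDS),
                 transitions = tr,
                 background = stats::setNames(q, famscan:::AMINO_ACIDS),
                 match_columns = seq_len(M), n_train = 0L,
                 params = list(), calibration = NULL),
            class = "profile_hmm")
}

random_aa_seq <- function(L, prob = unname(famscan:::BACKGROUND_FREQS)) {
  paste(sample(famscan:::AMINO_ACIDS, L, replace = TRUE, prob = prob),
        collapse = "")
}
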