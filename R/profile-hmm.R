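## Profile hidden Markov models: construction from labeled alignments,
## local-alignment scoring, Gumbel E-value calibration, and logos.

#' Decide which alignment columns are match columns
#'
#' Column `k` is assigned to a match state when the fraction of non-gap
#' residues in it is at least `symfrac` (the HMMER-style occupancy rule).
#'
#' @param aln Alignment as a data frame with columns `id` and `seq` (gapped,
#'   equal length, gap symbol `-`).
#' @param symfrac Occupancy threshold in (0, 1], default 0.5.
#' @return Logical vector, one element per alignment column.
#' @export
assign_match_columns <- function(aln, symfrac = 0.5) {
  stopifnot(symfrac > 0, symfrac <= 1)
  m <- aln_matrix(aln)
  occ <- colMeans(m != "-")
  mask <- occ >= symfrac
  if (!any(mask)) abort("no consensus columns: no column passes symfrac")
  mask
}

## Alignment tibble -> character matrix (rows x columns), with validation.
aln_matrix <- function(aln) {
  stopifnot(all(c("id", "seq") %in% names(aln)))
  if (nrow(aln) < 1L) abort("alignment has no rows")
  w <- unique(nchar(aln$seq))
  if (length(w) != 1L) abort("alignment rows have unequal lengths")
  if (w == 0L) abort("alignment has zero columns")
  m <- matrix(unlist(strsplit(toupper(aln$seq), "", fixed = TRUE)),
              nrow = nrow(aln), ncol = w, byrow = TRUE)
  rownames(m) <- aln$id
  m
}

## Henikoff position-based sequence weights, computed on match columns only.
## Weights are normalized to sum to the number of rows.
henikoff_weights <- function(m, match_mask) {
  n <- nrow(m)
  w <- numeric(n)
  for (k in which(match_mask)) {
    col <- m[, k]
    res <- col != "-"
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    contrib <- 1 / (r * as.numeric(tab[col[res]]))
    w[res] <- w[res] + contrib
  }
  if (sum(w) == 0) return(rep(1, n))
  w * n / sum(w)
}

#' Build a profile HMM from a (subfamily-restricted) alignment
#'
#' Match-state emissions are background-smoothed weighted counts,
#' `e_k(a) = (c_k(a) + tau * q(a)) / (C_k + tau)`; insert emissions equal the
#' background; state transition probabilities are weighted counts of each
#' row's implied match/insert/delete path with add-one smoothing. The
#' background `q` is the package's canonical amino-acid frequency table unless
#' `background = "training"`.
#'
#' @param aln Alignment tibble (`id`, `seq`, optional `label`).
#' @param name Profile name.
#' @param subfamily,region Labels recorded on the profile.
#' @param symfrac Match-column occupancy threshold (default 0.5).
#' @param tau Pseudocount mass added per match column (default 5).
#' @param weighting `"henikoff"` (position-based, default) or `"uniform"`.
#' @param background `"canonical"` (default) or `"training"` (frequencies
#'   counted from the alignment with add-one smoothing).
#' @return An object of class `profile_hmm`.
#' @export
build_profile <- function(aln, name = "profile", subfamily = NA_character_,
                          region = NA_character_, symfrac = 0.5, tau = 5,
                          weighting = c("henikoff", "uniform"),
                          background = c("canonical", "training")) {
  weighting <- match.arg(weighting)
  background <- match.arg(background)
  stopifnot(tau >= 0)
  m <- aln_matrix(aln)
  bad <- setdiff(unique(as.vector(m)), c(AMINO_ACIDS, "-", "X"))
  if (length(bad)) abort(paste0("invalid alignment characters: ",
                                paste(bad, collapse = ", ")))
  mask <- assign_match_columns(aln, symfrac)
  M <- sum(mask)
  q <- if (background == "training") {
    res <- as.vector(m)
    res <- res[res %in% AMINO_ACIDS]
    cnt <- table(factor(res, levels = AMINO_ACIDS))
    as.numeric(cnt + 1) / sum(cnt + 1)
  } else {
    unname(BACKGROUND_FREQS)
  }
  w <- if (weighting == "henikoff") henikoff_weights(m, mask) else rep(1, nrow(m))

  ## weighted residue counts per match column ('X' contributes background mass)
  match_cols <- which(mask)
  match_emit <- matrix(0, nrow = M, ncol = 20,
                       dimnames = list(NULL, AMINO_ACIDS))
  for (j in seq_len(M)) {
    col <- m[, match_cols[j]]
    counts <- numeric(20)
    for (i in seq_along(col)) {
      a <- col[i]
      if (a == "-") next
      if (a == "X") counts <- counts + w[i] * q
      else counts[match(a, AMINO_ACIDS)] <- counts[match(a, AMINO_ACIDS)] + w[i]
    }
    match_emit[j, ] <- (counts + tau * q) / (sum(counts) + tau)
  }

  ## transition counts from each row's implied state path
  cMM <- cMI <- cMD <- cIM <- cII <- cDM <- cDD <- numeric(max(M - 1L, 0L))
  col_state <- cumsum(mask)   # match index of each column (valid where mask)
  for (i in seq_len(nrow(m))) {
    prev <- NULL  # list(type, k)
    for (cc in seq_len(ncol(m))) {
      a <- m[i, cc]
      if (mask[cc]) {
        k <- col_state[cc]
        cur <- list(type = if (a == "-") "D" else "M", k = k)
        if (!is.null(prev) && prev$k >= 1L && prev$k < M) {
          kk <- prev$k
          if (prev$type == "M") {
            if (cur$type == "M") cMM[kk] <- cMM[kk] + w[i]
            else cMD[kk] <- cMD[kk] + w[i]
          } else if (prev$type == "I") {
            cIM[kk] <- cIM[kk] + w[i]   # I -> M or I -> (D): count as I->M
          } else {
            if (cur$type == "M") cDM[kk] <- cDM[kk] + w[i]
            else cDD[kk] <- cDD[kk] + w[i]
          }
        }
        prev <- cur
      } else if (a != "-") {
        k <- col_state[cc]  # insert residues attach to the preceding match state
        if (k >= 1L && k < M) {
          if (!is.null(prev) && prev$type == "I" && prev$k == k) {
            cII[k] <- cII[k] + w[i]
          } else if (!is.null(prev) && prev$type == "M" && prev$k == k) {
            cMI[k] <- cMI[k] + w[i]
          }
          prev <- list(type = "I", k = k)
        }
      }
    }
  }
  norm3 <- function(a, b, c) {
    s <- (a + 1) + (b + 1) + (c + 1)
    list((a + 1) / s, (b + 1) / s, (c + 1) / s)
  }
  norm2 <- function(a, b) {
    s <- (a + 1) + (b + 1)
    list((a + 1) / s, (b + 1) / s)
  }
  if (M > 1L) {
    t3 <- norm3(cMM, cMI, cMD)
    ti <- norm2(cIM, cII)
    td <- norm2(cDM, cDD)
    trans <- list(MM = t3[[1]], MI = t3[[2]], MD = t3[[3]],
                  IM = ti[[1]], II = ti[[2]],
                  DM = td[[1]], DD = td[[2]])
  } else {
    trans <- list(MM = numeric(0), MI = numeric(0), MD = numeric(0),
                  IM = numeric(0), II = numeric(0),
                  DM = numeric(0), DD = numeric(0))
  }

  structure(list(
    name = name, subfamily = subfamily, region = region,
    M = M, match_emit = match_emit,
    insert_emit = setNames(q, AMINO_ACIDS),
    transitions = trans,
    background = setNames(q, AMINO_ACIDS),
    match_columns = match_cols,
    n_train = nrow(m),
    params = list(symfrac = symfrac, tau = tau, weighting = weighting,
                  background = background),
    calibration = NULL
  ), class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %s  subfamily=%s region=%s  M=%d  %s\n",
              x$name, x$subfamily, x$region, x$M,
              if (is.null(x$calibration)) "uncalibrated"
              else sprintf("Gumbel(mu=%.2f, lambda=%.3f)",
                           x$calibration$mu, x$calibration$lambda)))
  invisible(x)
}

## Precompute the log-space parameter list consumed by the C++ DP kernels.
hmm_log_params <- function(hmm) {
  if (!is.null(hmm$.log_params)) return(hmm$.log_params)
  M <- hmm$M
  q <- unname(hmm$background)
  lodds <- log(hmm$match_emit) - matrix(log(q), nrow = M, ncol = 20, byrow = TRUE)
  liodds <- log(unname(hmm$insert_emit)) - log(q)
  k <- seq_len(M)
  entry <- 2 * (M - k + 1) / (M * (M + 1))
  eps <- 1 / (M - k + 1)
  pad <- function(v) {
    out <- rep(-Inf, M)
    if (length(v)) out[seq_along(v)] <- log(v)
    out
  }
  list(M = M, lodds = lodds, liodds = liodds,
       lentry = log(entry), leps = log(eps),
       l1meps = ifelse(eps < 1, log(1 - eps), -Inf),
       lmm = pad(hmm$transitions$MM), lmi = pad(hmm$transitions$MI),
       lmd = pad(hmm$transitions$MD), lim = pad(hmm$transitions$IM),
       lii = pad(hmm$transitions$II), ldm = pad(hmm$transitions$DM),
       ldd = pad(hmm$transitions$DD))
}

#' Forward log-odds score of a sequence against a profile, in bits
#'
#' Sums over all local alignments (paths entering at any match state and
#' exiting from any match state; flanking residues emitted at background).
#' `bit_score = log2 P(seq | hmm) / P(seq | background)`.
#'
#' @param hmm A `profile_hmm`.
#' @param seq Amino-acid string (`X` permitted, scored at background odds).
#' @return Bit score (scalar).
#' @export
forward_bits <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nchar(seq) > 0L)
  .phmm_forward(hmm_log_params(hmm), aa_encode(seq)) / log(2)
}

#' Forward bit scores for many sequences
#'
#' @param hmm A `profile_hmm`.
#' @param seqs Character vector of amino-acid strings.
#' @return Numeric vector of bit scores.
#' @export
forward_bits_many <- function(hmm, seqs) {
  .phmm_forward_many(hmm_log_params(hmm), lapply(seqs, aa_encode)) / log(2)
}

#' Viterbi alignment of a sequence against a profile
#'
#' Maximum-probability local alignment under the same model as
#' [forward_bits()]; the Viterbi score never exceeds the forward score.
#'
#' @inheritParams forward_bits
#' @return A list with `bits` (Viterbi bit score), `path` (tibble with
#'   columns `state` in M/I/D, `position` (profile match state), `res_index`
#'   (1-based target residue, 0 for deletes)), and `span` (first/last target
#'   residue emitted by a match state, 1-based inclusive).
#' @export
viterbi_hmm <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"), nchar(seq) > 0L)
  v <- .phmm_viterbi(hmm_log_params(hmm), aa_encode(seq))
  path <- v$path
  list(bits = v$log_odds / log(2),
       path = tibble(state = c("M", "I", "D")[path[, 1]],
                     position = path[, 2], res_index = path[, 3]),
       span = v$span)
}

#' Calibrate a profile's Gumbel E-value parameters
#'
#' Scores `n_cal` i.i.d. background sequences of length `len_cal` with
#' [forward_bits()] and fits a Gumbel distribution by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma_Euler / lambda`.
#'
#' @param hmm A `profile_hmm`.
#' @param n_cal Number of null sequences (default 200, minimum 100).
#' @param len_cal Null sequence length (default `2 * M`).
#' @param seed Integer seed, recorded on the profile.
#' @return The profile with a `calibration` record (`mu`, `lambda`, `n_cal`,
#'   `len_cal`, `seed`).
#' @export
calibrate <- function(hmm, n_cal = 200L, len_cal = 2L * hmm$M, seed = 1L) {
  stopifnot(inherits(hmm, "profile_hmm"), n_cal >= 100L, len_cal >= 1L)
  q <- unname(hmm$background)
  scores <- with_seed(seed, {
    seqs <- replicate(n_cal, paste(
      sample(AMINO_ACIDS, len_cal, replace = TRUE, prob = q), collapse = ""))
    forward_bits_many(hmm, seqs)
  })
  s <- sd(scores)
  if (!is.finite(s) || s == 0) abort("calibration scores have zero variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  hmm$calibration <- list(mu = mu, lambda = lambda, n_cal = as.integer(n_cal),
                          len_cal = as.integer(len_cal), seed = as.integer(seed))
  hmm
}

#' E-value of a bit score under a calibrated profile
#'
#' `E = n_targets * (1 - exp(-exp(-lambda * (S - mu))))`, the expected number
#' of targets scoring at least `S` in a search of `n_targets` null sequences.
#'
#' @param hmm A calibrated `profile_hmm`.
#' @param bit_score Bit score(s).
#' @param n_targets Number of targets in the search (>= 1).
#' @return E-value(s), same length as `bit_score`.
#' @export
hmm_evalue <- function(hmm, bit_score, n_targets = 1L) {
  if (is.null(hmm$calibration)) abort("profile is not calibrated")
  stopifnot(n_targets >= 1)
  cal <- hmm$calibration
  n_targets * (-expm1(-exp(-cal$lambda * (bit_score - cal$mu))))
}

#' Per-position relative entropy and letter heights (HMM logo)
#'
#' `R_k = sum_a e_k(a) log2(e_k(a) / q(a))`; a letter's height is
#' `e_k(a) * R_k`. A position is flagged as harbouring an indel when its
#' match-to-delete or match-to-insert core transition probability exceeds
#' `indel_threshold`.
#'
#' @param hmm A `profile_hmm`.
#' @param indel_threshold Flagging threshold (default 0.10).
#' @return A tibble with one row per (position, letter): `position`,
#'   `relative_entropy`, `letter`, `height` (letters sorted by descending
#'   height within a position), `indel`.
#' @export
hmm_logo <- function(hmm, indel_threshold = 0.10) {
  stopifnot(inherits(hmm, "profile_hmm"))
  M <- hmm$M
  q <- unname(hmm$background)
  rel_ent <- vapply(seq_len(M), function(k) {
    e <- hmm$match_emit[k, ]
    sum(ifelse(e > 0, e * log2(e / q), 0))
  }, numeric(1))
  indel <- rep(FALSE, M)
  if (M > 1L) {
    indel[seq_len(M - 1L)] <- hmm$transitions$MD > indel_threshold |
      hmm$transitions$MI > indel_threshold
  }
  purrr::map_dfr(seq_len(M), function(k) {
    h <- hmm$match_emit[k, ] * rel_ent[k]
    ord <- order(h, decreasing = TRUE)
    tibble(position = k, relative_entropy = rel_ent[k],
           letter = AMINO_ACIDS[ord], height = unname(h[ord]),
           indel = indel[k])
  })
}

#' Serialize a profile HMM to JSON
#'
#' Versioned schema; probabilities are written at full double precision so
#' that `read_hmm_json(write_hmm_json(x))` reproduces them exactly.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_json <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  obj <- list(
    schema = "famscan/profile_hmm", schema_version = 1L,
    name = hmm$name, subfamily = hmm$subfamily, region = hmm$region,
    M = hmm$M,
    match_emit = unclass(hmm$match_emit),
    insert_emit = as.list(hmm$insert_emit),
    transitions = hmm$transitions,
    background = as.list(hmm$background),
    match_columns = hmm$match_columns,
    n_train = hmm$n_train,
    params = hmm$params,
    calibration = hmm$calibration
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Deserialize a profile HMM from JSON
#'
#' @param path Path written by [write_hmm_json()].
#' @return A `profile_hmm`.
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "famscan/profile_hmm")) {
    abort("not a famscan profile_hmm JSON file")
  }
  me <- matrix(unlist(obj$match_emit), nrow = obj$M, ncol = 20)
  colnames(me) <- AMINO_ACIDS
  cal <- obj$calibration
  if (!is.null(cal)) cal <- as.list(cal)
  structure(list(
    name = obj$name, subfamily = obj$subfamily, region = obj$region,
    M = as.integer(obj$M), match_emit = me,
    insert_emit = setNames(unlist(obj$insert_emit), AMINO_ACIDS),
    transitions = lapply(obj$transitions, as.numeric),
    background = setNames(unlist(obj$background), AMINO_ACIDS),
    match_columns = as.integer(obj$match_columns),
    n_train = as.integer(obj$n_train),
    params = as.list(obj$params),
    calibration = cal
  ), class = "profile_hmm")
}

#' @export
tidy.profile_hmm <- function(x, ...) hmm_logo(x, ...)

#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(name = x$name, subfamily = x$subfamily, region = x$region,
         n_match_states = x$M, n_train = x$n_train,
         calibrated = !is.null(x$calibration),
         gumbel_mu = x$calibration$mu %||% NA_real_,
         gumbel_lambda = x$calibration$lambda %||% NA_real_)
}

#' Plot an HMM logo
#'
#' Stacked letter heights per match position (total height = relative entropy
#' in bits); positions flagged as indel-prone are marked with a vertical line.
#'
#' @param object A `profile_hmm`.
#' @param ... Passed to [hmm_logo()].
#' @return A ggplot object.
#' @export
autoplot.profile_hmm <- function(object, ...) {
  lg <- hmm_logo(object, ...)
  top <- dplyr::slice_max(dplyr::group_by(lg, .data$position), .data$height,
                          n = 1, with_ties = FALSE)
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$letter)) +
    ggplot2::geom_col(width = 0.9, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = top$position[top$indel],
                        colour = "red", linewidth = 0.3) +
    ggplot2::geom_text(data = top,
                       ggplot2::aes(y = .data$relative_entropy,
                                    label = .data$letter),
                       vjust = -0.3, size = 2.5, inherit.aes = FALSE) +
    ggplot2::labs(x = "match position", y = "relative entropy (bits)",
                  title = object$name) +
    ggplot2::theme_minimal()
}
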