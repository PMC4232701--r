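## Genome scanning, best-E-value classification, reciprocal validation,
## exon-evidence ortholog calls, and presence/absence reconstruction.

#' Scan translated genome contigs with an HMM library
#'
#' Every peptide segment from [six_frame_segments()] is scored against every
#' calibrated profile in the library; hits with `E <= e_max` are retained.
#' The E-value search size `n_targets` is the number of segments scanned. Hit
#' intervals are the contig coordinates of the Viterbi match span. Overlapping
#' hits of the same (subfamily, region) on one segment are already unique by
#' construction (one score per segment per profile).
#'
#' @param contigs Contig tibble (`id`, `seq`, optional `species`).
#' @param library An [build_library()] `hmm_library`.
#' @param e_max E-value acceptance threshold (default 1e-5).
#' @param min_len Minimum translated segment length (default 20).
#' @return Tibble of hits: `target` (segment id), `contig_id`, `species`,
#'   `region`, `subfamily`, `bit_score`, `evalue`, `nuc_start`, `nuc_end`,
#'   `strand`, `frame`, `span_start`, `span_end`, `aa_seq`.
#' @export
scan_genome <- function(contigs, library, e_max = 1e-5, min_len = 20L) {
  stopifnot(inherits(library, "hmm_library"), e_max > 0)
  segs <- six_frame_segments(contigs, min_len = min_len)
  if (nrow(segs) == 0L) return(empty_hits())
  n_targets <- nrow(segs)
  segs$target <- sprintf("%s|%s%d|%d-%d", segs$contig_id,
                         segs$strand, abs(segs$frame),
                         segs$nuc_start, segs$nuc_end)
  out <- vector("list", length(library$profiles))
  for (pi in seq_along(library$profiles)) {
    hmm <- library$profiles[[pi]]
    if (is.null(hmm$calibration)) abort(sprintf("profile %s not calibrated", hmm$name))
    bits <- forward_bits_many(hmm, segs$aa_seq)
    ev <- hmm_evalue(hmm, bits, n_targets)
    keep <- which(ev <= e_max)
    if (!length(keep)) next
    rows <- purrr::map_dfr(keep, function(i) {
      v <- viterbi_hmm(hmm, segs$aa_seq[i])
      s <- segs[i, ]
      # residue span (1-based inclusive) -> contig coordinates (0-based half-open)
      i1 <- v$span[1]; i2 <- v$span[2]
      if (s$strand == "+") {
        hs <- s$nuc_start + 3L * (i1 - 1L)
        he <- s$nuc_start + 3L * i2
      } else {
        hs <- s$nuc_end - 3L * i2
        he <- s$nuc_end - 3L * (i1 - 1L)
      }
      tibble(target = s$target, contig_id = s$contig_id, species = s$species,
             region = hmm$region, subfamily = hmm$subfamily,
             bit_score = bits[i], evalue = ev[i],
             nuc_start = hs, nuc_end = he, strand = s$strand, frame = s$frame,
             span_start = i1, span_end = i2, aa_seq = s$aa_seq)
    })
    out[[pi]] <- rows
  }
  hits <- dplyr::bind_rows(out)
  if (nrow(hits) == 0L) return(empty_hits())
  dplyr::arrange(hits, .data$contig_id, .data$nuc_start, .data$subfamily)
}

empty_hits <- function() {
  tibble(target = character(), contig_id = character(), species = character(),
         region = character(), subfamily = character(),
         bit_score = numeric(), evalue = numeric(),
         nuc_start = integer(), nuc_end = integer(), strand = character(),
         frame = integer(), span_start = integer(), span_end = integer(),
         aa_seq = character())
}

#' Build a classification matrix (profiles x targets) from hits
#'
#' The tidy form of the classic published layout: one row per
#' (profile, target) cell holding the E-value and bit score. At most one cell
#' per pair is kept (the best E-value).
#'
#' @param hits Hit tibble from [scan_genome()], or any data frame with columns
#'   `target`, `subfamily`, `evalue`, `bit_score` (optionally `region`).
#' @return A tibble with class `classification_matrix`.
#' @export
classification_matrix <- function(hits) {
  stopifnot(all(c("target", "subfamily", "evalue", "bit_score") %in% names(hits)))
  grp <- intersect(c("target", "region", "subfamily"), names(hits))
  cm <- hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (any(!is.finite(cm$evalue)) || any(cm$evalue < 0)) {
    abort("classification matrix requires finite, non-negative e-values")
  }
  class(cm) <- c("classification_matrix", class(cm))
  cm
}

#' Read a transcribed classification table (TSV) as a classification matrix
#'
#' Expects tab-separated columns `target`, `region`, `subfamily`, `evalue`,
#' `bit_score` (character-valued cells are parsed; a decimal comma in a bit
#' score is read as a decimal point). Lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return A `classification_matrix` tibble.
#' @export
read_classification_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  df$evalue <- as.numeric(df$evalue)
  df$bit_score <- as.numeric(sub(",", ".", df$bit_score, fixed = TRUE))
  classification_matrix(as_tibble(df))
}

#' Best-E-value classification of one target column
#'
#' Returns the subfamily with the minimum E-value in the column (the bold cell
#' of the published table layout). Ties on E-value are broken by higher bit
#' score, then lexicographically by subfamily name, and flagged ambiguous.
#'
#' @param cm A `classification_matrix`.
#' @param target Target (column) identifier. If the matrix carries a `region`
#'   column and `region` is given, the column is restricted to that region.
#' @param region Optional region restriction.
#' @return One-row tibble: `target`, `subfamily`, `evalue`, `bit_score`,
#'   `ambiguous`.
#' @export
classify_column <- function(cm, target, region = NULL) {
  col <- cm[cm$target == target, , drop = FALSE]
  if (!is.null(region) && "region" %in% names(col)) {
    col <- col[col$region == region, , drop = FALSE]
  }
  if (nrow(col) == 0L) abort(sprintf("no entries for target %s", target))
  best_e <- min(col$evalue)
  cand <- col[col$evalue == best_e, , drop = FALSE]
  ambiguous <- nrow(cand) > 1L
  cand <- cand[order(-cand$bit_score, cand$subfamily), , drop = FALSE]
  tibble(target = target, subfamily = cand$subfamily[1],
         evalue = cand$evalue[1], bit_score = cand$bit_score[1],
         ambiguous = ambiguous)
}

#' Classify every target column of a classification matrix
#'
#' @param cm A `classification_matrix`.
#' @return Tibble with one row per target (see [classify_column()]).
#' @export
classify_columns <- function(cm) {
  purrr::map_dfr(unique(cm$target), function(tg) classify_column(cm, tg))
}

#' Assign each scanned target to its best-E-value subfamily
#'
#' Applies the best-E-value rule of [classify_column()] to every target
#' segment in a hit table: the segment's subfamily is the profile row with the
#' minimum E-value (ties broken by higher bit score, then name, and flagged);
#' only the winning subfamily's hits are retained. Because all five subfamily
#' profiles are homologous, secondary cross-subfamily hits on a true gene are
#' expected and must not feed ortholog calls.
#'
#' @param hits Hit tibble from [scan_genome()].
#' @return The subset of `hits` whose subfamily won its target's column, with
#'   an added `ambiguous` flag.
#' @export
classify_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    hits$ambiguous <- logical(0)
    return(hits)
  }
  winners <- hits |>
    dplyr::group_by(.data$target) |>
    dplyr::arrange(.data$evalue, -.data$bit_score, .data$subfamily,
                   .by_group = TRUE) |>
    dplyr::summarise(
      win_subfamily = dplyr::first(.data$subfamily),
      ambiguous = sum(.data$evalue == min(.data$evalue)) > 1L &&
        length(unique(.data$subfamily[.data$evalue == min(.data$evalue)])) > 1L,
      .groups = "drop")
  hits |>
    dplyr::inner_join(winners, by = "target") |>
    dplyr::filter(.data$subfamily == .data$win_subfamily) |>
    dplyr::select(-"win_subfamily")
}

#' Reciprocal validation of hits against the full library including decoys
#'
#' Each hit's peptide segment is re-scored against every profile (subfamily
#' profiles and decoys). The hit is reciprocally confirmed when the best
#' scoring profile over the whole library belongs to the same subfamily as the
#' forward-search assignment. With no decoys and a single subfamily the check
#' is vacuous; such hits are flagged `reciprocal_tested = FALSE`.
#'
#' @param hits Hit tibble from [scan_genome()].
#' @param library The `hmm_library` (profiles plus decoys).
#' @return `hits` with added columns `reciprocal_best` (best profile's
#'   subfamily), `reciprocal_ok`, `reciprocal_tested`.
#' @export
reciprocal_validate <- function(hits, library) {
  all_profiles <- c(library$profiles, library$decoys)
  tested <- length(library$decoys) > 0L ||
    length(unique(purrr::map_chr(library$profiles, "subfamily"))) > 1L
  if (nrow(hits) == 0L) {
    hits$reciprocal_best <- character(0)
    hits$reciprocal_ok <- logical(0)
    hits$reciprocal_tested <- logical(0)
    return(hits)
  }
  if (!tested) {
    warn("reciprocal validation untested: no decoys and a single-subfamily library")
  }
  peptides <- unique(hits$aa_seq)
  best <- matrix(-Inf, nrow = length(peptides), ncol = length(all_profiles))
  for (j in seq_along(all_profiles)) {
    best[, j] <- forward_bits_many(all_profiles[[j]], peptides)
  }
  best_sub <- purrr::map_chr(all_profiles, "subfamily")[max.col(best, ties.method = "first")]
  names(best_sub) <- peptides
  hits$reciprocal_best <- unname(best_sub[hits$aa_seq])
  hits$reciprocal_ok <- if (tested) hits$reciprocal_best == hits$subfamily else TRUE
  hits$reciprocal_tested <- tested
  hits
}

#' Aggregate hits into per-(species, subfamily) ortholog calls
#'
#' Hits are grouped by species and subfamily; the number of distinct fragment
#' regions hit is counted across contigs (exons of one gene may sit on
#' different contigs in a draft assembly, so same-contig linkage is not
#' required). A group is `accepted` when it covers at least
#' `exon_evidence_min` distinct regions (two nearly adjacent region matches
#' indicate distinct exons of a real gene) and every grouped hit passed
#' reciprocal validation; single-region groups are `ambiguous`; groups whose
#' hits fail reciprocal validation are `rejected`.
#'
#' @param hits Hit tibble carrying reciprocal flags
#'   (see [reciprocal_validate()]).
#' @param exon_evidence_min Minimum distinct regions for acceptance (default 2).
#' @return Tibble of calls: `species`, `subfamily`, `n_regions_hit`,
#'   `n_contigs`, `best_evalue`, `reciprocal_ok`, `status`.
#' @export
call_orthologs <- function(hits, exon_evidence_min = 2L) {
  if (!"reciprocal_ok" %in% names(hits)) {
    abort("hits must carry reciprocal flags; run reciprocal_validate() first")
  }
  if (nrow(hits) == 0L) {
    return(tibble(species = character(), subfamily = character(),
                  n_regions_hit = integer(), n_contigs = integer(),
                  best_evalue = numeric(), reciprocal_ok = logical(),
                  status = character()))
  }
  hits |>
    dplyr::group_by(.data$species, .data$subfamily) |>
    dplyr::summarise(
      n_regions_hit = dplyr::n_distinct(.data$region),
      n_contigs = dplyr::n_distinct(.data$contig_id),
      best_evalue = min(.data$evalue),
      reciprocal_ok = all(.data$reciprocal_ok),
      .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      !.data$reciprocal_ok ~ "rejected",
      .data$n_regions_hit >= exon_evidence_min ~ "accepted",
      TRUE ~ "ambiguous"))
}

#' Presence/absence matrix with parsimony gain/loss events
#'
#' Builds the species x subfamily occupancy matrix from accepted ortholog
#' calls and places gain/loss events on a supplied species tree by Fitch
#' parsimony (equal gain/loss cost; one binary character per subfamily).
#' Branches whose reconstruction is ambiguous are annotated `"?"`. With
#' `method = "dollo"` a single gain is forced at the root of the subtree
#' spanning the present tips and all other transitions are losses.
#'
#' @param calls Tibble from [call_orthologs()].
#' @param species_tree An [ape::phylo] rooted species tree covering every
#'   species in `calls`.
#' @param method `"fitch"` (default) or `"dollo"`.
#' @return An object of class `presence_absence`: list with `matrix` (tibble
#'   `species`, `subfamily`, `state` in present/absent), `events` (tibble
#'   `subfamily`, `edge`, `node`, `event` in gain/loss/`?`), and `tree`.
#' @export
presence_absence <- function(calls, species_tree, method = c("fitch", "dollo")) {
  method <- match.arg(method)
  stopifnot(inherits(species_tree, "phylo"))
  species <- species_tree$tip.label
  missing_sp <- setdiff(unique(calls$species), species)
  if (length(missing_sp)) {
    abort(paste0("species missing from tree: ", paste(missing_sp, collapse = ", ")))
  }
  subfams <- sort(unique(calls$subfamily))
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  mat <- tidyr::expand_grid(species = species, subfamily = subfams) |>
    dplyr::left_join(
      dplyr::transmute(acc, species = .data$species,
                       subfamily = .data$subfamily, present = TRUE),
      by = c("species", "subfamily")) |>
    dplyr::mutate(state = ifelse(is.na(.data$present), "absent", "present")) |>
    dplyr::select(-"present")
  rec <- purrr::map(subfams, function(sf) {
    present <- mat$species[mat$subfamily == sf & mat$state == "present"]
    reconstruct_events(species_tree, present, method = method)
  })
  events <- purrr::map2_dfr(rec, subfams, function(r, sf) {
    ev <- r$events
    if (nrow(ev)) ev$subfamily <- sf
    ev
  })
  scores <- tibble(subfamily = subfams,
                   parsimony_score = purrr::map_int(rec, function(r) as.integer(r$score)))
  structure(list(matrix = mat, events = events, scores = scores,
                 tree = species_tree, method = method),
            class = "presence_absence")
}

## Fitch (or Dollo) reconstruction of a binary presence character on a rooted
## tree. Returns list(events, score): `events` has one row per edge where the
## state changes, event = "gain" (absent -> present), "loss", or "?" where the
## parsimony reconstruction is ambiguous on that edge; an initial gain at the
## root (the character being present at the root) is recorded with edge = NA.
## `score` is the Fitch parsimony count of within-tree changes.
reconstruct_events <- function(tree, present_tips, method = "fitch") {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  empty <- tibble(edge = integer(), parent = integer(), node = integer(),
                  event = character())
  root_gain <- tibble(edge = NA_integer_, parent = NA_integer_,
                      node = ntip + 1L, event = "gain")
  tip_state <- ifelse(tree$tip.label %in% present_tips, 1L, 0L)
  if (all(tip_state == 0L)) return(list(events = empty, score = 0L))
  if (all(tip_state == 1L)) return(list(events = root_gain, score = 0L))
  ## state sets coded as bitmask: 1 = {absent}, 2 = {present}, 3 = both
  sets <- integer(ntip + nnode)
  sets[seq_len(ntip)] <- tip_state + 1L
  post_edge <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- unique(post_edge[, 1])
  score <- 0L
  for (v in ord) {
    children <- edge[edge[, 1] == v, 2]
    s <- Reduce(function(a, b) {
      inter <- bitwAnd(a, b)
      if (inter != 0L) {
        inter
      } else {
        score <<- score + 1L
        bitwOr(a, b)
      }
    }, sets[children])
    sets[v] <- s
  }
  root <- ntip + 1L
  if (method == "dollo") {
    ## single gain at the MRCA of present tips; losses wherever a lineage
    ## inside that subtree has no present descendant
    present_idx <- which(tip_state == 1L)
    mrca <- if (length(present_idx) == 1L) present_idx else ape::getMRCA(tree, present_idx)
    desc_present <- logical(ntip + nnode)
    desc_present[present_idx] <- TRUE
    for (v in ord) {
      children <- edge[edge[, 1] == v, 2]
      desc_present[v] <- any(desc_present[children])
    }
    in_sub <- logical(ntip + nnode)
    in_sub[mrca] <- TRUE
    for (j in rev(seq_len(nrow(post_edge)))) {  # preorder over edges
      p <- post_edge[j, 1]; v <- post_edge[j, 2]
      if (in_sub[p]) in_sub[v] <- TRUE
    }
    state <- as.integer(in_sub & desc_present)
    state[mrca] <- 1L
    ev <- purrr::map_dfr(seq_len(nrow(edge)), function(j) {
      p <- edge[j, 1]; v <- edge[j, 2]
      if (!in_sub[p] && v != mrca) return(empty)
      pstate <- state[p]
      vstate <- if (v == mrca) 1L else state[v]
      if (v == mrca) {
        return(tibble(edge = j, parent = p, node = v, event = "gain"))
      }
      if (pstate == vstate) return(empty)
      tibble(edge = j, parent = p, node = v,
             event = if (vstate > pstate) "gain" else "loss")
    })
    if (mrca == root) ev <- dplyr::bind_rows(root_gain, ev)
    n_loss <- sum(ev$event == "loss")
    return(list(events = ev, score = n_loss + as.integer(mrca != root)))
  }
  ## Fitch final states: root takes its set (ambiguous if both); a child takes
  ## the parent's final state when that state is in the child's set, else its
  ## own set (ambiguous if the set has both states).
  final <- integer(ntip + nnode)   # 0 absent, 1 present, 2 ambiguous
  decode <- function(s) if (s == 1L) 0L else if (s == 2L) 1L else 2L
  final[root] <- decode(sets[root])
  for (j in rev(seq_len(nrow(post_edge)))) {
    p <- post_edge[j, 1]; v <- post_edge[j, 2]
    fp <- final[p]
    sv <- sets[v]
    final[v] <- if (fp != 2L && bitwAnd(sv, fp + 1L) != 0L) fp else decode(sv)
  }
  ev <- purrr::map_dfr(seq_len(nrow(edge)), function(j) {
    p <- edge[j, 1]; v <- edge[j, 2]
    fp <- final[p]; fv <- final[v]
    if (fp == fv) return(empty)
    if (fp == 2L || fv == 2L) {
      return(tibble(edge = j, parent = p, node = v, event = "?"))
    }
    tibble(edge = j, parent = p, node = v,
           event = if (fv > fp) "gain" else "loss")
  })
  if (final[root] == 1L) {
    ev <- dplyr::bind_rows(root_gain, ev)
  } else if (final[root] == 2L) {
    ev <- dplyr::bind_rows(
      tibble(edge = NA_integer_, parent = NA_integer_, node = root, event = "?"), ev)
  }
  list(events = ev, score = score)
}

#' @export
print.presence_absence <- function(x, ...) {
  n_sp <- length(unique(x$matrix$species))
  n_sf <- length(unique(x$matrix$subfamily))
  cat(sprintf("<presence_absence> %d species x %d subfamilies; %d events (%s parsimony)\n",
              n_sp, n_sf, nrow(x$events), x$method))
  invisible(x)
}

#' @export
tidy.presence_absence <- function(x, ...) x$matrix

#' Plot a presence/absence matrix
#'
#' Filled tiles mark gene presence per species and subfamily (the standard
#' occupancy-summary layout used alongside a species tree).
#'
#' @param object A `presence_absence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_absence <- function(object, ...) {
  m <- object$matrix
  m$species <- factor(m$species, levels = object$tree$tip.label)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$subfamily, y = .data$species,
                                  fill = .data$state)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(present = "steelblue4", absent = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write hits, classification matrices, or presence/absence tables as TSV
#'
#' @param x A tibble (hits, classification matrix, or `presence_absence`
#'   matrix component).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_out <- function(x, path) {
  if (inherits(x, "presence_absence")) x <- x$matrix
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
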