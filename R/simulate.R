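## Synthetic gene families, genomes, and truth tables.
##
## The generator emulates the structure the scanning pipeline assumes: a
## K-subfamily GPCR-like protein family that diverged from a common ancestor,
## with subfamily-diagnostic slow-evolving motif columns, one subfamily
## lacking its C-terminal cytoplasmic tail, per-branch gene duplication and
## loss on a species tree, and genes emitted as exons scattered across small
## contigs on random strands.

DEFAULT_SPECIES_TREE <-
  "(((sp01:0.06,sp02:0.06):0.10,(sp03:0.08,sp04:0.08):0.08):0.14,((sp05:0.10,(sp06:0.05,sp07:0.05):0.05):0.10,((sp08:0.06,sp09:0.06):0.06,(sp10:0.04,(sp11:0.02,sp12:0.02):0.02):0.08):0.08):0.10);"

#' Simulation configuration with defaults
#'
#' Defaults describe a five-subfamily receptor-like family of 350 residues on
#' a 12-species ultrametric tree of height 0.3 substitutions/site, with
#' 15 diagnostic motif columns per subfamily evolving at 5% of the family
#' rate, one tail-less subfamily, and two-exon genes whose exons usually land
#' on separate small contigs.
#'
#' @param species_tree Newick string (with branch lengths) for the species tree.
#' @param subfamilies Subfamily names (K >= 2).
#' @param root_length Root protein length L (residues).
#' @param b_sub Branch length from the family root to each subfamily ancestor.
#' @param alpha Gamma shape for among-site rate variation.
#' @param n_motif_cols Diagnostic motif columns per subfamily (disjoint).
#' @param motif_rate Rate multiplier on a subfamily's own motif columns.
#' @param tail_subfamily Subfamily lacking the C-terminal tail.
#' @param tail_len Number of C-terminal residues that subfamily lacks.
#' @param lambda_dup,lambda_loss Per-lineage duplication/loss rates per unit
#'   branch length.
#' @param exons_per_gene Exons per emitted gene.
#' @param intron_len Intron length range (used when exons share a contig).
#' @param flank_len Background flank length range on each side of an exon.
#' @param split_prob Probability that a gene's exons are emitted on separate
#'   contigs (draft-assembly fragmentation).
#' @param n_decoy_families Unrelated decoy families simulated alongside.
#' @param n_decoy_contigs Gene-free background contigs per species.
#' @param decoy_contig_len Length of those background contigs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species_tree = DEFAULT_SPECIES_TREE,
                       subfamilies = c("TypeI", "TypeIIa-1", "TypeIIa-2",
                                       "TypeIIa-3", "TypeIIb"),
                       root_length = 350L,
                       b_sub = 1.2,
                       alpha = 1.0,
                       n_motif_cols = 15L,
                       motif_rate = 0.05,
                       tail_subfamily = "TypeI",
                       tail_len = 45L,
                       lambda_dup = 0.05,
                       lambda_loss = 0.3,
                       exons_per_gene = 2L,
                       intron_len = c(150L, 400L),
                       flank_len = c(400L, 1200L),
                       split_prob = 0.9,
                       n_decoy_families = 2L,
                       n_decoy_contigs = 2L,
                       decoy_contig_len = 2000L) {
  stopifnot(length(subfamilies) >= 2L, root_length >= 50L, b_sub >= 0,
            alpha > 0, n_motif_cols >= 0L, motif_rate >= 0,
            lambda_dup >= 0, lambda_loss >= 0, exons_per_gene >= 1L,
            split_prob >= 0, split_prob <= 1,
            length(subfamilies) * n_motif_cols <= root_length)
  structure(list(
    species_tree = species_tree, subfamilies = subfamilies,
    root_length = as.integer(root_length), b_sub = b_sub, alpha = alpha,
    n_motif_cols = as.integer(n_motif_cols), motif_rate = motif_rate,
    tail_subfamily = tail_subfamily, tail_len = as.integer(tail_len),
    lambda_dup = lambda_dup, lambda_loss = lambda_loss,
    exons_per_gene = as.integer(exons_per_gene),
    intron_len = as.integer(intron_len), flank_len = as.integer(flank_len),
    split_prob = split_prob,
    n_decoy_families = as.integer(n_decoy_families),
    n_decoy_contigs = as.integer(n_decoy_contigs),
    decoy_contig_len = as.integer(decoy_contig_len)
  ), class = "sim_config")
}

## Evolve an integer-coded sequence over branch length t with per-column rate
## multipliers, under `model`.
evolve_seq <- function(codes, t, col_rates, model) {
  if (t <= 0) return(codes)
  out <- codes
  for (r in unique(col_rates)) {
    idx <- which(col_rates == r)
    if (r <= 0) next
    P <- transition_matrix(model, t, r)
    cum <- t(apply(P, 1, cumsum))
    u <- runif(length(idx))
    out[idx] <- rowSums(cum[codes[idx], , drop = FALSE] < u) + 1L
  }
  out
}

#' Simulate a labeled multi-subfamily protein family on a species tree
#'
#' A root protein is drawn from the model's equilibrium; each subfamily
#' ancestor evolves from it over branch `b_sub` and receives its diagnostic
#' motif residues; each subfamily then evolves along the species tree under
#' JTT + gamma (per-column category rates, motif columns slowed by
#' `motif_rate`), with per-branch duplication and loss events drawn from
#' Poisson processes. The tail-less subfamily's sequences are truncated by
#' `tail_len` residues. Because evolution is substitution-only, sequences are
#' mutually aligned column-for-column; the tail-less subfamily is padded with
#' gaps.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (all outputs are a pure function of config + seed).
#' @return List of class `sim_family`: `proteins` (tibble `gene_id`, `species`,
#'   `subfamily`, `seq`, `aligned`), `alignment` (tibble `id`, `seq`, `label`
#'   ready for [build_library()]), `events` (tibble `subfamily`, `lineage`,
#'   `parent_node`, `child_node`, `type` in dup/loss), `decoy_alignments`
#'   (named list), `motif_cols`, `tree`, `config`, `seed`.
#' @export
simulate_family <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    tree <- ape::read.tree(text = config$species_tree)
    model <- subst_model(alpha = config$alpha, k = 4L, p_inv = 0)
    L <- config$root_length
    K <- length(config$subfamilies)
    rates <- sample(gamma_rates(config$alpha, 4L), L, replace = TRUE)
    root <- sample.int(20L, L, replace = TRUE, prob = model$pi)
    motif_pool <- sample.int(L, K * config$n_motif_cols)
    motif_cols <- split(motif_pool, rep(seq_len(K), each = config$n_motif_cols))
    names(motif_cols) <- config$subfamilies

    proteins <- list()
    events <- list()
    for (si in seq_len(K)) {
      sf <- config$subfamilies[si]
      anc <- evolve_seq(root, config$b_sub, rates, model)
      mc <- motif_cols[[sf]]
      if (length(mc)) {
        anc[mc] <- sample.int(20L, length(mc), replace = TRUE, prob = model$pi)
      }
      col_rates <- rates
      col_rates[mc] <- col_rates[mc] * config$motif_rate
      ## walk the species tree carrying a list of gene lineages
      ntip <- length(tree$tip.label)
      lineage_counter <- 0L
      new_lineage <- function() {
        lineage_counter <<- lineage_counter + 1L
        lineage_counter
      }
      walk <- function(node, lineages) {
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        if (!length(kids)) {  # tip
          sp <- tree$tip.label[node]
          for (gi in seq_along(lineages)) {
            lin <- lineages[[gi]]
            gene_id <- sprintf("%s_%s_g%d", sp, sf, gi)
            proteins[[length(proteins) + 1L]] <<- tibble(
              gene_id = gene_id, species = sp, subfamily = sf,
              codes = list(lin$codes))
          }
          return(invisible(NULL))
        }
        for (child in kids) {
          t_edge <- tree$edge.length[which(tree$edge[, 1] == node &
                                             tree$edge[, 2] == child)]
          surv <- list()
          for (lin in lineages) {
            if (runif(1) < 1 - exp(-config$lambda_loss * t_edge)) {
              events[[length(events) + 1L]] <<- tibble(
                subfamily = sf, lineage = lin$id, parent_node = node,
                child_node = child, type = "loss")
              next
            }
            evolved <- evolve_seq(lin$codes, t_edge, col_rates, model)
            surv <- c(surv, list(list(id = lin$id, codes = evolved)))
            n_dup <- rpois(1, config$lambda_dup * t_edge)
            for (d in seq_len(n_dup)) {
              ## duplicate splits mid-branch: copy evolves over half the branch
              dup_codes <- evolve_seq(lin$codes, t_edge / 2, col_rates, model)
              did <- new_lineage()
              events[[length(events) + 1L]] <<- tibble(
                subfamily = sf, lineage = did, parent_node = node,
                child_node = child, type = "dup")
              surv <- c(surv, list(list(id = did, codes = dup_codes)))
            }
          }
          walk(child, surv)
        }
      }
      root_node <- ntip + 1L
      walk(root_node, list(list(id = new_lineage(), codes = anc)))
    }
    proteins <- dplyr::bind_rows(proteins)
    if (nrow(proteins) == 0L) abort("empty family: all genes lost in all species")

    tail_mask <- proteins$subfamily == config$tail_subfamily
    to_seq <- function(codes, tailless) {
      aa <- AMINO_ACIDS[codes]
      if (tailless && config$tail_len > 0L) {
        aa <- aa[seq_len(length(aa) - config$tail_len)]
      }
      paste(aa, collapse = "")
    }
    proteins$seq <- purrr::map2_chr(proteins$codes, tail_mask, to_seq)
    proteins$aligned <- ifelse(
      tail_mask,
      paste0(proteins$seq, strrep("-", config$tail_len)),
      proteins$seq)
    proteins$codes <- NULL

    decoys <- list()
    for (dn in seq_len(config$n_decoy_families)) {
      droot <- sample.int(20L, L, replace = TRUE, prob = model$pi)
      danc <- evolve_seq(droot, config$b_sub, rates, model)
      dseqs <- purrr::map_chr(seq_len(8L), function(i) {
        paste(AMINO_ACIDS[evolve_seq(danc, 0.3, rates, model)], collapse = "")
      })
      decoys[[paste0("decoy", dn)]] <- tibble(
        id = sprintf("decoy%d_s%d", dn, seq_along(dseqs)), seq = dseqs)
    }

    structure(list(
      proteins = proteins,
      alignment = tibble(id = proteins$gene_id, seq = proteins$aligned,
                         label = proteins$subfamily),
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble(subfamily = character(), lineage = integer(),
               parent_node = integer(), child_node = integer(),
               type = character()),
      decoy_alignments = decoys,
      motif_cols = motif_cols, tree = tree, config = config, seed = seed
    ), class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family> %d genes, %d subfamilies, %d species; %d dup / %d loss events\n",
              nrow(x$proteins), length(unique(x$proteins$subfamily)),
              length(x$tree$tip.label),
              sum(x$events$type == "dup"), sum(x$events$type == "loss")))
  invisible(x)
}

## Codon table grouped by amino acid (stops excluded), for reverse translation.
codons_by_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

random_nuc <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Emit genomes (contigs) and a truth table from simulated tip proteins
#'
#' Each tip protein is reverse-translated (uniform synonymous codon choice),
#' split into exons at codon boundaries, and embedded at a random position and
#' strand in background-composition contigs. With probability `split_prob` a
#' gene's exons are placed on separate contigs (emulating a fragmented draft
#' assembly); otherwise the exons share one contig, separated by GT..AG
#' introns. Gene-free background contigs are added per species. Translating
#' the truth intervals and concatenating the per-exon translations reproduces
#' each source protein exactly.
#'
#' @param family A `sim_family` from [simulate_family()].
#' @param seed Integer seed.
#' @return List of class `sim_genome`: `contigs` (tibble `id`, `seq`,
#'   `species`), `truth` (tibble `gene_id`, `species`, `subfamily`,
#'   `contig_id`, `start`, `end`, `strand`, `exon_index`, `aa_start`,
#'   `aa_end`, `protein`), `seed`.
#' @export
emit_genome <- function(family, seed = 1L) {
  stopifnot(inherits(family, "sim_family"))
  config <- family$config
  cba <- codons_by_aa()
  with_seed(seed, {
    contigs <- list()
    truth <- list()
    ctr <- 0L
    new_contig_id <- function(sp) {
      ctr <<- ctr + 1L
      sprintf("%s_ctg%03d", sp, ctr)
    }
    for (gi in seq_len(nrow(family$proteins))) {
      g <- family$proteins[gi, ]
      aa <- split_chars(g$seq)
      n_aa <- length(aa)
      cds <- vapply(aa, function(a) sample(cba[[a]], 1L), character(1))
      n_ex <- min(config$exons_per_gene, max(1L, n_aa %/% 40L))
      ## codon-boundary cut points, roughly equal exons with jitter
      if (n_ex > 1L) {
        base <- round(n_aa * seq_len(n_ex - 1L) / n_ex)
        cuts <- pmin(pmax(base + sample(-10:10, n_ex - 1L, replace = TRUE), 20L),
                     n_aa - 20L)
        cuts <- sort(unique(cuts))
        n_ex <- length(cuts) + 1L
      } else {
        cuts <- integer(0)
      }
      bounds <- c(0L, cuts, n_aa)   # codon offsets of exon boundaries
      exon_nuc <- vapply(seq_len(n_ex), function(e) {
        paste(cds[(bounds[e] + 1L):bounds[e + 1L]], collapse = "")
      }, character(1))
      split_gene <- n_ex > 1L && runif(1) < config$split_prob
      place_exon <- function(nuc, sp) {
        fl <- sample(config$flank_len[1]:config$flank_len[2], 2L, replace = TRUE)
        strand <- sample(c("+", "-"), 1L)
        insert <- if (strand == "+") nuc else reverse_complement(nuc)
        seq <- paste0(random_nuc(fl[1]), insert, random_nuc(fl[2]))
        id <- new_contig_id(sp)
        contigs[[length(contigs) + 1L]] <<- tibble(id = id, seq = seq, species = sp)
        list(contig_id = id, start = fl[1], end = fl[1] + nchar(nuc),
             strand = strand)
      }
      if (split_gene) {
        for (e in seq_len(n_ex)) {
          loc <- place_exon(exon_nuc[e], g$species)
          truth[[length(truth) + 1L]] <- tibble(
            gene_id = g$gene_id, species = g$species, subfamily = g$subfamily,
            contig_id = loc$contig_id, start = loc$start, end = loc$end,
            strand = loc$strand, exon_index = e,
            aa_start = bounds[e], aa_end = bounds[e + 1L], protein = g$seq)
        }
      } else {
        introns <- vapply(seq_len(max(n_ex - 1L, 0L)), function(e) {
          paste0("GT", random_nuc(sample(config$intron_len[1]:config$intron_len[2], 1L) - 4L), "AG")
        }, character(1))
        fl <- sample(config$flank_len[1]:config$flank_len[2], 2L, replace = TRUE)
        strand <- sample(c("+", "-"), 1L)
        gene_nuc <- exon_nuc[1]
        exon_off <- c(0L)
        for (e in seq_len(n_ex - 1L)) {
          gene_nuc <- paste0(gene_nuc, introns[e], exon_nuc[e + 1L])
          exon_off <- c(exon_off, nchar(gene_nuc) - nchar(exon_nuc[e + 1L]))
        }
        glen <- nchar(gene_nuc)
        insert <- if (strand == "+") gene_nuc else reverse_complement(gene_nuc)
        seq <- paste0(random_nuc(fl[1]), insert, random_nuc(fl[2]))
        id <- new_contig_id(g$species)
        contigs[[length(contigs) + 1L]] <- tibble(id = id, seq = seq,
                                                  species = g$species)
        for (e in seq_len(n_ex)) {
          ## exon coordinates inside the (possibly reverse-complemented) insert
          off <- exon_off[e]
          elen <- nchar(exon_nuc[e])
          if (strand == "+") {
            s0 <- fl[1] + off
          } else {
            s0 <- fl[1] + (glen - off - elen)
          }
          truth[[length(truth) + 1L]] <- tibble(
            gene_id = g$gene_id, species = g$species, subfamily = g$subfamily,
            contig_id = id, start = s0, end = s0 + elen, strand = strand,
            exon_index = e, aa_start = bounds[e], aa_end = bounds[e + 1L],
            protein = g$seq)
        }
      }
    }
    ## gene-free background contigs
    for (sp in family$tree$tip.label) {
      for (d in seq_len(config$n_decoy_contigs)) {
        contigs[[length(contigs) + 1L]] <- tibble(
          id = new_contig_id(sp), seq = random_nuc(config$decoy_contig_len),
          species = sp)
      }
    }
    structure(list(contigs = dplyr::bind_rows(contigs),
                   truth = dplyr::bind_rows(truth), seed = seed),
              class = "sim_genome")
  })
}

#' Simulate a protein alignment on a tree under the substitution model
#'
#' Root sequence drawn from the model's equilibrium; per-site rates drawn from
#' the model's discrete-gamma categories (a site drawn invariant with
#' probability `p_inv` has rate 0); sites then evolve independently along the
#' tree by per-branch transition sampling.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param model A [subst_model()].
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return Alignment tibble (`id`, `seq`) with one row per tip.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1L)
  with_seed(seed, {
    rates <- sample(gamma_rates(model$alpha, model$k), n_sites, replace = TRUE)
    if (model$p_inv > 0) {
      rates <- rates / (1 - model$p_inv)
      rates[runif(n_sites) < model$p_inv] <- 0
    }
    root_seq <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
    ntip <- length(tree$tip.label)
    seqs <- vector("list", ntip)
    walk <- function(node, codes) {
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      if (!length(kids)) {
        seqs[[node]] <<- codes
        return(invisible(NULL))
      }
      for (child in kids) {
        t_edge <- tree$edge.length[tree$edge[, 1] == node & tree$edge[, 2] == child]
        walk(child, evolve_seq(codes, t_edge, rates, model))
      }
    }
    walk(ntip + 1L, root_seq)
    tibble(id = tree$tip.label,
           seq = vapply(seqs, function(s) paste(AMINO_ACIDS[s], collapse = ""),
                        character(1)))
  })
}

#' Truth presence/absence occupancy from a simulated family
#'
#' @param family A `sim_family`.
#' @return Tibble `species` x `subfamily` with `state` present/absent.
#' @export
truth_presence <- function(family) {
  tidyr::expand_grid(species = family$tree$tip.label,
                     subfamily = family$config$subfamilies) |>
    dplyr::left_join(
      dplyr::distinct(family$proteins, .data$species, .data$subfamily) |>
        dplyr::mutate(present = TRUE),
      by = c("species", "subfamily")) |>
    dplyr::mutate(state = ifelse(is.na(.data$present), "absent", "present")) |>
    dplyr::select(-"present")
}

#' Score pipeline recovery against the simulation truth
#'
#' A call is correct iff its subfamily matches a planted gene of that species
#' and at least one supporting hit interval overlaps a truth exon of that
#' gene. Fragment-level accuracy asks, for every planted exon, whether the
#' best-E-value hit overlapping it carries the true subfamily (missed exons
#' count as errors).
#'
#' @param calls Tibble from [call_orthologs()].
#' @param hits Hit tibble (with reciprocal flags) supporting the calls.
#' @param genome A `sim_genome` (for the truth table).
#' @param family The `sim_family` (for true occupancy).
#' @param pa Optional `presence_absence` object to score cell accuracy.
#' @return List: `fragment_accuracy`, `call_precision`, `call_recall`,
#'   `per_subfamily` (tibble), `pa_accuracy` (NA if `pa` missing).
#' @export
score_recovery <- function(calls, hits, genome, family, pa = NULL) {
  truth <- genome$truth
  ## fragment-level: best overlapping hit per planted exon
  frag_ok <- vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    ov <- hits[hits$contig_id == tr$contig_id &
                 hits$nuc_start < tr$end & hits$nuc_end > tr$start, , drop = FALSE]
    if (nrow(ov) == 0L) return(NA)
    ov$subfamily[which.min(ov$evalue)] == tr$subfamily
  }, logical(1))
  fragment_accuracy <- sum(frag_ok, na.rm = TRUE) / length(frag_ok)

  occ <- dplyr::distinct(truth, .data$species, .data$subfamily)
  acc <- calls[calls$status == "accepted", , drop = FALSE]
  correct <- vapply(seq_len(nrow(acc)), function(i) {
    cl <- acc[i, ]
    tr <- truth[truth$species == cl$species & truth$subfamily == cl$subfamily, ,
                drop = FALSE]
    if (nrow(tr) == 0L) return(FALSE)
    hs <- hits[hits$species == cl$species & hits$subfamily == cl$subfamily, ,
               drop = FALSE]
    any(vapply(seq_len(nrow(tr)), function(j) {
      any(hs$contig_id == tr$contig_id[j] & hs$nuc_start < tr$end[j] &
            hs$nuc_end > tr$start[j])
    }, logical(1)))
  }, logical(1))
  call_precision <- if (nrow(acc)) mean(correct) else NA_real_
  recovered <- dplyr::semi_join(occ, acc[correct, , drop = FALSE],
                                by = c("species", "subfamily"))
  call_recall <- if (nrow(occ)) nrow(recovered) / nrow(occ) else NA_real_

  per_subfamily <- occ |>
    dplyr::count(.data$subfamily, name = "n_true") |>
    dplyr::left_join(
      acc[correct, , drop = FALSE] |>
        dplyr::distinct(.data$species, .data$subfamily) |>
        dplyr::count(.data$subfamily, name = "n_recovered"),
      by = "subfamily") |>
    dplyr::mutate(n_recovered = dplyr::coalesce(.data$n_recovered, 0L),
                  recall = .data$n_recovered / .data$n_true)

  pa_accuracy <- NA_real_
  if (!is.null(pa)) {
    tp <- truth_presence(family)
    cmp <- dplyr::inner_join(pa$matrix, tp, by = c("species", "subfamily"),
                             suffix = c("_called", "_true"))
    pa_accuracy <- mean(cmp$state_called == cmp$state_true)
  }
  list(fragment_accuracy = fragment_accuracy,
       call_precision = call_precision, call_recall = call_recall,
       per_subfamily = per_subfamily, pa_accuracy = pa_accuracy)
}
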