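test_that("every transcribed table column classifies to its bold cell", {
  cm <- read_classification_tsv(table1_path())
  expected <- tibble::tribble(
    ~target,            ~region,       ~subfamily,   ~evalue,
    "AESE012567234.1",  "TM1 to TM4",  "Type IIa-1", 7.1e-50,
    "AESE011658775.1",  "TM1 to TM4",  "Type IIa-2", 8.5e-68,
    "AESE011105720.1",  "TM1 to TM4",  "Type I",     3.4e-48,
    "AESE010056425.1",  "TM6 to TM7",  "Type IIa-1", 5.5e-33,
    "AESE011520245.1",  "TM6 to TM7",  "Type IIa-2", 1.3e-40,
    "AESE012567234.1",  "TM6 to TM7",  "Type I",     1.8e-38,
    "22569.4_6",        "Tm1 to Tm4",  "Type IIa-1", 3.4e-75,
    "42790.2_1",        "Tm1 to Tm4",  "Type IIa-1", 2.5e-59,
    "31731.1_3",        "Tm1 to Tm4",  "Type IIa-1", 1.7e-41,
    "30359.1_1",        "Tm6 to Tm7",  "Type IIa-1", 6.7e-48,
    "36401.1_5",        "Tm6 to Tm7",  "Type IIa-1", 3.6e-45)
  for (i in seq_len(nrow(expected))) {
    got <- classify_column(cm, expected$target[i], region = expected$region[i])
    expect_identical(got$subfamily, expected$subfamily[i])
    expect_equal(got$evalue, expected$evalue[i])
    ## the winner is the argmin of the printed column
    col <- cm[cm$target == expected$target[i] & cm$region == expected$region[i], ]
    expect_equal(got$evalue, min(col$evalue))
  }
})

test_that("classification ties break by bit score then name, with a flag", {
  cm <- classification_matrix(tibble::tibble(
    target = "t", subfamily = c("a", "b", "c"),
    evalue = c(1e-10, 1e-10, 1e-5), bit_score = c(50, 60, 80)))
  got <- classify_column(cm, "t")
  expect_identical(got$subfamily, "b")    # higher bit score wins the tie
  expect_true(got$ambiguous)
  single <- classification_matrix(tibble::tibble(
    target = "t", subfamily = "a", evalue = 1e-3, bit_score = 10))
  expect_identical(classify_column(single, "t")$subfamily, "a")
  expect_error(classify_column(cm, "missing"), "no entries")
})

test_that("scanning an empty or segment-free genome yields no hits", {
  fam <- simulate_family(sim_config(), seed = 3)
  regions <- default_regions(fam$config)
  lib <- cached("tiny_lib", {
    build_library(fam$alignment, regions,
                  decoy_alns = fam$decoy_alignments, n_cal = 100, seed = 2)
  })
  short <- tibble::tibble(id = "s", seq = "ATGATG", species = "sp01")
  expect_equal(nrow(scan_genome(short, lib)), 0L)
})

test_that("a planted exon is recovered with an overlapping hit interval", {
  res <- cached_pipeline()
  truth <- res$genome$truth
  hits <- res$hits
  overlaps <- vapply(seq_len(nrow(truth)), function(i) {
    any(hits$contig_id == truth$contig_id[i] &
          hits$nuc_start < truth$end[i] & hits$nuc_end > truth$start[i] &
          hits$subfamily == truth$subfamily[i])
  }, logical(1))
  expect_gte(mean(overlaps), 0.95)
})

test_that("hits are invariant to contig order and strand of embedding", {
  fam <- simulate_family(sim_config(), seed = 3)
  regions <- default_regions(fam$config)
  lib <- cached("tiny_lib", {
    build_library(fam$alignment, regions,
                  decoy_alns = fam$decoy_alignments, n_cal = 100, seed = 2)
  })
  gen <- emit_genome(fam, seed = 4)
  contigs <- gen$contigs[gen$contigs$species == "sp01", ][1:4, ]
  h1 <- scan_genome(contigs, lib)
  h2 <- scan_genome(contigs[rev(seq_len(nrow(contigs))), ], lib)
  key <- function(h) {
    h <- dplyr::arrange(h, .data$contig_id, .data$nuc_start, .data$subfamily,
                        .data$region)
    h[, c("contig_id", "region", "subfamily", "bit_score", "nuc_start",
          "nuc_end", "strand")]
  }
  expect_equal(key(h1), key(h2))
  ## reverse-complement every contig: same intervals with flipped strand
  rc <- contigs
  rc$seq <- vapply(rc$seq, reverse_complement, character(1))
  h3 <- scan_genome(rc, lib)
  L <- stats::setNames(nchar(contigs$seq), contigs$id)
  h3$new_start <- L[h3$contig_id] - h3$nuc_end
  h3$new_end <- L[h3$contig_id] - h3$nuc_start
  a <- dplyr::arrange(h1[, c("contig_id", "region", "subfamily", "bit_score")],
                      .data$contig_id, .data$region, .data$subfamily)
  b <- dplyr::arrange(h3[, c("contig_id", "region", "subfamily", "bit_score")],
                      .data$contig_id, .data$region, .data$subfamily)
  expect_equal(a, b)
  expect_setequal(
    paste(h1$contig_id, h1$nuc_start, h1$nuc_end, h1$subfamily),
    paste(h3$contig_id, h3$new_start, h3$new_end, h3$subfamily))
})

test_that("reciprocal validation distinguishes family members from decoys", {
  res <- cached_pipeline()
  lib <- res$library
  fam <- res$family
  ## segments simulated from a subfamily validate to it
  hits <- res$hits
  expect_gte(mean(hits$reciprocal_ok), 0.95)
  ## a decoy-family peptide is claimed by a decoy profile
  decoy_pep <- substr(fam$decoy_alignments[[1]]$seq[1], 30, 120)
  fake <- hits[1, ]
  fake$aa_seq <- decoy_pep
  checked <- reciprocal_validate(fake, lib)
  expect_match(checked$reciprocal_best, "^decoy:")
  expect_false(checked$reciprocal_ok)
})

test_that("ortholog calls require two regions of evidence and reciprocal support", {
  base <- tibble::tibble(
    target = c("t1", "t2"), contig_id = c("c1", "c2"), species = "sp",
    region = c("TM1-4", "TM6-7"), subfamily = "fam1",
    bit_score = c(50, 60), evalue = c(1e-20, 1e-25),
    nuc_start = c(0L, 0L), nuc_end = c(90L, 90L), strand = "+",
    frame = 1L, span_start = 1L, span_end = 30L, aa_seq = "X",
    reciprocal_best = "fam1", reciprocal_ok = TRUE, reciprocal_tested = TRUE)
  calls <- call_orthologs(base, exon_evidence_min = 2)
  expect_identical(calls$status, "accepted")
  expect_equal(calls$n_regions_hit, 2L)
  expect_equal(calls$n_contigs, 2L)       # exons on different contigs accepted
  lone <- call_orthologs(base[1, ], exon_evidence_min = 2)
  expect_identical(lone$status, "ambiguous")
  bad <- base; bad$reciprocal_ok <- FALSE
  expect_identical(call_orthologs(bad, 2)$status, "rejected")
  expect_error(call_orthologs(dplyr::select(base, -"reciprocal_ok")),
               "reciprocal")
})

test_that("Fitch reconstruction matches simple expectations and the brute-force oracle", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  calls <- tibble::tibble(species = c("a", "b", "c", "d"), subfamily = "f",
                          status = "accepted")
  pa <- presence_absence(calls, tree)
  expect_true(all(pa$matrix$state == "present"))
  expect_equal(nrow(pa$events), 1L)            # a single gain at the root
  expect_identical(pa$events$event, "gain")
  expect_true(is.na(pa$events$edge))

  pa2 <- presence_absence(calls[1:3, ], tree)  # absent only in d
  losses <- pa2$events[pa2$events$event == "loss", ]
  expect_equal(nrow(losses), 1L)
  expect_equal(losses$node, which(tree$tip.label == "d"))

  expect_error(presence_absence(
    tibble::tibble(species = "zz", subfamily = "f", status = "accepted"), tree),
    "missing from tree")

  ## random patterns on random small trees: parsimony score equals brute force
  set.seed(17)
  for (trial in 1:25) {
    ntips <- sample(4:8, 1)
    tr <- ape::rtree(ntips)
    present <- sample(tr$tip.label, sample(1:(ntips - 1), 1))
    rec <- famscan:::reconstruct_events(tr, present)
    expect_equal(rec$score, oracle_fitch_score(tr, present),
                 info = sprintf("trial %d", trial))
  }
})

test_that("presence/absence is a deterministic function of accepted calls", {
  res <- cached_pipeline()
  pa1 <- presence_absence(res$calls, res$family$tree)
  pa2 <- presence_absence(res$calls, res$family$tree)
  expect_identical(pa1$matrix, pa2$matrix)
  expect_identical(pa1$events, pa2$events)
  ## only accepted calls count
  demoted <- res$calls
  demoted$status <- "ambiguous"
  pa3 <- presence_absence(demoted, res$family$tree)
  expect_true(all(pa3$matrix$state == "absent"))
})

test_that("Dollo reconstruction forces a single gain", {
  tree <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  calls <- tibble::tibble(species = c("a", "c"), subfamily = "f",
                          status = "accepted")
  pa <- presence_absence(calls, tree, method = "dollo")
  ev <- pa$events
  expect_equal(sum(ev$event == "gain"), 1L)
  expect_true(all(ev$event %in% c("gain", "loss")))
})
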