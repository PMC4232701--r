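test_that("match columns follow the occupancy rule", {
  aln <- tibble::tibble(id = paste0("r", 1:4),
                        seq = c("AC-A", "AC-A", "A--A", "-CA-"))
  mask <- assign_match_columns(aln, symfrac = 0.5)
  expect_identical(mask, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(assign_match_columns(tibble::tibble(id = "x", seq = "-"), 0.5),
               "no consensus")
  set.seed(3)
  for (trial in 1:20) {
    aln <- random_ungapped_alignment(sample(2:8, 1), sample(5:30, 1),
                                     seed = trial, gap_frac = 0.4)
    mask <- tryCatch(assign_match_columns(aln, 0.5), error = function(e) NULL)
    m <- matrix(unlist(strsplit(aln$seq, "")), nrow = nrow(aln), byrow = TRUE)
    brute <- colSums(m != "-") / nrow(m) >= 0.5
    if (is.null(mask)) expect_false(any(brute)) else expect_identical(mask, brute)
  }
})

test_that("profile emissions interpolate between counts and background", {
  aln <- tibble::tibble(id = c("a", "b"), seq = c("ACD", "ACD"))
  h0 <- build_profile(aln, tau = 0)
  expect_equal(unname(h0$match_emit[1, "A"]), 1)
  expect_equal(unname(h0$match_emit[2, "C"]), 1)
  expect_equal(unname(h0$match_emit[3, "D"]), 1)
  hinf <- build_profile(aln, tau = 1e12)
  expect_equal(hinf$match_emit[2, ], famscan:::BACKGROUND_FREQS,
               tolerance = 1e-9)
  ## hand-tallied weighted counts for a 5-row fixture (uniform weights)
  aln5 <- tibble::tibble(id = paste0("r", 1:5),
                         seq = c("AC", "AC", "AD", "GC", "AC"))
  h5 <- build_profile(aln5, tau = 0, weighting = "uniform")
  expect_equal(unname(h5$match_emit[1, c("A", "G")]), c(4, 1) / 5)
  expect_equal(unname(h5$match_emit[2, c("C", "D")]), c(4, 1) / 5)
})

test_that("emission and transition distributions are normalized after build", {
  for (trial in 1:15) {
    aln <- random_ungapped_alignment(sample(2:10, 1), sample(8:40, 1),
                                     seed = 100 + trial, gap_frac = 0.25)
    h <- tryCatch(build_profile(aln), error = function(e) NULL)
    if (is.null(h)) next
    expect_true(all(abs(rowSums(h$match_emit) - 1) < 1e-12))
    expect_equal(sum(h$insert_emit), 1, tolerance = 1e-12)
    if (h$M > 1) {
      tr <- h$transitions
      expect_true(all(abs(tr$MM + tr$MI + tr$MD - 1) < 1e-12))
      expect_true(all(abs(tr$IM + tr$II - 1) < 1e-12))
      expect_true(all(abs(tr$DM + tr$DD - 1) < 1e-12))
      expect_true(all(unlist(tr) >= 0))
    }
  }
})

test_that("forward and Viterbi match exhaustive path enumeration (M <= 3, L <= 6)", {
  set.seed(7)
  for (trial in 1:40) {
    M <- sample(1:3, 1)
    h <- random_small_hmm(M, seed = trial)
    L <- sample(1:6, 1)
    s <- random_aa_seq(L)
    f_dp <- famscan:::.phmm_forward(famscan:::hmm_log_params(h),
                                    famscan:::aa_encode(s))
    expect_equal(f_dp, oracle_forward_ln(h, s), tolerance = 1e-9)
    v <- viterbi_hmm(h, s)
    expect_equal(v$bits * log(2), oracle_viterbi_ln(h, s), tolerance = 1e-9)
  }
})

test_that("Viterbi score never exceeds the forward score", {
  set.seed(21)
  for (trial in 1:250) {
    h <- random_small_hmm(sample(1:4, 1), seed = 1000 + trial)
    s <- random_aa_seq(sample(1:12, 1))
    expect_lte(viterbi_hmm(h, s)$bits, forward_bits(h, s) + 1e-9)
  }
})

test_that("a background-emitting single-state profile scores a length-free constant", {
  aln1 <- tibble::tibble(id = c("a", "b"), seq = c("A", "A"))
  h1 <- build_profile(aln1, tau = 1e12)   # emissions ~ background
  bits <- vapply(c(5, 20, 60, 200), function(L) {
    forward_bits(h1, random_aa_seq(L))
  }, numeric(1))
  ## entry/exit constant: log2(L * (1-p) / p) with p = L/(L+2) gives 1 bit
  expect_equal(bits, rep(1, 4), tolerance = 1e-9)
})

test_that("background flanks shift the score only through the length model", {
  ## fragment-like conditions: the matched span is a minority of the target,
  ## as for a short profile hit inside a translated segment
  set.seed(31)
  aln <- tibble::tibble(id = c("a", "b"),
                        seq = replicate(2, random_aa_seq(20)))
  aln$seq[2] <- aln$seq[1]
  h <- build_profile(aln, tau = 2)
  core <- paste0(random_aa_seq(20), aln$seq[1], random_aa_seq(20))
  base <- forward_bits(h, core)
  for (i in 1:10) {
    flanked <- paste0(core, random_aa_seq(10))
    expect_lte(abs(forward_bits(h, flanked) - base), 0.5)
    flanked2 <- paste0(random_aa_seq(10), core)
    expect_lte(abs(forward_bits(h, flanked2) - base), 0.5)
  }
})

test_that("a deterministic single-path instance has equal forward and Viterbi scores", {
  ## with M = 1 and a length-1 target exactly one legal path exists
  h <- random_small_hmm(1, seed = 1)
  h$match_emit[1, ] <- c(1, rep(0, 19))   # one-hot on 'A'
  f <- forward_bits(h, "A")
  v <- viterbi_hmm(h, "A")
  expect_equal(v$bits, f, tolerance = 1e-12)
  expect_equal(v$span, c(1L, 1L))
})

test_that("Viterbi path and span track the consensus alignment", {
  h <- random_small_hmm(3, seed = 1)
  h$match_emit[] <- 1e-8 / 19
  h$match_emit[1, 1] <- 1 - 1e-8    # A
  h$match_emit[2, 2] <- 1 - 1e-8    # C
  h$match_emit[3, 3] <- 1 - 1e-8    # D
  v <- viterbi_hmm(h, "GGACDGG")
  expect_identical(v$path$state, c("M", "M", "M"))
  expect_equal(v$path$position, 1:3)
  expect_equal(v$span, c(3L, 5L))
})

test_that("Gumbel calibration recovers parameters and is seed-reproducible", {
  ## method-of-moments on true Gumbel draws
  set.seed(5)
  mu <- 5; lambda <- 0.7
  x <- mu - log(-log(runif(5000))) / lambda
  lam_hat <- pi / (sd(x) * sqrt(6))
  mu_hat <- mean(x) - 0.5772156649015329 / lam_hat
  expect_lt(abs(lam_hat - lambda) / lambda, 0.1)
  expect_lt(abs(mu_hat - mu) / mu, 0.1)

  h <- cached_small_profile()
  h2 <- calibrate(h, n_cal = 150, seed = 9)
  h3 <- calibrate(h, n_cal = 150, seed = 9)
  expect_identical(h2$calibration, h3$calibration)
  ## zero-variance degenerate case
  hone <- random_small_hmm(1, seed = 2)
  hone$match_emit[1, ] <- famscan:::BACKGROUND_FREQS  # constant 1-bit scores
  expect_error(calibrate(hone, n_cal = 100, seed = 1), "zero variance")
})

test_that("E-values follow the Gumbel closed form and monotonicity", {
  h <- cached_small_profile()
  cal <- h$calibration
  expect_equal(hmm_evalue(h, cal$mu, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_lt(hmm_evalue(h, cal$mu + 60, 1), 1e-12)
  s <- seq(cal$mu - 5, cal$mu + 20, length.out = 40)
  ev <- hmm_evalue(h, s, 1000)
  expect_true(all(diff(ev) <= 0))
  expect_true(all(ev >= 0))
  huncal <- random_small_hmm(2, seed = 3)
  expect_error(hmm_evalue(huncal, 10, 1), "not calibrated")
})

test_that("logo relative entropy matches direct summation and flags indels", {
  h <- cached_small_profile()
  lg <- hmm_logo(h)
  q <- unname(h$background)
  for (k in c(1, 5, h$M)) {
    e <- h$match_emit[k, ]
    direct <- sum(e * log2(e / q))
    expect_equal(unique(lg$relative_entropy[lg$position == k]), direct,
                 tolerance = 1e-12)
  }
  ## background emissions -> zero relative entropy; one-hot -> log2(20)
  hbg <- random_small_hmm(2, seed = 4)
  hbg$match_emit[1, ] <- unname(famscan:::BACKGROUND_FREQS)
  hbg$background[] <- famscan:::BACKGROUND_FREQS
  lg2 <- hmm_logo(hbg)
  expect_equal(unique(lg2$relative_entropy[lg2$position == 1]), 0,
               tolerance = 1e-12)
  huni <- random_small_hmm(1, seed = 5)
  huni$match_emit[1, ] <- c(1, rep(0, 19))
  huni$background[] <- rep(1 / 20, 20)
  expect_equal(unique(hmm_logo(huni)$relative_entropy), log2(20),
               tolerance = 1e-12)
  ## indel flag reacts to a strong match->delete transition
  hind <- random_small_hmm(3, seed = 6)
  hind$transitions$MD[1] <- 0.5
  hind$transitions$MM[1] <- 0.4
  hind$transitions$MI[1] <- 0.1
  expect_true(hmm_logo(hind)$indel[hmm_logo(hind)$position == 1][1])
})

test_that("JSON serialization round-trips every probability exactly", {
  h <- cached_small_profile()
  path <- tempfile(fileext = ".json")
  write_hmm_json(h, path)
  h2 <- read_hmm_json(path)
  expect_identical(unname(h2$match_emit), unname(h$match_emit))
  expect_identical(h2$transitions, h$transitions)
  expect_identical(unname(h2$background), unname(h$background))
  expect_identical(h2$calibration$mu, h$calibration$mu)
  expect_identical(h2$calibration$lambda, h$calibration$lambda)
  expect_identical(h2$M, h$M)
  s <- random_aa_seq(30)
  expect_identical(forward_bits(h, s), forward_bits(h2, s))
})
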