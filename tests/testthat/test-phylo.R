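test_that("transition matrices are stochastic, reversible, and have the right limits", {
  mod <- subst_model(alpha = 1, k = 4)
  expect_equal(transition_matrix(mod, 0), diag(20), tolerance = 1e-12,
               ignore_attr = TRUE)
  Pinf <- transition_matrix(mod, 500)
  for (i in 1:20) expect_equal(unname(Pinf[i, ]), unname(mod$pi),
                               tolerance = 1e-9)
  set.seed(2)
  for (t in runif(5, 0.01, 3)) {
    P <- transition_matrix(mod, t)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12, ignore_attr = TRUE)
    ## detailed balance pi_a P_ab = pi_b P_ba
    flux <- diag(mod$pi) %*% P
    expect_equal(flux, t(flux), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("discrete gamma category rates have probability-weighted mean one", {
  for (alpha in c(0.05, 0.3, 1, 5, 42)) {
    r <- gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
  expect_equal(gamma_rates(1, 1), 1)
})

test_that("pruning matches the two-taxon closed form", {
  t2 <- ape::read.tree(text = "(a:0.3,b:0.5);")
  aln <- tibble::tibble(id = c("a", "b"), seq = c("ACDEFGHIKL", "AFDEWGHIKM"))
  mod <- subst_model(alpha = 1, k = 1)
  got <- site_loglik(t2, aln, mod)
  P <- transition_matrix(mod, 0.8)
  expected <- vapply(1:10, function(i) {
    x <- substr(aln$seq[1], i, i); y <- substr(aln$seq[2], i, i)
    log(mod$pi[[x]] * P[x, y])
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-10)
  ## identical sequences at t = 0 give ln pi(residue)
  t0 <- ape::read.tree(text = "(a:0,b:0);")
  same <- tibble::tibble(id = c("a", "b"), seq = c("ACD", "ACD"))
  expect_equal(site_loglik(t0, same, mod),
               log(unname(mod$pi[c("A", "C", "D")])), tolerance = 1e-12)
})

test_that("the likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(23)
  mod <- subst_model(alpha = 0.7, k = 4, p_inv = 0.1)
  tr <- ape::rtree(7)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  aln <- simulate_alignment(tr, subst_model(alpha = 0.7, k = 4), 60, seed = 8)
  base <- sum(site_loglik(tr, aln, mod))
  for (og in tr$tip.label[c(2, 5)]) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(sum(site_loglik(rr, aln, mod)), base, tolerance = 1e-8)
  }
  expect_equal(sum(site_loglik(ape::unroot(tr), aln, mod)), base,
               tolerance = 1e-8)
})

test_that("the total likelihood is exchangeable under column permutation", {
  set.seed(29)
  tr <- ape::rtree(5)
  mod <- subst_model(alpha = 1, k = 4)
  aln <- simulate_alignment(tr, mod, 40, seed = 9)
  perm <- sample(40)
  aln2 <- aln
  aln2$seq <- vapply(aln$seq, function(s) {
    paste(strsplit(s, "")[[1]][perm], collapse = "")
  }, character(1))
  expect_equal(sum(site_loglik(tr, aln, mod)), sum(site_loglik(tr, aln2, mod)),
               tolerance = 1e-10)
})

test_that("gaps and X are treated as missing data", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.4);")
  mod <- subst_model(alpha = 1, k = 1)
  aln <- tibble::tibble(id = c("a", "b"), seq = c("A-X", "AC-"))
  ll <- site_loglik(tr, aln, mod)
  ## site 1: both known; sites 2 and 3: only one known -> ln pi
  expect_equal(ll[2], log(unname(mod$pi["C"])), tolerance = 1e-12)
  expect_equal(ll[3], rep(0, 1) + log(sum(mod$pi)), tolerance = 1e-12)
  expect_error(site_loglik(tr, tibble::tibble(id = c("a", "z"), seq = c("A", "A")),
                           mod), "taxa")
})

test_that("optimizing from the truth does not decrease the likelihood", {
  set.seed(31)
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.4)
  mod <- subst_model(alpha = 1, k = 4)
  aln <- simulate_alignment(tr, mod, 150, seed = 10)
  ll0 <- sum(site_loglik(tr, aln, mod))
  fit <- optimize_phylo(tr, aln, mod, free = "brlen")
  expect_gte(fit$loglik, ll0 - 1e-9)
})

test_that("gamma shape recovery orders low- and high-heterogeneity data correctly", {
  set.seed(37)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  ok <- 0L
  n <- 12L
  for (i in seq_len(n)) {
    a_low <- simulate_alignment(tr, subst_model(alpha = 0.5, k = 4), 200,
                                seed = 100 + i)
    a_high <- simulate_alignment(tr, subst_model(alpha = 5, k = 4), 200,
                                 seed = 200 + i)
    f_low <- optimize_phylo(tr, a_low, subst_model(alpha = 1, k = 4),
                            free = c("brlen", "alpha"), max_sweeps = 4)
    f_high <- optimize_phylo(tr, a_high, subst_model(alpha = 1, k = 4),
                             free = c("brlen", "alpha"), max_sweeps = 4)
    if (f_low$model$alpha < f_high$model$alpha) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.95)
})

test_that("monophyly checks agree with exhaustive bipartition enumeration", {
  ## cherry on a quartet
  q <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(check_monophyly(q, c("a", "b")))
  expect_false(check_monophyly(q, c("a", "c")))
  ## complement symmetry on an unrooted tree
  t6 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1,f:1);")
  expect_identical(check_monophyly(t6, c("a", "b", "c")),
                   check_monophyly(t6, c("d", "e", "f")))
  expect_error(check_monophyly(q, c("a", "zz")), "unknown")
  set.seed(41)
  for (trial in 1:30) {
    tr <- ape::rtree(sample(4:7, 1))
    n <- length(tr$tip.label)
    taxa <- sample(tr$tip.label, sample(2:(n - 1), 1))
    if (length(taxa) >= n) next
    expect_identical(check_monophyly(tr, taxa), oracle_monophyletic(tr, taxa),
                     info = sprintf("trial %d", trial))
  }
})

test_that("positive and negative constraint filters partition any tree set", {
  quartets <- list(
    ab = ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);"),
    ac = ape::read.tree(text = "((a:1,c:1):1,b:1,d:1);"),
    ad = ape::read.tree(text = "((a:1,d:1):1,b:1,c:1);"))
  pos <- filter_topologies(quartets, c("a", "b"), "positive")
  neg <- filter_topologies(quartets, c("a", "b"), "negative")
  expect_length(pos, 1L)
  expect_length(neg, 2L)
  expect_setequal(names(c(pos, neg)), names(quartets))
  expect_warning(filter_topologies(quartets["ab"], c("a", "b"), "negative"),
                 "no topologies")
})

test_that("branch-length error shrinks as sites grow", {
  set.seed(43)
  tr <- ape::rtree(5)
  tr$edge.length <- runif(nrow(tr$edge), 0.15, 0.45)
  mod <- subst_model(alpha = 1, k = 4)
  err_at <- function(nsites, seed) {
    aln <- simulate_alignment(tr, mod, nsites, seed = seed)
    t0 <- tr; t0$edge.length <- rep(0.2, nrow(tr$edge))
    fit <- optimize_phylo(t0, aln, mod, free = "brlen")
    median(abs(fit$tree$edge.length - tr$edge.length) / tr$edge.length)
  }
  e100 <- median(vapply(1:3, function(i) err_at(100, 300 + i), numeric(1)))
  e1000 <- median(vapply(1:3, function(i) err_at(1000, 400 + i), numeric(1)))
  expect_lt(e1000, e100)
})

test_that("pruning agrees with an independent likelihood implementation", {
  ## dual route: famscan's pruning vs phangorn::pml on the same model
  set.seed(47)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  mod <- subst_model(alpha = 0.7, k = 4)
  aln <- simulate_alignment(tr, mod, 120, seed = 12)
  chars <- t(vapply(aln$seq, function(s) strsplit(s, "")[[1]], character(120)))
  rownames(chars) <- aln$id
  dat <- phangorn::phyDat(chars, type = "AA")
  fit <- phangorn::pml(tr, dat, model = "JTT", k = 4, shape = 0.7)
  expect_equal(sum(site_loglik(tr, aln, mod)), fit$logLik, tolerance = 1e-6)
  ## and with invariant sites
  mod_i <- subst_model(alpha = 0.7, k = 4, p_inv = 0.15)
  fit_i <- phangorn::pml(tr, dat, model = "JTT", k = 4, shape = 0.7, inv = 0.15)
  expect_equal(sum(site_loglik(tr, aln, mod_i)), fit_i$logLik, tolerance = 1e-6)
})
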