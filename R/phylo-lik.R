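## Protein likelihood on fixed topologies: JTT exchangeabilities,
## discrete-gamma rate variation with invariant sites, Felsenstein pruning,
## coordinate-ascent branch/model optimization, and monophyly utilities.

#' Construct an amino-acid substitution model
#'
#' JTT exchangeabilities with either the model's own equilibrium frequencies
#' or empirical frequencies counted from an alignment (add-one smoothing).
#' The rate matrix is scaled to one expected substitution per unit branch
#' length at `p_inv = 0`; under invariant sites the variable-site rates are
#' rescaled by `1/(1 - p_inv)` so branch lengths remain comparable.
#'
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param k Number of discrete gamma categories (default 4, equal-probability
#'   categories represented by their means).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param frequencies `"model"` (JTT defaults) or `"empirical"` (counted from
#'   `aln`).
#' @param aln Alignment tibble, required when `frequencies = "empirical"`.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(alpha = 1, k = 4L, p_inv = 0,
                        frequencies = c("model", "empirical"), aln = NULL) {
  frequencies <- match.arg(frequencies)
  stopifnot(alpha > 0, k >= 1L, p_inv >= 0, p_inv < 1)
  ord <- match(AMINO_ACIDS, JTT_PAML_ORDER)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- JTT_EXCH_LOWER
  S <- S + t(S)
  S <- S[ord, ord]
  pi <- if (frequencies == "empirical") {
    if (is.null(aln)) abort("empirical frequencies require an alignment")
    res <- unlist(strsplit(toupper(aln$seq), "", fixed = TRUE))
    cnt <- table(factor(res[res %in% AMINO_ACIDS], levels = AMINO_ACIDS))
    as.numeric(cnt + 1) / sum(cnt + 1)
  } else {
    JTT_FREQS_PAML[ord]
  }
  pi <- pi / sum(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  ## symmetric eigendecomposition: B = D^(1/2) Q D^(-1/2)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(name = "JTT", S = S, pi = setNames(pi, AMINO_ACIDS),
                 Q = Q, alpha = alpha, k = as.integer(k), p_inv = p_inv,
                 frequencies = frequencies,
                 eig = list(values = eig$values,
                            right = diag(1 / sp) %*% eig$vectors,
                            left = t(eig$vectors) %*% diag(sp))),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s + G(alpha=%.3g, k=%d) + I(p_inv=%.3g), %s frequencies\n",
              x$name, x$alpha, x$k, x$p_inv, x$frequencies))
  invisible(x)
}

#' Discrete-gamma category rates (equal-probability categories, mean rates)
#'
#' @param alpha Gamma shape.
#' @param k Number of categories.
#' @return Length-`k` vector of rates with probability-weighted mean 1.
#' @export
gamma_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  ## mean of Gamma(alpha, alpha) over (a, b], times k: uses the identity
  ## E[X; X <= x] = F_{alpha+1}(x) for the unit-mean gamma
  up <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  k * diff(up)
}

#' Transition probability matrix P(t) = exp(Q r t)
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param rate Rate multiplier.
#' @return A 20x20 row-stochastic matrix in `AMINO_ACIDS` order.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "subst_model"), t >= 0, rate >= 0)
  e <- model$eig
  P <- e$right %*% (exp(e$values * t * rate) * e$left)
  dimnames(P) <- list(AMINO_ACIDS, AMINO_ACIDS)
  P
}

## --- internal pruning machinery -------------------------------------------

## Pattern-compress an alignment against a tree's tip order. Gaps, 'X' and
## unknown characters are missing data (partial likelihood 1 for all states).
prep_phylo_data <- function(tree, aln) {
  stopifnot(inherits(tree, "phylo"), all(c("id", "seq") %in% names(aln)))
  if (!setequal(tree$tip.label, aln$id)) {
    abort("alignment taxa and topology taxa differ")
  }
  m <- aln_matrix(aln)[tree$tip.label, , drop = FALSE]
  codes <- matrix(match(m, AMINO_ACIDS), nrow = nrow(m))  # NA = missing
  key <- apply(codes, 2, function(col) paste(ifelse(is.na(col), "-", col), collapse = ","))
  pat_index <- match(key, unique(key))
  upat <- which(!duplicated(key))
  weights <- as.vector(table(factor(pat_index, levels = seq_along(upat))))
  pat_codes <- codes[, upat, drop = FALSE]
  ntip <- nrow(m)
  npat <- ncol(pat_codes)
  tipp <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    P <- matrix(0, 20, npat)
    known <- !is.na(pat_codes[i, ])
    P[cbind(pat_codes[i, known], which(known))] <- 1
    P[, !known] <- 1
    tipp[[i]] <- P
  }
  ## invariant-site component: sum_a pi_a * [all non-missing residues == a]
  compat <- matrix(TRUE, 20, npat)
  for (i in seq_len(ntip)) {
    known <- !is.na(pat_codes[i, ])
    if (any(known)) {
      ki <- which(known)
      compat[, ki] <- compat[, ki] &
        (matrix(seq_len(20), 20, length(ki)) ==
           matrix(pat_codes[i, ki], 20, length(ki), byrow = TRUE))
    }
  }
  list(tipp = tipp, weights = weights, pat_index = pat_index,
       npat = npat, compat = compat)
}

## Down (post-order) partial likelihoods for one category rate.
## Returns list over nodes of 20 x npat matrices (tips included).
down_partials <- function(tree, tipp, model, rate) {
  edge <- tree$edge
  el <- tree$edge.length
  ntot <- max(edge)
  down <- vector("list", ntot)
  down[seq_along(tipp)] <- tipp
  post <- ape::reorder.phylo(tree, "postorder")
  pedge <- post$edge
  pel <- post$edge.length
  for (j in seq_len(nrow(pedge))) {
    p <- pedge[j, 1]; v <- pedge[j, 2]
    P <- transition_matrix(model, pel[j], rate)
    contrib <- P %*% down[[v]]
    down[[p]] <- if (is.null(down[[p]])) contrib else down[[p]] * contrib
  }
  down
}

## Per-pattern site likelihood (linear scale) for one category rate.
pattern_lik_one_rate <- function(tree, tipp, model, rate) {
  down <- down_partials(tree, tipp, model, rate)
  root <- length(tipp) + 1L
  as.vector(model$pi %*% down[[root]])
}

## Combine gamma categories and invariant sites into per-pattern likelihoods.
pattern_site_lik <- function(tree, pd, model) {
  rates <- gamma_rates(model$alpha, model$k)
  if (model$p_inv > 0) rates <- rates / (1 - model$p_inv)
  var_lik <- 0
  for (r in rates) {
    var_lik <- var_lik + pattern_lik_one_rate(tree, pd$tipp, model, r) / length(rates)
  }
  inv_lik <- if (model$p_inv > 0) as.vector(model$pi %*% pd$compat) else 0
  model$p_inv * inv_lik + (1 - model$p_inv) * var_lik
}

#' Per-site log-likelihoods of an alignment on a fixed topology
#'
#' Felsenstein pruning under the model's JTT + discrete-gamma (+ invariant
#' sites) settings. Gaps and `X` are treated as missing data. Pattern
#' compression is undone before returning.
#'
#' @param tree An [ape::phylo] with branch lengths, taxa matching `aln$id`.
#' @param aln Alignment tibble (`id`, `seq`).
#' @param model A `subst_model`.
#' @return Numeric vector of natural-log per-site likelihoods.
#' @export
site_loglik <- function(tree, aln, model) {
  pd <- prep_phylo_data(tree, aln)
  lik <- pattern_site_lik(tree, pd, model)
  ll <- log(lik)[pd$pat_index]
  if (any(!is.finite(ll))) {
    abort(sprintf("non-finite likelihood at site %d", which(!is.finite(ll))[1]))
  }
  ll
}

## Up (pre-order) partials: for each non-root node v with parent u, the vector
## over states of u of the likelihood of all data outside subtree(v), with the
## root prior folded in. up[[root]] = pi.
up_partials <- function(tree, down, model, rate) {
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  el <- post$edge.length
  ntot <- max(edge)
  root <- length(down) - tree$Nnode + 1L  # ntip + 1
  npat <- ncol(down[[1]])
  up <- vector("list", ntot)      # outside partial, as a function of the
                                  # state at the PARENT of each node (the
                                  # node's own edge transition not applied)
  H <- vector("list", ntot)       # outside partial as a function of the
                                  # state at the node itself
  H[[root]] <- matrix(model$pi, 20, npat)
  ## preorder: parents before children
  for (j in rev(seq_len(nrow(edge)))) {
    p <- edge[j, 1]; v <- edge[j, 2]
    sibs <- edge[edge[, 1] == p, 2]
    sibs <- sibs[sibs != v]
    A <- H[[p]]
    for (w in sibs) {
      jw <- which(edge[, 2] == w)
      A <- A * (transition_matrix(model, el[jw], rate) %*% down[[w]])
    }
    up[[v]] <- A
    H[[v]] <- crossprod(transition_matrix(model, el[j], rate), A)
  }
  up
}

## --- optimization ----------------------------------------------------------

#' Optimize branch lengths and rate-model parameters on a fixed topology
#'
#' Coordinate ascent: per-branch scalar optimization (Brent, tolerance 1e-6)
#' using cached pre/post-order partials, interleaved with scalar optimization
#' of the gamma shape and the invariant-sites proportion. The total
#' log-likelihood is non-decreasing across sweeps; iteration stops when a
#' sweep improves it by less than `tol` or after `max_sweeps` sweeps.
#'
#' @param tree [ape::phylo] with positive initial branch lengths.
#' @param aln Alignment tibble.
#' @param model A `subst_model` (its `alpha`/`p_inv` are the starting values).
#' @param free Character vector from `c("brlen", "alpha", "p_inv")`.
#' @param max_sweeps Maximum coordinate-ascent sweeps (default 20).
#' @param tol Convergence tolerance on the total log-likelihood (default 1e-6).
#' @return An object of class `phylo_fit`: list with `tree` (fitted branch
#'   lengths), `model`, `loglik`, `site_loglik`, and `n_sweeps`.
#' @export
optimize_phylo <- function(tree, aln, model,
                           free = c("brlen", "alpha", "p_inv"),
                           max_sweeps = 20L, tol = 1e-6) {
  stopifnot(all(free %in% c("brlen", "alpha", "p_inv")))
  if (any(tree$edge.length <= 0)) tree$edge.length[tree$edge.length <= 0] <- 1e-6
  pd <- prep_phylo_data(tree, aln)
  total_ll <- function(tr, mod) {
    sum(pd$weights * log(pattern_site_lik(tr, pd, mod)))
  }
  ll <- total_ll(tree, model)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    ll_start <- ll
    if ("brlen" %in% free) {
      post <- ape::reorder.phylo(tree, "postorder")
      for (j in seq_len(nrow(post$edge))) {
        res <- optimize_one_branch(tree, pd, model, post$edge[j, 2])
        if (res$loglik > ll) {
          tree <- res$tree
          ll <- res$loglik
        }
      }
    }
    if ("alpha" %in% free) {
      f <- function(la) {
        m2 <- model; m2$alpha <- exp(la)
        total_ll(tree, m2)
      }
      op <- optimize(f, lower = log(0.05), upper = log(50), maximum = TRUE,
                     tol = 1e-4)
      if (op$objective > ll) {
        model$alpha <- exp(op$maximum)
        ll <- op$objective
      }
    }
    if ("p_inv" %in% free) {
      f <- function(p) {
        m2 <- model; m2$p_inv <- p
        total_ll(tree, m2)
      }
      op <- optimize(f, lower = 0, upper = 0.9, maximum = TRUE, tol = 1e-4)
      if (op$objective > ll) {
        model$p_inv <- op$maximum
        ll <- op$objective
      }
    }
    if (ll - ll_start < tol || sweeps >= max_sweeps) break
  }
  slik <- site_loglik(tree, aln, model)
  structure(list(tree = tree, model = model, loglik = ll,
                 site_loglik = slik, n_sweeps = sweeps),
            class = "phylo_fit")
}

## Brent optimization of a single branch using cached partials for all other
## branches. `node` is the child node of the edge being optimized.
optimize_one_branch <- function(tree, pd, model, node) {
  rates <- gamma_rates(model$alpha, model$k)
  if (model$p_inv > 0) rates <- rates / (1 - model$p_inv)
  inv_lik <- if (model$p_inv > 0) as.vector(model$pi %*% pd$compat) else 0
  A_list <- vector("list", length(rates))
  D_list <- vector("list", length(rates))
  for (ci in seq_along(rates)) {
    down <- down_partials(tree, pd$tipp, model, rates[ci])
    up <- up_partials(tree, down, model, rates[ci])
    A_list[[ci]] <- up[[node]]
    D_list[[ci]] <- down[[node]]
  }
  f <- function(t) {
    var_lik <- 0
    for (ci in seq_along(rates)) {
      P <- transition_matrix(model, t, rates[ci])
      var_lik <- var_lik +
        colSums(A_list[[ci]] * (P %*% D_list[[ci]])) / length(rates)
    }
    lik <- model$p_inv * inv_lik + (1 - model$p_inv) * var_lik
    sum(pd$weights * log(lik))
  }
  op <- optimize(f, lower = 1e-8, upper = 10, maximum = TRUE, tol = 1e-6)
  j <- which(tree$edge[, 2] == node)
  tree$edge.length[j] <- op$maximum
  list(tree = tree, loglik = op$objective)
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("<phylo_fit> lnL = %.4f  (alpha=%.3g, p_inv=%.3g, %d sweeps)\n",
              x$loglik, x$model$alpha, x$model$p_inv, x$n_sweeps))
  invisible(x)
}

#' @export
glance.phylo_fit <- function(x, ...) {
  tibble(loglik = x$loglik, alpha = x$model$alpha, p_inv = x$model$p_inv,
         n_sweeps = x$n_sweeps, n_branches = length(x$tree$edge.length),
         tree_length = sum(x$tree$edge.length))
}

#' @export
tidy.phylo_fit <- function(x, ...) {
  tibble(site = seq_along(x$site_loglik), loglik = x$site_loglik)
}

## --- monophyly utilities ---------------------------------------------------

#' Is a taxon set monophyletic on an unrooted topology?
#'
#' True iff the bipartition (taxon set | complement) exists as an edge of the
#' unrooted tree. By bipartition symmetry the complement of a monophyletic set
#' is also monophyletic.
#'
#' @param tree [ape::phylo].
#' @param taxa Character vector, a proper non-trivial subset of the tips.
#' @return Logical scalar.
#' @export
check_monophyly <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown)) {
    abort(paste0("unknown taxa: ", paste(unknown, collapse = ", ")))
  }
  if (length(taxa) == 0L || length(taxa) >= length(tips)) {
    abort("taxon set must be a proper non-trivial subset of the tips")
  }
  if (length(taxa) == 1L || length(taxa) == length(tips) - 1L) return(TRUE)
  utree <- ape::unroot(tree)
  target <- sort(match(taxa, utree$tip.label))
  ntip <- length(utree$tip.label)
  edge <- ape::reorder.phylo(utree, "postorder")$edge
  below <- vector("list", max(edge))
  for (i in seq_len(ntip)) below[[i]] <- i
  for (j in seq_len(nrow(edge))) {
    p <- edge[j, 1]; v <- edge[j, 2]
    below[[p]] <- c(below[[p]], below[[v]])
    side <- sort(below[[v]])
    if (identical(side, target) ||
        identical(sort(setdiff(seq_len(ntip), side)), target)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Filter candidate topologies by a monophyly constraint
#'
#' Positive constraints keep trees where the taxon set is monophyletic;
#' negative constraints keep trees where it is not (the two partitions are
#' complementary for any tree set).
#'
#' @param trees A list of [ape::phylo] objects (or a `multiPhylo`).
#' @param taxa Taxon set for the constraint.
#' @param mode `"positive"` or `"negative"`.
#' @return The retained subset, as a plain list (empty with a warning if no
#'   tree satisfies the constraint).
#' @export
filter_topologies <- function(trees, taxa, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) > 0L)
  mono <- vapply(trees, check_monophyly, logical(1), taxa = taxa)
  keep <- if (mode == "positive") mono else !mono
  if (!any(keep)) warn("no topologies satisfy the constraint")
  trees[keep]
}
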