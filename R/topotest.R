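## Constrained-topology hypothesis tests from per-site log-likelihoods:
## RELL resampling, the Shimodaira-Hasegawa test, and the approximately
## unbiased (AU) test via multiscale bootstrap.

#' RELL bootstrap of per-site log-likelihoods
#'
#' Each replicate draws `round(scale * n)` site indices with replacement and
#' sums the per-site log-likelihoods of every topology (resampling estimated
#' log-likelihoods: no refitting).
#'
#' @param table Sites x topologies matrix of per-site natural-log likelihoods
#'   (column names identify topologies), or a data frame of the same shape.
#' @param B Number of replicates (>= 100).
#' @param scale Resampling scale factor r (> 0); replicates use
#'   `n' = round(r * n)` sites.
#' @param seed Integer seed.
#' @return B x topologies matrix of resampled total log-likelihoods.
#' @export
rell_resample <- function(table, B = 1000L, scale = 1, seed = 1L) {
  tbl <- as.matrix(table)
  n <- nrow(tbl)
  if (n < 2L) abort("single-site table cannot be resampled")
  stopifnot(B >= 100L, scale > 0)
  n2 <- max(1L, as.integer(round(scale * n)))
  with_seed(seed, {
    counts <- rmultinom(B, n2, prob = rep(1 / n, n))  # n x B
    out <- t(counts) %*% tbl                          # B x K
    colnames(out) <- colnames(tbl)
    out
  })
}

#' Shimodaira-Hasegawa test for topology comparison
#'
#' Each topology's RELL replicate totals are centered by its replicate mean;
#' the replicate statistic for topology i is the maximum centered value over
#' topologies minus topology i's centered value, and the p-value is the
#' fraction of replicates with a statistic at least the observed
#' `delta_i = max lnL - lnL_i`. The test is conservative by construction.
#'
#' @inheritParams rell_resample
#' @return A tibble: `topology`, `loglik`, `delta`, `p_sh`.
#' @export
sh_test <- function(table, B = 1000L, seed = 1L) {
  tbl <- as.matrix(table)
  if (ncol(tbl) < 2L) abort("need >= 2 topologies")
  totals <- colSums(tbl)
  delta <- max(totals) - totals
  R <- rell_resample(tbl, B = B, scale = 1, seed = seed)
  Rc <- sweep(R, 2, colMeans(R))          # centered replicate totals
  stat <- apply(Rc, 1, max) - Rc           # B x K replicate statistics
  p <- colMeans(sweep(stat, 2, delta, ">=") * 1)
  tibble(topology = colnames(tbl) %||% paste0("tree", seq_along(totals)),
         loglik = unname(totals), delta = unname(delta), p_sh = unname(p))
}

#' Approximately unbiased (AU) test via multiscale bootstrap
#'
#' For each scale r, `BP_i(r)` is the fraction of scale-r RELL replicates in
#' which topology i attains the maximum total (ties split equally).
#' `Phi^-1(1 - BP_i(r))` is regressed on `d * sqrt(r) + c / sqrt(r)` by
#' weighted least squares (binomial delta-method weights); the AU p-value is
#' `1 - Phi(d - c)`. BP values are clamped to `[1/(2B), 1 - 1/(2B)]` before
#' the normal transform; topologies with BP of 0 or 1 at every scale are
#' flagged degenerate and given the corresponding clamp-limit p-value.
#'
#' @inheritParams rell_resample
#' @param scales Resampling scale factors; at least two distinct values
#'   spanning both sides of 1 (default `seq(0.5, 1.4, by = 0.1)`).
#' @return A tibble: `topology`, `loglik`, `delta`, `p_au`, `d`, `c`,
#'   `degenerate`, and a list-column `bp` of per-scale bootstrap proportions.
#' @export
au_test <- function(table, scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                    seed = 1L) {
  tbl <- as.matrix(table)
  K <- ncol(tbl)
  if (K < 2L) abort("need >= 2 topologies")
  if (length(unique(scales)) < 2L || min(scales) >= 1 || max(scales) <= 1) {
    abort("need >= 2 distinct scales spanning values below and above 1")
  }
  totals <- colSums(tbl)
  delta <- max(totals) - totals
  bp <- matrix(0, nrow = length(scales), ncol = K)
  for (si in seq_along(scales)) {
    R <- rell_resample(tbl, B = B, scale = scales[si], seed = seed + si)
    mx <- apply(R, 1, max)
    isnax <- (R == mx)                      # ties split equally
    bp[si, ] <- colMeans(isnax / rowSums(isnax))
  }
  fits <- apply(bp, 2, fit_au_curve, scales = scales, B = B)
  tibble(topology = colnames(tbl) %||% paste0("tree", seq_len(K)),
         loglik = unname(totals), delta = unname(delta),
         p_au = purrr::map_dbl(fits, "p"),
         d = purrr::map_dbl(fits, "d"),
         c = purrr::map_dbl(fits, "c"),
         degenerate = purrr::map_lgl(fits, "degenerate"),
         bp = purrr::map(seq_len(K), function(i) {
           tibble(scale = scales, bp = bp[, i])
         }))
}

#' Fit the AU signed-distance/curvature model to one BP(r) curve
#'
#' Weighted least squares of `Phi^-1(1 - BP(r))` on `d * sqrt(r) + c /
#' sqrt(r)` with binomial delta-method weights; `p = 1 - Phi(d - c)`. With
#' `B = Inf` the curve is taken as noise-free: no clamping, equal-precision
#' weights up to the delta-method factor.
#'
#' @param bp Bootstrap proportions, one per scale.
#' @param scales Resampling scale factors.
#' @param B Replicates per scale used to estimate `bp` (Inf for exact curves).
#' @return List with `d`, `c`, `p`, `degenerate`.
#' @export
fit_au_curve <- function(bp, scales, B = Inf) {
  stopifnot(length(bp) == length(scales))
  clamp_lim <- if (is.finite(B)) 1 / (2 * B) else 0
  clamp <- pmin(pmax(bp, clamp_lim), 1 - clamp_lim)
  degenerate <- all(bp <= clamp_lim) || all(bp >= 1 - clamp_lim)
  z <- qnorm(1 - clamp)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- dnorm(z)^2 / (clamp * (1 - clamp))  # inverse delta-method variance / B
  beta <- tryCatch({
    XtWX <- crossprod(X * w, X)
    XtWz <- crossprod(X * w, z)
    solve(XtWX, XtWz)
  }, error = function(e) matrix(c(NA_real_, NA_real_), 2))
  d <- beta[1]; cc <- beta[2]
  p <- if (degenerate || anyNA(beta) || any(!is.finite(z))) {
    if (mean(bp) > 0.5) 1 - clamp_lim else clamp_lim
  } else {
    1 - pnorm(d - cc)
  }
  list(d = d, c = cc, p = p, degenerate = degenerate)
}

#' Run SH and AU tests over candidate topologies for one alignment
#'
#' Convenience wrapper: per-topology branch lengths are re-optimized once on
#' the original alignment (standard RELL practice: replicates are not
#' refitted), the site log-likelihood table is assembled, and both tests are
#' run from it.
#'
#' @param trees List of candidate [ape::phylo] topologies (named, optionally).
#' @param aln Alignment tibble (`id`, `seq`).
#' @param model A `subst_model`.
#' @param B Replicates per scale.
#' @param scales AU scale set.
#' @param seed Integer seed.
#' @param optimize_model Also re-optimize `alpha`/`p_inv` per topology
#'   (default FALSE: branch lengths only).
#' @return An object of class `topo_test`: tibble with one row per topology
#'   (`topology`, `loglik`, `delta`, `p_sh`, `p_au`, `d`, `c`, `degenerate`,
#'   `bp`), with the site log-likelihood table in `attr(, "site_loglik")`.
#' @export
topology_test <- function(trees, aln, model, B = 1000L,
                          scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                          optimize_model = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  nm <- names(trees) %||% paste0("tree", seq_along(trees))
  nm[nm == ""] <- paste0("tree", which(nm == ""))
  free <- if (optimize_model) c("brlen", "alpha", "p_inv") else "brlen"
  tbl <- vapply(trees, function(tr) {
    fit <- optimize_phylo(tr, aln, model, free = free)
    fit$site_loglik
  }, numeric(nchar(aln$seq[1])))
  colnames(tbl) <- nm
  sh <- sh_test(tbl, B = B, seed = seed)
  au <- au_test(tbl, scales = scales, B = B, seed = seed)
  out <- dplyr::left_join(sh, dplyr::select(au, -"loglik", -"delta"),
                          by = "topology")
  attr(out, "site_loglik") <- tbl
  attr(out, "B") <- B
  attr(out, "scales") <- scales
  attr(out, "seed") <- seed
  class(out) <- c("topo_test", class(out))
  out
}

#' @export
tidy.topo_test <- function(x, ...) {
  dplyr::select(as_tibble(x), -"bp")
}

#' @export
glance.topo_test <- function(x, ...) {
  tibble(n_topologies = nrow(x), best = x$topology[x$delta == 0][1],
         B = attr(x, "B") %||% NA_integer_,
         n_scales = length(attr(x, "scales") %||% numeric()))
}

#' Plot multiscale bootstrap proportion curves
#'
#' One curve per topology: BP(r) against the scale factor r, the raw material
#' of the AU test's (d, c) fit.
#'
#' @param object A `topo_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topo_test <- function(object, ...) {
  curves <- tidyr::unnest(dplyr::select(as_tibble(object), "topology", "bp"),
                          "bp")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$scale, y = .data$bp,
                                       colour = .data$topology)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "resampling scale r", y = "bootstrap proportion BP(r)") +
    ggplot2::theme_minimal()
}

#' Write a site log-likelihood table as TSV
#'
#' Columns: `site`, then one column per topology.
#'
#' @param table Sites x topologies matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_loglik_tsv <- function(table, path) {
  df <- data.frame(site = seq_len(nrow(table)), as.data.frame(table))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
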