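# ---- population-genetic statistics --------------------------------------

# Split a dosage matrix into per-population allele frequency / sample-size
# summaries used by the Weir & Cockerham estimator.
pop_summaries <- function(genotypes, popmap, pops = NULL) {
  idx <- match(rownames(genotypes), popmap$individuals$individual_id)
  if (anyNA(idx)) stop("individuals missing from population map")
  pop <- popmap$individuals$population_id[idx]
  if (is.null(pops)) pops <- popmap$populations$population_id
  grp <- factor(pop, levels = pops)
  keep <- !is.na(grp)
  g <- genotypes[keep, , drop = FALSE]
  grp <- grp[keep]
  nm <- !is.na(g)
  n <- rowsum(nm + 0L, grp)                      # diploid sample sizes
  alt <- rowsum(ifelse(nm, g, 0L), grp)
  het <- rowsum(ifelse(nm, (g == 1L) + 0L, 0L), grp)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0, het / n, NA_real_)
  list(n = n, p = p, h = h, pops = pops)
}

# Per-site Weir & Cockerham (1984) variance components for diploids:
# a (among populations), b (among individuals within populations),
# c (within individuals). Rows of n/p/h are populations, columns sites.
wc_components <- function(n, p, h) {
  use <- !is.na(p) & n >= 1
  r <- colSums(use)
  n_use <- ifelse(use, n, 0)
  p_use <- ifelse(use, p, 0)
  h_use <- ifelse(use, h, 0)
  nbar <- colSums(n_use) / r
  nc <- (colSums(n_use) - colSums(n_use^2) / colSums(n_use)) / (r - 1)
  pbar <- colSums(n_use * p_use) / (r * nbar)
  s2 <- colSums(n_use * (p_use - rep(pbar, each = nrow(p)))^2 * use) /
    ((r - 1) * nbar)
  hbar <- colSums(n_use * h_use) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; c[bad] <- NA_real_
  data.frame(a = a, b = b, c = c)
}

#' Weir & Cockerham F_ST
#'
#' Multi-locus Weir & Cockerham (1984) theta, using the ratio-of-sums
#' ("weighted") convention `sum(a) / sum(a + b + c)` over sites; per-site
#' variance components a, b, c are retained for audit. With
#' `pairwise = TRUE` a symmetric population-by-population matrix of
#' pairwise theta is also computed. Sites with an undefined denominator
#' (fewer than two usable populations, or zero total variance) are
#' skipped. Pairwise theta can legitimately be negative for undifferentiated
#' pairs; no clamping is applied here.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param popmap a [population_map].
#' @param pops optional character vector restricting which populations are
#'   used (default: all).
#' @param pairwise also compute the pairwise theta matrix.
#' @return list of class `"fst_result"`: `theta` (global estimate),
#'   `components` (per-site a, b, c), and `pairwise` (matrix or `NULL`).
#' @export
weir_cockerham_fst <- function(genotypes, popmap, pops = NULL,
                               pairwise = FALSE) {
  s <- pop_summaries(genotypes, popmap, pops)
  if (length(s$pops) < 2) stop("need at least 2 populations")
  comp <- wc_components(s$n, s$p, s$h)
  denom <- comp$a + comp$b + comp$c
  ok <- is.finite(denom) & denom > 0
  if (!any(ok)) stop("no usable site for F_ST (fewer than 2 populations ",
                     "with data at every site?)")
  theta <- sum(comp$a[ok]) / sum(denom[ok])
  pw <- NULL
  if (pairwise) {
    np <- length(s$pops)
    pw <- matrix(0, np, np, dimnames = list(s$pops, s$pops))
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      cij <- wc_components(s$n[c(i, j), , drop = FALSE],
                           s$p[c(i, j), , drop = FALSE],
                           s$h[c(i, j), , drop = FALSE])
      d <- cij$a + cij$b + cij$c
      use <- is.finite(d) & d > 0
      pw[i, j] <- pw[j, i] <- sum(cij$a[use]) / sum(d[use])
    }
  }
  structure(list(theta = theta, components = comp, pairwise = pw,
                 populations = s$pops),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham F_ST:", format(x$theta, digits = 4), "over",
      sum(is.finite(x$components$a)), "sites;",
      length(x$populations), "populations\n")
  invisible(x)
}

#' Per-population nucleotide diversity
#'
#' Expected pairwise difference per site,
#' `pi = sum_sites [c_ref * c_alt / choose(n, 2)] / denominator_sites`,
#' where `c_ref`, `c_alt` are observed allele counts and
#' `n = c_ref + c_alt`. The denominator counts all callable sites —
#' polymorphic and monomorphic — and is supplied by the caller (for
#' synthetic data, the number of simulated sites).
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param popmap a [population_map].
#' @param denominator_sites total callable site count (>= number of
#'   variant sites).
#' @return data frame `population_id`, `pi`.
#' @export
nucleotide_diversity <- function(genotypes, popmap, denominator_sites) {
  if (denominator_sites <= 0) stop("denominator_sites must be positive")
  if (denominator_sites < ncol(genotypes))
    stop("denominator_sites must be >= number of variant sites")
  s <- pop_summaries(genotypes, popmap)
  n_all <- 2 * s$n
  c_alt <- s$p * n_all
  c_ref <- n_all - c_alt
  contrib <- ifelse(n_all >= 2, c_ref * c_alt / choose(n_all, 2), 0)
  pi <- rowSums(contrib, na.rm = TRUE) / denominator_sites
  data.frame(population_id = s$pops, pi = as.numeric(pi),
             stringsAsFactors = FALSE)
}

#' PLINK-style LD pruning
#'
#' Slides a window of `window_snps` variants advancing by `step`; within
#' each window, pairs of retained variants with squared Pearson correlation
#' of dosages above `r2_max` are resolved by removing the later variant.
#' Deterministic for a fixed variant order. Defaults echo the
#' `indep-pairwise 50 10 0.2` convention.
#'
#' @param genotypes individuals x variants dosage matrix (>= 2 variants).
#' @param window_snps window width in variants.
#' @param step window advance in variants.
#' @param r2_max squared-correlation threshold above which a pair is pruned.
#' @return character vector of kept variant ids.
#' @export
ld_prune <- function(genotypes, window_snps = 50L, step = 10L,
                     r2_max = 0.2) {
  nv <- ncol(genotypes)
  stopifnot(nv >= 2)
  ids <- colnames(genotypes)
  keep <- rep(TRUE, nv)
  starts <- seq(1L, max(1L, nv - 1L), by = step)
  for (st in starts) {
    en <- min(st + window_snps - 1L, nv)
    w <- which(keep[st:en]) + st - 1L
    if (length(w) < 2) next
    r2 <- suppressWarnings(stats::cor(genotypes[, w, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0
    for (i in seq_along(w)) {
      if (!keep[w[i]]) next
      for (j in seq_along(w)) {
        if (j <= i || !keep[w[j]]) next
        if (r2[i, j] > r2_max) keep[w[j]] <- FALSE
      }
    }
  }
  ids[keep]
}

#' Principal-component structure proxies
#'
#' Singular value decomposition of the column-centered dosage matrix
#' (missing dosages replaced by the column mean) on an LD-pruned variant
#' set. Individual scores are `U %*% D`; population scores are the means of
#' member individuals. Eigenvalues are `d^2 / (n - 1)`.
#'
#' @param genotypes individuals x variants dosage matrix (pruned).
#' @param popmap a [population_map].
#' @param k number of components to retain (default 3).
#' @return list of class `"structure_proxies"`: `ind_scores`,
#'   `pop_scores`, `eigenvalues`.
#' @export
pca_structure <- function(genotypes, popmap, k = 3L) {
  if (k <= 0) stop("k must be positive")
  if (k >= min(dim(genotypes))) stop("k must be < min(n_ind, n_var)")
  X <- genotypes
  mu <- colMeans(X, na.rm = TRUE)
  nab <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nab)) X[nab] <- mu[nab[, 2]]
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(genotypes), paste0("PC", seq_len(k)))
  idx <- match(rownames(genotypes), popmap$individuals$individual_id)
  pop <- factor(popmap$individuals$population_id[idx],
                levels = popmap$populations$population_id)
  pop_scores <- apply(scores, 2, function(cl) tapply(cl, pop, mean))
  structure(list(ind_scores = scores, pop_scores = as.matrix(pop_scores),
                 eigenvalues = sv$d^2 / (nrow(X) - 1)),
            class = "structure_proxies")
}

#' Permutation comparison of F_ST at adaptive versus random variants
#'
#' Compares the multi-locus Weir-Cockerham theta of a candidate adaptive
#' variant set against the null distribution of `n_draws` random variant
#' sets of the same size, using precomputed per-site variance components so
#' subset estimates are ratio-of-sums over the subset. One-sided p-value:
#' `(1 + #(random >= adaptive)) / (1 + n_draws)`.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param popmap a [population_map].
#' @param adaptive_ids variant ids of the candidate set.
#' @param n_draws number of random draws.
#' @param seed RNG seed.
#' @return list: `theta_adaptive`, `theta_random` (vector), `mean_random`,
#'   `p_value`.
#' @export
fst_adaptive_vs_random <- function(genotypes, popmap, adaptive_ids,
                                   n_draws = 1000L, seed = 1L) {
  ids <- colnames(genotypes)
  if (!length(adaptive_ids)) stop("adaptive_ids is empty")
  if (!all(adaptive_ids %in% ids)) stop("adaptive_ids outside universe")
  if (length(adaptive_ids) > length(ids))
    stop("adaptive set larger than universe")
  s <- pop_summaries(genotypes, popmap)
  comp <- wc_components(s$n, s$p, s$h)
  denom <- comp$a + comp$b + comp$c
  ok <- is.finite(denom) & denom > 0
  a <- ifelse(ok, comp$a, 0)
  d <- ifelse(ok, denom, 0)
  names(a) <- names(d) <- ids
  subset_theta <- function(set) sum(a[set]) / sum(d[set])
  theta_ad <- subset_theta(adaptive_ids)
  set.seed(seed)
  m <- length(adaptive_ids)
  theta_rand <- vapply(seq_len(n_draws), function(i)
    subset_theta(sample(ids, m)), 0)
  list(theta_adaptive = theta_ad, theta_random = theta_rand,
       mean_random = mean(theta_rand),
       p_value = (1 + sum(theta_rand >= theta_ad)) / (1 + n_draws))
}
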