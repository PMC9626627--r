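# ---- isolation by distance / environment and variance partitioning ------

#' Geographic, genetic and environmental distance matrices
#'
#' Builds the three population-by-population distance matrices used in
#' isolation-by-distance / isolation-by-environment testing: great-circle
#' (haversine) distance in km (Earth mean radius 6371.0088 km), Rousset
#' linearized genetic distance `F_ST / (1 - F_ST)` with negative pairwise
#' theta clamped to zero before linearization, and Euclidean distance on
#' z-scored environmental variables.
#'
#' @param popmap a [population_map].
#' @param fst an `"fst_result"` computed with `pairwise = TRUE`.
#' @param env_pop populations x variables `env_matrix`.
#' @return named list of three symmetric matrices: `geographic_km`,
#'   `linearized_fst`, `environmental`.
#' @export
distance_matrices <- function(popmap, fst, env_pop) {
  pc <- popmap$populations
  stopifnot(!is.null(fst$pairwise))
  pops <- pc$population_id
  stopifnot(identical(sort(pops), sort(rownames(fst$pairwise))),
            identical(sort(pops), sort(rownames(env_pop))))
  xy <- as.matrix(pc[, c("lon", "lat")])
  n <- nrow(xy)
  geo <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) {
    d <- geosphere::distHaversine(xy[i, , drop = FALSE],
                                  xy[(i + 1):n, , drop = FALSE],
                                  r = 6371.0088)
    geo[i, (i + 1):n] <- geo[(i + 1):n, i] <- d
  }
  th <- pmax(fst$pairwise[pops, pops], 0)
  if (any(th[upper.tri(th)] >= 1)) {
    warning("pairwise theta of 1 encountered; linearized distance set to 1e6")
    lin <- ifelse(th >= 1, 1e6, th / (1 - th))
  } else lin <- th / (1 - th)
  diag(lin) <- 0
  ez <- scale(unclass(env_pop)[pops, , drop = FALSE])
  envd <- as.matrix(stats::dist(ez))
  dimnames(envd) <- list(pops, pops)
  list(geographic_km = geo, linearized_fst = lin, environmental = envd)
}

lower_vec <- function(m) m[lower.tri(m)]

#' Mantel test
#'
#' Pearson correlation between the strictly-lower-triangle entries of two
#' distance matrices, with significance from joint row/column permutations
#' of the second matrix. The p-value is one-sided (upper tail:
#' association), `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`.
#'
#' @param A,B symmetric distance matrices over the same populations, in
#'   the same order.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `"mantel_result"`: `r`, `p_value`, `n_perm`,
#'   `perm_r`, `partial` (`NA`; see [partial_mantel()]).
#' @export
mantel_test <- function(A, B, n_perm = 999L, seed = 1L) {
  stopifnot(identical(dim(A), dim(B)), n_perm >= 1)
  a <- lower_vec(A); b <- lower_vec(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(a, b)
  n <- nrow(A)
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(n)
    stats::cor(a, lower_vec(B[o, o]))
  }, 0)
  structure(list(r = r_obs,
                 p_value = (1 + sum(perm_r >= r_obs)) / (1 + n_perm),
                 n_perm = n_perm, perm_r = perm_r, partial = NA_character_),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Mantel statistic between the residuals of the lower-triangle vectors of
#' `A` and `B` after least-squares removal of `C` (the residual method).
#' Permutations shuffle the population labels of `A` before
#' residualization.
#'
#' @inheritParams mantel_test
#' @param C the controlled distance matrix.
#' @return a `"mantel_result"` with `partial = "C"` recorded.
#' @export
partial_mantel <- function(A, B, C, n_perm = 999L, seed = 1L) {
  stopifnot(identical(dim(A), dim(B)), identical(dim(A), dim(C)))
  b <- lower_vec(B); cc <- lower_vec(C)
  if (stats::sd(lower_vec(A)) == 0 || stats::sd(b) == 0)
    stop("constant distance matrix: Mantel r undefined")
  res_on <- function(y, x) stats::lm.fit(cbind(1, x), y)$residuals
  rb <- res_on(b, cc)
  partial_r <- function(avec) {
    ra <- res_on(avec, cc)
    if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(0)
    stats::cor(ra, rb)
  }
  r_obs <- partial_r(lower_vec(A))
  n <- nrow(A)
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    o <- sample.int(n)
    partial_r(lower_vec(A[o, o]))
  }, 0)
  structure(list(r = r_obs,
                 p_value = (1 + sum(perm_r >= r_obs)) / (1 + n_perm),
                 n_perm = n_perm, perm_r = perm_r, partial = "C"),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  kind <- if (is.na(x$partial)) "Mantel" else "Partial Mantel"
  cat(kind, "test: r =", format(x$r, digits = 4), ", p =",
      format(x$p_value, digits = 4), "(", x$n_perm, "permutations )\n")
  invisible(x)
}

# Adjusted R^2 (Ezekiel) of a multivariate least-squares fit of Y on X.
adj_r2 <- function(Y, X) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (is.null(X) || ncol(X) == 0) return(c(r2 = 0, adj = 0, p = 0))
  Xc <- sweep(X, 2, colMeans(X))
  qr_x <- qr(Xc)
  if (qr_x$rank < ncol(Xc)) stop("rank-deficient predictor set")
  fit <- qr.fitted(qr_x, Yc)
  r2 <- sum(fit^2) / sum(Yc^2)
  p <- qr_x$rank
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  c(r2 = r2, adj = adj, p = p)
}

#' Partial-RDA variance partitioning
#'
#' Decomposes the adjusted variance of a multivariate allele-frequency
#' response into fractions attributable exclusively to climate, geography
#' and population structure, plus their shared components, via the
#' adjusted R-squared (Ezekiel correction) of the seven nested
#' least-squares models and inclusion-exclusion. Individual fractions can
#' be slightly negative; all fractions sum exactly to the full-model
#' adjusted R-squared.
#'
#' @param freqs an [allele_freq_matrix] (missing cells mean-imputed).
#' @param clim populations x variables climate matrix (kept variables).
#' @param geog populations x 2 matrix of lon/lat.
#' @param struct populations x k matrix of structure proxies (e.g.
#'   population PCA scores from [pca_structure()]).
#' @return list of class `"variance_partition"`: `fractions` (named
#'   vector: `clim_exclusive`, `geog_exclusive`, `struct_exclusive`,
#'   shared terms, `residual`), `adj_r2` of all seven models, `total`.
#' @export
partial_rda_partition <- function(freqs, clim, geog, struct) {
  Y <- freqs$freq
  mu <- colMeans(Y, na.rm = TRUE)
  nab <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(nab)) Y[nab] <- mu[nab[, 2]]
  X <- list(clim = as.matrix(clim), geog = as.matrix(geog),
            struct = as.matrix(struct))
  n <- nrow(Y)
  ptot <- sum(vapply(X, ncol, 0L))
  if (n <= ptot + 1) stop("need more populations than total predictors")
  fits <- list(
    c = adj_r2(Y, X$clim), g = adj_r2(Y, X$geog), s = adj_r2(Y, X$struct),
    cg = adj_r2(Y, cbind(X$clim, X$geog)),
    cs = adj_r2(Y, cbind(X$clim, X$struct)),
    gs = adj_r2(Y, cbind(X$geog, X$struct)),
    cgs = adj_r2(Y, cbind(X$clim, X$geog, X$struct)))
  A <- vapply(fits, `[[`, 0, "adj")
  total <- A[["cgs"]]
  frac <- c(clim_exclusive = total - A[["gs"]],
            geog_exclusive = total - A[["cs"]],
            struct_exclusive = total - A[["cg"]])
  # three-set inclusion-exclusion on adjusted R^2 (varpart convention):
  # triple overlap, then pairwise overlaps minus the triple term
  s_cgs <- A[["c"]] + A[["g"]] + A[["s"]] - A[["cg"]] - A[["cs"]] -
    A[["gs"]] + total
  o_cs <- A[["c"]] + A[["s"]] - A[["cs"]]
  o_cg <- A[["c"]] + A[["g"]] - A[["cg"]]
  o_gs <- A[["g"]] + A[["s"]] - A[["gs"]]
  shared_all <- s_cgs
  shared_cg <- o_cg - shared_all
  shared_cs <- o_cs - shared_all
  shared_gs <- o_gs - shared_all
  fractions <- c(frac,
                 shared_clim_geog = shared_cg,
                 shared_clim_struct = shared_cs,
                 shared_geog_struct = shared_gs,
                 shared_all = shared_all)
  fractions <- c(fractions, residual = 1 - total)
  structure(list(fractions = fractions,
                 adj_r2 = A, total = total),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (adjusted R^2 =",
      format(x$total, digits = 4), "):\n")
  print(round(x$fractions, 4))
  invisible(x)
}
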