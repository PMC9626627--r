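# ---- genotype-environment association scans -----------------------------

#' Prune correlated environmental variables
#'
#' Walks variables in descending importance and keeps a variable only if
#' its absolute Spearman correlation with every already-kept variable is
#' strictly below `r_max` (default 0.6, the conventional multicollinearity
#' guard for redundancy analysis).
#'
#' @param env an `env_matrix` (sites x variables).
#' @param importance character vector ranking all variables, most important
#'   first (e.g. from [variable_importance()]).
#' @param r_max absolute Spearman correlation cutoff.
#' @return character vector of kept variable names, in importance order.
#' @export
select_env_variables <- function(env, importance = colnames(env),
                                 r_max = 0.6) {
  if (!nrow(env) || !ncol(env)) stop("empty environmental matrix")
  stopifnot(all(colnames(env) %in% importance))
  importance <- importance[importance %in% colnames(env)]
  rho <- abs(stats::cor(unclass(env)[, importance, drop = FALSE],
                        method = "spearman"))
  kept <- character()
  for (v in importance) {
    if (!length(kept) || all(rho[v, kept] < r_max)) kept <- c(kept, v)
  }
  kept
}

#' Latent-factor association scan
#'
#' Deterministic least-squares formulation of the latent factor mixed
#' model: K latent factors are estimated as the leading left singular
#' vectors of the column-centered (mean-imputed) dosage matrix, then each
#' variant is regressed on each environmental variable plus the factors.
#' The z-scores are recalibrated with a genomic inflation factor
#' `lambda = median(z^2) / qchisq(0.5, 1)` per variable, p-values come from
#' `z^2 / lambda` against chi-square(1), and Benjamini-Hochberg q-values
#' are computed per variable; a variant is a hit if `q <= fdr` for at
#' least one variable. `K = 0` reduces to a plain per-variant regression
#' scan.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param env_ind individuals x variables environmental matrix (each
#'   individual typically inherits its population's values; see
#'   [env_for_individuals()]).
#' @param K number of latent factors (default 3); must be < n individuals.
#' @param fdr false-discovery-rate cutoff (default 0.05).
#' @param refine estimate the latent factors per variable from the
#'   environment-residualized genotype matrix (the least-squares
#'   latent-factor estimator; default TRUE). With `refine = FALSE` the
#'   factors come from the raw genotype SVD, where loci under strong
#'   clinal selection pull the environmental axes into the factors and
#'   mask their own signal.
#' @return list of class `"lfmm_fit"`: matrices `effect`, `z`, `p`, `q`
#'   (variants x variables), `lambda` per variable, factor scores `U`,
#'   `hits` (variant ids significant for >= 1 variable), `hit_variables`
#'   (named list), `K`, `fdr`.
#' @export
lfmm_scan <- function(genotypes, env_ind, K = 3L, fdr = 0.05,
                      refine = TRUE) {
  n <- nrow(genotypes)
  if (K >= n) stop("K must be < number of individuals")
  if (K < 0) stop("K must be >= 0")
  stopifnot(nrow(env_ind) == n)
  sds <- apply(env_ind, 2, stats::sd)
  if (any(sds == 0))
    stop("constant environmental variable: ",
         paste(colnames(env_ind)[sds == 0], collapse = ", "))
  Y <- genotypes
  mu <- colMeans(Y, na.rm = TRUE)
  nab <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(nab)) Y[nab] <- mu[nab[, 2]]
  Yc <- sweep(Y, 2, colMeans(Y))
  U <- if (K > 0) svd(Yc, nu = K, nv = 0)$u else NULL
  out <- lfmm_core(Y, env_ind, U, fdr, K = K,
                   residual_factors = refine && K > 0)
  structure(c(out, list(U = U, K = K, fdr = fdr, refined = refine)),
            class = "lfmm_fit")
}

# Per-variable scan. With residual_factors, the K factors are the leading
# left singular vectors of the genotype matrix residualized on [1, e]
# (least-squares latent-factor estimation), recomputed per variable;
# otherwise the supplied U is used for every variable.
lfmm_core <- function(Y, env_ind, U, fdr, K = if (is.null(U)) 0L else
                        ncol(U), residual_factors = FALSE) {
  n <- nrow(Y)
  nv <- ncol(Y)
  vars <- colnames(env_ind)
  eff <- z <- p <- q <- matrix(NA_real_, nv, length(vars),
                               dimnames = list(colnames(Y), vars))
  lambda <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    Uv <- U
    if (residual_factors) {
      D <- cbind(1, scale(env_ind[, v]))
      R <- Y - D %*% solve(crossprod(D), crossprod(D, Y))
      Uv <- svd(R, nu = K, nv = 0)$u
    }
    X <- cbind(1, scale(env_ind[, v]), Uv)
    XtX_inv <- solve(crossprod(X))
    B <- XtX_inv %*% crossprod(X, Y)            # coefficients, p x nv
    res <- Y - X %*% B
    df <- n - ncol(X)
    sigma2 <- colSums(res^2) / df
    se <- sqrt(XtX_inv[2, 2] * sigma2)
    beta <- B[2, ]
    zz <- beta / se
    lam <- stats::median(zz^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
    lam <- max(lam, 1e-12)
    pv <- stats::pchisq(zz^2 / lam, df = 1, lower.tail = FALSE)
    eff[, v] <- beta; z[, v] <- zz; p[, v] <- pv
    q[, v] <- stats::p.adjust(pv, method = "BH")
    lambda[v] <- lam
  }
  hit_mat <- q <= fdr
  hits <- rownames(q)[rowSums(hit_mat, na.rm = TRUE) > 0]
  hit_variables <- apply(hit_mat, 1, function(r) vars[which(r)],
                         simplify = FALSE)
  list(effect = eff, z = z, p = p, q = q, lambda = lambda,
       hits = hits, hit_variables = hit_variables[hits])
}

#' @export
print.lfmm_fit <- function(x, ...) {
  cat("Latent-factor association scan: K =", x$K, ",", nrow(x$q),
      "variants x", ncol(x$q), "variables\n")
  cat("  genomic inflation lambda:",
      paste(format(x$lambda, digits = 3), collapse = " "), "\n")
  cat("  hits at FDR", x$fdr, ":", length(x$hits), "\n")
  invisible(x)
}

#' Convert population-level environment to individual level
#'
#' Each individual inherits the environmental values of its population.
#'
#' @param env_pop populations x variables `env_matrix`.
#' @param popmap a [population_map].
#' @param individuals ordered individual ids (e.g. genotype rownames).
#' @return individuals x variables numeric matrix.
#' @export
env_for_individuals <- function(env_pop, popmap, individuals) {
  pop <- popmap$individuals$population_id[
    match(individuals, popmap$individuals$individual_id)]
  if (anyNA(pop)) stop("individuals missing from population map")
  out <- unclass(env_pop)[match(pop, rownames(env_pop)), , drop = FALSE]
  rownames(out) <- individuals
  out
}

#' Redundancy-analysis loading outlier scan
#'
#' Regresses centered population allele frequencies on the standardized
#' retained environmental variables, extracts constrained axes from the
#' singular value decomposition of the fitted values, and flags variants
#' whose loading (correlation of the variant's frequency vector with the
#' axis site scores) lies more than `sd_cutoff` standard deviations from
#' the mean loading on any of the first `k_axes` axes. SVD sign
#' indeterminacy is fixed by making the largest-magnitude site score of
#' each axis positive.
#'
#' @param freqs an [allele_freq_matrix]; missing cells are mean-imputed
#'   per variant.
#' @param env_pop populations x variables `env_matrix` restricted to the
#'   kept variables (see [select_env_variables()]).
#' @param sd_cutoff loading outlier cutoff in standard deviations
#'   (default 3).
#' @param k_axes number of constrained axes scanned; the default
#'   (`NULL`) scans every constrained axis, so no retained environmental
#'   dimension is silently dropped.
#' @return list of class `"rda_fit"`: `site_scores`, `loadings`,
#'   `eigenvalues`, `loading_mean`, `loading_sd`, `hits`, `k_axes`,
#'   `sd_cutoff`.
#' @export
rda_scan <- function(freqs, env_pop, sd_cutoff = 3, k_axes = NULL) {
  Y <- freqs$freq
  stopifnot(nrow(Y) == nrow(env_pop))
  if (nrow(Y) <= ncol(env_pop))
    stop("need more populations than environmental variables")
  mu <- colMeans(Y, na.rm = TRUE)
  nab <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(nab)) Y[nab] <- mu[nab[, 2]]
  Yc <- sweep(Y, 2, colMeans(Y))
  X <- scale(unclass(env_pop))
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("singular predictor cross-product; prune correlated variables ",
         "with select_env_variables() first")
  H <- X %*% solve(XtX, t(X))
  Yhat <- H %*% Yc
  if (is.null(k_axes)) k_axes <- ncol(X)
  k <- min(k_axes, ncol(X), nrow(Y) - 1L)
  sv <- svd(Yhat, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  flip <- apply(scores, 2, function(s) sign(s[which.max(abs(s))]))
  scores <- sweep(scores, 2, flip, `*`)
  rownames(scores) <- rownames(Y)
  colnames(scores) <- paste0("RDA", seq_len(k))
  loadings <- suppressWarnings(stats::cor(Yc, scores))
  loadings[!is.finite(loadings)] <- 0
  # null-bulk location/scale: median and MAD-consistent SD, so a dense
  # candidate tail cannot drag the cutoff outward
  mns <- apply(loadings, 2, stats::median)
  sds <- apply(loadings, 2, stats::mad)
  out_mat <- abs(sweep(loadings, 2, mns)) >
    sweep(matrix(1, nrow(loadings), k), 2, sd_cutoff * sds, `*`)
  hits <- rownames(loadings)[rowSums(out_mat) > 0]
  structure(list(site_scores = scores, loadings = loadings,
                 eigenvalues = sv$d[seq_len(k)]^2 / (nrow(Y) - 1),
                 loading_mean = mns, loading_sd = sds,
                 hits = hits, k_axes = k, sd_cutoff = sd_cutoff),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("RDA loading scan:", nrow(x$loadings), "variants,", x$k_axes,
      "axes, cutoff", x$sd_cutoff, "SD ->", length(x$hits), "hits\n")
  invisible(x)
}

#' Intersect the two association scans into the core adaptive set
#'
#' Core adaptive variants are those flagged both by the latent-factor scan
#' and as redundancy-analysis loading outliers.
#'
#' @param lfmm an `"lfmm_fit"`.
#' @param rda an `"rda_fit"` (or a character vector of hit ids).
#' @param variants optional [variant_table] for per-class counts.
#' @return list of class `"gea_result"`: `table` (data frame with
#'   per-variant flags), `core` ids, `counts_by_class`.
#' @export
intersect_core <- function(lfmm, rda, variants = NULL) {
  rda_hits <- if (is.character(rda)) rda else rda$hits
  universe_l <- rownames(lfmm$q)
  universe_r <- if (is.character(rda)) rda else rownames(rda$loadings)
  if (length(universe_r) && !any(universe_r %in% universe_l))
    stop("association scans cover disjoint variant universes")
  core <- intersect(lfmm$hits, rda_hits)
  tab <- data.frame(variant_id = universe_l,
                    lfmm_hit = universe_l %in% lfmm$hits,
                    rda_hit = universe_l %in% rda_hits,
                    stringsAsFactors = FALSE)
  tab$core_hit <- tab$lfmm_hit & tab$rda_hit
  tab$q_min <- apply(lfmm$q, 1, min)[tab$variant_id]
  counts <- NULL
  if (!is.null(variants)) {
    tab$vclass <- variants$vclass[match(tab$variant_id,
                                        variants$variant_id)]
    counts <- table(factor(tab$vclass[tab$core_hit],
                           levels = VCLASS_LEVELS))
  }
  structure(list(table = tab, core = core, counts_by_class = counts),
            class = "gea_result")
}

#' @export
print.gea_result <- function(x, ...) {
  cat("GEA result:", sum(x$table$lfmm_hit), "LFMM hits,",
      sum(x$table$rda_hit), "RDA hits,", length(x$core),
      "core adaptive variants\n")
  if (!is.null(x$counts_by_class)) print(x$counts_by_class)
  invisible(x)
}
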