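test_that("variable pruning keeps the higher-ranked of correlated pairs", {
  set.seed(8)
  base <- stats::rnorm(30)
  E <- make_env(cbind(base, base * 1.01 + stats::rnorm(30, 0, 1e-4),
                      stats::rnorm(30)),
                vars = c("BIO1", "BIO2", "BIO3"))
  kept <- select_env_variables(E, importance = c("BIO2", "BIO1", "BIO3"))
  expect_identical(kept, c("BIO2", "BIO3"))
  # mutually independent variables all survive
  E2 <- make_env(matrix(stats::rnorm(30 * 4), 30))
  expect_length(select_env_variables(E2), 4L)
  expect_identical(formals(select_env_variables)$r_max, 0.6)
})

test_that("K = 0 scan equals an independently coded per-variant regression", {
  sim <- small_sim()
  G <- sim$genotypes[, 1:60]
  E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))[, 1:2]
  fit <- lfmm_scan(G, E, K = 0)
  v <- "BIO2"
  for (l in sample(colnames(G), 5)) {
    y <- G[, l]
    y[is.na(y)] <- mean(y, na.rm = TRUE)
    m <- summary(stats::lm(y ~ scale(E[, v])))
    expect_equal(unname(fit$effect[l, v]), m$coefficients[2, 1],
                 tolerance = 1e-9)
    expect_equal(unname(fit$z[l, v]), m$coefficients[2, 3],
                 tolerance = 1e-9)
  }
})

test_that("q-values dominate p-values and respect the FDR flag", {
  sim <- small_sim()
  G <- sim$genotypes[, 1:100]
  E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))
  fit <- lfmm_scan(G, E, K = 2)
  expect_true(all(fit$q >= fit$p - 1e-12))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  expect_true(all(fit$lambda > 0))
  hits2 <- rownames(fit$q)[apply(fit$q <= fit$fdr, 1, any)]
  expect_setequal(fit$hits, hits2)
})

test_that("scan input validation catches degenerate designs", {
  sim <- small_sim()
  G <- sim$genotypes[, 1:20]
  E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))
  Ebad <- cbind(E, CONST = 1)
  expect_error(lfmm_scan(G, Ebad, K = 2), "constant")
  expect_error(lfmm_scan(G, E, K = nrow(G)), "K must be <")
})

test_that("the latent-factor scan recovers planted clines", {
  sim <- small_sim()
  G <- maf_filter(sim$genotypes, 0.10)
  E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))
  fit <- lfmm_scan(G, E, K = 3)
  planted <- intersect(sim$truth$variant_id, colnames(G))
  expect_gte(mean(planted %in% fit$hits), 0.55)
  expect_lt(mean(!(fit$hits %in% planted)), 0.35)
})

test_that("core-set power grows with effect size", {
  recall <- vapply(c(0.3, 0.8, 1.6), function(b) {
    cfg <- sim_config(seed = 13, n_pops = 14, n_ind_per_pop = 6,
                      n_neutral = 300, n_adaptive = 20, n_env = 8,
                      n_causal_env = 4, beta_range = c(b, b + 0.2))
    sim <- simulate_landscape(cfg)
    G <- maf_filter(sim$genotypes, 0.10)
    E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))
    fit <- lfmm_scan(G, E, K = 3)
    mean(intersect(sim$truth$variant_id, colnames(G)) %in% fit$hits)
  }, 0)
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], recall[1])
})

test_that("RDA loadings match an independent eigendecomposition oracle", {
  set.seed(33)
  n <- 10; L <- 50
  Y <- matrix(stats::rnorm(n * L), n,
              dimnames = list(paste0("P", 1:n), paste0("v", 1:L)))
  X <- matrix(stats::rnorm(n * 3), n,
              dimnames = list(paste0("P", 1:n), paste0("BIO", 1:3)))
  fr <- list(freq = (Y - min(Y)) / diff(range(Y)),
             n_alleles = matrix(10L, n, L, dimnames = dimnames(Y)))
  class(fr) <- "allele_freq"
  fit <- rda_scan(fr, make_env(X, sites = rownames(X),
                               vars = colnames(X)), k_axes = 3)
  # oracle: eigendecomposition of Yhat' Yhat gives axis scores Yhat %*% v
  Yc <- sweep(fr$freq, 2, colMeans(fr$freq))
  Xs <- scale(X)
  Yhat <- Xs %*% solve(crossprod(Xs), crossprod(Xs, Yc))
  eig <- eigen(crossprod(Yhat), symmetric = TRUE)
  for (a in 1:3) {
    sc_o <- Yhat %*% eig$vectors[, a]
    agree <- abs(stats::cor(sc_o, fit$site_scores[, a]))
    expect_gt(agree, 1 - 1e-8)
  }
  expect_equal(fit$eigenvalues, eig$values[1:3] / (n - 1),
               tolerance = 1e-8)
})

test_that("pure-noise loadings yield roughly the nominal outlier fraction", {
  set.seed(7)
  n <- 24; L <- 8000
  Y <- matrix(stats::rnorm(n * L), n,
              dimnames = list(paste0("P", 1:n), paste0("v", 1:L)))
  fr <- list(freq = (Y - min(Y)) / diff(range(Y)),
             n_alleles = matrix(10L, n, L, dimnames = dimnames(Y)))
  class(fr) <- "allele_freq"
  X <- matrix(stats::rnorm(n * 3), n,
              dimnames = list(paste0("P", 1:n), paste0("BIO", 1:3)))
  fit <- rda_scan(fr, make_env(X, sites = rownames(X),
                               vars = colnames(X)))
  frac <- length(fit$hits) / L
  # ~ 3 axes x 2 * Phi(-3) = 0.8%, allow generous sampling slack
  expect_lt(frac, 0.03)
  expect_gt(frac, 0.0005)
  expect_identical(formals(rda_scan)$sd_cutoff, 3)
})

test_that("rda_scan flags planted loci and demands a sane design", {
  # enough populations that a 3-SD loading is attainable
  sim <- simulate_landscape(sim_config(seed = 23, n_pops = 24,
                                       n_ind_per_pop = 8,
                                       n_neutral = 600, n_adaptive = 30,
                                       n_env = 8, n_causal_env = 4))
  G <- maf_filter(sim$genotypes, 0.10)
  fr <- allele_frequencies(G, sim$popmap)
  kept <- select_env_variables(sim$env_current)
  fit <- rda_scan(fr, env_matrix(unclass(sim$env_current)[, kept,
                                                          drop = FALSE]))
  planted <- intersect(sim$truth$variant_id, colnames(fr$freq))
  expect_gt(mean(planted %in% fit$hits), 0.5)
  # hits are strongly enriched for planted loci
  expect_gt(mean(fit$hits %in% planted), 0.5)
  # collinear design is refused
  E_sing <- unclass(sim$env_current)[, c(1, 1)]
  colnames(E_sing) <- c("BIO1", "BIO1b")
  expect_error(rda_scan(fr, env_matrix(E_sing)), "singular|prune")
})

test_that("core intersection behaves like a set intersection", {
  sim <- small_sim()
  G <- maf_filter(sim$genotypes, 0.10)
  E <- env_for_individuals(sim$env_current, sim$popmap, rownames(G))
  lf <- lfmm_scan(G, E, K = 2)
  res_empty <- intersect_core(lf, character(0) , sim$variants)
  expect_length(res_empty$core, 0)
  res_same <- intersect_core(lf, lf$hits, sim$variants)
  expect_setequal(res_same$core, lf$hits)
  expect_true(all(res_same$table$core_hit ==
                    (res_same$table$lfmm_hit & res_same$table$rda_hit)))
  expect_error(intersect_core(lf, c("zzz1", "zzz2")), "disjoint")
})
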