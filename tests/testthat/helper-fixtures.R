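# Shared fixtures and independent oracles. Everything is generated in
# code; heavier default-scale objects are cached per session.

fixture_env <- new.env(parent = emptyenv())

# small landscape for module-level tests (fast, still structured)
small_sim <- function(seed = 21) {
  key <- paste0("small_", seed)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- simulate_landscape(sim_config(
      seed = seed, n_pops = 12, n_ind_per_pop = 6,
      n_neutral = 400, n_adaptive = 20, n_env = 8, n_causal_env = 4))
  fixture_env[[key]]
}

# a tiny hand-built dataset: 3 populations x 4 individuals, 6 variants
toy_data <- function() {
  G <- rbind(
    i1 = c(0L, 1L, 2L, 0L, 1L, 1L),
    i2 = c(1L, 1L, 2L, 0L, NA, 1L),
    i3 = c(0L, 0L, 2L, 0L, 1L, 0L),
    i4 = c(2L, 1L, 2L, 0L, 0L, 1L),
    i5 = c(2L, 2L, 0L, 0L, 1L, 2L),
    i6 = c(1L, 2L, 0L, 0L, NA, 2L),
    i7 = c(2L, 2L, 0L, 0L, 1L, 1L),
    i8 = c(2L, 1L, 0L, 0L, 0L, 2L),
    i9 = c(1L, 1L, 1L, 0L, 1L, 1L),
    i10 = c(1L, 2L, 1L, 0L, 1L, 1L),
    i11 = c(0L, 1L, 1L, 0L, 0L, 1L),
    i12 = c(1L, 1L, 1L, 0L, 1L, 1L))
  colnames(G) <- paste0("v", 1:6)
  pm <- population_map(
    data.frame(individual_id = rownames(G),
               population_id = rep(c("A", "B", "C"), each = 4)),
    data.frame(population_id = c("A", "B", "C"),
               lon = c(100, 101, 103), lat = c(40, 42, 45)))
  vt <- variant_table(colnames(G), chrom = "LG01", pos = 1:6 * 100,
                      vclass = c("SNP", "SNP", "SNP", "SNP", "INDEL", "SV"),
                      ref_allele = "A",
                      alt_allele = c("T", "C", "G", "T", "AAAA",
                                     strrep("ACGT", 20)),
                      ancestral = "ref",
                      func_class = c("synonymous", "deleterious", "LOF",
                                     "synonymous", "tolerated",
                                     "noncoding"))
  list(G = G, pm = pm, vt = vt)
}

# direct scalar transcription of the diploid variance-components
# estimator (Weir & Cockerham 1984), one site at a time
wc_fst_oracle <- function(G, pop) {
  pops <- unique(pop)
  A <- D <- 0
  for (j in seq_len(ncol(G))) {
    n_i <- p_i <- h_i <- numeric(length(pops))
    for (k in seq_along(pops)) {
      g <- G[pop == pops[k], j]
      g <- g[!is.na(g)]
      n_i[k] <- length(g)
      p_i[k] <- if (length(g)) sum(g) / (2 * length(g)) else NA
      h_i[k] <- if (length(g)) mean(g == 1) else NA
    }
    use <- !is.na(p_i) & n_i >= 1
    r <- sum(use)
    if (r < 2) next
    n_i <- n_i[use]; p_i <- p_i[use]; h_i <- h_i[use]
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc > 0) { A <- A + a; D <- D + a + b + cc }
  }
  A / D
}

# exhaustive Mantel p-value by enumerating all n! label permutations
mantel_exhaustive <- function(A, B) {
  n <- nrow(A)
  perms <- gtools_permutations(n)
  a <- A[lower.tri(A)]
  r_obs <- stats::cor(a, B[lower.tri(B)])
  r_all <- apply(perms, 1, function(o) {
    Bp <- B[o, o]
    stats::cor(a, Bp[lower.tri(Bp)])
  })
  mean(r_all >= r_obs - 1e-12)
}

# all permutations of 1..n (n small), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Spearman rho by explicit rank-then-Pearson
spearman_oracle <- function(x, y)
  stats::cor(rank(x), rank(y))

# straightforward O(pops x cells) loops for forward / reverse offsets
forward_oracle <- function(Tp, Tg, km, d) {
  out <- numeric(nrow(Tp))
  for (i in seq_len(nrow(Tp))) {
    best <- Inf
    for (g in seq_len(nrow(Tg)))
      if (km[i, g] <= d)
        best <- min(best, sqrt(sum((Tp[i, ] - Tg[g, ])^2)))
    out[i] <- best
  }
  out
}

reverse_oracle <- function(Tp, Tg) {
  out <- numeric(nrow(Tg))
  for (g in seq_len(nrow(Tg))) {
    best <- Inf
    for (i in seq_len(nrow(Tp)))
      best <- min(best, sqrt(sum((Tg[g, ] - Tp[i, ])^2)))
    out[g] <- best
  }
  out
}

# simple env matrix over named sites
make_env <- function(values, sites = paste0("P", seq_len(nrow(values))),
                     vars = paste0("BIO", seq_len(ncol(values))), ...) {
  dimnames(values) <- list(sites, vars)
  env_matrix(values, ...)
}
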