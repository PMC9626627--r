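test_that("distance matrices follow their closed forms", {
  pm <- population_map(
    data.frame(individual_id = paste0("i", 1:3),
               population_id = c("A", "B", "C")),
    data.frame(population_id = c("A", "B", "C"),
               lon = c(100, 100, 100), lat = c(40, 41, 40)))
  fst <- structure(list(pairwise = matrix(c(0, 0.021, -0.01,
                                            0.021, 0, 0.3,
                                            -0.01, 0.3, 0), 3,
                                          dimnames = list(c("A", "B", "C"),
                                                          c("A", "B", "C")))),
                   class = "fst_result")
  E <- make_env(matrix(c(1, 2, 3, 4, 6, 8), 3),
                sites = c("A", "B", "C"), vars = c("BIO1", "BIO2"))
  d <- distance_matrices(pm, fst, E)
  # one degree of latitude on a meridian
  expect_equal(d$geographic_km["A", "B"], 6371.0088 * pi / 180,
               tolerance = 1e-6)
  expect_equal(d$geographic_km["A", "C"], 0)
  # Rousset linearization with clamping of negative theta
  expect_equal(d$linearized_fst["A", "B"], 0.021 / 0.979,
               tolerance = 1e-12)
  expect_equal(d$linearized_fst["A", "C"], 0)
  # Euclidean on z-scores
  ez <- scale(unclass(E))
  expect_equal(d$environmental["A", "B"],
               sqrt(sum((ez[1, ] - ez[2, ])^2)), tolerance = 1e-12)
})

test_that("theta of exactly 1 maps to the large sentinel with a warning", {
  pm <- population_map(
    data.frame(individual_id = paste0("i", 1:2),
               population_id = c("A", "B")),
    data.frame(population_id = c("A", "B"), lon = c(0, 1), lat = c(0, 1)))
  fst <- structure(list(pairwise = matrix(c(0, 1, 1, 0), 2,
                                          dimnames = list(c("A", "B"),
                                                          c("A", "B")))),
                   class = "fst_result")
  E <- make_env(matrix(c(1, 2, 5, 9), 2), sites = c("A", "B"))
  expect_warning(d <- distance_matrices(pm, fst, E), "1e6|sentinel|theta")
  expect_equal(d$linearized_fst["A", "B"], 1e6)
})

test_that("Mantel statistic and p behave at the self-comparison limit", {
  set.seed(2)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6)))
  res <- mantel_test(m, m, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  # a permutation can reproduce the identity ordering by chance
  expect_lte(res$p_value, 3 / 200)
  expect_error(mantel_test(m, matrix(0, 6, 6)), "constant")
})

test_that("Mantel p at n = 4 matches the exhaustive enumeration oracle", {
  set.seed(14)
  for (rep in 1:3) {
    A <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
    B <- as.matrix(stats::dist(matrix(stats::rnorm(8), 4)))
    exact <- mantel_exhaustive(A, B)
    res <- mantel_test(A, B, n_perm = 999, seed = rep)
    expect_lt(abs(res$p_value - exact), 0.08)
  }
})

test_that("Mantel r is invariant to adding a constant to a matrix", {
  set.seed(3)
  A <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5)))
  B <- as.matrix(stats::dist(matrix(stats::rnorm(10), 5)))
  B2 <- B + 7; diag(B2) <- 0
  expect_equal(mantel_test(A, B, 99, 1)$r, mantel_test(A, B2, 99, 1)$r,
               tolerance = 1e-12)
})

test_that("Mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  A <- as.matrix(stats::dist(matrix(stats::rnorm(16), 8)))
  B <- as.matrix(stats::dist(matrix(stats::rnorm(16), 8)))
  ours <- mantel_test(A, B, n_perm = 999, seed = 1)
  ref <- vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.06)
})

test_that("partial Mantel controls and collapses as expected", {
  set.seed(4)
  xy <- matrix(stats::rnorm(20), 10)
  A <- as.matrix(stats::dist(xy))
  B <- as.matrix(stats::dist(xy + stats::rnorm(20, 0, 0.3)))
  C <- as.matrix(stats::dist(matrix(stats::rnorm(20), 10)))
  # B = C -> residual correlation collapses
  self <- partial_mantel(A, B, B, n_perm = 99, seed = 1)
  expect_lt(abs(self$r), 0.15)
  # independent C -> partial close to plain
  plain <- mantel_test(A, B, n_perm = 99, seed = 1)
  part <- partial_mantel(A, B, C, n_perm = 99, seed = 1)
  expect_lt(abs(part$r - plain$r), 0.15)
  # A strongly associated with B, arbitrary C -> small p
  strong <- partial_mantel(A, A, C, n_perm = 999, seed = 1)
  expect_lte(strong$p_value, 0.01)
})

test_that("variance partitioning attributes constructed signal correctly", {
  set.seed(6)
  n <- 30
  clim <- matrix(stats::rnorm(n * 3), n)
  geog <- matrix(stats::rnorm(n * 2), n)
  struct <- matrix(stats::rnorm(n * 3), n)
  Y <- clim %*% matrix(stats::rnorm(3 * 40), 3) +
    matrix(stats::rnorm(n * 40, 0, 0.05), n)
  fr <- list(freq = (Y - min(Y)) / diff(range(Y)),
             n_alleles = matrix(1L, n, 40))
  class(fr) <- "allele_freq"
  vp <- partial_rda_partition(fr, clim, geog, struct)
  expect_gt(vp$fractions[["clim_exclusive"]], 0.9 * vp$total)
  expect_lt(abs(vp$fractions[["geog_exclusive"]]), 0.05)
  expect_lt(abs(vp$fractions[["struct_exclusive"]]), 0.05)
  # inclusion-exclusion identity
  expect_equal(sum(vp$fractions[setdiff(names(vp$fractions),
                                        "residual")]),
               vp$total, tolerance = 1e-9)

  # pure-noise response: all adjusted fractions near zero
  Y0 <- matrix(stats::rnorm(n * 40), n)
  fr0 <- list(freq = (Y0 - min(Y0)) / diff(range(Y0)),
              n_alleles = matrix(1L, n, 40))
  class(fr0) <- "allele_freq"
  vp0 <- partial_rda_partition(fr0, clim, geog, struct)
  expect_lt(max(abs(vp0$fractions[1:3])), 0.12)
})

test_that("variance partitioning matches vegan::varpart", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 25
  clim <- matrix(stats::rnorm(n * 2), n)
  geog <- matrix(stats::rnorm(n * 2), n)
  struct <- matrix(stats::rnorm(n * 2), n)
  Y <- clim %*% matrix(stats::rnorm(2 * 30), 2) +
    geog %*% matrix(stats::rnorm(2 * 30), 2) * 0.5 +
    matrix(stats::rnorm(n * 30), n)
  fr <- list(freq = (Y - min(Y)) / diff(range(Y)),
             n_alleles = matrix(1L, n, 30))
  class(fr) <- "allele_freq"
  vp <- partial_rda_partition(fr, clim, geog, struct)
  ref <- vegan::varpart(fr$freq, clim, geog, struct)
  ind <- ref$part$indfract$Adj.R.square
  # vegan order: [a]=X1 excl, [b]=X2 excl, [c]=X3 excl, then shared terms
  expect_equal(vp$fractions[["clim_exclusive"]], ind[1], tolerance = 1e-9)
  expect_equal(vp$fractions[["geog_exclusive"]], ind[2], tolerance = 1e-9)
  expect_equal(vp$fractions[["struct_exclusive"]], ind[3],
               tolerance = 1e-9)
  expect_equal(vp$fractions[["shared_all"]], ind[7], tolerance = 1e-9)
})

test_that("permutation p-values live on the k/(n_perm + 1) lattice", {
  set.seed(10)
  for (i in 1:5) {
    A <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6)))
    B <- as.matrix(stats::dist(matrix(stats::rnorm(12), 6)))
    p <- mantel_test(A, B, n_perm = 49, seed = i)$p_value
    expect_true(any(abs(p - (1:50) / 50) < 1e-12))
  }
})
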