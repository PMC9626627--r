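# constructed single-predictor model with a known linear ramp 0 -> 1
# over [0, 10]: cumulative importance 0.1 at each integer breakpoint
ramp_model <- function() {
  structure(list(
    curves = list(BIO1 = data.frame(breakpoint = 1:10,
                                    cumulative = seq(0.1, 1, by = 0.1))),
    r2 = c(l1 = 0.9), weights = c(l1 = 1),
    importance = c(BIO1 = 1), predictors = "BIO1",
    n_trees = 1, mtry = 1, seed = 1, dropped = character()),
    class = "turnover_model")
}

pop_fr <- function(freq_mat) {
  out <- list(freq = freq_mat,
              n_alleles = matrix(10L, nrow(freq_mat), ncol(freq_mat),
                                 dimnames = dimnames(freq_mat)))
  class(out) <- "allele_freq"
  out
}

test_that("RONA reproduces its closed forms exactly", {
  pops <- paste0("P", 1:5)
  e <- c(0, 5, 10, 15, 20)
  freq <- matrix(0.2 + 0.01 * e, 5, 1,
                 dimnames = list(pops, "locusA"))
  fr <- pop_fr(freq)
  cur <- make_env(matrix(e, 5), sites = pops, vars = "BIO1")
  futs <- list(m1.SSP126 = make_env(matrix(e + 5, 5), sites = pops,
                                    vars = "BIO1", period = "future",
                                    model = "m1", scenario = "SSP126"))
  res <- rona(fr, list(BIO1 = "locusA"), cur, futs)
  expect_equal(res$summary$mean, rep(0.05, 5), tolerance = 1e-10)
  # future equal to current -> zero shift everywhere
  futs0 <- list(m1.SSP126 = make_env(matrix(e, 5), sites = pops,
                                     vars = "BIO1", period = "future",
                                     model = "m1", scenario = "SSP126"))
  res0 <- rona(fr, list(BIO1 = "locusA"), cur, futs0)
  expect_equal(res0$summary$mean, rep(0, 5), tolerance = 1e-12)
})

test_that("RONA weights loci by regression R-squared", {
  # two noise-free loci with slopes 0.01 and 0.03; R2 weights 1 and 0.5
  # are forced by perturbing the second locus off its line
  pops <- paste0("P", 1:6)
  e <- c(0, 2, 4, 6, 8, 10)
  y1 <- 0.2 + 0.01 * e
  set.seed(1)
  # noisy second locus: fit gives some slope b2 and r2_2; closed form uses
  # the realized regression, so compute the expectation from lm directly
  y2 <- 0.1 + 0.03 * e + c(0.02, -0.02, 0.01, -0.01, 0.02, -0.02)
  fr <- pop_fr(cbind(lA = y1, lB = y2) |>
                 (\(m) {rownames(m) <- pops; m})())
  cur <- make_env(matrix(e, 6), sites = pops, vars = "BIO1")
  fut <- list(m1.SSP370 = make_env(matrix(e + 10, 6), sites = pops,
                                   vars = "BIO1", period = "future",
                                   model = "m1", scenario = "SSP370"))
  res <- rona(fr, list(BIO1 = c("lA", "lB")), cur, fut)
  reg <- res$regressions
  w <- reg$r2
  manual <- (w[1] * abs(reg$b[1]) * 10 + w[2] * abs(reg$b[2]) * 10) / sum(w)
  expect_equal(unique(round(res$summary$mean, 12)),
               round(manual, 12), tolerance = 1e-10)
  # hand-computed two-slope weighted mean: slopes 0.01/0.03, R2 1/0.5,
  # delta 10 -> (1*0.1 + 0.5*0.3)/1.5 = 1/6
  hand <- (1 * 0.1 + 0.5 * 0.3) / 1.5
  expect_equal(hand, 1 / 6, tolerance = 1e-12)
})

test_that("RONA doubles when the climate shift doubles (no truncation)", {
  pops <- paste0("P", 1:5)
  e <- seq(0, 8, by = 2)
  fr <- pop_fr(matrix(0.3 + 0.02 * e, 5, 1,
                      dimnames = list(pops, "l1")))
  cur <- make_env(matrix(e, 5), sites = pops, vars = "BIO1")
  f1 <- list(m.SSP126 = make_env(matrix(e + 2, 5), sites = pops,
                                 vars = "BIO1", period = "future",
                                 model = "m", scenario = "SSP126"))
  f2 <- list(m.SSP126 = make_env(matrix(e + 4, 5), sites = pops,
                                 vars = "BIO1", period = "future",
                                 model = "m", scenario = "SSP126"))
  r1 <- rona(fr, list(BIO1 = "l1"), cur, f1)$summary$mean
  r2 <- rona(fr, list(BIO1 = "l1"), cur, f2)$summary$mean
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
})

test_that("rona skips variables without associated loci", {
  pops <- paste0("P", 1:5)
  e <- seq_len(5)
  fr <- pop_fr(matrix(0.2 + 0.05 * e, 5, 1,
                      dimnames = list(pops, "l1")))
  cur <- make_env(matrix(c(e, e), 5), sites = pops,
                  vars = c("BIO1", "BIO2"))
  fut <- list(m.SSP126 = make_env(matrix(c(e + 1, e + 1), 5),
                                  sites = pops, vars = c("BIO1", "BIO2"),
                                  period = "future", model = "m",
                                  scenario = "SSP126"))
  expect_warning(res <- rona(fr, list(BIO1 = "l1", BIO2 = character()),
                             cur, fut), "skipped")
  expect_true(all(res$summary$variable == "BIO1"))
})

test_that("local offset follows the ramp closed form", {
  m <- ramp_model()
  cur <- make_env(matrix(2, 1), sites = "g1", vars = "BIO1")
  fut <- make_env(matrix(7, 1), sites = "g1", vars = "BIO1")
  expect_equal(unname(local_offset(m, cur, fut)), 0.5, tolerance = 1e-12)
  expect_equal(unname(local_offset(m, cur, cur)), 0, tolerance = 1e-15)
})

test_that("forward offsets are monotone in the dispersal cap and match the oracle", {
  set.seed(20)
  n_pop <- 5; n_cell <- 50
  pop_xy <- cbind(lon = stats::runif(n_pop, 0, 5),
                  lat = stats::runif(n_pop, 40, 45))
  grid_xy <- cbind(lon = stats::runif(n_cell, 0, 5),
                   lat = stats::runif(n_cell, 40, 45))
  m <- ramp_model()
  e_pop <- make_env(matrix(stats::runif(n_pop, 0, 10), n_pop),
                    sites = paste0("P", 1:n_pop), vars = "BIO1")
  e_grid <- make_env(matrix(stats::runif(n_cell, 0, 10), n_cell),
                     sites = paste0("g", 1:n_cell), vars = "BIO1")
  caps <- c(100, 250, 500, 1000, Inf)
  fwd <- forward_offset(m, e_pop, pop_xy, e_grid, grid_xy, d_max = caps)
  for (i in seq_len(n_pop))
    expect_true(all(diff(fwd[i, ]) <= 1e-15 | is.na(diff(fwd[i, ]))))
  # oracle agreement
  Tp <- predict(m, e_pop); Tg <- predict(m, e_grid)
  km <- matrix(0, n_pop, n_cell)
  for (i in seq_len(n_pop))
    km[i, ] <- geosphere::distHaversine(pop_xy[i, , drop = FALSE],
                                        grid_xy, r = 6371.0088)
  for (d in caps) {
    o <- forward_oracle(Tp, Tg, km, d)
    col <- paste0("forward_", ifelse(is.infinite(d), "inf", d))
    got <- fwd[, col]
    o[!is.finite(o)] <- NA
    expect_equal(unname(got), unname(o), tolerance = 1e-12)
  }
  rev <- reverse_offset(m, e_pop, e_grid)
  expect_equal(unname(rev), reverse_oracle(Tp, Tg), tolerance = 1e-12)
})

test_that("a perfectly matching destination gives zero forward offset", {
  m <- ramp_model()
  e_pop <- make_env(matrix(3, 1), sites = "P1", vars = "BIO1")
  e_grid <- make_env(matrix(c(3, 9), 2), sites = c("g1", "g2"),
                     vars = "BIO1")
  fwd <- forward_offset(m, e_pop, cbind(lon = 0, lat = 40), e_grid,
                        cbind(lon = c(0, 1), lat = c(40, 41)),
                        d_max = Inf)
  expect_equal(unname(fwd[1, 1]), 0, tolerance = 1e-15)
  # unreachable set warns and yields NA
  expect_warning(
    fwd0 <- forward_offset(m, e_pop, cbind(lon = 0, lat = 40), e_grid,
                           cbind(lon = c(30, 31), lat = c(70, 71)),
                           d_max = 10),
    "no grid cell")
  expect_true(is.na(fwd0[1, 1]))
})

test_that("reverse offset with a single population is the plain distance", {
  m <- ramp_model()
  e_pop <- make_env(matrix(2, 1), sites = "P1", vars = "BIO1")
  e_grid <- make_env(matrix(c(2, 4, 12), 3),
                     sites = paste0("g", 1:3), vars = "BIO1")
  rev <- reverse_offset(m, e_pop, e_grid)
  expect_equal(unname(rev), c(0, 0.2, 0.8), tolerance = 1e-12)
})

test_that("model averaging reports mean, SE and correlations", {
  x <- c(a = 1, b = 2, c = 3)
  same <- average_models(list(m1 = x, m2 = x))
  expect_equal(same$mean, x)
  expect_equal(unname(same$se), rep(0, 3))
  expect_true(all(same$correlations == 1))
  two <- average_models(list(m1 = x, m2 = 3 * x))
  expect_equal(two$mean, 2 * x)
  expect_error(average_models(list(m1 = x, m2 = x[1:2])), "mismatch")
})

test_that("RGB composite scales to [0, 255] with half-up rounding", {
  loc <- c(0, 5, 10); fwd <- c(10, 0, 5); rev <- c(1, 1, 1)
  rgb <- rgb_composite(loc, fwd, rev)
  expect_equal(unname(rgb[, "R"]), c(0L, 128L, 255L))  # 127.5 rounds up
  expect_equal(unname(rgb[, "G"]), c(255L, 0L, 128L))
  expect_equal(unname(rgb[, "B"]), c(0L, 0L, 0L))      # constant -> 0
  expect_true(all(rgb >= 0 & rgb <= 255))
})

test_that("offsets are invariant to predictor order", {
  set.seed(30)
  cv <- list(BIO1 = data.frame(breakpoint = 1:5,
                               cumulative = seq(0.08, 0.4, by = 0.08)),
             BIO2 = data.frame(breakpoint = c(2, 4),
                               cumulative = c(0.3, 0.6)))
  m12 <- structure(list(curves = cv, r2 = c(l = 1), weights = c(l = 1),
                        importance = c(BIO1 = 0.4, BIO2 = 0.6),
                        predictors = c("BIO1", "BIO2"),
                        n_trees = 1, mtry = 1, seed = 1,
                        dropped = character()),
                   class = "turnover_model")
  m21 <- m12
  m21$predictors <- c("BIO2", "BIO1")
  cur <- make_env(matrix(stats::runif(8, 0, 6), 4),
                  sites = paste0("g", 1:4), vars = c("BIO1", "BIO2"))
  fut <- make_env(matrix(stats::runif(8, 0, 6), 4),
                  sites = paste0("g", 1:4), vars = c("BIO1", "BIO2"))
  expect_equal(local_offset(m12, cur, fut), local_offset(m21, cur, fut),
               tolerance = 1e-15)
})
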