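# ---- synthetic landscape generator --------------------------------------
#
# Emulates the statistical structure the downstream analyses assume:
# hierarchically structured populations with isolation by distance,
# correlated bioclimatic predictors built from shared smooth spatial
# fields, neutral loci drifting under a Balding-Nichols model and
# adaptive loci whose population frequencies follow climatic clines.

#' Simulation configuration
#'
#' Collects every knob of the synthetic landscape in one validated list.
#' Defaults emulate the sampling design the pipeline targets: 24
#' populations of 10 individuals split into a northern and a southern
#' ancestry group, 19 correlated bioclimatic variables of which 6 drive
#' clinal adaptive loci of small effect, three variant classes, and future
#' climate projections for four models under two emission scenarios.
#'
#' @param seed integer RNG seed; every draw derives from it.
#' @param n_pops number of populations (>= 3).
#' @param n_ind_per_pop individuals sampled per population.
#' @param n_neutral,n_adaptive neutral / clinal locus counts.
#' @param n_env number of environmental variables (BIO1..BIOn).
#' @param n_causal_env how many variables drive adaptive loci.
#' @param beta_range magnitude range of logit-scale cline slopes.
#' @param drift_F Balding-Nichols differentiation parameter in (0,1) for
#'   populations around their ancestry group.
#' @param group_F Balding-Nichols differentiation between the two ancestry
#'   groups. The two defaults together are calibrated so genome-wide
#'   Weir-Cockerham F_ST is near 0.02, the weak differentiation typical
#'   of wide-ranging wind-pollinated trees.
#' @param env_noise_sd sd of logit-scale noise on adaptive frequencies.
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param sv_fraction,indel_fraction fractions of loci labelled SV / indel
#'   (the remainder are SNPs).
#' @param func_class_probs named probability vector over functional classes
#'   `synonymous, tolerated, deleterious, LOF, noncoding`; must sum to 1.
#' @param future_models names of the four future climate models.
#' @param scenarios emission scenario labels.
#' @param delta_scale named scenario -> multiplier on the future climate
#'   anomaly fields; the high-emission scenario must exceed the low one.
#' @param window future time window label.
#' @param lon_range,lat_range bounding box for population placement.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_pops = 24L,
                       n_ind_per_pop = 10L,
                       n_neutral = 5000L,
                       n_adaptive = 100L,
                       n_env = 19L,
                       n_causal_env = 6L,
                       beta_range = c(0.5, 1.5),
                       drift_F = 0.015,
                       group_F = 0.007,
                       env_noise_sd = 0.2,
                       missing_rate = 0.02,
                       sv_fraction = 0.02,
                       indel_fraction = 0.14,
                       func_class_probs = c(synonymous = 0.25,
                                            tolerated = 0.10,
                                            deleterious = 0.05,
                                            LOF = 0.02,
                                            noncoding = 0.58),
                       future_models = c("BCC-CSM2-MR", "ACCESS-CM2",
                                         "CanESM5", "GISS-E2-1-G"),
                       scenarios = c("SSP126", "SSP370"),
                       delta_scale = c(SSP126 = 0.6, SSP370 = 1.2),
                       window = "2061-2080",
                       lon_range = c(122, 134),
                       lat_range = c(40, 53)) {
  if (n_pops < 3) stop("n_pops must be >= 3 (regressions undefined below)")
  stopifnot(drift_F > 0, drift_F < 1, group_F > 0, group_F < 1,
            n_causal_env <= n_env,
            length(beta_range) == 2, beta_range[1] <= beta_range[2],
            sv_fraction + indel_fraction <= 1,
            all(scenarios %in% names(delta_scale)))
  if (abs(sum(func_class_probs) - 1) > 1e-8)
    stop("func_class_probs must sum to 1")
  if (all(c("SSP126", "SSP370") %in% names(delta_scale)) &&
      delta_scale[["SSP370"]] <= delta_scale[["SSP126"]])
    stop("delta_scale must be larger for SSP370 than for SSP126")
  cfg <- list(seed = as.integer(seed), n_pops = as.integer(n_pops),
              n_ind_per_pop = as.integer(n_ind_per_pop),
              n_neutral = as.integer(n_neutral),
              n_adaptive = as.integer(n_adaptive),
              n_env = as.integer(n_env),
              n_causal_env = as.integer(n_causal_env),
              beta_range = beta_range, drift_F = drift_F,
              group_F = group_F,
              env_noise_sd = env_noise_sd, missing_rate = missing_rate,
              sv_fraction = sv_fraction, indel_fraction = indel_fraction,
              func_class_probs = func_class_probs,
              future_models = future_models, scenarios = scenarios,
              delta_scale = delta_scale, window = window,
              lon_range = lon_range, lat_range = lat_range)
  class(cfg) <- "sim_config"
  cfg
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Smooth random field as a sum of cosine basis functions of (lon, lat);
# deterministic given its parameter list, so the identical field can be
# evaluated at population sites and later at grid-cell centers.
make_field <- function(n_waves = 16L, length_scale = 1.8) {
  list(w = stats::rnorm(n_waves),
       kx = stats::rnorm(n_waves) / length_scale,
       ky = stats::rnorm(n_waves) / length_scale,
       phase = stats::runif(n_waves, 0, 2 * pi))
}

eval_field <- function(f, lon, lat) {
  v <- numeric(length(lon))
  for (k in seq_along(f$w))
    v <- v + f$w[k] * cos(f$kx[k] * lon + f$ky[k] * lat + f$phase[k])
  v / sqrt(sum(f$w^2) / 2 + 1e-12)   # approx unit variance over phases
}

# Environmental model: each variable loads on a latitudinal/longitudinal
# trend plus one of a few shared latent fields (inducing blocks of highly
# correlated variables) plus its own small field. The family fields are
# decorrelated over the sampled population sites (fixed linear
# combinations of the raw fields and the coordinate trends, hence still
# smooth functions evaluable anywhere): the climate syndromes of the
# simulated landscape are distinct axes rather than reshuffled copies of
# one another.
build_env_model <- function(cfg, lon, lat) {
  n_groups <- 4L   # broad variable families (cf. temperature/precipitation)
  raw <- lapply(seq_len(n_groups), function(i) make_field())
  lat0 <- mean(cfg$lat_range); lon0 <- mean(cfg$lon_range)
  lat_split <- stats::median(lat)
  # nuisance columns: intercept-free latitude/longitude trends and the
  # north/south step, the directions neutral structure lives along
  nuis_at <- function(ln, lt)
    cbind((lt - lat0) / diff(cfg$lat_range),
          (ln - lon0) / diff(cfg$lon_range),
          (lt >= lat_split) - 0.5)
  Braw <- vapply(raw, eval_field, numeric(length(lon)), lon, lat)
  N <- nuis_at(lon, lat)
  n_nuis <- ncol(N)
  B <- cbind(Braw, N)
  Cmat <- matrix(0, n_groups, ncol(B))
  for (g in seq_len(n_groups)) {
    prev <- if (g > 1) B %*% t(Cmat[seq_len(g - 1), , drop = FALSE])
      else NULL
    fit <- stats::lm.fit(cbind(1, prev, N), B[, g])
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    Cmat[g, g] <- 1
    if (g > 1)
      Cmat[g, ] <- Cmat[g, ] -
        colSums(cf[1 + seq_len(g - 1)] * Cmat[seq_len(g - 1), , drop = FALSE])
    Cmat[g, n_groups + seq_len(n_nuis)] <-
      Cmat[g, n_groups + seq_len(n_nuis)] - cf[g + seq_len(n_nuis)]
    v <- B %*% Cmat[g, ]
    Cmat[g, ] <- Cmat[g, ] / max(stats::sd(v), 1e-8)
  }
  latent <- list(raw = raw, C = Cmat, nuis_at = nuis_at)
  # the leading (causal-eligible) variables alternate between the two
  # dominant families -- a temperature-like and a precipitation-like
  # syndrome -- the remainder spread over all four families
  vars <- lapply(seq_len(cfg$n_env), function(j) {
    g <- if (j <= max(6L, cfg$n_causal_env)) ((j - 1L) %% 2L) + 1L
      else ((j - 1L) %% n_groups) + 1L
    list(group = g,
         trend_lat = stats::runif(1, 0.1, 0.4) * sample(c(-1, 1), 1),
         trend_lon = stats::runif(1, -0.15, 0.15),
         w_latent = stats::runif(1, 0.9, 1.3),
         own = make_field(),
         w_own = if (j <= max(6L, cfg$n_causal_env))
           stats::runif(1, 0.08, 0.18) else stats::runif(1, 0.45, 0.75),
         center = stats::runif(1, -5, 25),
         scale = stats::runif(1, 1, 10))
  })
  # per-model anomaly fields: a shared component plus model-specific noise
  delta <- list(shared = lapply(seq_len(cfg$n_env), function(j) make_field()),
                models = lapply(cfg$future_models, function(m)
                  lapply(seq_len(cfg$n_env), function(j) make_field())))
  names(delta$models) <- cfg$future_models
  list(latent = latent, vars = vars, delta = delta, n_groups = n_groups)
}

# adjusted family-field values at arbitrary sites
eval_latent <- function(model, cfg, g, lon, lat) {
  B <- cbind(vapply(model$latent$raw, eval_field, numeric(length(lon)),
                    lon, lat),
             model$latent$nuis_at(lon, lat))
  as.numeric(B %*% model$latent$C[g, ])
}

eval_env <- function(model, cfg, lon, lat, site_ids,
                     period = "current", mdl = "none", scenario = "none") {
  lat0 <- mean(cfg$lat_range); lon0 <- mean(cfg$lon_range)
  vals <- vapply(seq_len(cfg$n_env), function(j) {
    v <- model$vars[[j]]
    raw <- v$trend_lat * (lat - lat0) / diff(cfg$lat_range) * 3 +
      v$trend_lon * (lon - lon0) / diff(cfg$lon_range) * 3 +
      v$w_latent * eval_latent(model, cfg, v$group, lon, lat) +
      v$w_own * eval_field(v$own, lon, lat)
    v$center + v$scale * raw
  }, numeric(length(lon)))
  if (length(lon) == 1L) vals <- matrix(vals, nrow = 1)
  if (period == "future") {
    sc <- cfg$delta_scale[[scenario]]
    for (j in seq_len(cfg$n_env)) {
      v <- model$vars[[j]]
      d <- 0.7 * eval_field(model$delta$shared[[j]], lon, lat) +
        0.3 * eval_field(model$delta$models[[mdl]][[j]], lon, lat) + 1
      vals[, j] <- vals[, j] + sc * v$scale * 0.5 * d
    }
  }
  dimnames(vals) <- list(site_ids, paste0("BIO", seq_len(cfg$n_env)))
  env_matrix(vals, period = period, model = mdl,
             scenario = if (period == "future") scenario else "none",
             window = if (period == "future") cfg$window else "")
}

#' Generate a synthetic landscape-genomics dataset
#'
#' Produces all inputs the analysis pipeline consumes, plus a truth table
#' for parameter-recovery tests. Populations are placed uniformly in the
#' bounding box and split into a northern and a southern ancestry group at
#' the median latitude. Neutral locus frequencies follow a hierarchical
#' Balding-Nichols model (ancestral -> group -> population, differentiation
#' `drift_F` at each level), which yields isolation by distance through the
#' latitudinal group split. Adaptive locus frequencies follow
#' `logit(p) = alpha + beta * z(e_causal) + noise`. Genotypes are drawn as
#' `Binomial(2, p)` and masked at `missing_rate`. Future environments add
#' smooth anomaly fields scaled per scenario, with a component shared
#' across climate models.
#'
#' @param cfg a [sim_config].
#' @param dir optional directory; when given, all outputs are also written
#'   as VCF/TSV files via the package writers.
#' @return list with `variants`, `genotypes`, `popmap`, `env_current`,
#'   `env_future` (list named model.scenario), and `truth` (data frame of
#'   adaptive loci with causal variable, intercept and slope; population
#'   groups and per-locus ancestral allele as attributes).
#' @export
simulate_landscape <- function(cfg = sim_config(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  pops <- sprintf("P%02d", seq_len(cfg$n_pops))
  lon <- stats::runif(cfg$n_pops, cfg$lon_range[1], cfg$lon_range[2])
  lat <- stats::runif(cfg$n_pops, cfg$lat_range[1], cfg$lat_range[2])
  group <- ifelse(lat >= stats::median(lat), "north", "south")

  env_model <- build_env_model(cfg, lon, lat)
  env_cur <- eval_env(env_model, cfg, lon, lat, pops)
  env_fut <- list()
  for (m in cfg$future_models) for (sc in cfg$scenarios)
    env_fut[[paste(m, sc, sep = ".")]] <-
      eval_env(env_model, cfg, lon, lat, pops,
               period = "future", mdl = m, scenario = sc)

  n_loci <- cfg$n_neutral + cfg$n_adaptive
  vid <- sprintf("var%05d", seq_len(n_loci))
  adaptive_ids <- sample(vid, cfg$n_adaptive)
  is_adapt <- vid %in% adaptive_ids

  # neutral: hierarchical Balding-Nichols
  bn <- function(p, F) {
    shape <- (1 - F) / F
    stats::rbeta(length(p), shape * p, shape * (1 - p))
  }
  p_anc <- stats::runif(n_loci, 0.1, 0.9)
  p_grp <- cbind(north = bn(p_anc, cfg$group_F),
                 south = bn(p_anc, cfg$group_F))
  P <- matrix(NA_real_, cfg$n_pops, n_loci, dimnames = list(pops, vid))
  for (i in seq_len(cfg$n_pops))
    P[i, ] <- bn(p_grp[, group[i]], cfg$drift_F)

  # adaptive: clinal in a causal environmental variable
  causal_vars <- paste0("BIO", seq_len(cfg$n_causal_env))
  # uneven allocation of loci over causal variables (adaptive variants
  # cluster on a few dominant climate axes, e.g. precipitation-heavy)
  causal_w <- rep_len(c(0.30, 0.20, 0.15, 0.10, 0.15, 0.10),
                      cfg$n_causal_env)
  causal_w <- causal_w / sum(causal_w)
  alloc <- rep(causal_vars, times = round(causal_w * cfg$n_adaptive))
  truth <- data.frame(variant_id = adaptive_ids,
                      causal_var = rep_len(alloc, cfg$n_adaptive),
                      alpha = logit(stats::runif(cfg$n_adaptive, 0.3, 0.7)),
                      beta = sample(c(-1, 1), cfg$n_adaptive, TRUE) *
                        stats::runif(cfg$n_adaptive, cfg$beta_range[1],
                                     cfg$beta_range[2]),
                      stringsAsFactors = FALSE)
  Ez <- scale(unclass(env_cur))
  for (k in seq_len(cfg$n_adaptive)) {
    e <- Ez[, truth$causal_var[k]]
    P[, truth$variant_id[k]] <-
      inv_logit(truth$alpha[k] + truth$beta[k] * e +
                  stats::rnorm(cfg$n_pops, 0, cfg$env_noise_sd))
  }

  # genotypes
  n_ind <- cfg$n_pops * cfg$n_ind_per_pop
  ind_pop <- rep(pops, each = cfg$n_ind_per_pop)
  inds <- paste0(ind_pop, "_", sprintf("i%02d", rep(seq_len(cfg$n_ind_per_pop),
                                                    cfg$n_pops)))
  G <- matrix(stats::rbinom(n_ind * n_loci, 2L,
                            P[rep(seq_len(cfg$n_pops),
                                  each = cfg$n_ind_per_pop), ]),
              nrow = n_ind, dimnames = list(inds, vid))
  if (cfg$missing_rate > 0)
    G[stats::runif(length(G)) < cfg$missing_rate] <- NA_integer_

  # variant metadata: classes, annotation, ancestral = REF
  vclass <- rep("SNP", n_loci)
  n_sv <- round(cfg$sv_fraction * n_loci)
  n_indel <- round(cfg$indel_fraction * n_loci)
  reclass <- sample(n_loci, n_sv + n_indel)
  vclass[reclass[seq_len(n_sv)]] <- "SV"
  if (n_indel > 0) vclass[reclass[n_sv + seq_len(n_indel)]] <- "INDEL"
  func <- sample(names(cfg$func_class_probs), n_loci, TRUE,
                 prob = cfg$func_class_probs)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  alt[vclass == "INDEL"] <- paste0(ref[vclass == "INDEL"],
                                   strrep("A", 3))
  alt[vclass == "SV"] <- paste0(ref[vclass == "SV"], strrep("ACGT", 20))
  variants <- variant_table(vid,
                            chrom = paste0("LG",
                                           sprintf("%02d", ((seq_len(n_loci) - 1L) %% 19L) + 1L)),
                            pos = seq_len(n_loci) * 137L + 1L,
                            vclass = vclass, ref_allele = ref,
                            alt_allele = alt,
                            ancestral = "ref", func_class = func)

  popmap <- population_map(data.frame(individual_id = inds,
                                      population_id = ind_pop,
                                      stringsAsFactors = FALSE),
                           data.frame(population_id = pops, lon = lon,
                                      lat = lat, stringsAsFactors = FALSE))
  attr(truth, "pop_group") <- stats::setNames(group, pops)
  attr(truth, "pop_freq") <- P
  attr(truth, "ancestral") <- stats::setNames(rep("ref", n_loci), vid)

  out <- list(variants = variants, genotypes = G, popmap = popmap,
              env_current = env_cur, env_future = env_fut, truth = truth,
              env_model = env_model, cfg = cfg)
  if (!is.null(dir)) write_landscape(out, dir)
  out
}

write_landscape <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(sim$variants, sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_table_tsv(sim$variants, file.path(dir, "variants.tsv"))
  write_table_tsv(sim$popmap, file.path(dir, "populations.tsv"))
  write_table_tsv(sim$env_current, file.path(dir, "env_current_none_none.tsv"))
  for (nm in names(sim$env_future)) {
    e <- sim$env_future[[nm]]
    write_table_tsv(e, file.path(dir, sprintf("env_future_%s_%s.tsv",
                                              attr(e, "model"),
                                              attr(e, "scenario"))))
  }
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Inflate derived-allele burden in designated populations
#'
#' Planting tool for genetic-load recovery tests: the genotypes of the
#' designated populations are redrawn at deleterious and loss-of-function
#' sites with the population ALT (= derived) allele frequency multiplied by
#' `factor` (capped at 1). `factor = 1` returns the input unchanged. The
#' planted population ordering is recorded for truth-table checks.
#'
#' @param sim result of [simulate_landscape()].
#' @param populations population ids to burden, in decreasing planted-load
#'   order; the inflation factor decays geometrically along the list so the
#'   ordering is strict.
#' @param factor multiplier (>= 1) applied to the first population.
#' @return `sim` with modified `genotypes` and a `load_truth` element.
#' @export
plant_load_gradient <- function(sim, populations, factor = 2) {
  if (factor < 1) stop("factor must be >= 1")
  probs <- sim$cfg$func_class_probs
  if (any(probs[c("deleterious", "LOF")] == 0))
    stop("func_class_probs assigns zero mass to deleterious or LOF sites")
  stopifnot(all(populations %in% sim$popmap$populations$population_id))
  fac <- 1 + (factor - 1) * 0.6^(seq_along(populations) - 1)
  sim$load_truth <- data.frame(population_id = populations, factor = fac,
                               stringsAsFactors = FALSE)
  if (factor == 1) return(sim)
  set.seed(sim$cfg$seed + 777L)
  sites <- sim$variants$variant_id[sim$variants$func_class %in%
                                     c("deleterious", "LOF")]
  P <- attr(sim$truth, "pop_freq")
  ind_pop <- sim$popmap$individuals$population_id[
    match(rownames(sim$genotypes), sim$popmap$individuals$individual_id)]
  for (j in seq_along(populations)) {
    rows <- which(ind_pop == populations[j])
    p_new <- pmin(P[populations[j], sites] * fac[j], 1)
    g <- matrix(stats::rbinom(length(rows) * length(sites), 2L,
                              rep(p_new, each = length(rows))),
                nrow = length(rows))
    miss <- is.na(sim$genotypes[rows, sites])
    g[miss] <- NA_integer_
    sim$genotypes[rows, sites] <- g
  }
  sim
}

#' Lay an environmental grid over the simulated range
#'
#' Evaluates the same environmental field functions used for population
#' sites at the centers of a regular lon/lat lattice covering the
#' simulation bounding box, for the current climate and every
#' model x scenario projection. Population sites are snapped to their
#' nearest cell.
#'
#' @param sim result of [simulate_landscape()].
#' @param resolution cells per axis (>= 2).
#' @return list with `coords` (cell centers), `current` (env_matrix),
#'   `future` (named list of env_matrix), and `pop_cell` (named integer:
#'   nearest cell per population).
#' @export
make_grid <- function(sim, resolution = 20L) {
  stopifnot(resolution >= 2)
  cfg <- sim$cfg
  cx <- seq(cfg$lon_range[1], cfg$lon_range[2], length.out = resolution + 1L)
  cy <- seq(cfg$lat_range[1], cfg$lat_range[2], length.out = resolution + 1L)
  cx <- (cx[-1] + cx[-length(cx)]) / 2
  cy <- (cy[-1] + cy[-length(cy)]) / 2
  cells <- expand.grid(lon = cx, lat = cy, KEEP.OUT.ATTRS = FALSE)
  ids <- sprintf("cell%05d", seq_len(nrow(cells)))
  cur <- eval_env(sim$env_model, cfg, cells$lon, cells$lat, ids)
  fut <- list()
  for (m in cfg$future_models) for (sc in cfg$scenarios)
    fut[[paste(m, sc, sep = ".")]] <-
      eval_env(sim$env_model, cfg, cells$lon, cells$lat, ids,
               period = "future", mdl = m, scenario = sc)
  pc <- sim$popmap$populations
  pop_cell <- vapply(seq_len(nrow(pc)), function(i)
    which.min((cells$lon - pc$lon[i])^2 + (cells$lat - pc$lat[i])^2), 1L)
  names(pop_cell) <- pc$population_id
  list(coords = cbind(lon = cells$lon, lat = cells$lat), current = cur,
       future = fut, pop_cell = pop_cell)
}
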