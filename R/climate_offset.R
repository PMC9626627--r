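# ---- RONA and genomic offsets -------------------------------------------

#' Risk of non-adaptedness (RONA)
#'
#' For each environmentally associated locus and variable, a linear
#' regression of population allele frequency on the current value of the
#' variable is fitted across populations; RONA for a population is the
#' absolute difference between the fitted frequency at the projected
#' future value and at the current value (fitted values truncated to
#' `[0,1]` before differencing — without truncation this is
#' `|b| * |delta_e|`). Per-locus values are averaged over the variable's
#' associated loci, weighted by each regression's R-squared (or equally
#' when `weight_by_r2 = FALSE`), and summarized as mean and standard
#' error across climate models per scenario.
#'
#' @param freqs an [allele_freq_matrix] over all populations.
#' @param hits_by_variable named list: variable -> character vector of
#'   associated locus ids. Variables with no associated locus are skipped
#'   with a warning.
#' @param env_cur populations x variables current `env_matrix`.
#' @param env_fut list of future `env_matrix` objects (one per
#'   model x scenario, tagged via their attributes).
#' @param weight_by_r2 weight loci by regression R-squared (default TRUE).
#' @return list of class `"rona_table"`: `per_model` (data frame:
#'   population, variable, model, scenario, rona), `summary` (population,
#'   variable, scenario, mean, se over models), `regressions` (locus-level
#'   intercept/slope/R2 per variable).
#' @export
rona <- function(freqs, hits_by_variable, env_cur, env_fut,
                 weight_by_r2 = TRUE) {
  pops <- rownames(freqs$freq)
  if (length(pops) < 3) stop("need at least 3 populations")
  stopifnot(identical(rownames(env_cur), pops))
  vars <- names(hits_by_variable)
  empty <- lengths(hits_by_variable) == 0
  if (any(empty)) {
    warning("no associated loci for variable(s): ",
            paste(vars[empty], collapse = ", "), "; skipped")
    vars <- vars[!empty]
  }
  regs <- list()
  per_model <- list()
  for (v in vars) {
    loci <- intersect(hits_by_variable[[v]], colnames(freqs$freq))
    e <- unclass(env_cur)[, v]
    fit_tab <- t(vapply(loci, function(l) {
      y <- freqs$freq[, l]
      ok <- !is.na(y)
      f <- stats::lm.fit(cbind(1, e[ok]), y[ok])
      b <- f$coefficients
      ssr <- sum(f$residuals^2)
      sst <- sum((y[ok] - mean(y[ok]))^2)
      c(a = b[1], b = b[2], r2 = if (sst > 0) 1 - ssr / sst else 0)
    }, c(a = 0, b = 0, r2 = 0)))
    colnames(fit_tab) <- c("a", "b", "r2")
    regs[[v]] <- data.frame(variable = v, locus = loci, fit_tab,
                            row.names = NULL, stringsAsFactors = FALSE)
    w <- if (weight_by_r2) pmax(fit_tab[, "r2"], 0) else
      rep(1, length(loci))
    if (sum(w) == 0) w <- rep(1, length(loci))
    for (nm in names(env_fut)) {
      ef <- env_fut[[nm]]
      e_f <- unclass(ef)[pops, v]
      # fitted frequencies truncated to [0,1] before differencing
      p_cur <- pmin(pmax(outer(e, fit_tab[, "b"]) +
                           rep(fit_tab[, "a"], each = length(e)), 0), 1)
      p_fut <- pmin(pmax(outer(e_f, fit_tab[, "b"]) +
                           rep(fit_tab[, "a"], each = length(e_f)), 0), 1)
      rn <- abs(p_fut - p_cur) %*% w / sum(w)
      per_model[[length(per_model) + 1L]] <-
        data.frame(population_id = pops, variable = v,
                   model = attr(ef, "model"),
                   scenario = attr(ef, "scenario"),
                   rona = as.numeric(rn), stringsAsFactors = FALSE)
    }
  }
  pm <- do.call(rbind, per_model)
  key <- interaction(pm$population_id, pm$variable, pm$scenario,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(pm, key), function(d)
    data.frame(population_id = d$population_id[1], variable = d$variable[1],
               scenario = d$scenario[1], mean = mean(d$rona),
               se = stats::sd(d$rona) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(per_model = pm, summary = summ,
                 regressions = do.call(rbind, regs),
                 weight_by_r2 = weight_by_r2),
            class = "rona_table")
}

#' @export
print.rona_table <- function(x, ...) {
  cat("RONA table:", length(unique(x$per_model$population_id)),
      "populations,", length(unique(x$per_model$variable)), "variables,",
      length(unique(x$per_model$model)), "models,",
      length(unique(x$per_model$scenario)), "scenarios\n")
  invisible(x)
}

offset_dist <- function(Tcur, Tfut) sqrt(rowSums((Tcur - Tfut)^2))

#' Local genomic offset
#'
#' Euclidean distance, in turnover-transformed (genomic composition)
#' space, between a site's current and projected future climate.
#'
#' @param model a `"turnover_model"`.
#' @param env_cur,env_fut aligned sites x predictors matrices (same cells).
#' @return numeric vector of per-site offsets (>= 0).
#' @export
local_offset <- function(model, env_cur, env_fut) {
  stopifnot(nrow(env_cur) == nrow(env_fut))
  offset_dist(predict(model, env_cur), predict(model, env_fut))
}

#' Forward genomic offset under dispersal caps
#'
#' For each population and maximum dispersal distance `d`, the minimum
#' offset between the population's transformed current climate and the
#' transformed future climate of any grid cell within `d` km
#' (great-circle). An empty reachable set yields `NA` with a warning.
#'
#' @param model a `"turnover_model"`.
#' @param env_pop_cur populations x predictors current climate.
#' @param pop_coords populations x 2 matrix (lon, lat).
#' @param grid_fut cells x predictors future climate.
#' @param grid_coords cells x 2 matrix (lon, lat).
#' @param d_max numeric vector of caps in km; `Inf` = unlimited.
#' @return matrix populations x caps of forward offsets; columns named
#'   `forward_<d>`.
#' @export
forward_offset <- function(model, env_pop_cur, pop_coords, grid_fut,
                           grid_coords, d_max = c(100, 250, 500, 1000, Inf)) {
  Tp <- predict(model, env_pop_cur)
  Tg <- predict(model, grid_fut)
  np <- nrow(Tp)
  out <- matrix(NA_real_, np, length(d_max),
                dimnames = list(rownames(env_pop_cur),
                                paste0("forward_",
                                       ifelse(is.infinite(d_max), "inf",
                                              d_max))))
  for (i in seq_len(np)) {
    d2 <- offset_dist(matrix(Tp[i, ], nrow(Tg), ncol(Tg), byrow = TRUE), Tg)
    km <- geosphere::distHaversine(pop_coords[i, , drop = FALSE],
                                   grid_coords, r = 6371.0088)
    for (j in seq_along(d_max)) {
      reach <- km <= d_max[j]
      if (!any(reach)) {
        warning("population ", rownames(out)[i],
                ": no grid cell within ", d_max[j], " km")
      } else out[i, j] <- min(d2[reach])
    }
  }
  out
}

#' Reverse genomic offset
#'
#' For each grid cell, the minimum offset between the cell's transformed
#' future climate and the transformed current climate of any contemporary
#' population: how well the best-matched existing population pre-adapts to
#' that location's future.
#'
#' @inheritParams forward_offset
#' @return numeric vector of per-cell reverse offsets.
#' @export
reverse_offset <- function(model, env_pop_cur, grid_fut) {
  Tp <- predict(model, env_pop_cur)
  Tg <- predict(model, grid_fut)
  if (!nrow(Tp)) stop("need at least one population")
  apply(Tg, 1, function(g)
    min(sqrt(colSums((t(Tp) - g)^2))))
}

#' Average offsets or RONA across climate models
#'
#' Arithmetic mean and standard error per cell/population across the
#' per-model inputs, plus the pairwise Pearson correlation matrix of the
#' per-model values.
#'
#' @param per_model named list of aligned numeric vectors (or matrices
#'   with identical dimnames), one per climate model.
#' @return list: `mean`, `se`, `correlations`.
#' @export
average_models <- function(per_model) {
  stopifnot(length(per_model) >= 1)
  m1 <- per_model[[1]]
  for (m in per_model[-1])
    if (!identical(dim(as.matrix(m)), dim(as.matrix(m1))) ||
        !identical(names(m), names(m1)))
      stop("mismatched indices across models")
  arr <- vapply(per_model, function(m) as.numeric(m),
                numeric(length(as.numeric(m1))))
  mn <- rowMeans(arr)
  se <- apply(arr, 1, stats::sd) / sqrt(ncol(arr))
  if (is.matrix(m1)) {
    mn <- matrix(mn, nrow(m1), ncol(m1), dimnames = dimnames(m1))
    se <- matrix(se, nrow(m1), ncol(m1), dimnames = dimnames(m1))
  } else names(mn) <- names(se) <- names(m1)
  cors <- suppressWarnings(stats::cor(arr))
  cors[!is.finite(cors)] <- 1   # constant inputs: perfectly concordant
  dimnames(cors) <- list(names(per_model), names(per_model))
  list(mean = mn, se = se, correlations = cors)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' RGB composite of the three offset formulations
#'
#' Min-max scales each of the local, forward (unlimited dispersal mapped
#' onto the grid) and reverse offsets to `[0, 255]` over the grid
#' (rounded half-up) and stacks them as the red, green and blue channels;
#' bright (white) cells are high on all three metrics. A constant metric
#' maps to 0 everywhere.
#'
#' @param local,forward,reverse aligned per-cell numeric vectors.
#' @return integer matrix cells x 3 with columns `R`, `G`, `B`.
#' @export
rgb_composite <- function(local, forward, reverse) {
  stopifnot(length(local) == length(forward),
            length(local) == length(reverse))
  chan <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(0L, length(x)))
    as.integer(round_half_up((x - rng[1]) / diff(rng) * 255))
  }
  out <- cbind(R = chan(local), G = chan(forward), B = chan(reverse))
  rownames(out) <- names(local)
  out
}
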