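# ---- end-to-end pipeline ------------------------------------------------

#' Default run configuration
#'
#' Assembles the stage parameters of the full pipeline, mirroring every
#' operation default: MAF filter, LFMM latent factors and FDR, RDA cutoff,
#' variable-pruning correlation cap, Mantel permutations, turnover-forest
#' size, dispersal caps, and the simulation settings. A YAML file with the
#' same field names can be loaded with [read_run_config()]; values in
#' `overrides` take precedence over the file, which takes precedence over
#' defaults.
#'
#' @param seed master seed; stage seeds derive from it.
#' @param out_dir output directory.
#' @param ... named overrides of any default field.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("geoffset_run_"),
                       ...) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              maf = 0.10, K = 3L, fdr = 0.05, sd_cutoff = 3,
              r_max = 0.6, k_axes = 3L, n_perm = 999L,
              n_trees = 500L, d_max = c(100, 250, 500, 1000, Inf),
              grid_resolution = 15L, n_fst_draws = 1000L,
              ld_window = 50L, ld_step = 10L, ld_r2 = 0.2,
              sim = list())
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file mirroring the `run_config` field names.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(y, list(...)))
}

stage_log <- function(dir, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste(..., collapse = " "))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

PIPELINE_STAGES <- c("simulate", "freqs", "fst", "pi", "pca", "gea",
                     "ibd_ibe", "turnover", "rona", "offset", "load")

#' Run the analysis pipeline end to end
#'
#' Executes the stages in dependency order on a synthetic landscape:
#' simulate, allele frequencies + MAF filter, F_ST (global, pairwise,
#' adaptive-vs-random), nucleotide diversity, LD pruning + PCA, the two
#' association scans and their core intersection, IBD/IBE Mantel tests and
#' variance partitioning, the turnover model, RONA, the three offset
#' formulations with model averaging and the RGB composite, and the
#' genetic-load proxies with offset correlations. Every stage writes its
#' TSV/JSON artifacts into `cfg$out_dir` and a manifest records
#' parameters, seeds and file checksums; a rerun with the identical
#' configuration reproduces identical artifacts.
#'
#' @param cfg a [run_config()].
#' @param stages subset of stages to run (dependencies must already have
#'   run into the same state object or an error names the missing stage).
#' @param state optionally, the state list returned by a previous partial
#'   run.
#' @return invisibly, the state list holding every intermediate object;
#'   element `manifest` is the manifest data frame.
#' @export
run_pipeline <- function(cfg = run_config(), stages = PIPELINE_STAGES,
                         state = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(cfg$out_dir, "pipeline.log")))
    file.remove(file.path(cfg$out_dir, "pipeline.log"))
  st <- if (is.null(state)) list(cfg = cfg) else state
  need <- function(what, stage) {
    if (is.null(st[[what]]))
      stop("stage '", stage, "' requires '", what,
           "'; run its producing stage first")
  }
  d <- cfg$out_dir

  if ("simulate" %in% stages) {
    st$sim <- simulate_landscape(do.call(sim_config,
                                         c(list(seed = cfg$seed), cfg$sim)),
                                 dir = file.path(d, "data"))
    st$grid <- make_grid(st$sim, resolution = cfg$grid_resolution)
    stage_log(d, "simulate", "loci:", ncol(st$sim$genotypes),
              "individuals:", nrow(st$sim$genotypes),
              "grid cells:", nrow(st$grid$coords))
  }

  if ("freqs" %in% stages) {
    need("sim", "freqs")
    G_f <- maf_filter(st$sim$genotypes, cfg$maf)
    st$kept <- attr(G_f, "kept")
    st$G <- G_f
    st$freqs <- allele_frequencies(G_f, st$sim$popmap)
    write_table_tsv(st$freqs, file.path(d, "freqs.tsv"))
    stage_log(d, "freqs", "variants in:", ncol(st$sim$genotypes),
              "kept after MAF >", cfg$maf, ":", length(st$kept))
  }

  if ("fst" %in% stages) {
    need("G", "fst")
    st$fst <- weir_cockerham_fst(st$G, st$sim$popmap, pairwise = TRUE)
    pw <- st$fst$pairwise
    idx <- which(upper.tri(pw), arr.ind = TRUE)
    write_tsv(data.frame(pop_i = rownames(pw)[idx[, 1]],
                         pop_j = colnames(pw)[idx[, 2]],
                         theta = pw[idx]),
              file.path(d, "fst.tsv"))
    stage_log(d, "fst", "global theta:", format(st$fst$theta, digits = 4))
  }

  if ("pi" %in% stages) {
    need("sim", "pi")
    st$pi <- nucleotide_diversity(st$sim$genotypes, st$sim$popmap,
                                  denominator_sites =
                                    ncol(st$sim$genotypes))
    write_tsv(st$pi, file.path(d, "pi.tsv"))
    stage_log(d, "pi", "mean pi:", format(mean(st$pi$pi), digits = 4))
  }

  if ("pca" %in% stages) {
    need("G", "pca")
    st$pruned <- ld_prune(st$G, cfg$ld_window, cfg$ld_step, cfg$ld_r2)
    st$pca <- pca_structure(st$G[, st$pruned, drop = FALSE],
                            st$sim$popmap, k = 3L)
    write_tsv(data.frame(population_id = rownames(st$pca$pop_scores),
                         st$pca$pop_scores),
              file.path(d, "pca_scores.tsv"))
    stage_log(d, "pca", "pruned:", ncol(st$G) - length(st$pruned),
              "kept:", length(st$pruned))
  }

  if ("gea" %in% stages) {
    need("G", "gea"); need("freqs", "gea")
    E_ind <- env_for_individuals(st$sim$env_current, st$sim$popmap,
                                 rownames(st$G))
    st$lfmm <- lfmm_scan(st$G, E_ind, K = cfg$K, fdr = cfg$fdr)
    # variable importance for pruning comes from a turnover forest on the
    # candidate loci, echoing the forest-ranking-then-prune convention
    lh <- intersect(st$lfmm$hits, colnames(st$freqs$freq))
    imp0 <- if (length(lh) >= 2) tryCatch({
      frh <- allele_freq_matrix(st$freqs$freq[, lh, drop = FALSE],
                                st$freqs$n_alleles[, lh, drop = FALSE])
      variable_importance(fit_turnover(frh, st$sim$env_current,
                                       n_trees = cfg$n_trees,
                                       seed = cfg$seed + 1L))$predictor
    }, error = function(e) colnames(st$sim$env_current))
    else colnames(st$sim$env_current)
    st$kept_vars <- select_env_variables(st$sim$env_current, imp0,
                                         r_max = cfg$r_max)
    env_kept <- st$sim$env_current[, st$kept_vars, drop = FALSE]
    st$rda <- rda_scan(st$freqs,
                       env_matrix(env_kept, period = "current"),
                       sd_cutoff = cfg$sd_cutoff, k_axes = cfg$k_axes)
    st$gea <- intersect_core(st$lfmm, st$rda, st$sim$variants)
    write_tsv(st$gea$table, file.path(d, "gea_hits.tsv"))
    stage_log(d, "gea", "lfmm hits:", length(st$lfmm$hits),
              "rda hits:", length(st$rda$hits),
              "core:", length(st$gea$core))
  }

  if ("ibd_ibe" %in% stages) {
    need("fst", "ibd_ibe"); need("gea", "ibd_ibe")
    st$dists <- distance_matrices(st$sim$popmap, st$fst,
                                  st$sim$env_current)
    st$mantel_ibd <- mantel_test(st$dists$linearized_fst,
                                 st$dists$geographic_km,
                                 n_perm = cfg$n_perm, seed = cfg$seed)
    st$mantel_ibe <- partial_mantel(st$dists$linearized_fst,
                                    st$dists$environmental,
                                    st$dists$geographic_km,
                                    n_perm = cfg$n_perm, seed = cfg$seed)
    mt <- data.frame(test = c("IBD", "IBE_partial"),
                     r = c(st$mantel_ibd$r, st$mantel_ibe$r),
                     p = c(st$mantel_ibd$p_value, st$mantel_ibe$p_value),
                     n_perm = cfg$n_perm)
    write_tsv(mt, file.path(d, "mantel.tsv"))
    core <- intersect(st$gea$core, colnames(st$freqs$freq))
    if (length(core) >= 2) {
      fr_core <- allele_freq_matrix(st$freqs$freq[, core, drop = FALSE],
                                    st$freqs$n_alleles[, core, drop = FALSE])
      # structure proxies for partitioning come from the pruned neutral
      # background (candidate loci excluded)
      bg <- setdiff(st$pruned, st$lfmm$hits)
      pca_bg <- pca_structure(st$G[, bg, drop = FALSE], st$sim$popmap,
                              k = 3L)
      st$varpart <- partial_rda_partition(
        fr_core,
        unclass(st$sim$env_current)[, st$kept_vars, drop = FALSE],
        as.matrix(st$sim$popmap$populations[, c("lon", "lat")]),
        pca_bg$pop_scores)
      write_tsv(data.frame(component = names(st$varpart$fractions),
                           fraction = st$varpart$fractions),
                file.path(d, "varpart.tsv"))
    }
    stage_log(d, "ibd_ibe", "IBD r:", format(st$mantel_ibd$r, digits = 3),
              "IBE partial r:", format(st$mantel_ibe$r, digits = 3))
  }

  if ("turnover" %in% stages) {
    need("gea", "turnover")
    core <- intersect(st$gea$core, colnames(st$freqs$freq))
    if (length(core) < 2) {
      # fall back to the wider candidate set when the intersection is
      # too small to model
      core <- intersect(st$lfmm$hits, colnames(st$freqs$freq))
      stage_log(d, "turnover",
                "core set < 2 loci; falling back to the LFMM hit set")
    }
    if (length(core) < 2) stop("turnover requires >= 2 candidate loci")
    fr_core <- allele_freq_matrix(st$freqs$freq[, core, drop = FALSE],
                                  st$freqs$n_alleles[, core, drop = FALSE])
    st$turnover <- fit_turnover(fr_core, st$sim$env_current,
                                n_trees = cfg$n_trees, seed = cfg$seed)
    jsonlite::write_json(
      list(importance = as.list(st$turnover$importance),
           r2 = as.list(st$turnover$r2),
           curves = st$turnover$curves),
      file.path(d, "turnover.json"), auto_unbox = TRUE, digits = NA)
    stage_log(d, "turnover", "loci:", length(st$turnover$r2),
              "dropped:", length(st$turnover$dropped),
              "top:", variable_importance(st$turnover)$predictor[1])
  }

  if ("rona" %in% stages) {
    need("gea", "rona")
    hit_vars <- lapply(st$lfmm$hit_variables, identity)
    vars <- unique(unlist(hit_vars))
    hits_by_var <- lapply(stats::setNames(vars, vars), function(v)
      intersect(names(Filter(function(h) v %in% h, hit_vars)),
                colnames(st$freqs$freq)))
    st$rona <- rona(st$freqs, hits_by_var, st$sim$env_current,
                    st$sim$env_future)
    write_tsv(st$rona$summary, file.path(d, "rona.tsv"))
    stage_log(d, "rona", "variables:",
              length(unique(st$rona$summary$variable)))
  }

  if ("offset" %in% stages) {
    need("turnover", "offset")
    st$offsets <- compute_offsets(st$turnover, st$sim, st$grid,
                                  d_max = cfg$d_max)
    for (sc in st$sim$cfg$scenarios) {
      o <- st$offsets[[sc]]
      write_tsv(data.frame(cell = rownames(st$grid$current),
                           lon = st$grid$coords[, "lon"],
                           lat = st$grid$coords[, "lat"],
                           local = o$local$mean,
                           reverse = o$reverse$mean, o$rgb),
                file.path(d, paste0("offsets_", sc, ".tsv")))
    }
    stage_log(d, "offset", "scenarios:",
              paste(names(st$offsets), collapse = ", "))
  }

  if ("load" %in% stages) {
    need("sim", "load")
    st$load <- load_ratios(st$sim$genotypes, st$sim$popmap,
                           st$sim$variants)
    st$svb <- sv_burden(st$sim$genotypes, st$sim$popmap, st$sim$variants)
    lt <- merge(merge(st$load, st$svb, by = "population_id"),
                st$pi, by = "population_id")
    write_tsv(lt, file.path(d, "load.tsv"))
    if (!is.null(st$offsets)) {
      sc <- st$sim$cfg$scenarios[length(st$sim$cfg$scenarios)]
      o <- st$offsets[[sc]]
      pm <- st$sim$popmap$populations$population_id
      om <- cbind(local = o$local$mean[st$grid$pop_cell],
                  forward = o$forward$mean[, ncol(o$forward$mean)],
                  reverse = o$reverse$mean[st$grid$pop_cell])
      rownames(om) <- pm
      st$load_corr <- correlate_load_offset(om, lt)
      write_tsv(st$load_corr, file.path(d, "load_offset_corr.tsv"))
    }
    stage_log(d, "load", "populations:", nrow(st$load))
  }

  st$manifest <- write_manifest(cfg, d)
  invisible(st)
}

#' Average offsets over climate models for each scenario
#'
#' Computes local, forward (all dispersal caps) and reverse offsets per
#' climate model on the grid and averages them across models, per
#' scenario, including the RGB composite of the averaged
#' local / forward(unlimited) / reverse channels.
#'
#' @param model a `"turnover_model"`.
#' @param sim a [simulate_landscape()] result.
#' @param grid a [make_grid()] result.
#' @param d_max dispersal caps in km.
#' @return per scenario, a list with `local`, `forward`, `reverse` (each
#'   an [average_models()] result) and `rgb`.
#' @export
compute_offsets <- function(model, sim, grid,
                            d_max = c(100, 250, 500, 1000, Inf)) {
  pops <- sim$popmap$populations
  pop_env <- unclass(sim$env_current)
  pop_xy <- as.matrix(pops[, c("lon", "lat")])
  out <- list()
  for (sc in sim$cfg$scenarios) {
    loc <- fwd <- rev_ <- list()
    for (m in sim$cfg$future_models) {
      fut <- grid$future[[paste(m, sc, sep = ".")]]
      loc[[m]] <- local_offset(model, grid$current, fut)
      fwd[[m]] <- forward_offset(model, pop_env, pop_xy, fut,
                                 grid$coords, d_max = d_max)
      rev_[[m]] <- reverse_offset(model, pop_env, fut)
    }
    avg_loc <- average_models(loc)
    avg_fwd <- average_models(fwd)
    avg_rev <- average_models(rev_)
    # map forward(unlimited) onto the grid via each cell's nearest pop?
    # RGB uses grid-aligned channels: local and reverse are per cell;
    # the forward channel is the unlimited-dispersal forward offset of
    # the population whose snapped cell is nearest each cell.
    fwd_inf <- avg_fwd$mean[, ncol(avg_fwd$mean)]
    cell_pop <- vapply(seq_len(nrow(grid$coords)), function(i)
      which.min((pops$lon - grid$coords[i, "lon"])^2 +
                  (pops$lat - grid$coords[i, "lat"])^2), 1L)
    out[[sc]] <- list(local = avg_loc, forward = avg_fwd,
                      reverse = avg_rev,
                      rgb = rgb_composite(avg_loc$mean,
                                          fwd_inf[cell_pop],
                                          avg_rev$mean))
  }
  out
}

write_manifest <- function(cfg, d) {
  files <- setdiff(list.files(d, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(d, files))
  params <- cfg[setdiff(names(cfg), "out_dir")]
  params$d_max <- ifelse(is.infinite(params$d_max), "inf",
                         as.character(params$d_max))
  manifest <- list(parameters = params,
                   files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Summarize a pipeline run as markdown
#'
#' Reads the artifacts of a completed (or partial) run directory and
#' renders a human-readable markdown report: hit counts by variant class,
#' predictor importance ranking, per-population RONA and offsets, Mantel
#' results and load correlations. Missing artifacts produce warnings and
#' a partial report; regeneration is idempotent.
#'
#' @param dir a [run_pipeline()] output directory.
#' @param path optional file to write the report to.
#' @return the report lines, invisibly.
#' @export
report <- function(dir, path = file.path(dir, "report.md")) {
  ln <- c("# geoffset pipeline report", "")
  add <- function(...) ln <<- c(ln, ...)
  grab <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) { warning("missing artifact: ", f); NULL }
    else read_tsv(fp)
  }
  gea <- grab("gea_hits.tsv")
  if (!is.null(gea)) {
    add("## Association scan", "",
        paste0("- LFMM hits: ", sum(gea$lfmm_hit)),
        paste0("- RDA hits: ", sum(gea$rda_hit)),
        paste0("- Core adaptive variants: ", sum(gea$core_hit)))
    if ("vclass" %in% names(gea) && any(gea$core_hit)) {
      tb <- table(gea$vclass[gea$core_hit])
      add(paste0("- Core by class: ",
                 paste(names(tb), tb, sep = "=", collapse = ", ")))
    }
    if (!any(gea$core_hit)) add("- (zero candidates)")
    add("")
  }
  tv <- file.path(dir, "turnover.json")
  if (file.exists(tv)) {
    imp <- unlist(jsonlite::read_json(tv)$importance)
    imp <- sort(imp, decreasing = TRUE)
    add("## Predictor importance", "",
        paste0(seq_along(imp), ". ", names(imp), " = ",
               signif(imp, 3)), "")
  }
  mt <- grab("mantel.tsv")
  if (!is.null(mt))
    add("## IBD / IBE", "",
        sprintf("- %s: r = %.3f, p = %.4f", mt$test, mt$r, mt$p), "")
  rn <- grab("rona.tsv")
  if (!is.null(rn)) {
    agg <- stats::aggregate(mean ~ scenario, rn, mean)
    add("## RONA (mean over populations and variables)", "",
        sprintf("- %s: %.4f", agg$scenario, agg$mean), "")
  }
  lc <- grab("load_offset_corr.tsv")
  if (!is.null(lc))
    add("## Offset vs load correlations", "",
        sprintf("- %s ~ %s: rho = %.3f, p = %.3f", lc$offset_metric,
                lc$proxy, lc$rho, lc$p_value), "")
  writeLines(ln, path)
  invisible(ln)
}
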