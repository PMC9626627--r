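# ---- genetic-load proxies -----------------------------------------------

derived_dosage <- function(genotypes, variants) {
  anc <- variants$ancestral[match(colnames(genotypes),
                                  variants$variant_id)]
  if (any(anc == "unknown"))
    stop("ancestral allele unknown for ",
         sum(anc == "unknown"), " variant(s)")
  d <- genotypes
  flip <- which(anc == "alt")
  if (length(flip)) d[, flip] <- 2L - d[, flip]
  d
}

#' Per-population genetic-load proxies
#'
#' Counts derived alleles at tolerated, deleterious and loss-of-function
#' sites relative to synonymous sites. In `allele_count` mode (default)
#' the numerator is the summed derived-allele dosage over the
#' population's individuals; in `segregating_variant` mode it is the
#' number of variants at which the derived allele is observed at least
#' once in the population. The derived allele is ALT where
#' `ancestral == "ref"` and REF where `ancestral == "alt"`.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param popmap a [population_map].
#' @param variants a [variant_table] with known ancestral states for the
#'   counted (functional + synonymous) sites.
#' @param mode `"allele_count"` or `"segregating_variant"`.
#' @return data frame of class `"load_table"`: per population the four
#'   counts and the three ratios `tolerated_syn`, `deleterious_syn`,
#'   `lof_syn`.
#' @export
load_ratios <- function(genotypes, popmap, variants,
                        mode = c("allele_count", "segregating_variant")) {
  mode <- match.arg(mode)
  classes <- c("synonymous", "tolerated", "deleterious", "LOF")
  fc <- variants$func_class[match(colnames(genotypes),
                                  variants$variant_id)]
  use <- fc %in% classes
  d <- derived_dosage(genotypes[, use, drop = FALSE],
                      variants[variants$func_class %in% classes &
                                 variants$variant_id %in%
                                 colnames(genotypes)[use], , drop = FALSE])
  fc <- fc[use]
  idx <- match(rownames(genotypes), popmap$individuals$individual_id)
  pop <- factor(popmap$individuals$population_id[idx],
                levels = popmap$populations$population_id)
  counts <- vapply(classes, function(cl) {
    cols <- which(fc == cl)
    if (!length(cols)) return(numeric(nlevels(pop)))
    sub <- d[, cols, drop = FALSE]
    if (mode == "allele_count") {
      rowsum(rowSums(sub, na.rm = TRUE), pop)[, 1]
    } else {
      pres <- rowsum(ifelse(is.na(sub), 0L, sub), pop) > 0
      rowSums(pres)
    }
  }, numeric(nlevels(pop)))
  counts <- matrix(counts, nrow = nlevels(pop),
                   dimnames = list(levels(pop), classes))
  if (any(counts[, "synonymous"] == 0))
    stop("zero synonymous derived-allele count in population(s): ",
         paste(levels(pop)[counts[, "synonymous"] == 0], collapse = ", "))
  out <- data.frame(population_id = levels(pop),
                    synonymous = counts[, "synonymous"],
                    tolerated = counts[, "tolerated"],
                    deleterious = counts[, "deleterious"],
                    lof = counts[, "LOF"],
                    tolerated_syn = counts[, "tolerated"] / counts[, "synonymous"],
                    deleterious_syn = counts[, "deleterious"] / counts[, "synonymous"],
                    lof_syn = counts[, "LOF"] / counts[, "synonymous"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("load_table", "data.frame")
  out
}

#' Structural-variant burden
#'
#' Per individual, the ratio of heterozygous structural variants to
#' heterozygous SNPs; per population, the mean over its individuals.
#' Individuals with no heterozygous SNP are excluded with a warning.
#'
#' @inheritParams load_ratios
#' @return data frame `population_id`, `sv_burden`.
#' @export
sv_burden <- function(genotypes, popmap, variants) {
  vc <- variants$vclass[match(colnames(genotypes), variants$variant_id)]
  if (!any(vc == "SV")) stop("no structural variants in dataset")
  if (!any(vc == "SNP")) stop("no SNPs in dataset")
  het_sv <- rowSums(genotypes[, vc == "SV", drop = FALSE] == 1L,
                    na.rm = TRUE)
  het_snp <- rowSums(genotypes[, vc == "SNP", drop = FALSE] == 1L,
                     na.rm = TRUE)
  keep <- het_snp > 0
  if (!all(keep))
    warning(sum(!keep), " individual(s) with no heterozygous SNP excluded")
  ratio <- het_sv[keep] / het_snp[keep]
  idx <- match(rownames(genotypes)[keep],
               popmap$individuals$individual_id)
  pop <- factor(popmap$individuals$population_id[idx],
                levels = popmap$populations$population_id)
  data.frame(population_id = levels(pop),
             sv_burden = as.numeric(tapply(ratio, pop, mean)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate genomic offsets with load proxies and diversity
#'
#' Spearman rank correlations (average ranks for ties, two-sided p from
#' the t approximation) between each offset metric and each genetic-load
#' proxy / diversity measure across populations.
#'
#' @param offsets data frame or matrix with a row per population and one
#'   column per offset metric (e.g. local, forward, reverse), rownames =
#'   population ids.
#' @param load data frame with `population_id` and proxy columns (e.g. a
#'   [load_ratios()] result merged with [sv_burden()] and
#'   [nucleotide_diversity()]).
#' @param proxies which load columns to correlate (default: all numeric
#'   ratio/burden/diversity columns present).
#' @return data frame `offset_metric`, `proxy`, `rho`, `p_value`
#'   (`NA` for constant vectors).
#' @export
correlate_load_offset <- function(offsets, load,
                                  proxies = intersect(
                                    c("tolerated_syn", "deleterious_syn",
                                      "lof_syn", "sv_burden", "pi"),
                                    colnames(load))) {
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 5) stop("need at least 5 populations")
  ord <- match(rownames(offsets), load$population_id)
  if (anyNA(ord)) stop("offset rownames must be population ids")
  out <- list()
  for (m in colnames(offsets)) for (pr in proxies) {
    x <- offsets[, m]; y <- load[[pr]][ord]
    if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(x) || anyNA(y)) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(offset_metric = m, proxy = pr,
                                          rho = rho, p_value = pv,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
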