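# ---- domain type constructors -------------------------------------------

VCLASS_LEVELS <- c("SNP", "INDEL", "SV")
FUNC_CLASS_LEVELS <- c("synonymous", "tolerated", "deleterious", "LOF",
                       "noncoding", "unknown")
ANCESTRAL_LEVELS <- c("ref", "alt", "unknown")

#' Construct a variant table
#'
#' A data frame describing the variants of a dataset: identifier, genomic
#' coordinate, variant class (SNP, short indel, or structural variant),
#' alleles, ancestral state and functional annotation category.
#'
#' @param variant_id character, unique variant identifiers.
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param vclass one of `"SNP"`, `"INDEL"`, `"SV"` per variant.
#' @param ref_allele,alt_allele allele strings (symbolic ALT such as
#'   `"<DEL>"` is permitted for SVs).
#' @param ancestral `"ref"`, `"alt"` or `"unknown"`: which allele is the
#'   ancestral state (derived-allele counts in the load module depend on it).
#' @param func_class functional annotation category: `"synonymous"`,
#'   `"tolerated"`, `"deleterious"`, `"LOF"`, `"noncoding"` or `"unknown"`.
#' @return A `data.frame` of class `"variant_table"`.
#' @export
variant_table <- function(variant_id, chrom, pos, vclass,
                          ref_allele, alt_allele,
                          ancestral = "unknown", func_class = "unknown") {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id))
    stop("variant_id values must be unique")
  pos <- as.integer(pos)
  if (any(pos < 1L))
    stop("positions must be >= 1")
  n <- length(variant_id)
  chk <- function(x, levels, what) {
    if (!n) return(character())
    x <- as.character(x)
    bad <- setdiff(unique(x), levels)
    if (length(bad))
      stop("invalid ", what, ": ", paste(bad, collapse = ", "))
    rep_len(x, n)
  }
  vclass <- chk(vclass, VCLASS_LEVELS, "vclass")
  ancestral <- chk(ancestral, ANCESTRAL_LEVELS, "ancestral")
  func_class <- chk(func_class, FUNC_CLASS_LEVELS, "func_class")
  bad <- vclass == "SNP" & (nchar(ref_allele) != 1L | nchar(alt_allele) != 1L)
  if (any(bad))
    stop("SNP records must have single-base REF and ALT: ",
         paste(variant_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  out <- data.frame(variant_id = variant_id,
                    chrom = as.character(chrom),
                    pos = pos,
                    vclass = vclass,
                    ref_allele = as.character(ref_allele),
                    alt_allele = as.character(alt_allele),
                    ancestral = ancestral,
                    func_class = func_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Construct a population map
#'
#' Links individuals to populations and populations to sampling coordinates.
#'
#' @param individuals data frame with columns `individual_id`,
#'   `population_id`.
#' @param populations data frame with columns `population_id`, `lon`, `lat`
#'   (decimal degrees).
#' @return list of class `"population_map"` with elements `individuals` and
#'   `populations`.
#' @export
population_map <- function(individuals, populations) {
  stopifnot(all(c("individual_id", "population_id") %in% names(individuals)),
            all(c("population_id", "lon", "lat") %in% names(populations)))
  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$population_id <- as.character(individuals$population_id)
  populations$population_id <- as.character(populations$population_id)
  if (anyDuplicated(individuals$individual_id))
    stop("duplicate individual ids")
  if (anyDuplicated(populations$population_id))
    stop("duplicate population ids")
  miss <- setdiff(individuals$population_id, populations$population_id)
  if (length(miss))
    stop("individuals assigned to unknown populations: ",
         paste(miss, collapse = ", "))
  if (any(abs(populations$lon) > 180) || any(abs(populations$lat) > 90))
    stop("coordinates outside [-180,180] x [-90,90]")
  out <- list(individuals = individuals[, c("individual_id", "population_id")],
              populations = populations[, c("population_id", "lon", "lat")])
  class(out) <- "population_map"
  out
}

#' Construct an environmental matrix
#'
#' Sites-by-variables matrix of environmental predictor values, tagged with
#' the climate period and, for projections, the climate model, emission
#' scenario and time window.
#'
#' @param values numeric matrix, sites in rows (rownames = site ids),
#'   variables in columns (colnames = variable names, e.g. BIO1..BIO19).
#' @param period `"current"` or `"future"`.
#' @param model climate model name, `"none"` for current climate.
#' @param scenario `"none"`, `"SSP126"` or `"SSP370"`.
#' @param window time window label such as `"2061-2080"`, `""` for current.
#' @return numeric matrix of class `"env_matrix"` with metadata attributes.
#' @export
env_matrix <- function(values, period = c("current", "future"),
                       model = "none",
                       scenario = c("none", "SSP126", "SSP370"),
                       window = "") {
  period <- match.arg(period)
  scenario <- match.arg(scenario)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("env_matrix requires site ids as rownames and variable names as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate variable names")
  if (anyNA(values))
    stop("env_matrix must not contain missing values")
  structure(values, class = c("env_matrix", class(values)),
            period = period, model = model, scenario = scenario,
            window = window)
}

#' Construct an allele-frequency matrix
#'
#' Population-by-variant alternate-allele frequencies with the number of
#' successfully genotyped alleles behind every cell.
#'
#' @param freq numeric matrix populations x variants, entries in `[0,1]` or
#'   `NA` where a population has no called genotype.
#' @param n_alleles integer matrix of identical shape: non-missing allele
#'   count per cell.
#' @return list of class `"allele_freq"` with elements `freq`, `n_alleles`.
#' @export
allele_freq_matrix <- function(freq, n_alleles) {
  freq <- as.matrix(freq)
  n_alleles <- as.matrix(n_alleles)
  stopifnot(identical(dim(freq), dim(n_alleles)))
  rng <- range(freq, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("allele frequencies must lie in [0,1]")
  cnt <- freq * n_alleles
  ok <- is.na(cnt) | abs(cnt - round(cnt)) < 1e-9
  if (!all(ok))
    stop("freq * n_alleles must be integral (allele counts)")
  out <- list(freq = freq, n_alleles = n_alleles)
  class(out) <- "allele_freq"
  out
}

#' @export
print.variant_table <- function(x, ...) {
  cat("Variant table:", nrow(x), "variants (",
      sum(x$vclass == "SNP"), "SNP,", sum(x$vclass == "INDEL"), "indel,",
      sum(x$vclass == "SV"), "SV )\n")
  NextMethod()
}

#' @export
print.population_map <- function(x, ...) {
  cat("Population map:", nrow(x$individuals), "individuals in",
      nrow(x$populations), "populations\n")
  invisible(x)
}

#' @export
print.allele_freq <- function(x, ...) {
  cat("Allele-frequency matrix:", nrow(x$freq), "populations x",
      ncol(x$freq), "variants\n")
  invisible(x)
}

# ---- VCF input -----------------------------------------------------------

#' Read genotypes and variant metadata from a VCF file
#'
#' Parses a VCF v4.2 file with diploid GT calls into a variant table and an
#' individuals-by-variants dosage matrix (count of ALT alleles, 0/1/2, `NA`
#' for missing `./.` calls). Multi-allelic records are skipped with a
#' message. Records are classified as SV when an `SVTYPE` INFO key or a
#' symbolic ALT allele is present, or when REF/ALT lengths differ by more
#' than 50 bp; as INDEL when lengths differ by 50 bp or less; otherwise SNP.
#'
#' @param path path to an (optionally gzipped) VCF file.
#' @param allowed_classes subset of `c("SNP","INDEL","SV")` to retain.
#' @return list with elements `variants` (a [variant_table]) and `genotypes`
#'   (integer matrix, individuals x variants).
#' @export
read_vcf <- function(path, allowed_classes = VCLASS_LEVELS) {
  allowed_classes <- match.arg(allowed_classes, VCLASS_LEVELS,
                               several.ok = TRUE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_fmt <- v@gt[, "FORMAT", drop = TRUE]
  if (!all(startsWith(gt_fmt, "GT")))
    stop("GT must be the first FORMAT key in every record")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    message("read_vcf: skipped ", sum(multi), " multi-allelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT genotypes")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  sv <- grepl("(^|;)SVTYPE=", info) | grepl("^<.+>$", alt)
  len_diff <- abs(nchar(ref) - nchar(alt))
  sv <- sv | (!grepl("^<", alt) & len_diff > 50L)
  indel <- !sv & len_diff > 0L
  vclass <- ifelse(sv, "SV", ifelse(indel, "INDEL", "SNP"))

  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])

  # diploid GT -> dosage; reject haploid / polyploid calls
  gt_clean <- sub(":.*$", "", gt)
  flat <- as.vector(gt_clean)
  miss <- is.na(flat) | flat %in% c("./.", ".|.", ".")
  ok <- miss | grepl("^[01][/|][01]$", flat)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    ridx <- (bad - 1L) %% nrow(gt_clean) + 1L
    stop("non-diploid or malformed genotype '", flat[bad],
         "' at record ", ids[ridx])
  }
  dos <- integer(length(flat))
  dos[miss] <- NA_integer_
  nm <- !miss
  dos[nm] <- (substr(flat[nm], 1, 1) == "1") + (substr(flat[nm], 3, 3) == "1")
  dosage <- matrix(dos, nrow = nrow(gt_clean),
                   dimnames = dimnames(gt_clean))

  vt <- variant_table(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                      vclass, ref, alt)
  keep <- vt$vclass %in% allowed_classes
  vt <- vt[keep, , drop = FALSE]
  class(vt) <- c("variant_table", "data.frame")
  G <- t(dosage[keep, , drop = FALSE])   # individuals x variants
  colnames(G) <- vt$variant_id
  list(variants = vt, genotypes = G)
}

#' Write a minimal VCF v4.2 file
#'
#' Emits the variant table and dosage matrix as a diploid GT-only VCF
#' (unphased; dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`).
#' SV records carry `SVTYPE` and `SVLEN` INFO keys.
#'
#' @param variants a [variant_table].
#' @param genotypes individuals x variants dosage matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  inds <- rownames(genotypes)
  if (is.null(inds)) inds <- paste0("ind", seq_len(nrow(genotypes)))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", inds), collapse = "\t"))
  info <- rep(".", nrow(variants))
  is_sv <- variants$vclass == "SV"
  if (any(is_sv)) {
    svlen <- nchar(variants$alt_allele[is_sv]) -
      nchar(variants$ref_allele[is_sv])
    svtype <- ifelse(grepl("^<", variants$alt_allele[is_sv]),
                     gsub("[<>]", "", variants$alt_allele[is_sv]),
                     ifelse(svlen >= 0, "INS", "DEL"))
    info[is_sv] <- paste0("SVTYPE=", svtype, ";SVLEN=", svlen)
  }
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(variants), ncol = nrow(genotypes))
  dosage_t <- t(genotypes)
  nm <- !is.na(dosage_t)
  gt[nm] <- code[dosage_t[nm] + 1L]
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref_allele, variants$alt_allele, ".", "PASS",
                info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- allele frequencies and MAF filtering --------------------------------

#' Per-population alternate-allele frequencies
#'
#' Computes, for every population and variant, the ALT-allele frequency
#' `p = sum(dosage) / (2 * n_non_missing)` over the population's members,
#' together with the number of observed alleles. Missing genotypes are
#' simply dropped from the denominator (no imputation); a population with
#' no called genotype at a variant yields an `NA` cell.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param popmap a [population_map]; every row of `genotypes` must be
#'   assigned to a population.
#' @return an [allele_freq_matrix].
#' @export
allele_frequencies <- function(genotypes, popmap) {
  inds <- rownames(genotypes)
  if (is.null(inds)) stop("genotype matrix must have individual rownames")
  idx <- match(inds, popmap$individuals$individual_id)
  if (anyNA(idx))
    stop("individuals missing from population map: ",
         paste(inds[is.na(idx)][seq_len(min(3, sum(is.na(idx))))],
               collapse = ", "))
  pop <- popmap$individuals$population_id[idx]
  pops <- popmap$populations$population_id
  grp <- factor(pop, levels = pops)
  nm <- !is.na(genotypes)
  alt <- rowsum(ifelse(nm, genotypes, 0L), grp)
  n_gt <- rowsum(nm + 0L, grp)
  n_alleles <- 2L * n_gt
  freq <- ifelse(n_alleles > 0, alt / n_alleles, NA_real_)
  rownames(freq) <- rownames(n_alleles) <- pops
  allele_freq_matrix(freq, n_alleles)
}

global_maf <- function(x) {
  if (inherits(x, "allele_freq")) {
    cnt <- x$freq * x$n_alleles
    tot_alt <- colSums(cnt, na.rm = TRUE)
    tot <- colSums(ifelse(is.na(x$freq), 0L, x$n_alleles))
  } else {
    tot_alt <- colSums(x, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(x))
  }
  p <- ifelse(tot > 0, tot_alt / tot, NA_real_)
  pmin(p, 1 - p)
}

#' Minor-allele-frequency filter
#'
#' Drops variants whose global minor-allele frequency, pooled over all
#' non-missing alleles across populations, does not strictly exceed
#' `threshold`. The default reproduces the common-variant filter
#' MAF > 10\% (strict inequality: a variant at exactly the threshold is
#' dropped).
#'
#' @param x an [allele_freq_matrix] or an individuals x variants dosage
#'   matrix.
#' @param threshold frequency in `[0, 0.5)`.
#' @return object of the same type restricted to passing variants, with the
#'   kept variant ids in attribute `"kept"`.
#' @export
maf_filter <- function(x, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold < 0.5)
  maf <- global_maf(x)
  keep <- !is.na(maf) & maf > threshold
  if (inherits(x, "allele_freq")) {
    out <- allele_freq_matrix(x$freq[, keep, drop = FALSE],
                              x$n_alleles[, keep, drop = FALSE])
    kept <- colnames(x$freq)[keep]
  } else {
    out <- x[, keep, drop = FALSE]
    kept <- colnames(x)[keep]
  }
  attr(out, "kept") <- kept
  out
}

# ---- TSV round-trip writers ---------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read tabular domain types as TSV
#'
#' Every tabular type round-trips through a plain TSV with a header row:
#' `read_table_tsv(write_table_tsv(x, path))` reproduces `x`.
#'
#' @param x a [variant_table], [population_map], `env_matrix` or
#'   [allele_freq_matrix] (long format: population, variant, freq,
#'   n_alleles).
#' @param path output path.
#' @return `path` invisibly (writer); the reconstructed object (reader).
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "variant_table")) {
    write_tsv(as.data.frame(x), path)
  } else if (inherits(x, "population_map")) {
    df <- merge(x$individuals, x$populations, by = "population_id",
                sort = FALSE)
    df <- df[match(x$individuals$individual_id, df$individual_id),
             c("individual_id", "population_id", "lon", "lat")]
    write_tsv(df, path)
  } else if (inherits(x, "env_matrix")) {
    df <- data.frame(site_id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    meta <- sprintf("# period=%s model=%s scenario=%s window=%s",
                    attr(x, "period"), attr(x, "model"),
                    attr(x, "scenario"), attr(x, "window"))
    writeLines(meta, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "allele_freq")) {
    idx <- which(!is.na(x$freq) | x$n_alleles > 0, arr.ind = TRUE)
    idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
    df <- data.frame(population_id = rownames(x$freq)[idx[, 1]],
                     variant_id = colnames(x$freq)[idx[, 2]],
                     freq = x$freq[idx],
                     n_alleles = x$n_alleles[idx])
    write_tsv(df, path)
  } else stop("unsupported type: ", paste(class(x), collapse = "/"))
  invisible(path)
}

#' @rdname write_table_tsv
#' @param type which domain type the file stores: `"variant_table"`,
#'   `"population_map"`, `"env_matrix"` or `"allele_freq"`.
#' @export
read_table_tsv <- function(path, type = c("variant_table", "population_map",
                                          "env_matrix", "allele_freq")) {
  type <- match.arg(type)
  switch(type,
    variant_table = {
      df <- read_tsv(path, colClasses = c(pos = "integer"))
      if (nrow(df) == 0)
        return(variant_table(character(), character(), integer(),
                             character(), character(), character()))
      variant_table(df$variant_id, df$chrom, df$pos, df$vclass,
                    df$ref_allele, df$alt_allele, df$ancestral,
                    df$func_class)
    },
    population_map = {
      df <- read_tsv(path)
      pops <- unique(df[, c("population_id", "lon", "lat")])
      population_map(df[, c("individual_id", "population_id")], pops)
    },
    env_matrix = {
      first <- readLines(path, n = 1)
      meta <- regmatches(first,
                         gregexpr("(period|model|scenario|window)=\\S*", first))[[1]]
      kv <- strsplit(meta, "=")
      vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "", "")
      names(vals) <- vapply(kv, `[`, "", 1)
      df <- read_tsv(path, comment.char = "#")
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df$site_id
      env_matrix(m, period = vals[["period"]], model = vals[["model"]],
                 scenario = vals[["scenario"]], window = vals[["window"]])
    },
    allele_freq = {
      df <- read_tsv(path)
      pops <- unique(df$population_id)
      vars <- unique(df$variant_id)
      freq <- matrix(NA_real_, length(pops), length(vars),
                     dimnames = list(pops, vars))
      n_all <- matrix(0L, length(pops), length(vars),
                      dimnames = list(pops, vars))
      i <- cbind(match(df$population_id, pops), match(df$variant_id, vars))
      freq[i] <- df$freq
      n_all[i] <- df$n_alleles
      allele_freq_matrix(freq, n_all)
    })
}
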