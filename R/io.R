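# File formats: PLINK .bed/.bim/.fam, TSV genotype fallback, summary
# statistics, density maps, phenotype tables and the serialisable run
# configuration.

#' Write genotypes as PLINK .bed/.bim/.fam
#'
#' SNP-major .bed with the standard magic bytes; dosages count `allele1`
#' (2 maps to the homozygous-A1 code, 1 heterozygous, 0 homozygous-A2,
#' `NA` to the missing code). The .bim carries chr, id, 0 cM, bp, a1, a2;
#' the .fam carries the sample ids.
#'
#' @param genotypes Sample-by-SNP dosage matrix with dimnames.
#' @param variant_meta Tibble with `snp_id`, `chr`, `bp`, `allele1`,
#'   `allele2`.
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, variant_meta, prefix) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  stopifnot(nrow(variant_meta) == m)
  write.table(
    data.frame(variant_meta$chr, variant_meta$snp_id, 0L, variant_meta$bp,
               variant_meta$allele1, variant_meta$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ids <- rownames(genotypes) %||% as.character(seq_len(n))
  write.table(data.frame(ids, ids, 0L, 0L, 0L, -9L),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # 2-bit codes: dosage 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, n, m)
  code[genotypes == 2L] <- 0L
  code[genotypes == 1L] <- 2L
  code[is.na(genotypes)] <- 1L
  n_pad <- 4L * ceiling(n / 4L)
  if (n_pad > n) code <- rbind(code, matrix(0L, n_pad - n, m))
  dim(code) <- c(4L, n_pad / 4L, m)
  bytes <- code[1, , ] + 4L * code[2, , ] + 16L * code[3, , ] + 64L * code[4, , ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read PLINK .bed/.bim/.fam genotypes
#'
#' @param prefix Path prefix (without extension).
#' @return List with `genotypes` (dosage matrix counting `allele1`, `NA`
#'   for missing) and `variant_meta`. Errors on malformed magic bytes or
#'   a .bed size inconsistent with the .bim/.fam dimensions.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t",
                    col.names = c("chr", "snp_id", "cm", "bp", "allele1", "allele2"),
                    colClasses = c("integer", "character", "numeric", "integer",
                                   "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), sep = "\t",
                    colClasses = c("character", "character", "character",
                                   "character", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = file.info(paste0(prefix, ".bed"))$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file: bad magic bytes")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * m) {
    abort(sprintf(".bed size (%d data bytes) does not match %d samples x %d variants",
                  length(body), n, m))
  }
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)
  geno <- matrix(lookup[codes + 1L], n, m,
                 dimnames = list(fam[[2]], bim$snp_id))
  list(genotypes = geno,
       variant_meta = tibble(snp_id = bim$snp_id, chr = bim$chr, bp = bim$bp,
                             allele1 = bim$allele1, allele2 = bim$allele2))
}

#' Write / read the TSV genotype fallback
#'
#' A transparent wide TSV: one row per sample (`sample_id` first column),
#' one column per SNP id, `NA` for missing calls. Variant metadata goes
#' to a companion `<path>.variants.tsv`.
#'
#' @param genotypes Dosage matrix.
#' @param variant_meta Variant tibble.
#' @param path Output TSV path.
#' @return `path` (write) or a list like [read_plink()]'s (read).
#' @export
write_genotypes_tsv <- function(genotypes, variant_meta, path) {
  df <- data.frame(sample_id = rownames(genotypes) %||%
                     as.character(seq_len(nrow(genotypes))),
                   genotypes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  write.table(variant_meta, paste0(path, ".variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "NA", colClasses = NA)
  geno <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- df[[1]]
  vm <- as_tibble(read.table(paste0(path, ".variants.tsv"), sep = "\t",
                             header = TRUE,
                             colClasses = c(snp_id = "character",
                                            allele1 = "character",
                                            allele2 = "character")))
  list(genotypes = geno, variant_meta = vm)
}

#' Write / read GWAS summary statistics TSV
#'
#' Header `snp_id, chr, bp, a1, a2, beta, se, p` with a1 the effect
#' allele.
#'
#' @param sumstats Summary-statistics tibble (see [generate_sumstats()]).
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_sumstats <- function(sumstats, path) {
  out <- data.frame(snp_id = sumstats$snp_id, chr = sumstats$chr,
                    bp = sumstats$bp, a1 = sumstats$effect_allele,
                    a2 = sumstats$other_allele, beta = sumstats$beta,
                    se = sumstats$se, p = sumstats$p_value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(snp_id = "character", a1 = "character",
                                  a2 = "character"))
  tibble(snp_id = df$snp_id, chr = df$chr, bp = df$bp,
         effect_allele = df$a1, other_allele = df$a2,
         beta = df$beta, se = df$se, p_value = df$p)
}

#' Write / read a density map as gridded TSV
#'
#' First line: a `#`-prefixed JSON header with the origin, cell size and
#' grid dimensions; then the density values, one raster row (fixed y)
#' per line.
#'
#' @param map A [density_map()].
#' @param path TSV path.
#' @return `path` (write) or a [density_map()] (read).
#' @export
write_density_map <- function(map, path) {
  hdr <- jsonlite::toJSON(list(x_min = map$origin[1], y_min = map$origin[2],
                               cell_km = map$cell_km,
                               nx = nrow(map$values), ny = ncol(map$values)),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  write.table(t(map$values), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) abort("density map file lacks its JSON header")
  hdr <- jsonlite::fromJSON(sub("^#", "", first))
  vals <- as.matrix(read.table(path, sep = "\t", skip = 1, header = FALSE))
  density_map(t(vals), cell_km = hdr$cell_km,
              origin = c(hdr$x_min, hdr$y_min))
}

#' Write / read a phenotype table keyed by sample id
#'
#' @param phenotypes Tibble with a `sample_id` column.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                       colClasses = c(sample_id = "character")))
}

#' Run configuration with the analysis defaults pre-filled
#'
#' All pipeline thresholds in one serialisable object: QC boundaries
#' (SNP missingness 0.02, MAF 0.01, HWE P 1e-8, sample missingness 0.01,
#' kinship 0.088), clumping (r-squared 0.1, 250 kb window), the PRS
#' inclusion threshold 0.05 and genome-wide 5e-8, quantile count 20 with
#' reference bin 11, covariate tiers, and the scenario configuration used
#' when simulating. Round-trips byte-identically through
#' [write_run_config()] / [read_run_config()].
#'
#' @param ... Overrides of the defaults.
#' @return A `run_config` (named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    snp_missing_max = 0.02, maf_min = 0.01, hwe_p_min = 1e-8,
    sample_missing_max = 0.01, kinship_threshold = 0.088,
    ancestry_k = 4, n_pcs = 15,
    clump_r2 = 0.1, clump_window_kb = 250,
    p_threshold = 0.05, gw_threshold = 5e-8,
    quantile_k = 20, quantile_reference = 11,
    covariates = c("age", "sex", "deprivation_index"),
    extended_covariates = c("age", "sex", "deprivation_index", "education"),
    scenario = "trait_to_disorder", n_individuals = 2000, n_snps = 300,
    seed = 1L, out_dir = "prscreen-run",
    genotypes = NULL, sumstats = NULL, phenotypes = NULL, density_map = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) abort(paste0("unknown config fields: ",
                                    paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Output path, `.yaml`/`.yml` or `.json`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (grepl("\\.json$", path)) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE), path)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path) else yaml::read_yaml(path)
  do.call(run_config, x)
}
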