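# Stage runners behind the command-line surface. Each stage reads its
# inputs from the fixed filenames of a run directory, so downstream
# stages auto-discover upstream outputs, and writes tables carrying a
# provenance header (package version, seed, config hash).

run_paths <- function(dir) {
  list(config = file.path(dir, "run_config.yaml"),
       plink = file.path(dir, "genotypes"),
       sumstats = file.path(dir, "sumstats.tsv"),
       phenotypes = file.path(dir, "phenotypes.tsv"),
       map = file.path(dir, "density_map.tsv"),
       qc_report = file.path(dir, "qc_report.json"),
       keep_variants = file.path(dir, "retained_variants.txt"),
       keep_samples = file.path(dir, "retained_samples.txt"),
       pcs = file.path(dir, "pcs.tsv"),
       scores = file.path(dir, "scores.tsv"),
       associations = file.path(dir, "associations.tsv"),
       quantiles = file.path(dir, "quantile_trend.tsv"),
       migration = file.path(dir, "migration.tsv"),
       follow_up = file.path(dir, "follow_up.tsv"))
}

provenance_line <- function(config) {
  # hash the analysis parameters only, not filesystem paths
  x <- unclass(config)
  x <- x[setdiff(names(x), c("out_dir", "genotypes", "sumstats",
                             "phenotypes", "density_map"))]
  sprintf("#prscreen %s seed=%s config_hash=%s",
          as.character(packageVersion("prscreen")),
          config$seed, rlang::hash(x))
}

write_tsv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"))
  invisible(path)
}

read_tsv_prov <- function(path, ...) {
  as_tibble(read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                       comment.char = "#", ...))
}

stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- run_paths(dir)
  scfg <- scenario_config(scenario = config$scenario,
                          n_individuals = config$n_individuals,
                          n_snps = config$n_snps,
                          n_control_traits = 3,
                          seed = config$seed)
  cohort <- simulate_cohort(scfg)
  write_plink(cohort$genotypes, cohort$variant_meta, p$plink)
  ss <- withr::with_seed(config$seed + 1L, generate_sumstats(cohort, "oracle"))
  write_sumstats(ss, p$sumstats)
  pheno <- dplyr::left_join(cohort$samples, cohort$locations, by = "sample_id")
  write_tsv_prov(pheno, p$phenotypes, config)
  write_density_map(cohort$density_map, p$map)
  write_run_config(config, p$config)
  inform(sprintf("simulate: %d individuals x %d SNPs (scenario %s, seed %d)",
                 nrow(cohort$genotypes), ncol(cohort$genotypes),
                 scfg$scenario, scfg$seed))
  invisible(dir)
}

stage_qc <- function(dir) {
  p <- run_paths(dir)
  config <- read_run_config(p$config)
  g <- read_plink(p$plink)
  vqc <- variant_qc(g$genotypes, config$snp_missing_max, config$maf_min,
                    config$hwe_p_min)
  sqc <- sample_qc(g$genotypes, config$sample_missing_max, variants = vqc$keep)
  sub <- g$genotypes[sqc$keep, vqc$keep, drop = FALSE]
  kin <- kinship_prune(sub, config$kinship_threshold)
  sub <- sub[kin$keep, , drop = FALSE]
  k <- min(config$n_pcs, nrow(sub) - 1L, ncol(sub))
  pcs <- prs_pca(sub, k)
  anc <- ancestry_cluster(pcs, k = config$ancestry_k)
  report <- dplyr::bind_rows(
    vqc$report, sqc$report,
    tibble(filter = "kinship", axis = "sample",
           removed = length(kin$removed), remaining = length(kin$keep)),
    tibble(filter = "ancestry", axis = "sample",
           removed = length(kin$keep) - length(anc$majority),
           remaining = length(anc$majority)))
  writeLines(jsonlite::toJSON(report, dataframe = "rows", pretty = TRUE),
             p$qc_report)
  writeLines(vqc$keep, p$keep_variants)
  writeLines(anc$majority, p$keep_samples)
  write_tsv_prov(pcs[pcs$sample_id %in% anc$majority, ], p$pcs, config)
  inform(sprintf("qc: %d variants, %d samples retained",
                 length(vqc$keep), length(anc$majority)))
  invisible(report)
}

stage_prs <- function(dir) {
  p <- run_paths(dir)
  config <- read_run_config(p$config)
  g <- read_plink(p$plink)
  keep_v <- readLines(p$keep_variants)
  keep_s <- readLines(p$keep_samples)
  geno <- g$genotypes[keep_s, keep_v, drop = FALSE]
  vm <- g$variant_meta[g$variant_meta$snp_id %in% keep_v, ]
  ss <- read_sumstats(p$sumstats)
  best <- build_prs(geno, vm, ss, "best_fit", p_t = config$p_threshold,
                    r2_threshold = config$clump_r2,
                    window_kb = config$clump_window_kb)
  gw <- tryCatch(
    build_prs(geno, vm, ss, "gw_significant", p_t = config$gw_threshold,
              r2_threshold = config$clump_r2,
              window_kb = config$clump_window_kb),
    error = function(e) {
      warn(paste0("no genome-wide significant variants: ", conditionMessage(e)))
      NULL
    })
  write_tsv_prov(dplyr::bind_rows(best, gw), p$scores, config)
  inform(sprintf("prs: best-fit over %d SNPs%s", best$n_snps[1],
                 if (is.null(gw)) "" else sprintf(", GW-significant over %d", gw$n_snps[1])))
  invisible(p$scores)
}

analysis_table_from_run <- function(dir) {
  p <- run_paths(dir)
  pheno <- read_tsv_prov(p$phenotypes, colClasses = c(sample_id = "character"))
  scores <- read_tsv_prov(p$scores, colClasses = c(sample_id = "character"))
  pcs <- read_tsv_prov(p$pcs, colClasses = c(sample_id = "character"))
  best <- scores[scores$label == "best_fit", c("sample_id", "score")]
  names(best)[2] <- "prs"
  tab <- dplyr::inner_join(pheno, best, by = "sample_id")
  dplyr::inner_join(tab, pcs, by = "sample_id")
}

stage_phewas <- function(dir) {
  p <- run_paths(dir)
  config <- read_run_config(p$config)
  tab <- analysis_table_from_run(dir)
  tab <- tab[!tab$diagnosed, , drop = FALSE]
  traits <- intersect(c("trait", grep("^control_", names(tab), value = TRUE)),
                      names(tab))
  pcs_avail <- grep("^PC[0-9]+$", names(tab), value = TRUE)
  res <- prs_screen(tab, traits, prs = "prs",
                    covariates = c(config$covariates, pcs_avail))
  write_tsv_prov(res, p$associations, config)
  inform(sprintf("phewas: %d traits screened, Bonferroni cutoff %.3g",
                 length(traits), bonferroni_cutoff(res)))
  invisible(res)
}

stage_quantiles <- function(dir) {
  p <- run_paths(dir)
  config <- read_run_config(p$config)
  tab <- analysis_table_from_run(dir)
  undiag <- tab[!tab$diagnosed, , drop = FALSE]
  bins <- bin_by_prs(undiag$prs, k = config$quantile_k)
  pcs_avail <- grep("^PC[0-9]+$", names(tab), value = TRUE)
  trend <- fit_quantile_trend(undiag, "trait", bins,
                              covariates = c(config$covariates, pcs_avail),
                              reference = config$quantile_reference)
  trend <- append_case_groups(trend, tab)
  out <- trend$table
  if (any(out$group_type == "case")) {
    cls <- classify_concordance(trend)
    out <- dplyr::left_join(out, cls[, c("group", "classification")], by = "group")
  }
  write_tsv_prov(out, p$quantiles, config)
  invisible(trend)
}

stage_migration <- function(dir) {
  p <- run_paths(dir)
  config <- read_run_config(p$config)
  map <- read_density_map(p$map)
  pheno <- read_tsv_prov(p$phenotypes, colClasses = c(sample_id = "character"))
  mig <- migration_table(pheno, map)
  write_tsv_prov(mig, p$migration, config)
  tab <- dplyr::inner_join(pheno,
                           dplyr::select(mig, -"years_at_residence"),
                           by = "sample_id")
  fu <- follow_up_associations(
    tab, outcomes = c("distance_km", "density_change", "years_at_residence"),
    exposure = "trait",
    tiers = list(base = c("age", "sex"),
                 extended = config$extended_covariates))
  write_tsv_prov(fu, p$follow_up, config)
  invisible(fu)
}

#' Run the full pipeline on a simulated cohort
#'
#' Convenience wrapper running simulate, qc, prs, phewas, quantiles and
#' migration into one run directory with fixed filenames.
#'
#' @param config A [run_config()].
#' @param dir Run directory (defaults to `config$out_dir`).
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config, dir = config$out_dir) {
  stage_simulate(config, dir)
  stage_qc(dir)
  stage_prs(dir)
  stage_phewas(dir)
  stage_quantiles(dir)
  stage_migration(dir)
  invisible(dir)
}
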