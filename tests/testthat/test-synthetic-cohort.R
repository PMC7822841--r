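# Generator properties: determinism, Hardy-Weinberg marginals, block LD,
# Balding-Nichols drift recovery, the liability-threshold disorder, the
# causal scenarios and the summary-statistics modes.

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- scenario_config("pleiotropy", n_individuals = 300, n_snps = 60,
                         missing_rate = 0.02, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$samples, b$samples)
  expect_identical(a$locations, b$locations)
  expect_identical(a$variant_meta, b$variant_meta)
})

test_that("without structure or LD, genotypes sit at Hardy-Weinberg proportions", {
  cfg <- scenario_config("null", n_individuals = 2000, n_snps = 60,
                         ld_rho = 0, fst = 0, seed = 1)
  g <- withr::with_seed(11, simulate_genotypes(cfg))
  hwe_p <- apply(g$genotypes, 2, function(x) hwe_test(x)$p_value)
  # uniform p under the null; allow binomial slack on the 5% rate
  expect_lt(mean(hwe_p < 0.05), 0.15)
  expect_gt(mean(hwe_p), 0.3)
})

test_that("within-block LD exceeds between-block LD at high ld_rho", {
  cfg <- scenario_config("null", n_individuals = 2000, n_snps = 500,
                         ld_block_size = 10, ld_rho = 0.9, seed = 1)
  g <- withr::with_seed(2, simulate_genotypes(cfg))
  m <- ncol(g$genotypes)
  block <- rep(seq_len(50), each = 10)
  r2_adj <- r2_cross <- numeric(0)
  for (j in seq_len(m - 1)) {
    r2 <- cor(g$genotypes[, j], g$genotypes[, j + 1])^2
    if (block[j] == block[j + 1]) r2_adj <- c(r2_adj, r2)
    else r2_cross <- c(r2_cross, r2)
  }
  expect_gt(mean(r2_adj), mean(r2_cross))
  expect_gt(mean(r2_adj), 0.3)   # LD is substantial, not token
  expect_lt(mean(r2_cross), 0.05)
})

test_that("Hudson-type Fst estimates recover the drift parameter", {
  cfg <- scenario_config("structure", n_individuals = 2000, n_snps = 1000,
                         ld_rho = 0, n_subpops = 2, fst = 0.1, seed = 1)
  g <- withr::with_seed(3, simulate_genotypes(cfg))
  p1 <- colMeans(g$genotypes[g$subpop == 1, ]) / 2
  p2 <- colMeans(g$genotypes[g$subpop == 2, ]) / 2
  n1 <- 2 * sum(g$subpop == 1)
  n2 <- 2 * sum(g$subpop == 2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- mean(num) / mean(den)
  expect_lt(abs(fst_hat - 0.1), 0.03)
})

test_that("liability is standardised and the case rate matches prevalence", {
  co <- quick_cohort("null", n = 20000, m = 100, seed = 5)
  expect_lt(abs(var(co$samples$liability) - 1), 0.05)
  p <- 0.01
  sd3 <- 3 * sqrt(p * (1 - p) / 20000)
  expect_lt(abs(mean(co$samples$diagnosed) - p), sd3)
  expect_true(all(co$samples$diagnosed[co$samples$medicated]))
})

test_that("null heritability leaves diagnosis independent of genotype", {
  ps <- vapply(1:40, function(i) {
    co <- quick_cohort("null", n = 800, m = 60, seed = 100 + i,
                       h2_liability = 0, prevalence = 0.2)
    prs <- oracle_prs(co, sumstats_seed = 500 + i, p_t = 1)
    tab <- cohort_table(co, prs = prs)
    prs_associate(tab, "diagnosed_true", family = "logistic")$p_value
  }, numeric(1))
  # p-values approximately uniform: mean near 0.5, rejections near 5%
  expect_lt(abs(mean(ps) - 0.5), 0.15)
  expect_lte(sum(ps < 0.05), 7)
})

test_that("positive medication slope selects higher-liability cases for treatment", {
  hits <- vapply(1:100, function(i) {
    co <- quick_cohort("null", n = 600, m = 40, seed = 1000 + i,
                       prevalence = 0.1, medication_prob_slope = 2)
    s <- co$samples
    med <- s$liability[s$medicated]
    non <- s$liability[s$diagnosed & !s$medicated]
    length(med) > 0 && length(non) > 0 && mean(med) > mean(non)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("disorder-to-trait effects attenuate in the undiagnosed subset", {
  co <- quick_cohort("disorder_to_trait", n = 8000, m = 100, seed = 9,
                     prevalence = 0.05, trait_effect = 1.5)
  prs <- oracle_prs(co)
  tab <- cohort_table(co, prs = prs)
  full <- prs_associate(tab, "trait")
  undiag <- prs_associate(tab[!tab$diagnosed, ], "trait")
  expect_lt(abs(undiag$beta), abs(full$beta))
})

test_that("adjusting for the true subpopulation collapses the structure signal", {
  co <- quick_cohort("structure", n = 4000, m = 400, seed = 10,
                     n_subpops = 2, fst = 0.15, env_gradient = c(-0.5, 0.5))
  prs <- oracle_prs(co)
  tab <- cohort_table(co, prs = prs)
  tab$subpop_ind <- as.numeric(tab$subpop == 2)
  unadj <- prs_associate(tab, "trait")
  adj <- prs_associate(tab, "trait", covariates = "subpop_ind")
  expect_gt(abs(unadj$beta), 0.02)        # confounding present
  expect_lt(abs(adj$beta), 0.5 * abs(unadj$beta))
})

test_that("scenario separability: only the configured arrow associates PRS and trait", {
  n_rep <- 20
  reject <- function(scenario, i, ...) {
    co <- quick_cohort(scenario, n = 1500, m = 100, seed = 2000 + i,
                       prevalence = 0.05, ...)
    prs <- oracle_prs(co, sumstats_seed = 3000 + i)
    tab <- cohort_table(co, prs = prs)
    prs_associate(tab[!tab$diagnosed, ], "trait")$p_value < 0.05
  }
  null_rej <- vapply(1:n_rep, function(i) reject("null", i), logical(1))
  t2d_rej <- vapply(1:n_rep, function(i)
    reject("trait_to_disorder", i, trait_effect = 0.5), logical(1))
  pleio_rej <- vapply(1:n_rep, function(i)
    reject("pleiotropy", i, trait_effect = 0.5), logical(1))
  expect_lte(sum(null_rej), 3)            # near-nominal type I
  expect_gte(mean(t2d_rej), 0.8)          # power at the stated effect
  expect_gte(mean(pleio_rej), 0.8)
})

test_that("oracle sumstats are exact in the zero-noise limit and null otherwise", {
  co <- quick_cohort("trait_to_disorder", n = 400, m = 120, seed = 12)
  ss <- withr::with_seed(1, generate_sumstats(co, "oracle", n_discovery = 1e14))
  expect_equal(ss$beta, co$variant_meta$true_effect, tolerance = 1e-3)
  causal <- co$effects$idx
  expect_lt(max(ss$p_value[causal]), 1e-10)

  # null SNPs at finite discovery size: uniform p-values
  co0 <- quick_cohort("null", n = 300, m = 5000, seed = 13, h2_liability = 0,
                      ld_rho = 0)
  ss0 <- withr::with_seed(2, generate_sumstats(co0, "oracle", n_discovery = 1e5))
  ks <- suppressWarnings(stats::ks.test(ss0$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort-GWAS mode ranks causal SNPs highly", {
  hits <- vapply(1:20, function(i) {
    co <- quick_cohort("null", n = 2000, m = 60, seed = 4000 + i,
                       n_causal = 5, h2_liability = 0.5, prevalence = 0.2,
                       ld_rho = 0)
    ss <- generate_sumstats(co, "cohort_gwas")
    top <- ss$snp_id[order(ss$p_value)][1:6]   # top decile of 60
    mean(co$variant_meta$snp_id[co$effects$idx] %in% top) >= 3 / 5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("migration couples to the trait only when requested", {
  cfg0 <- scenario_config("null", n_individuals = 4000, n_snps = 50,
                          n_causal = 5, seed = 20)
  co <- simulate_cohort(cfg0)
  mig <- migration_table(co$locations, co$density_map)
  r <- cor(mig$distance_km, co$samples$trait)
  expect_lt(abs(r), 2 / sqrt(4000))

  hits <- vapply(1:20, function(i) {
    cfg <- scenario_config("null", n_individuals = 3000, n_snps = 50,
                           n_causal = 5, migration_coupling = 0.3,
                           seed = 5000 + i)
    coc <- simulate_cohort(cfg)
    migc <- migration_table(coc$locations, coc$density_map)
    tab <- dplyr::mutate(cohort_table(coc, migration = migc))
    r <- prs_associate(tab, "distance_km", prs = "trait")
    r$beta > 0 && r$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  still <- simulate_locations(co$samples, cfg0, trait = co$samples$trait,
                              map = co$density_map, p_move = 0)
  d <- migration_table(still$locations, co$density_map)
  expect_true(all(d$distance_km == 0))
})
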