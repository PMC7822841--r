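# Variant/sample filters with their strict boundary semantics, the KING
# kinship estimator and pruning, PCA and ancestry clustering.

test_that("HWE chi-square is exact on closed-form fixtures", {
  # perfect HW proportions: chi-square identically 0
  x <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  expect_equal(hwe_test(x)$chisq, 0)
  # zero heterozygotes at p = 0.5: chi-square equals n
  y <- c(rep(0L, 50), rep(2L, 50))
  h <- hwe_test(y)
  expect_equal(h$chisq, 100)
  expect_lt(h$p_value, 1e-8)
})

test_that("variant filters respect their boundaries and order", {
  # columns: perfect HWE (kept), zero-het (HWE fail), monomorphic (MAF fail)
  g <- geno_from_counts(c(25, 50, 25), c(50, 0, 50), c(100, 0, 0))
  colnames(g) <- c("ok", "nohet", "mono")
  rownames(g) <- sprintf("s%03d", 1:100)
  res <- variant_qc(g)
  expect_identical(res$keep, "ok")
  expect_identical(res$report$filter, c("missingness", "maf", "hwe"))
  expect_equal(res$report$removed, c(0L, 1L, 1L))

  # SNP missingness: 2/100 = 0.02 retained (not > 0.02), 3/100 removed
  g2 <- cbind(a = c(rep(NA, 2), rep(1L, 98)), b = c(rep(NA, 3), rep(1L, 97)),
              c = rep(c(0L, 1L), 50))
  res2 <- variant_qc(g2, maf_min = 0, hwe_p_min = 0)
  expect_true("a" %in% res2$keep)
  expect_false("b" %in% res2$keep)

  # MAF exactly at the boundary is retained (rule is strictly <)
  g3 <- cbind(boundary = c(rep(1L, 2), rep(0L, 98)),   # MAF 0.01
              below = c(1L, rep(0L, 99)))              # MAF 0.005
  res3 <- variant_qc(g3, hwe_p_min = 0)
  expect_identical(res3$keep, "boundary")
})

test_that("conjunctive reading removes only SNPs failing both rules", {
  g <- cbind(miss_only = c(rep(NA, 5), rep(1L, 95)),
             both = c(rep(NA, 5), rep(0L, 95)))
  dis <- variant_qc(g, hwe_p_min = 0)
  con <- variant_qc(g, hwe_p_min = 0, conjunctive = TRUE)
  expect_identical(dis$keep, character(0))
  expect_identical(con$keep, "miss_only")
})

test_that("sample missingness boundary is strict", {
  g <- matrix(1L, 3, 100, dimnames = list(c("clean", "edge", "bad"), NULL))
  g["edge", 1] <- NA      # 1/100 = boundary, retained
  g["bad", 1:2] <- NA     # 2/100 > 0.01, removed
  res <- sample_qc(g)
  expect_identical(res$keep, c("clean", "edge"))
})

test_that("variant QC is idempotent and row-order invariant", {
  cfg <- scenario_config("null", n_individuals = 300, n_snps = 80,
                         missing_rate = 0.03, maf_range = c(0.005, 0.5), seed = 1)
  g <- withr::with_seed(42, simulate_genotypes(cfg))$genotypes
  r1 <- variant_qc(g)
  r2 <- variant_qc(g[, r1$keep, drop = FALSE])
  expect_identical(sort(r1$keep), sort(r2$keep))
  perm <- withr::with_seed(1, sample(nrow(g)))
  r3 <- variant_qc(g[perm, , drop = FALSE])
  expect_identical(r1$keep, r3$keep)
})

test_that("KING kinship: duplicates near 0.5, unrelated near 0, unbiased", {
  cfg <- scenario_config("null", n_individuals = 40, n_snps = 1000,
                         ld_rho = 0, seed = 1)
  g <- withr::with_seed(5, simulate_genotypes(cfg))$genotypes
  kin <- king_kinship(g)
  expect_equal(nrow(kin), choose(40, 2))
  expect_lt(abs(kin$kinship[1]), 0.05)        # one unrelated pair
  expect_lt(quantile(abs(kin$kinship), 0.95), 0.06)
  expect_lt(abs(mean(kin$kinship)), 0.01)     # >200 pairs, unbiased

  dup <- rbind(g, g[1:2, ])
  rownames(dup) <- c(rownames(g), "dupA", "dupB")
  kd <- king_kinship(dup)
  k1 <- kd$kinship[(kd$id1 == rownames(g)[1] & kd$id2 == "dupA") |
                     (kd$id1 == "dupA" & kd$id2 == rownames(g)[1])]
  expect_gte(k1, 0.45)
  expect_lte(k1, 0.55)
})

test_that("kinship pruning removes exactly one member per related pair", {
  cfg <- scenario_config("null", n_individuals = 20, n_snps = 1000,
                         ld_rho = 0, seed = 1)
  g <- withr::with_seed(6, simulate_genotypes(cfg))$genotypes
  dup <- rbind(g, g[1:3, ])
  rownames(dup) <- c(rownames(g), paste0("dup", 1:3))
  pr <- kinship_prune(dup)
  expect_equal(nrow(dup) - length(pr$keep), 3)
  for (i in 1:3) {
    pair <- c(rownames(g)[i], paste0("dup", i))
    expect_equal(sum(pair %in% pr$keep), 1)
  }
  # permissive threshold removes nobody
  expect_equal(length(kinship_prune(dup, threshold = 1.0)$keep), nrow(dup))
  # row order does not change the retained set
  perm <- withr::with_seed(2, sample(nrow(dup)))
  pr2 <- kinship_prune(dup[perm, , drop = FALSE])
  expect_setequal(pr$keep, pr2$keep)
})

test_that("PCA separates drifted subpopulations and ignores their absence", {
  cfg <- scenario_config("structure", n_individuals = 600, n_snps = 1500,
                         n_subpops = 2, fst = 0.1, ld_rho = 0, seed = 1)
  g <- withr::with_seed(7, simulate_genotypes(cfg))
  pcs <- prs_pca(g$genotypes, 2)
  r <- cor(pcs$PC1, as.numeric(g$subpop == 2))
  expect_gt(abs(r), 0.9)

  ok <- vapply(1:10, function(i) {
    cfg0 <- scenario_config("null", n_individuals = 200, n_snps = 400,
                            ld_rho = 0, seed = 1)
    g0 <- withr::with_seed(100 + i, simulate_genotypes(cfg0))
    lab <- withr::with_seed(200 + i, rbinom(200, 1, 0.5))
    p0 <- prs_pca(g0$genotypes, 5)
    all(abs(cor(as.matrix(p0[, -1]), lab)) < 0.2)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("PCA handles edge cases deterministically", {
  cfg <- scenario_config("null", n_individuals = 50, n_snps = 30, seed = 1)
  g <- withr::with_seed(8, simulate_genotypes(cfg))$genotypes
  g[, 1] <- 1L                      # zero-variance column
  p <- prs_pca(g, 3)
  expect_true(all(is.finite(as.matrix(p[, -1]))))
  expect_identical(prs_pca(g, 3), p)          # deterministic, incl. signs
  p0 <- prs_pca(g, 0)
  expect_identical(names(p0), "sample_id")
})

test_that("ancestry clustering recovers blobs and picks the majority", {
  centres <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  lab <- rep(1:4, times = c(90, 10, 10, 10))
  xy <- centres[lab, ] + withr::with_seed(9, matrix(rnorm(240, sd = 0.3), ncol = 2))
  pcs <- tibble::tibble(sample_id = as.character(1:120),
                        PC1 = xy[, 1], PC2 = xy[, 2])
  cl <- ancestry_cluster(pcs, k = 4)
  # adjusted-Rand surrogate: every blob maps to exactly one cluster
  expect_equal(length(unique(paste(lab, cl$cluster))), 4)
  expect_setequal(cl$majority, pcs$sample_id[lab == 1])

  same <- tibble::tibble(sample_id = as.character(1:10), PC1 = 1, PC2 = 1)
  cs <- ancestry_cluster(same, k = 4)
  expect_setequal(cs$majority, same$sample_id)
  expect_error(ancestry_cluster(same[1:3, ], k = 4), "fewer samples")
})
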