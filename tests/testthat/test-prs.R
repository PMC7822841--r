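# Harmonisation, clumping (against an independent brute-force oracle),
# thresholding boundaries and scoring exactness/invariances.

test_that("harmonisation keeps, flips and excludes correctly", {
  vm <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4"),
                       chr = 1L, bp = c(100L, 200L, 300L, 400L),
                       allele1 = c("A", "G", "A", "C"),
                       allele2 = c("C", "A", "T", "T"))
  ss <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4"),
                       effect_allele = c("A", "A", "A", "G"),
                       other_allele = c("C", "G", "T", "T"),
                       beta = c(0.2, 0.2, 0.3, 0.1),
                       se = 0.05, p_value = 0.01)
  h <- harmonise(ss, vm)
  expect_setequal(h$snp_id, c("s1", "s2"))
  expect_equal(h$beta[h$snp_id == "s1"], 0.2)       # direct match
  expect_false(h$flipped[h$snp_id == "s1"])
  expect_equal(h$beta[h$snp_id == "s2"], -0.2)      # flipped exactly once
  expect_true(h$flipped[h$snp_id == "s2"])
  excl <- attr(h, "excluded")
  expect_equal(excl$reason[excl$snp_id == "s3"], "ambiguous")
  expect_equal(excl$reason[excl$snp_id == "s4"], "allele_mismatch")

  # flipped weight contributes beta * (2 - dosage): 1-SNP hand example
  geno <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(letters[1:3], "s2"))
  sc <- prs_score(geno, h[h$snp_id == "s2", ], standardise = FALSE)
  expect_equal(sc$score, 0.2 * (2 - c(0, 1, 2)))
  expect_error(harmonise(ss[3, ], vm), "no variant shared")
})

test_that("duplicate ids are dropped with a logged reason", {
  vm <- tibble::tibble(snp_id = c("s1", "s2"), chr = 1L, bp = c(1L, 2L),
                       allele1 = "A", allele2 = "C")
  ss <- tibble::tibble(snp_id = c("s1", "s1", "s2"),
                       effect_allele = "A", other_allele = "C",
                       beta = 0.1, se = 0.05, p_value = 0.01)
  h <- harmonise(ss, vm)
  expect_identical(h$snp_id, "s2")
  expect_true("duplicate" %in% attr(h, "excluded")$reason)
})

test_that("clumping obeys its forced small cases", {
  # mutually uncorrelated SNPs: everyone is an index
  g <- withr::with_seed(1, matrix(rbinom(300 * 6, 2, 0.4), 300, 6,
                                  dimnames = list(NULL, paste0("s", 1:6))))
  st <- tibble::tibble(snp_id = paste0("s", 1:6), chr = 1L,
                       bp = as.integer(1:6 * 1e4),
                       p_value = seq(0.01, 0.06, by = 0.01))
  cl <- clump(st, g, r2_threshold = 0.9)
  expect_setequal(cl$snp_id, st$snp_id)

  # three perfectly correlated SNPs in one window: only the smallest P stays
  x <- withr::with_seed(2, rbinom(200, 2, 0.3))
  g2 <- cbind(a = x, b = x, c = x)
  st2 <- tibble::tibble(snp_id = c("a", "b", "c"), chr = 1L,
                        bp = c(1000L, 2000L, 3000L),
                        p_value = c(1e-8, 1e-4, 1e-2))
  cl2 <- clump(st2, g2)
  expect_identical(cl2$snp_id, "a")
  expect_setequal(cl2$members[[1]], c("b", "c"))

  # beyond the window nothing is claimed even at r2 = 1
  st3 <- st2
  st3$bp <- c(0L, 300000L, 600000L)
  expect_setequal(clump(st3, g2)$snp_id, c("a", "b", "c"))
})

test_that("clumping matches an exhaustive brute-force oracle on random instances", {
  for (i in 1:30) {
    inst <- withr::with_seed(6000 + i, random_clump_instance(
      n_snps = sample(20:60, 1)))
    got <- sort(clump(inst$stats, inst$ld)$snp_id)
    want <- brute_force_clump(inst$stats, inst$ld)
    expect_identical(got, want)
  }
})

test_that("clump output is invariant to input row order", {
  inst <- withr::with_seed(77, random_clump_instance(40))
  a <- clump(inst$stats, inst$ld)
  perm <- withr::with_seed(1, sample(nrow(inst$stats)))
  b <- clump(inst$stats[perm, ], inst$ld)
  expect_identical(a$snp_id, b$snp_id)
})

test_that("P-value thresholding is strict and supports sentinel lists", {
  st <- tibble::tibble(snp_id = c("a", "b", "c"),
                       p_value = c(0.04, 0.05, 0.06))
  expect_identical(threshold_variants(st, 0.05)$snp_id, "a")
  expect_equal(nrow(threshold_variants(st, 1.0)), 3)
  expect_equal(nrow(threshold_variants(st, 0)), 0)
  expect_identical(threshold_variants(st, sentinel_ids = c("b", "c"))$snp_id,
                   c("b", "c"))
})

test_that("scoring reproduces the hand-computed dot product", {
  geno <- matrix(c(0L, 2L, 1L, 0L, 2L, 1L), 2, 3,
                 dimnames = list(c("i1", "i2"), c("s1", "s2", "s3")))
  st <- tibble::tibble(snp_id = c("s1", "s2", "s3"),
                       beta = log(c(1.2, 0.9, 1.5)), flipped = FALSE)
  sc <- prs_score(geno, st, standardise = FALSE)
  expect_equal(sc$score,
               c(1 * log(0.9) + 2 * log(1.5), 2 * log(1.2) + 1 * log(1.5)),
               tolerance = 1e-12)
  # all-zero weights give all-zero scores
  st0 <- dplyr::mutate(st, beta = 0)
  expect_equal(prs_score(geno, st0, standardise = FALSE)$score, c(0, 0))
  # doubling weights leaves standardised scores unchanged
  s1 <- prs_score(geno, st)$score
  s2 <- prs_score(geno, dplyr::mutate(st, beta = beta * 2))$score
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(prs_score(geno, st[0, ]), "empty SNP subset")
})

test_that("missing dosages are imputed at twice the effect-allele frequency", {
  geno <- matrix(c(0L, 2L, NA, 2L), 4, 1, dimnames = list(NULL, "s1"))
  st <- tibble::tibble(snp_id = "s1", beta = 1, flipped = FALSE)
  sc <- prs_score(geno, st, standardise = FALSE)
  expect_equal(sc$score[3], 2 * mean(c(0, 2, 2)) / 2)
})

test_that("recoding a SNP's counted allele leaves standardised scores unchanged", {
  for (i in 1:10) {
    co <- withr::with_seed(7000 + i, {
      cfg <- scenario_config("null", n_individuals = 150, n_snps = 30, seed = 1)
      simulate_genotypes(cfg)
    })
    st <- withr::with_seed(7100 + i,
      tibble::tibble(snp_id = co$variant_meta$snp_id,
                     beta = rnorm(30) / 10, flipped = FALSE))
    base <- prs_score(co$genotypes, st)$score
    # recode SNP 5's counted allele: dosage -> 2 - dosage; harmonisation
    # against the recoded target stores the negated beta and a flip flag
    g2 <- co$genotypes
    g2[, 5] <- 2L - g2[, 5]
    st2 <- st
    st2$beta[5] <- -st$beta[5]
    st2$flipped[5] <- TRUE
    recoded <- prs_score(g2, st2)$score
    expect_equal(base, recoded, tolerance = 1e-12)
  }
})

test_that("the lenient profile explains at least as much trait variance as GW-only", {
  wins <- vapply(1:20, function(i) {
    co <- quick_cohort("trait_to_disorder", n = 1500, m = 150, seed = 8000 + i,
                       trait_effect = 0.5, n_causal = 20)
    # discovery size in the regime where most causal SNPs pass P < 0.05
    # but few reach genome-wide significance, as in an underpowered GWAS
    ss <- withr::with_seed(8100 + i,
                           generate_sumstats(co, "oracle", n_discovery = 2500))
    best <- build_prs(co$genotypes, co$variant_meta, ss, "best_fit")
    gw <- tryCatch(build_prs(co$genotypes, co$variant_meta, ss, "gw_significant"),
                   error = function(e) NULL)
    if (is.null(gw)) return(TRUE)   # nothing GW-significant: lenient wins
    tab <- cohort_table(co, prs = best)
    r_best <- prs_associate(tab, "trait")$r2_incremental
    tab$prs <- gw$score[match(tab$sample_id, gw$sample_id)]
    r_gw <- prs_associate(tab, "trait")$r2_incremental
    r_best >= r_gw
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
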