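# Independent oracles and small fixture builders used across the suite.

# Exhaustive, deliberately naive implementation of the greedy clumping
# definition: repeated full scans, correlations computed from first
# principles. Kept independent of prscreen::clump().
brute_force_clump <- function(stats, ld, r2_threshold = 0.1, window_kb = 250) {
  st <- as.data.frame(stats)
  claimed <- rep(FALSE, nrow(st))
  index_ids <- character(0)
  repeat {
    open <- which(!claimed)
    if (length(open) == 0) break
    # most significant unclaimed: min p, ties by bp then id
    best <- open[1]
    for (i in open[-1]) {
      if (st$p_value[i] < st$p_value[best] ||
          (st$p_value[i] == st$p_value[best] && st$bp[i] < st$bp[best]) ||
          (st$p_value[i] == st$p_value[best] && st$bp[i] == st$bp[best] &&
           st$snp_id[i] < st$snp_id[best])) {
        best <- i
      }
    }
    claimed[best] <- TRUE
    index_ids <- c(index_ids, st$snp_id[best])
    for (i in which(!claimed)) {
      if (st$chr[i] != st$chr[best]) next
      if (abs(st$bp[i] - st$bp[best]) > window_kb * 1000) next
      x <- ld[, st$snp_id[best]]
      y <- ld[, st$snp_id[i]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      num <- sum((x - mean(x)) * (y - mean(y)))
      den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      if (den == 0) next
      if ((num / den)^2 >= r2_threshold) claimed[i] <- TRUE
    }
  }
  sort(index_ids)
}

# random harmonised-stats + LD-source instance for clump testing
random_clump_instance <- function(n_snps = 50, n_ind = 120) {
  cfg <- scenario_config("null", n_individuals = n_ind, n_snps = n_snps,
                         n_causal = 5, ld_block_size = 5, ld_rho = 0.8, seed = 1)
  g <- simulate_genotypes(cfg)
  # compress positions so windows bite, and scatter over 2 chromosomes
  vm <- g$variant_meta
  vm$chr <- rep(1:2, length.out = n_snps)
  vm$bp <- sample.int(600000, n_snps)
  stats <- tibble::tibble(snp_id = vm$snp_id, chr = vm$chr, bp = vm$bp,
                          p_value = runif(n_snps), flipped = FALSE,
                          beta = rnorm(n_snps), se = 0.1)
  list(stats = stats, ld = g$genotypes)
}

# dosage matrix with explicit per-column genotype counts (n0, n1, n2)
geno_from_counts <- function(...) {
  cols <- list(...)
  do.call(cbind, lapply(cols, function(cnt) {
    c(rep(0L, cnt[1]), rep(1L, cnt[2]), rep(2L, cnt[3]))
  }))
}

quick_cohort <- function(scenario = "trait_to_disorder", n = 2000, m = 200,
                         seed = 1, ...) {
  simulate_cohort(scenario_config(scenario, n_individuals = n, n_snps = m,
                                  seed = seed, ...))
}

# PRS from oracle summary statistics for a cohort, default best-fit
oracle_prs <- function(cohort, n_discovery = 1e6, profile = "best_fit",
                       sumstats_seed = 99, ...) {
  ss <- withr::with_seed(sumstats_seed,
                         generate_sumstats(cohort, "oracle",
                                           n_discovery = n_discovery))
  build_prs(cohort$genotypes, cohort$variant_meta, ss, profile = profile, ...)
}
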