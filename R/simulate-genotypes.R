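#' Simulate LD-blocked biallelic genotypes with optional population structure
#'
#' Dosages are generated from a latent-Gaussian haplotype model: within each
#' LD block a pair of latent AR(1) Gaussian vectors (correlation `ld_rho`
#' between adjacent SNPs) is thresholded at the quantile of each SNP's
#' allele frequency, and the two haplotypes are summed to a 0/1/2 dosage.
#' This keeps each SNP at Hardy–Weinberg proportions marginally while
#' inducing tunable r-squared between neighbours. Population structure uses
#' Balding–Nichols drift: each subpopulation's allele frequency is a Beta
#' draw around the ancestral frequency with variance governed by `fst`.
#'
#' Blocks are laid out contiguously on one chromosome, each spanning about
#' 100 kb. Allele pairs are drawn from the strand-unambiguous combinations
#' (A/C, A/G, T/C, T/G) so that default harmonisation retains every SNP.
#'
#' Draws come from the current RNG state; use [simulate_cohort()] for a
#' fully seeded, reproducible cohort.
#'
#' @param config A [scenario_config()].
#' @return A list with `genotypes` (an `n_individuals` by `n_snps` integer
#'   dosage matrix with sample/SNP dimnames; `NA` marks missing calls),
#'   `variant_meta` (tibble: `snp_id`, `chr`, `bp`, `allele1` = counted
#'   allele, `allele2`, `true_effect`, initially 0) and `subpop` (integer
#'   labels).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_individuals
  m <- config$n_snps
  b <- config$ld_block_size
  rho <- config$ld_rho
  K <- config$n_subpops
  fst <- config$fst

  block <- rep(seq_len(ceiling(m / b)), each = b)[seq_len(m)]
  p0 <- runif(m, config$maf_range[1], config$maf_range[2])
  # Balding-Nichols: subpop frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
  if (K > 1 && fst > 0) {
    a <- (1 - fst) / fst
    pk <- matrix(rbeta(K * m, rep(p0 * a, each = K), rep((1 - p0) * a, each = K)),
                 nrow = K)
    pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
  } else {
    pk <- matrix(rep(p0, each = K), nrow = K)
  }
  subpop <- sample(rep_len(seq_len(K), n))

  thr <- qnorm(pk)[subpop, , drop = FALSE]       # n x m threshold matrix
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    if (rho > 0) {
      w <- sqrt(1 - rho^2)
      for (j in 2:m) {
        if (block[j] == block[j - 1]) z[, j] <- rho * z[, j - 1] + w * z[, j]
      }
    }
    dos <- dos + (z < thr)
  }
  storage.mode(dos) <- "integer"
  if (config$missing_rate > 0) {
    dos[runif(n * m) < config$missing_rate] <- NA_integer_
  }

  snp_id <- sprintf("snp%05d", seq_len(m))
  sample_id <- sprintf("id%06d", seq_len(n))
  dimnames(dos) <- list(sample_id, snp_id)

  spacing <- max(1L, as.integer(round(1e5 / b)))
  pos_in_block <- unlist(lapply(split(seq_len(m), block), seq_along), use.names = FALSE)
  bp <- (block - 1L) * 100000L + (pos_in_block - 1L) * spacing + 1L

  pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  pick <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
  swap <- runif(m) < 0.5
  a1 <- ifelse(swap, pick[, 2], pick[, 1])
  a2 <- ifelse(swap, pick[, 1], pick[, 2])

  list(
    genotypes = dos,
    variant_meta = tibble(snp_id = snp_id, chr = 1L, bp = bp,
                          allele1 = a1, allele2 = a2, true_effect = 0),
    subpop = subpop
  )
}
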