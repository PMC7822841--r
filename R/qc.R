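# Variant/sample quality control, kinship pruning, PCA and ancestry
# clustering. Filter boundaries follow the conventional strict
# inequalities: variants with missingness > 0.02, MAF < 0.01 or HWE
# P < 1e-8 are removed; samples with missingness > 0.01 are removed;
# sample pairs at kinship >= 0.088 lose one member.

#' Hardy-Weinberg chi-square test for a dosage vector
#'
#' 1-df goodness-of-fit chi-square of observed genotype counts against the
#' Hardy-Weinberg expectation at the observed allele frequency, over
#' non-missing calls; no continuity correction. Monomorphic variants give
#' a statistic of 0.
#'
#' @param x Dosages in \{0, 1, 2, NA\}.
#' @return List with `chisq` and `p_value`.
#' @export
hwe_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(chisq = NA_real_, p_value = NA_real_))
  obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- exp > 0
  chisq <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Variant quality control
#'
#' Applies, in fixed order, the per-SNP missingness, minor-allele-frequency
#' and Hardy-Weinberg filters. The missingness and MAF rules are
#' independent removal rules by default (a SNP failing either is removed);
#' `conjunctive = TRUE` selects the literal conjunctive reading in which a
#' SNP must fail both to be removed.
#'
#' @param genotypes Sample-by-SNP dosage matrix (0/1/2/NA) with SNP
#'   column names.
#' @param snp_missing_max Remove SNPs with missing-call fraction strictly
#'   greater than this (default 0.02).
#' @param maf_min Remove SNPs with MAF strictly below this (default 0.01).
#' @param hwe_p_min Remove SNPs with HWE P strictly below this
#'   (default 1e-8).
#' @param conjunctive Use the conjunctive missingness-and-MAF rule.
#' @return List with `keep` (retained SNP ids) and `report` (a
#'   `qc_report` tibble of per-filter removal counts in application
#'   order).
#' @export
variant_qc <- function(genotypes, snp_missing_max = 0.02, maf_min = 0.01,
                       hwe_p_min = 1e-8, conjunctive = FALSE) {
  if (is.null(dim(genotypes)) || ncol(genotypes) == 0 || nrow(genotypes) == 0) {
    abort("empty genotype matrix")
  }
  ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  miss <- colMeans(is.na(genotypes))
  freq <- allele_freq(genotypes)
  maf <- pmin(freq, 1 - freq)
  hwe_p <- apply(genotypes, 2, function(x) hwe_test(x)$p_value)

  fail_miss <- miss > snp_missing_max
  fail_maf <- maf < maf_min
  if (conjunctive) {
    fail1 <- fail_miss & fail_maf
    step1 <- c(missingness_and_maf = sum(fail1))
    alive <- !fail1
  } else {
    step1 <- c(missingness = sum(fail_miss),
               maf = sum(fail_maf & !fail_miss))
    alive <- !(fail_miss | fail_maf)
  }
  fail_hwe <- alive & !is.na(hwe_p) & hwe_p < hwe_p_min
  removed <- c(step1, hwe = sum(fail_hwe))
  alive <- alive & !fail_hwe

  report <- tibble(filter = names(removed), axis = "variant",
                   removed = as.integer(removed),
                   remaining = ncol(genotypes) - cumsum(as.integer(removed)))
  list(keep = ids[alive], report = structure(report, class = c("qc_report", class(report))))
}

#' Sample quality control on missing-call fraction
#'
#' Removes samples whose missing-call fraction over the supplied variants
#' is strictly greater than `sample_missing_max`; a sample exactly at the
#' boundary is retained.
#'
#' @param genotypes Sample-by-SNP dosage matrix with sample row names.
#' @param sample_missing_max Removal boundary (default 0.01).
#' @param variants Optional SNP ids (e.g. [variant_qc()] survivors) over
#'   which to compute missingness; all columns by default.
#' @return List with `keep` (retained sample ids) and `report`.
#' @export
sample_qc <- function(genotypes, sample_missing_max = 0.01, variants = NULL) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0) abort("empty genotype matrix")
  g <- if (is.null(variants)) genotypes else genotypes[, variants, drop = FALSE]
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  miss <- rowMeans(is.na(g))
  keep <- miss <= sample_missing_max
  report <- tibble(filter = "sample_missingness", axis = "sample",
                   removed = sum(!keep), remaining = sum(keep))
  list(keep = ids[keep], report = structure(report, class = c("qc_report", class(report))))
}

#' Pairwise KING-robust kinship estimates
#'
#' KING method-of-moments estimator from heterozygote and
#' opposite-homozygote sharing: for a pair (i, j), with counts restricted
#' to SNPs non-missing in both members,
#' `kinship = (N_het,het - 2 N_AA,aa) / (N_het(i) + N_het(j))`.
#' This form needs no allele frequencies, is unbiased for unrelated
#' pairs in a homogeneous sample, and estimates near 0.5 for
#' duplicates/MZ twins. (The between-family variant that divides by twice
#' the smaller heterozygote count guards against strong ancestry
#' heterogeneity at the cost of a small downward bias in homogeneous
#' cohorts; the symmetric denominator is preferred here.)
#'
#' @param genotypes Sample-by-SNP dosage matrix.
#' @return Tibble `id1`, `id2`, `kinship` over all unordered pairs.
#' @export
king_kinship <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2) abort("need at least two samples")
  ids <- rownames(genotypes) %||% as.character(seq_len(n))
  obs <- !is.na(genotypes)
  if (any(rowSums(obs) == 0)) abort("sample with all-missing genotypes")
  g <- genotypes
  g[!obs] <- 0L
  H <- (g == 1L) * 1
  A0 <- (g == 0L & obs) * 1
  A2 <- (g == 2L) * 1
  Ob <- obs * 1
  n_hh <- tcrossprod(H)
  n_opp <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  # het counts of each member, restricted to the pair's shared non-missing SNPs
  het_i <- tcrossprod(H, Ob)
  kin <- (n_hh - 2 * n_opp) / (het_i + t(het_i))
  iu <- which(upper.tri(kin), arr.ind = TRUE)
  tibble(id1 = ids[iu[, 1]], id2 = ids[iu[, 2]],
         kinship = kin[iu])
}

#' Prune related samples by kinship
#'
#' Flags every pair with kinship at or above `threshold` (0.088, the
#' third-degree cutoff) and removes exactly one member per related pair:
#' greedily, the individual involved in the most flagged pairs is removed
#' first, ties broken by sample-id order, until no flagged pair remains.
#'
#' @param genotypes Sample-by-SNP dosage matrix.
#' @param threshold Kinship at or above which a pair is related.
#' @return List with `keep` (retained sample ids), `removed`, and
#'   `kinship` (the pairwise estimate tibble).
#' @export
kinship_prune <- function(genotypes, threshold = 0.088) {
  kin <- king_kinship(genotypes)
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  flagged <- kin[kin$kinship >= threshold, , drop = FALSE]
  removed <- character(0)
  pairs <- flagged
  ids_ord <- sort(ids)      # tie-break on id order, invariant to row order
  while (nrow(pairs) > 0) {
    counts <- table(factor(c(pairs$id1, pairs$id2), levels = ids_ord))
    worst <- names(counts)[which.max(counts)]   # which.max: first = id order
    removed <- c(removed, worst)
    pairs <- pairs[pairs$id1 != worst & pairs$id2 != worst, , drop = FALSE]
  }
  list(keep = setdiff(ids, removed), removed = removed, kinship = kin)
}

#' Principal components of the genotype matrix
#'
#' PCs of the column-standardised dosage matrix: centred at twice the
#' allele frequency and scaled by `sqrt(2 p (1 - p))` (Patterson
#' convention; `scaling = "sd"` uses the sample SD instead).
#' Zero-variance columns are dropped and missing dosages mean-imputed.
#' Signs follow a deterministic convention: each component's
#' largest-magnitude loading is positive.
#'
#' @param genotypes Sample-by-SNP dosage matrix.
#' @param k Number of components; `k = 0` returns ids only.
#' @param scaling `"patterson"` or `"sd"`.
#' @return Tibble `sample_id`, `PC1` ... `PCk`.
#' @export
prs_pca <- function(genotypes, k, scaling = c("patterson", "sd")) {
  ids <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  k <- check_count(k, "k", 0L)
  if (k == 0L) return(tibble(sample_id = ids))
  if (k > min(dim(genotypes))) abort("`k` exceeds matrix rank bound")
  Xs <- standardise_dosages(genotypes, match.arg(scaling))
  # eigen of the n x n cross-product: cheap when n << m
  G <- tcrossprod(Xs)
  e <- eigen(G, symmetric = TRUE)
  d <- sqrt(pmax(e$values[seq_len(k)], 0))
  U <- e$vectors[, seq_len(k), drop = FALSE]
  scores <- sweep(U, 2, d, "*")
  for (j in seq_len(k)) {
    if (d[j] > 0) {
      load <- crossprod(Xs, U[, j]) / d[j]
      if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(scores))
}

#' Ancestry clustering on the first two PCs
#'
#' k-means (default k = 4, 10 restarts, fixed seed) on PC1-PC2; the
#' largest cluster is returned as the analysis subset, emulating the
#' selection of the majority-ancestry group.
#'
#' @param pc_coords Tibble from [prs_pca()] with `PC1`, `PC2`.
#' @param k Number of clusters.
#' @param seed Seed for the k-means restarts.
#' @return List with `cluster` (labels per sample), `majority` (ids in
#'   the largest cluster) and `sizes`.
#' @export
ancestry_cluster <- function(pc_coords, k = 4, seed = 1L) {
  if (!all(c("PC1", "PC2") %in% names(pc_coords))) abort("need PC1 and PC2 columns")
  if (nrow(pc_coords) < k) abort("fewer samples than clusters")
  xy <- as.matrix(pc_coords[, c("PC1", "PC2")])
  if (nrow(unique(xy)) < k) {
    # degenerate: fewer distinct points than clusters; assign by point identity
    lab <- as.integer(factor(paste(xy[, 1], xy[, 2])))
  } else {
    km <- withr::with_seed(seed, kmeans(xy, centers = k, nstart = 10))
    lab <- km$cluster
  }
  sizes <- table(lab)
  major <- names(sizes)[which.max(sizes)]
  list(cluster = lab,
       majority = pc_coords$sample_id[lab == as.integer(major)],
       sizes = as.integer(sizes))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
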