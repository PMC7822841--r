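# Polygenic score construction: allele harmonisation, greedy LD
# clumping, P-value thresholding and weighted scoring.

#' Harmonise GWAS summary statistics against target variant metadata
#'
#' Joins summary statistics to the target's variants by SNP id and aligns
#' effect alleles: a record whose effect allele equals the target's
#' counted allele (`allele1`) is kept as is; one whose effect allele
#' equals `allele2` is sign-flipped (beta negated, dosage orientation
#' recorded via `flipped = TRUE`); records whose alleles match neither
#' orientation are excluded. Strand-ambiguous A/T and C/G pairs are
#' excluded by default, as are duplicated ids.
#'
#' @param sumstats Tibble with `snp_id`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p_value` (as from [generate_sumstats()] or
#'   [read_sumstats()]).
#' @param variant_meta Target variant tibble with `snp_id`, `chr`, `bp`,
#'   `allele1`, `allele2`.
#' @param drop_ambiguous Exclude A/T and C/G SNPs (default `TRUE`).
#' @return Harmonised tibble (`snp_id`, `chr`, `bp`, `beta`, `se`,
#'   `p_value`, `flipped`) with the excluded records and their reasons in
#'   attribute `"excluded"`. Errors if no variant survives.
#' @export
harmonise <- function(sumstats, variant_meta, drop_ambiguous = TRUE) {
  ss <- as_tibble(sumstats)
  vm <- as_tibble(variant_meta)
  excluded <- tibble(snp_id = character(0), reason = character(0))

  dup <- unique(c(ss$snp_id[duplicated(ss$snp_id)],
                  vm$snp_id[duplicated(vm$snp_id)]))
  if (length(dup)) {
    excluded <- dplyr::bind_rows(excluded, tibble(snp_id = dup, reason = "duplicate"))
    ss <- ss[!ss$snp_id %in% dup, ]
    vm <- vm[!vm$snp_id %in% dup, ]
  }

  # positions come from the target side
  ss <- ss[, setdiff(names(ss), c("chr", "bp"))]
  j <- dplyr::inner_join(ss, vm[, c("snp_id", "chr", "bp", "allele1", "allele2")],
                         by = "snp_id")
  if (drop_ambiguous) {
    amb <- (j$effect_allele == "A" & j$other_allele == "T") |
      (j$effect_allele == "T" & j$other_allele == "A") |
      (j$effect_allele == "C" & j$other_allele == "G") |
      (j$effect_allele == "G" & j$other_allele == "C")
    excluded <- dplyr::bind_rows(excluded,
                                 tibble(snp_id = j$snp_id[amb], reason = "ambiguous"))
    j <- j[!amb, ]
  }

  same <- j$effect_allele == j$allele1 & j$other_allele == j$allele2
  flip <- j$effect_allele == j$allele2 & j$other_allele == j$allele1
  mism <- !(same | flip)
  excluded <- dplyr::bind_rows(excluded,
                               tibble(snp_id = j$snp_id[mism],
                                      reason = "allele_mismatch"))
  j <- j[!mism, ]
  if (nrow(j) == 0) {
    abort("no variant shared between summary statistics and target after harmonisation")
  }
  flip <- flip[!mism]
  out <- tibble(snp_id = j$snp_id, chr = j$chr, bp = j$bp,
                beta = ifelse(flip, -j$beta, j$beta),
                se = j$se, p_value = j$p_value, flipped = flip)
  attr(out, "excluded") <- excluded
  out
}

#' Greedy LD clumping of harmonised summary statistics
#'
#' Sorts variants by ascending P (ties by position then id), repeatedly
#' takes the most significant unclaimed variant as an index SNP, and
#' claims every unclaimed variant on the same chromosome within
#' `window_kb` kb either side whose squared dosage correlation with the
#' index is at or above `r2_threshold`. LD is the squared Pearson
#' correlation computed from `ld_source` (pairwise-complete over
#' missing calls).
#'
#' @param stats Harmonised tibble from [harmonise()] (needs `snp_id`,
#'   `chr`, `bp`, `p_value`).
#' @param ld_source Sample-by-SNP dosage matrix containing every variant
#'   in `stats` (column names are SNP ids).
#' @param r2_threshold Claim variants with r-squared at or above this
#'   (default 0.1).
#' @param window_kb Half-window in kb around the index SNP (default 250,
#'   i.e. a 500 kb span).
#' @return Tibble of index variants (`snp_id`, `chr`, `bp`, `p_value`,
#'   `n_clumped`) with claimed member ids in list-column `members`.
#' @export
clump <- function(stats, ld_source, r2_threshold = 0.1, window_kb = 250) {
  st <- as_tibble(stats)
  if (any(is.na(st$bp))) abort("missing bp positions")
  missing_ld <- setdiff(st$snp_id, colnames(ld_source))
  if (length(missing_ld)) {
    abort(paste0("ld_source lacks variants: ", paste(head(missing_ld, 5), collapse = ", ")))
  }
  ord <- order(st$p_value, st$bp, st$snp_id)
  st <- st[ord, ]
  n <- nrow(st)
  claimed <- logical(n)
  idx_rows <- integer(0)
  members <- list()
  win <- window_kb * 1000
  for (i in seq_len(n)) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    cand <- which(!claimed & st$chr == st$chr[i] & abs(st$bp - st$bp[i]) <= win)
    mem <- character(0)
    if (length(cand)) {
      r <- suppressWarnings(
        cor(ld_source[, st$snp_id[i]], ld_source[, st$snp_id[cand], drop = FALSE],
            use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      hit <- cand[!is.na(r2) & r2 >= r2_threshold]
      claimed[hit] <- TRUE
      mem <- st$snp_id[hit]
    }
    idx_rows <- c(idx_rows, i)
    members <- c(members, list(mem))
  }
  out <- st[idx_rows, c("snp_id", "chr", "bp", "p_value")]
  out$n_clumped <- lengths(members) + 1L
  out$members <- members
  out
}

#' P-value thresholding of clumped variants
#'
#' Retains variants with P strictly below `p_t`. The best-fit profile
#' uses `p_t = 0.05`; the genome-wide-significant profile uses
#' `p_t = 5e-8` or an explicit sentinel-id list.
#'
#' @param stats Tibble with `snp_id` and `p_value` (typically the
#'   harmonised stats restricted to clump index SNPs).
#' @param p_t Inclusion threshold (strict `<`).
#' @param sentinel_ids Optional explicit SNP-id list overriding `p_t`.
#' @return The retained subset of `stats`.
#' @export
threshold_variants <- function(stats, p_t = 0.05, sentinel_ids = NULL) {
  if (!is.null(sentinel_ids)) return(stats[stats$snp_id %in% sentinel_ids, ])
  stats[stats$p_value < p_t, ]
}

#' Compute polygenic scores
#'
#' The score of individual i is the sum over the selected variants of the
#' harmonised effect-allele dosage weighted by the (sign-flipped where
#' needed) log odds ratio. Flipped variants count `2 - dosage`; missing
#' dosages are imputed with twice the sample effect-allele frequency.
#' Scores are standardised to zero mean / unit SD by default for
#' downstream regression.
#'
#' @param genotypes Sample-by-SNP dosage matrix (dosages count the
#'   target's `allele1`).
#' @param stats Harmonised, clumped, thresholded tibble (`snp_id`,
#'   `beta`, `flipped`).
#' @param standardise Standardise scores (default `TRUE`).
#' @param label Profile label, e.g. `"best_fit"` or `"gw_significant"`.
#' @param p_threshold The inclusion threshold that produced `stats`
#'   (recorded in the output).
#' @return PRS profile tibble (`sample_id`, `score`, `n_snps`, `label`,
#'   `p_threshold`) with the SNP set in attribute `"snp_set"`.
#' @export
prs_score <- function(genotypes, stats, standardise = TRUE,
                      label = "best_fit", p_threshold = NA_real_) {
  if (nrow(stats) == 0) abort("empty SNP subset: no variants to score")
  miss <- setdiff(stats$snp_id, colnames(genotypes))
  if (length(miss)) abort(paste0("genotypes lack variants: ", paste(head(miss, 5), collapse = ", ")))
  X <- genotypes[, stats$snp_id, drop = FALSE]
  flip <- stats$flipped %||% rep(FALSE, nrow(stats))
  # flipped records carry the beta re-oriented to the target's counted
  # allele; undo that to weight the effect-allele dosage (2 - d) by the
  # discovery-scale log OR
  w <- ifelse(flip, -stats$beta, stats$beta)
  X[, flip] <- 2 - X[, flip, drop = FALSE]
  # mean imputation at the effect-allele frequency
  if (anyNA(X)) {
    mu <- 2 * allele_freq(X)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  score <- as.vector(X %*% w)
  if (standardise) {
    s <- sd(score)
    score <- if (s > 0) (score - mean(score)) / s else score - mean(score)
  }
  out <- tibble(sample_id = rownames(genotypes) %||% as.character(seq_len(nrow(genotypes))),
                score = score, n_snps = nrow(stats),
                label = label, p_threshold = p_threshold)
  attr(out, "snp_set") <- stats$snp_id
  out
}

#' Build a polygenic risk score profile end to end
#'
#' Convenience wrapper chaining [harmonise()], [clump()],
#' [threshold_variants()] and [prs_score()]. `profile = "best_fit"` uses
#' the lenient P < 0.05 inclusion rule; `profile = "gw_significant"`
#' restricts to genome-wide significant index SNPs (P < 5e-8, or an
#' explicit sentinel list).
#'
#' @param genotypes Target dosage matrix.
#' @param variant_meta Target variant tibble.
#' @param sumstats Discovery summary statistics.
#' @param profile `"best_fit"` or `"gw_significant"`.
#' @param p_t Override of the profile's P threshold.
#' @param sentinel_ids Explicit sentinel SNP ids for the GW profile.
#' @param r2_threshold,window_kb Clumping parameters.
#' @param standardise Standardise the scores.
#' @return PRS profile tibble (see [prs_score()]).
#' @export
build_prs <- function(genotypes, variant_meta, sumstats,
                      profile = c("best_fit", "gw_significant"),
                      p_t = NULL, sentinel_ids = NULL,
                      r2_threshold = 0.1, window_kb = 250,
                      standardise = TRUE) {
  profile <- match.arg(profile)
  if (is.null(p_t)) p_t <- if (profile == "best_fit") 0.05 else 5e-8
  h <- harmonise(sumstats, variant_meta)
  idx <- clump(h, genotypes, r2_threshold = r2_threshold, window_kb = window_kb)
  sel <- threshold_variants(h[h$snp_id %in% idx$snp_id, ], p_t = p_t,
                            sentinel_ids = sentinel_ids)
  if (nrow(sel) == 0) abort("no variant passes the inclusion threshold")
  prs_score(genotypes, sel, standardise = standardise,
            label = profile, p_threshold = p_t)
}
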