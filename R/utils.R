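# shared internal helpers

# Wald p-value from estimate/se, clamped into (0, 1] so downstream filters
# on strict inequalities never see an exact zero.
wald_p <- function(estimate, se) {
  p <- 2 * pnorm(-abs(estimate / se))
  p[is.nan(p)] <- 1            # 0/0: no information
  pmax(p, .Machine$double.xmin)
}

# effect-allele frequency of a dosage vector/matrix column (dosages count
# the effect allele, 0/1/2, NA allowed)
allele_freq <- function(x) {
  colMeans(as.matrix(x), na.rm = TRUE) / 2
}

# column-standardise a dosage matrix; zero-variance columns are dropped.
# scaling = "patterson": sd replaced by sqrt(2p(1-p)); "sd": sample sd.
standardise_dosages <- function(geno, scaling = c("patterson", "sd")) {
  scaling <- match.arg(scaling)
  p <- allele_freq(geno)
  ctr <- 2 * p
  s <- if (scaling == "patterson") sqrt(2 * p * (1 - p)) else apply(geno, 2, sd, na.rm = TRUE)
  keep <- which(is.finite(s) & s > 0)
  if (length(keep) == 0L) abort("all variants have zero variance")
  x <- sweep(geno[, keep, drop = FALSE], 2, ctr[keep], "-")
  x <- sweep(x, 2, s[keep], "/")
  x[is.na(x)] <- 0             # mean imputation after centring
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prop <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be in %s%g, %g%s", name,
                         if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]"))
  as.numeric(x)
}
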