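# broom-style accessors for the fitted result objects.

#' Tidy a quantile trend
#'
#' @param x A `quantile_trend`.
#' @param ... Ignored.
#' @return Tibble with one row per bin / case group: `group`,
#'   `group_type`, `n`, `estimate`, `ci_low`, `ci_high`.
#' @export
tidy.quantile_trend <- function(x, ...) {
  dplyr::select(x$table, "group", "group_type", "n",
                "estimate", "ci_low", "ci_high")
}

#' Glance at a quantile trend
#'
#' @param x A `quantile_trend`.
#' @param ... Ignored.
#' @return One-row tibble: trait, family, bin count, reference bin, the
#'   least-squares slope of bin coefficients on bin index with its
#'   P-value, and case-group concordance labels when case groups are
#'   appended.
#' @export
glance.quantile_trend <- function(x, ...) {
  qt <- x$table[x$table$group_type == "quantile", ]
  idx <- as.numeric(qt$group)
  sm <- summary(lm(qt$estimate ~ idx))$coefficients
  out <- tibble(trait = x$trait, family = x$family, k = x$k,
                reference = x$reference,
                trend_slope = sm["idx", 1], trend_slope_p = sm["idx", 4])
  if (any(x$table$group_type == "case")) {
    cls <- classify_concordance(x)
    out$concordance <- paste(cls$group, cls$classification,
                             sep = ":", collapse = ", ")
  }
  out
}

#' Tidy a PRS screen
#'
#' @param x A `prs_screen`.
#' @param ... Ignored.
#' @return The association table as a plain tibble.
#' @export
tidy.prs_screen <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Glance at a PRS screen
#'
#' @param x A `prs_screen`.
#' @param ... Ignored.
#' @return One-row tibble: traits screened, Bonferroni cutoff, and hit
#'   counts at each significance tier.
#' @export
glance.prs_screen <- function(x, ...) {
  tibble(n_traits = attr(x, "n_traits"),
         bonferroni_cutoff = attr(x, "bonferroni_cutoff"),
         n_bonferroni = sum(x$bonferroni),
         n_stringent = sum(x$stringent))
}
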