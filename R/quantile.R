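# PRS-quantile trait trends with diagnosed case groups appended: the
# signature contrast between the undiagnosed population's PRS-by-trait
# gradient and trait values in non-medicated / medicated cases.

#' Assign equal-count PRS bins
#'
#' Rank-based binning into `k` equal-count bins ordered by ascending PRS
#' (bin 1 = lowest 5\% of genetic liability at the default `k = 20`).
#' Ties are broken by stable sample order; bin sizes differ by at most
#' one, the larger bins coming first.
#'
#' @param prs Numeric score vector (finite).
#' @param k Number of bins (default 20).
#' @return Integer bin labels in `1..k`, same length/order as `prs`.
#' @export
bin_by_prs <- function(prs, k = 20) {
  if (any(!is.finite(prs))) abort("PRS values must be finite")
  n <- length(prs)
  k <- check_count(k, "k")
  if (n < k) abort("fewer observations than bins")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[order(prs)] <- rep(seq_len(k), times = sizes)
  bins
}

qt_fit <- function(frame, covariates, levels_all, reference, family) {
  frame$.bin <- factor(frame$.bin, levels = levels_all)
  frame$.bin <- stats::relevel(frame$.bin, ref = as.character(reference))
  rhs <- if (length(covariates)) paste(c(".bin", covariates), collapse = " + ") else ".bin"
  f <- stats::as.formula(paste(".y ~", rhs))
  fit <- if (family == "linear") lm(f, data = frame) else
    suppressWarnings(glm(f, data = frame, family = binomial()))
  sm <- summary(fit)$coefficients
  counts <- table(frame$.bin)[levels_all]
  est <- se <- rep(NA_real_, length(levels_all))
  names(est) <- names(se) <- levels_all
  est[as.character(reference)] <- 0
  se[as.character(reference)] <- 0
  for (l in levels_all) {
    nm <- paste0(".bin", l)
    if (nm %in% rownames(sm)) {
      est[l] <- sm[nm, 1]
      se[l] <- sm[nm, 2]
    }
  }
  tibble(group = levels_all,
         n = as.integer(counts),
         estimate = as.numeric(est),
         ci_low = as.numeric(est - 1.96 * se),
         ci_high = as.numeric(est + 1.96 * se))
}

#' Fit the PRS-quantile trait trend
#'
#' Regresses the trait on one-hot bin indicators (the reference bin,
#' the 11th by default, omitted so its coefficient is identically zero)
#' plus covariates, by linear or logistic regression. Each bin's
#' coefficient estimates the trait difference between that PRS stratum
#' and the reference stratum; 95\% Wald confidence intervals are
#' reported. With no covariates and a linear family the coefficients
#' equal the bin trait means minus the reference bin mean exactly.
#'
#' @param data Per-individual tibble for the screened (undiagnosed)
#'   subset.
#' @param trait Trait column name.
#' @param bins Integer bin labels from [bin_by_prs()].
#' @param covariates Covariate column names.
#' @param reference Reference bin index (default 11).
#' @param family `"linear"` or `"logistic"`.
#' @return A `quantile_trend` object; its `table` has one row per bin
#'   (`group`, `n`, `estimate`, `ci_low`, `ci_high`, `group_type`). Bins
#'   emptied by missing-data deletion are flagged with `NA` estimates
#'   and a warning.
#' @export
fit_quantile_trend <- function(data, trait, bins, covariates = character(),
                               reference = 11, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(bins) != nrow(data)) abort("`bins` must match `data` rows")
  k <- max(bins)
  if (!reference %in% seq_len(k)) abort("`reference` is not a bin index")
  cols <- c(trait, covariates)
  frame <- as.data.frame(data[, cols, drop = FALSE])
  names(frame)[1] <- ".y"
  frame$.bin <- bins
  ok <- complete.cases(frame)
  frame <- frame[ok, , drop = FALSE]
  lv <- as.character(seq_len(k))
  if (!all(lv %in% as.character(frame$.bin))) {
    warn("one or more bins are empty after missing-data deletion")
  }
  tab <- qt_fit(frame, covariates, lv, reference, family)
  tab$group_type <- "quantile"
  structure(
    list(table = tab, reference = reference, trait = trait, family = family,
         covariates = covariates, frame = frame, k = k),
    class = "quantile_trend")
}

#' Append diagnosed case groups to a quantile trend
#'
#' Refits the trend regression with the diagnosed individuals added as
#' extra factor levels beyond the 20 quantiles — a non-medicated and a
#' medicated group when medication status is available (a single `case`
#' group otherwise) — reflecting the expected higher genetic burden of
#' diagnosed individuals. The undiagnosed individuals keep their original
#' bins; the case groups' coefficients are estimated against the same
#' reference bin in the same regression.
#'
#' @param trend A [fit_quantile_trend()] result (fitted on the
#'   undiagnosed subset only).
#' @param data Full-cohort tibble with the trait, the covariates used in
#'   `trend`, and logical `diagnosed` / `medicated` columns.
#' @return The `quantile_trend` with case-group rows
#'   (`group_type = "case"`) appended and all coefficients refitted
#'   jointly. Zero diagnosed individuals gives a warning and the trend
#'   unchanged.
#' @export
append_case_groups <- function(trend, data) {
  stopifnot(inherits(trend, "quantile_trend"))
  if (!"diagnosed" %in% names(data)) abort("`data` needs a `diagnosed` column")
  cases <- data[data$diagnosed %in% TRUE, , drop = FALSE]
  if (nrow(cases) == 0) {
    warn("no diagnosed individuals; case groups omitted")
    return(trend)
  }
  have_med <- "medicated" %in% names(cases) && any(cases$medicated)
  grp <- if (have_med) ifelse(cases$medicated, "medicated", "non_medicated")
         else rep("case", nrow(cases))
  extra <- as.data.frame(cases[, c(trend$trait, trend$covariates), drop = FALSE])
  names(extra)[1] <- ".y"
  extra$.bin <- grp
  extra <- extra[complete.cases(extra), , drop = FALSE]
  frame <- rbind(trend$frame, extra)
  case_levels <- if (have_med) c("non_medicated", "medicated") else "case"
  lv <- c(as.character(seq_len(trend$k)), case_levels)
  tab <- qt_fit(frame, trend$covariates, lv, trend$reference, trend$family)
  tab$group_type <- c(rep("quantile", trend$k), rep("case", length(case_levels)))
  trend$table <- tab
  trend$case_groups <- case_levels
  trend
}

#' Test case groups against the top PRS quantile
#'
#' For each diagnosed case group, regresses the trait on a group
#' indicator contrasting the case group with the top 5\% PRS bin of the
#' undiagnosed population, with covariate adjustment, and reports the
#' Wald effect and P-value.
#'
#' @param data Full-cohort tibble with trait, PRS, covariates and
#'   `diagnosed` / `medicated` columns.
#' @param trait,prs,covariates Column names.
#' @param family `"linear"` or `"logistic"`.
#' @param k Number of PRS bins defining the top quantile (default 20).
#' @return Tibble with one row per case group: `group`, `n_cases`,
#'   `n_top`, `estimate`, `se`, `p_value`.
#' @export
case_vs_top_quantile <- function(data, trait, prs = "prs",
                                 covariates = character(),
                                 family = c("linear", "logistic"), k = 20) {
  family <- match.arg(family)
  undiag <- data[!(data$diagnosed %in% TRUE), , drop = FALSE]
  cases <- data[data$diagnosed %in% TRUE, , drop = FALSE]
  if (nrow(cases) == 0) abort("no diagnosed individuals to contrast")
  bins <- bin_by_prs(undiag[[prs]], k = k)
  top <- undiag[bins == k, , drop = FALSE]
  have_med <- "medicated" %in% names(cases) && any(cases$medicated)
  groups <- if (have_med) {
    list(non_medicated = cases[!cases$medicated, , drop = FALSE],
         medicated = cases[cases$medicated, , drop = FALSE])
  } else list(case = cases)
  purrr::imap_dfr(groups, function(gdat, gname) {
    if (nrow(gdat) == 0) return(NULL)
    df <- rbind(
      data.frame(.y = top[[trait]], .grp = 0, top[, covariates, drop = FALSE]),
      data.frame(.y = gdat[[trait]], .grp = 1, gdat[, covariates, drop = FALSE]))
    df <- df[complete.cases(df), , drop = FALSE]
    rhs <- if (length(covariates)) paste(c(".grp", covariates), collapse = " + ") else ".grp"
    f <- stats::as.formula(paste(".y ~", rhs))
    fit <- if (family == "linear") lm(f, data = df) else
      suppressWarnings(glm(f, data = df, family = binomial()))
    sm <- summary(fit)$coefficients
    tibble(group = gname, n_cases = sum(df$.grp == 1), n_top = sum(df$.grp == 0),
           estimate = sm[".grp", 1], se = sm[".grp", 2],
           p_value = wald_p(sm[".grp", 1], sm[".grp", 2]))
  })
}

#' Classify trend/case-group concordance
#'
#' The trend direction is the sign of the least-squares slope of the bin
#' coefficients on bin index over the 20 quantiles. A case group is
#' `concordant` when its coefficient has the same sign as a nominally
#' significant (P < `alpha`) trend slope, `discordant` when the signs
#' oppose, and `flat` when the trend slope is not significant. This
#' operationalises the visual rule of reading whether diagnosed
#' individuals continue the gradient seen across the PRS strata.
#'
#' @param trend A `quantile_trend` with case groups appended.
#' @param alpha Nominal significance level for the trend slope.
#' @return Tibble: `group`, `classification`, `slope`, `slope_p`.
#' @export
classify_concordance <- function(trend, alpha = 0.05) {
  stopifnot(inherits(trend, "quantile_trend"))
  qt <- trend$table[trend$table$group_type == "quantile", ]
  ct <- trend$table[trend$table$group_type == "case", ]
  if (nrow(ct) == 0) abort("trend has no appended case groups")
  idx <- as.numeric(qt$group)
  fit <- lm(qt$estimate ~ idx)
  sm <- summary(fit)$coefficients
  slope <- sm["idx", 1]
  slope_p <- sm["idx", 4]
  cls <- vapply(ct$estimate, function(est) {
    if (slope_p >= alpha) "flat"
    else if (sign(est) == sign(slope)) "concordant"
    else "discordant"
  }, character(1))
  tibble(group = ct$group, classification = cls,
         slope = slope, slope_p = slope_p)
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat(sprintf("<quantile_trend> trait: %s | %s | %d bins, reference %d\n",
              x$trait, x$family, x$k, x$reference))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}
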