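# PRS-trait association screening with covariate adjustment, incremental
# variance explained, Bonferroni + stringent significance flags, profile
# concordance and the PC-count sensitivity analysis.

nagelkerke_r2 <- function(fit, null_dev, n) {
  cox_snell <- 1 - exp((fit$deviance - null_dev) / n)
  cox_snell / (1 - exp(-null_dev / n))
}

#' Test one trait for association with a PRS
#'
#' Fits a covariates-only and a covariates-plus-PRS regression on
#' complete cases (listwise deletion over trait, PRS and covariates) and
#' reports the PRS term's Wald statistics together with the incremental
#' variance explained: the R-squared difference for linear models and the
#' Nagelkerke pseudo-R-squared difference for logistic models.
#'
#' @param data Tibble with one row per individual (e.g. from
#'   [cohort_table()]).
#' @param trait Trait column name.
#' @param prs PRS column name (default `"prs"`).
#' @param covariates Character vector of covariate column names.
#' @param family `"linear"` or `"logistic"`; `"auto"` picks logistic for
#'   0/1 traits.
#' @return One-row `AssociationResult` tibble: `trait`, `family`, `beta`,
#'   `se`, `p_value`, `r2_incremental`, `n_used`, `covariate_set`,
#'   `prs_label`, `converged`. Separation or non-convergence in the
#'   logistic fit flags `converged = FALSE` rather than erroring.
#' @export
prs_associate <- function(data, trait, prs = "prs", covariates = character(),
                          family = c("auto", "linear", "logistic")) {
  family <- match.arg(family)
  cols <- c(trait, prs, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[, cols])
  names(df)[1:2] <- c(".y", ".prs")
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  y <- df$.y
  if (length(unique(y)) < 2) abort(paste0("constant trait: ", trait))
  if (family == "auto") {
    family <- if (all(y %in% c(0, 1))) "logistic" else "linear"
  }
  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_cov <- stats::as.formula(paste(".y ~", rhs_cov))
  f_full <- stats::as.formula(paste(".y ~ .prs +", rhs_cov))

  converged <- TRUE
  if (family == "linear") {
    fit_cov <- lm(f_cov, data = df)
    fit_full <- lm(f_full, data = df)
    sm <- summary(fit_full)$coefficients
    r2_inc <- summary(fit_full)$r.squared - summary(fit_cov)$r.squared
  } else {
    handler <- function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
    fit_cov <- withCallingHandlers(glm(f_cov, data = df, family = binomial()),
                                   warning = handler)
    fit_full <- withCallingHandlers(glm(f_full, data = df, family = binomial()),
                                    warning = handler)
    if (!fit_full$converged) converged <- FALSE
    sm <- summary(fit_full)$coefficients
    null_dev <- fit_cov$null.deviance
    r2_inc <- nagelkerke_r2(fit_full, null_dev, n) -
      nagelkerke_r2(fit_cov, null_dev, n)
  }
  beta <- sm[".prs", 1]
  se <- sm[".prs", 2]
  tibble(trait = trait, family = family, beta = beta, se = se,
         p_value = wald_p(beta, se),
         r2_incremental = max(0, r2_inc),
         n_used = n,
         covariate_set = if (length(covariates)) paste(covariates, collapse = "+") else "none",
         prs_label = prs, converged = converged)
}

#' Screen many traits for PRS association
#'
#' Runs [prs_associate()] for every trait and applies the two-tier
#' significance rule: `bonferroni` flags P below 0.05 divided by the
#' number of traits screened, and `stringent` flags P below 1e-7 (the
#' conservative threshold guarding against subtle confounding at biobank
#' sample sizes). Results are sorted by P.
#'
#' @param data Per-individual tibble.
#' @param traits Character vector of trait column names.
#' @param prs,covariates Passed to [prs_associate()].
#' @param families Optional named character vector (`"linear"` /
#'   `"logistic"`) per trait; auto-detected otherwise.
#' @return A `prs_screen` tibble of association results with `bonferroni`
#'   and `stringent` flags; the cutoff is in attribute
#'   `"bonferroni_cutoff"`.
#' @export
prs_screen <- function(data, traits, prs = "prs", covariates = character(),
                       families = NULL) {
  if (length(traits) < 1) abort("need at least one trait")
  res <- purrr::map_dfr(traits, function(tr) {
    fam <- if (!is.null(families) && tr %in% names(families)) families[[tr]] else "auto"
    prs_associate(data, tr, prs = prs, covariates = covariates, family = fam)
  })
  cutoff <- 0.05 / length(traits)
  res$bonferroni <- res$p_value < cutoff
  res$stringent <- res$p_value < 1e-7
  res <- dplyr::arrange(res, .data$p_value)
  structure(res, class = c("prs_screen", class(res)),
            bonferroni_cutoff = cutoff, n_traits = length(traits))
}

#' Bonferroni cutoff of a screen
#' @param x A `prs_screen`.
#' @return The corrected significance cutoff (0.05 / number of traits).
#' @export
bonferroni_cutoff <- function(x) attr(x, "bonferroni_cutoff")

#' Concordance between best-fit and GW-significant PRS screens
#'
#' Compares, trait by trait, the association results obtained with the
#' best-fit PRS and with the genome-wide-significant-only PRS: effect
#' signs, nominal significance (P < 0.05) of the GW profile, and the
#' count of stringent best-fit hits that replicate (GW-nominal with the
#' same sign).
#'
#' @param results_best_fit,results_gw Association tables over the same
#'   trait set (e.g. two [prs_screen()] outputs).
#' @return Tibble (`trait`, `beta_best_fit`, `beta_gw`, `p_best_fit`,
#'   `p_gw`, `sign_agreement`, `gw_nominal`, `stringent_best_fit`,
#'   `replicated`) with summary counts in attribute `"summary"`.
#' @export
compare_profiles <- function(results_best_fit, results_gw) {
  a <- as_tibble(results_best_fit)
  b <- as_tibble(results_gw)
  if (!setequal(a$trait, b$trait)) abort("trait sets differ between profiles")
  j <- dplyr::inner_join(
    dplyr::select(a, "trait", beta_best_fit = "beta", p_best_fit = "p_value"),
    dplyr::select(b, "trait", beta_gw = "beta", p_gw = "p_value"),
    by = "trait")
  j$sign_agreement <- sign(j$beta_best_fit) == sign(j$beta_gw)
  j$gw_nominal <- j$p_gw < 0.05
  j$stringent_best_fit <- j$p_best_fit < 1e-7
  j$replicated <- j$stringent_best_fit & j$gw_nominal & j$sign_agreement
  attr(j, "summary") <- list(n_stringent = sum(j$stringent_best_fit),
                             n_replicated = sum(j$replicated))
  j
}

#' Sensitivity of an association to the number of PCs adjusted for
#'
#' Refits the PRS-trait association with increasing numbers of principal
#' components in the covariate set and reports each estimate together
#' with its ratio to the smallest-k estimate. Stable ratios near 1
#' indicate the association is not driven by population structure
#' captured by the additional PCs.
#'
#' @param data Per-individual tibble containing `PC1`, `PC2`, ...
#' @param trait,prs,covariates,family As in [prs_associate()];
#'   `covariates` are the non-PC covariates.
#' @param k_list PC counts to adjust for (default 15 and 40).
#' @return Tibble with one row per k: `k`, `beta`, `se`, `p_value`,
#'   `r2_incremental`, `beta_ratio`.
#' @export
pc_sensitivity <- function(data, trait, prs = "prs", covariates = character(),
                           k_list = c(15, 40), family = "auto") {
  k_list <- sort(unique(as.integer(k_list)))
  pcs_needed <- paste0("PC", seq_len(max(k_list)))
  if (!all(pcs_needed %in% names(data))) {
    abort(sprintf("data has fewer than %d PC columns", max(k_list)))
  }
  res <- purrr::map_dfr(k_list, function(k) {
    r <- prs_associate(data, trait, prs = prs,
                       covariates = c(covariates, paste0("PC", seq_len(k))),
                       family = family)
    dplyr::mutate(dplyr::select(r, "beta", "se", "p_value", "r2_incremental"),
                  k = k, .before = 1)
  })
  res$beta_ratio <- res$beta / res$beta[1]
  res
}
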