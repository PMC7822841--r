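# Disorder, trait, location and summary-statistic simulation, plus the
# seeded orchestrator that assembles a full synthetic cohort.

# unit-norm effect direction over a random causal subset
draw_effect_direction <- function(m, n_causal) {
  idx <- sort(sample.int(m, n_causal))
  u <- rnorm(n_causal)
  u <- u / sqrt(sum(u^2))
  list(idx = idx, u = u)
}

# standardised polygenic score for a weight direction; empirically scaled
# to mean 0 / sd 1 so LD between causal SNPs cannot inflate the variance
std_genetic_score <- function(geno, idx, u) {
  X <- geno[, idx, drop = FALSE]
  p <- allele_freq(X)
  s <- sqrt(2 * p * (1 - p))
  s[s == 0] <- 1
  Xs <- sweep(sweep(X, 2, 2 * p, "-"), 2, s, "/")
  Xs[is.na(Xs)] <- 0
  g <- as.vector(Xs %*% u)
  sdg <- sd(g)
  if (!is.finite(sdg) || sdg == 0) sdg <- 1
  list(score = (g - mean(g)) / sdg, scale = sdg, col_sd = s)
}

#' Simulate a liability-threshold disorder with diagnosis and medication
#'
#' Liability is the sum of a standardised genetic score over `n_causal`
#' SNPs (variance `h2_liability`), any scenario-specific contribution
#' (`pleiotropy`: a heritable mediator; `trait_to_disorder`:
#' `trait_effect` times the standardised trait), and a Gaussian residual;
#' the total is standardised empirically so its variance is 1. Individuals
#' above the `1 - prevalence` normal quantile are true cases; a random
#' `misclassification_rate` fraction of true cases is relabelled
#' unaffected (true status is kept for oracle checks). Among labelled
#' cases, medication is Bernoulli with probability
#' `plogis(medication_prob_slope * (liability - threshold))`, so a
#' positive slope makes medicated cases genetically more burdened on
#' average than non-medicated cases.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param config A [scenario_config()].
#' @param trait Standardisable trait vector; required for scenario
#'   `trait_to_disorder` (the trait must be simulated first).
#' @param effects Optional effect direction (as returned in the result's
#'   `effects` element) to share the causal set with a pre-simulated
#'   trait; drawn fresh otherwise.
#' @return List: `status` tibble (`liability`, `diagnosed_true`,
#'   `diagnosed`, `medicated`), `true_effect` (per-SNP direct effect of
#'   one effect-allele dose on standardised liability, a log-odds-ratio
#'   proxy), `effects`, `genetic_score` (standardised), and `mediator`
#'   (the latent mediator for scenario `pleiotropy`, else `NULL`).
#' @export
simulate_disorder <- function(genotypes, config, trait = NULL, effects = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  check_prop(config$h2_liability, "h2_liability")
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  h2 <- config$h2_liability
  te <- config$trait_effect
  h2t <- config$h2_trait

  eff <- effects %||% draw_effect_direction(m, config$n_causal)
  gs <- std_genetic_score(genotypes, eff$idx, eff$u)
  beta_dos <- numeric(m)
  if (h2 > 0) {
    beta_dos[eff$idx] <- sqrt(h2) * eff$u / (gs$scale * gs$col_sd)
  }

  extra <- 0
  mediator <- NULL
  med_eff <- NULL
  if (config$scenario == "pleiotropy") {
    med_eff <- draw_effect_direction(m, config$n_causal)
    gm <- std_genetic_score(genotypes, med_eff$idx, med_eff$u)
    mediator <- sqrt(h2t) * gm$score + sqrt(1 - h2t) * rnorm(n)
    extra <- te * mediator
    beta_dos[med_eff$idx] <- beta_dos[med_eff$idx] +
      te * sqrt(h2t) * med_eff$u / (gm$scale * gm$col_sd)
  } else if (config$scenario == "trait_to_disorder") {
    if (is.null(trait)) {
      abort("scenario `trait_to_disorder` needs the trait simulated first")
    }
    sd_t <- sd(trait)
    if (sd_t == 0) sd_t <- 1
    extra <- te * (trait - mean(trait)) / sd_t
    # the trait's genetic part shares the disorder's causal direction
    beta_dos[eff$idx] <- beta_dos[eff$idx] +
      te * sqrt(h2t) * eff$u / (gs$scale * gs$col_sd * sd_t)
  }

  raw <- sqrt(h2) * gs$score + extra + sqrt(1 - h2) * rnorm(n)
  s_tot <- sd(raw)
  if (!is.finite(s_tot) || s_tot == 0) s_tot <- 1
  liability <- (raw - mean(raw)) / s_tot

  thr <- qnorm(1 - config$prevalence)
  diagnosed_true <- liability > thr
  flipped <- diagnosed_true & runif(n) < config$misclassification_rate
  diagnosed <- diagnosed_true & !flipped
  medicated <- rep(FALSE, n)
  idx_dx <- which(diagnosed)
  if (length(idx_dx)) {
    pr <- plogis(config$medication_prob_slope * (liability[idx_dx] - thr))
    medicated[idx_dx] <- runif(length(idx_dx)) < pr
  }

  list(
    status = tibble(liability = as.numeric(liability),
                    diagnosed_true = diagnosed_true,
                    diagnosed = diagnosed, medicated = medicated),
    true_effect = beta_dos / s_tot,
    effects = eff, mediator_effects = med_eff,
    genetic_score = gs$score, mediator = mediator
  )
}

#' Simulate the scenario trait (and optional control traits)
#'
#' Generates the behavioural trait under the configured causal scenario
#' (see [scenario_config()]). `null` traits are pure noise; `pleiotropy`
#' traits load on the latent mediator; `structure` traits take the
#' per-subpopulation `env_gradient` offset with no individual-level
#' genetic effect; `disorder_to_trait` traits shift by `trait_effect` in
#' true (pre-misclassification) cases; `trait_to_disorder` traits have
#' their own genetic basis (heritability `h2_trait`) on the disorder's
#' causal SNP set. Medicated individuals are additionally shifted by
#' `medication_trait_shift`, and the genotype-independent deprivation
#' index contributes `deprivation_trait_effect` per SD when supplied.
#'
#' @param cohort A list/cohort carrying the pieces the scenario needs:
#'   `genotypes`, `subpop`, and (depending on scenario/options) `status`,
#'   `mediator`, `effects`, `deprivation`.
#' @param config A [scenario_config()].
#' @return Numeric trait vector; for scenario `trait_to_disorder` the
#'   shared effect direction is attached as attribute `"effects"`.
#' @export
simulate_trait <- function(cohort, config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(cohort$genotypes)
  te <- config$trait_effect
  h2t <- config$h2_trait
  eff_out <- NULL

  trait <- switch(
    config$scenario,
    null = rnorm(n),
    pleiotropy = {
      if (is.null(cohort$mediator)) {
        abort("scenario `pleiotropy` needs the disorder (and its mediator) simulated first")
      }
      te * cohort$mediator + rnorm(n)
    },
    structure = {
      if (is.null(cohort$subpop)) abort("scenario `structure` needs subpopulation labels")
      config$env_gradient[cohort$subpop] + rnorm(n)
    },
    disorder_to_trait = {
      if (is.null(cohort$status)) {
        abort("scenario `disorder_to_trait` needs the disorder simulated first")
      }
      rnorm(n) + te * cohort$status$diagnosed_true
    },
    trait_to_disorder = {
      eff_out <- cohort$effects %||% draw_effect_direction(ncol(cohort$genotypes),
                                                           config$n_causal)
      gs <- std_genetic_score(cohort$genotypes, eff_out$idx, eff_out$u)
      sqrt(h2t) * gs$score + sqrt(1 - h2t) * rnorm(n)
    },
    abort(paste0("unknown scenario: ", config$scenario))
  )

  if (!is.null(cohort$deprivation) && config$deprivation_trait_effect != 0) {
    trait <- trait + config$deprivation_trait_effect * cohort$deprivation
  }
  if (!is.null(cohort$status) && config$medication_trait_shift != 0) {
    trait <- trait + config$medication_trait_shift * cohort$status$medicated
  }
  if (!is.null(eff_out)) attr(trait, "effects") <- eff_out
  trait
}

#' Simulate birth/current residence coordinates on a density raster
#'
#' Birth coordinates are uniform on the map; a fraction `p_move` of
#' individuals relocate by a log-normal displacement whose log-magnitude
#' increases by `migration_coupling` per SD of the risk-taking-like trait
#' and by `migration_dep_coupling` per deprivation-index SD (the
#' confounding path). Time at current residence decreases with the
#' displacement. Coordinates are clamped inside the map.
#'
#' @param samples Tibble with `sample_id` and optionally
#'   `deprivation_index`.
#' @param config A [scenario_config()].
#' @param trait Risk-taking-like trait driving migration when
#'   `migration_coupling != 0`; required in that case.
#' @param map A [density_map()]; generated with [make_density_map()] when
#'   `NULL`.
#' @param p_move Fraction of movers; `0` makes every displacement zero.
#' @return List with `locations` (tibble: `sample_id`, `birth_e`,
#'   `birth_n`, `current_e`, `current_n`, `years_at_residence`) and `map`.
#' @export
simulate_locations <- function(samples, config, trait = NULL, map = NULL,
                               p_move = 0.7) {
  n <- nrow(samples)
  ext <- config$map_extent_km
  if (is.null(map)) {
    map <- make_density_map(extent_km = ext, cell_km = config$map_cell_km)
  }
  if (config$migration_coupling != 0 && is.null(trait)) {
    abort("migration-trait coupling requested but no trait supplied")
  }
  tr <- if (is.null(trait)) numeric(n) else as.numeric(scale(trait))
  dep <- samples$deprivation_index %||% numeric(n)

  birth_e <- runif(n, 0, ext)
  birth_n <- runif(n, 0, ext)
  move <- runif(n) < p_move
  mag <- ifelse(move,
                exp(log(8) + config$migration_coupling * tr +
                      config$migration_dep_coupling * dep + 0.9 * rnorm(n)),
                0)
  ang <- runif(n, 0, 2 * pi)
  eps <- 1e-6
  cur_e <- pmin(pmax(birth_e + mag * cos(ang), 0), ext - eps)
  cur_n <- pmin(pmax(birth_n + mag * sin(ang), 0), ext - eps)
  d <- sqrt((cur_e - birth_e)^2 + (cur_n - birth_n)^2)
  years <- pmax(0, round(25 - 0.05 * d + 8 * rnorm(n)))

  list(
    locations = tibble(sample_id = samples$sample_id,
                       birth_e = birth_e, birth_n = birth_n,
                       current_e = cur_e, current_n = cur_n,
                       years_at_residence = years),
    map = map
  )
}

#' Generate GWAS summary statistics for the simulated disorder
#'
#' `mode = "oracle"` emulates a large external discovery GWAS: the
#' estimated log odds ratio is the true per-allele effect plus Gaussian
#' noise with the standard case-control standard error
#' `1 / sqrt(2 p (1-p) n phi (1-phi))` at the nominal discovery size `n`
#' and case fraction `phi`; P-values are two-sided Wald. `mode =
#' "cohort_gwas"` runs a per-SNP logistic regression of diagnosis on
#' dosage in an independently simulated discovery cohort.
#'
#' @param cohort A cohort from [simulate_cohort()] (oracle mode uses its
#'   `variant_meta$true_effect` and target allele frequencies; gwas mode
#'   regresses its own diagnosis labels).
#' @param mode `"oracle"` or `"cohort_gwas"`.
#' @param n_discovery,phi Nominal discovery sample size and case fraction
#'   (oracle mode).
#' @return Summary-statistics tibble: `snp_id`, `chr`, `bp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p_value`.
#' @export
generate_sumstats <- function(cohort, mode = c("oracle", "cohort_gwas"),
                              n_discovery = 1e5, phi = 0.5) {
  mode <- match.arg(mode)
  vm <- cohort$variant_meta
  geno <- cohort$genotypes
  if (mode == "oracle") {
    if (is.null(vm$true_effect) || all(!is.finite(vm$true_effect))) {
      abort("oracle mode needs true effects in `variant_meta$true_effect`")
    }
    p <- allele_freq(geno)
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    se <- 1 / sqrt(2 * p * (1 - p) * n_discovery * phi * (1 - phi))
    beta <- vm$true_effect + rnorm(length(se)) * se
  } else {
    y <- cohort$samples$diagnosed
    if (is.null(y)) abort("cohort_gwas mode needs a cohort with diagnosis labels")
    fits <- lapply(seq_len(ncol(geno)), function(j) {
      x <- geno[, j]
      ok <- !is.na(x)
      f <- suppressWarnings(glm(y[ok] ~ x[ok], family = binomial()))
      summary(f)$coefficients[2, 1:2]
    })
    fits <- do.call(rbind, fits)
    beta <- fits[, 1]
    se <- fits[, 2]
  }
  tibble(snp_id = vm$snp_id, chr = vm$chr, bp = vm$bp,
         effect_allele = vm$allele1, other_allele = vm$allele2,
         beta = as.numeric(beta), se = as.numeric(se),
         p_value = wald_p(beta, se))
}

#' Simulate a full synthetic cohort under one causal scenario
#'
#' Seeds the RNG from `config$seed` and assembles genotypes, disorder
#' status, the scenario trait, control traits, covariates and residence
#' locations in the causal order the scenario requires (trait before
#' disorder for `trait_to_disorder`, disorder before trait otherwise).
#' Identical configurations give bit-identical cohorts.
#'
#' @param config A [scenario_config()].
#' @param map Optional pre-built [density_map()].
#' @return A `prs_cohort`: list with `genotypes`, `variant_meta` (with
#'   `true_effect` filled in), `samples` (sample metadata, status, trait
#'   and control-trait columns), `locations`, `density_map`, `subpop`,
#'   `effects` and `config`.
#' @export
simulate_cohort <- function(config, map = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    g <- simulate_genotypes(config)
    n <- config$n_individuals
    dep <- rnorm(n)
    samples <- tibble(
      sample_id = rownames(g$genotypes),
      age = sample(38:71, n, replace = TRUE),
      sex = rbinom(n, 1, 0.5),
      deprivation_index = dep,
      education = -0.3 * dep + sqrt(1 - 0.3^2) * rnorm(n),
      subpop = g$subpop
    )
    work <- list(genotypes = g$genotypes, subpop = g$subpop, deprivation = dep)

    if (config$scenario == "trait_to_disorder") {
      trait <- simulate_trait(work, config)
      dis <- simulate_disorder(g$genotypes, config, trait = trait,
                               effects = attr(trait, "effects"))
      work$status <- dis$status
      trait <- as.numeric(trait) +
        config$medication_trait_shift * dis$status$medicated
    } else {
      dis <- simulate_disorder(g$genotypes, config)
      work$status <- dis$status
      work$mediator <- dis$mediator
      trait <- as.numeric(simulate_trait(work, config))
    }

    samples <- dplyr::bind_cols(samples, dis$status)
    samples$trait <- trait
    if (config$n_control_traits > 0) {
      ctrl <- matrix(rnorm(n * config$n_control_traits), n)
      colnames(ctrl) <- paste0("control_", seq_len(config$n_control_traits))
      samples <- dplyr::bind_cols(samples, as_tibble(ctrl))
    }

    loc <- simulate_locations(samples, config, trait = trait, map = map)
    vm <- g$variant_meta
    vm$true_effect <- dis$true_effect

    structure(
      list(genotypes = g$genotypes, variant_meta = vm, samples = samples,
           locations = loc$locations, density_map = loc$map,
           subpop = g$subpop, effects = dis$effects, config = config),
      class = "prs_cohort"
    )
  })
}

#' True standardised genetic score of a simulated cohort
#'
#' Recomputes the standardised polygenic score implied by the cohort's
#' stored causal effect direction — the generative ground truth a PRS
#' built from noisy summary statistics estimates. Useful for recovery
#' tests (e.g. defining the generative PRS-trait regression coefficient).
#'
#' @param cohort A `prs_cohort`.
#' @return Numeric vector, mean 0 / SD 1.
#' @export
true_genetic_score <- function(cohort) {
  stopifnot(inherits(cohort, "prs_cohort"))
  std_genetic_score(cohort$genotypes, cohort$effects$idx, cohort$effects$u)$score
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf(
    "<prs_cohort> %d individuals x %d SNPs | scenario: %s | cases: %d (%d medicated)\n",
    nrow(x$genotypes), ncol(x$genotypes), x$config$scenario,
    sum(x$samples$diagnosed), sum(x$samples$medicated)))
  invisible(x)
}

#' Per-sample analysis table for a cohort
#'
#' Joins sample metadata, trait columns and (optionally) a PRS profile,
#' PC coordinates and the migration table into one tibble keyed by
#' `sample_id`, ready for the regression functions.
#'
#' @param cohort A `prs_cohort`.
#' @param prs Optional PRS profile tibble from [prs_score()].
#' @param pcs Optional PC coordinate tibble from [prs_pca()].
#' @param migration Optional migration table from [migration_table()].
#' @return A tibble with one row per individual.
#' @export
cohort_table <- function(cohort, prs = NULL, pcs = NULL, migration = NULL) {
  out <- cohort$samples
  if (!is.null(prs)) {
    out <- dplyr::left_join(out, dplyr::select(prs, "sample_id", prs = "score"),
                            by = "sample_id")
  }
  if (!is.null(pcs)) out <- dplyr::left_join(out, pcs, by = "sample_id")
  if (!is.null(migration)) out <- dplyr::left_join(out, migration, by = "sample_id")
  out
}
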