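#' Configuration for a synthetic cohort under one causal scenario
#'
#' Builds a validated configuration object describing how a cohort of
#' LD-blocked biallelic genotypes, a liability-threshold disorder, a
#' behavioural trait, diagnosis/medication labels and residence locations
#' should be generated. The `scenario` field selects which single causal
#' arrow links genotype, trait and disorder:
#'
#' * `"null"` — the trait is pure noise, independent of genotype.
#' * `"pleiotropy"` — a latent heritable mediator (e.g. an addiction-like
#'   function) drives both the trait and a contribution to disorder
#'   liability; the trait itself is not causal for the disorder
#'   (horizontal pleiotropy, confounded-by-function).
#' * `"structure"` — subpopulations differ both in risk-allele frequencies
#'   (Balding–Nichols drift, controlled by `fst`) and in trait means
#'   (`env_gradient`); there is no individual-level genetic effect on the
#'   trait, so any PRS–trait association is pure stratification.
#' * `"disorder_to_trait"` — the disorder (true, pre-misclassification
#'   status) shifts the trait by `trait_effect`; genetic risk reaches the
#'   trait only through disorder onset.
#' * `"trait_to_disorder"` — the trait is itself heritable (heritability
#'   `h2_trait`, causal SNPs shared with the disorder's causal set) and
#'   adds `trait_effect` times its standardised value to liability
#'   (vertical pleiotropy, trait causal for the disorder).
#'
#' @param scenario One of `"null"`, `"pleiotropy"`, `"structure"`,
#'   `"disorder_to_trait"`, `"trait_to_disorder"`.
#' @param n_individuals,n_snps Cohort dimensions.
#' @param ld_block_size SNPs per LD block; blocks span roughly 100 kb so
#'   that the default 250 kb clumping window covers a few blocks. The last
#'   block may be short.
#' @param ld_rho Within-block latent AR(1) correlation in `[0, 1)` used to
#'   induce LD between neighbouring SNPs.
#' @param maf_range Interval in `(0, 0.5]` from which ancestral minor
#'   allele frequencies are drawn uniformly.
#' @param n_causal Number of causal SNPs for disorder liability.
#' @param h2_liability Heritability of liability in `[0, 1]`; liability is
#'   standardised so genetic + residual variance is 1.
#' @param prevalence Disorder prevalence; cases are individuals whose
#'   liability exceeds the `1 - prevalence` normal quantile. Default 0.01,
#'   the conventional schizophrenia figure.
#' @param n_subpops,fst Number of subpopulations and the Balding–Nichols
#'   drift parameter; `fst = 0` or one subpopulation means no structure.
#' @param env_gradient Per-subpopulation additive trait offsets (recycled /
#'   defaulted to a symmetric gradient of total range 1 trait SD) used by
#'   the `structure` scenario.
#' @param trait_effect Effect size of the scenario's causal arrow.
#' @param h2_trait Heritability of the trait for scenarios in which the
#'   trait has its own genetic basis (`pleiotropy`, `trait_to_disorder`).
#' @param misclassification_rate Fraction of true cases whose diagnosis
#'   label is flipped to unaffected; true status is retained separately.
#' @param medication_prob_slope Slope of the logistic dependence of
#'   medication on liability among diagnosed individuals. Positive values
#'   reproduce medicated cases having higher average genetic burden than
#'   non-medicated cases.
#' @param medication_trait_shift Additive trait shift applied to medicated
#'   individuals (on the trait's SD scale); negative values oppose a
#'   positive genetic trend, the BMI-like reversal pattern.
#' @param deprivation_trait_effect Loading of the (simulated, genotype-
#'   independent) deprivation index on the trait; used to study
#'   attenuation of follow-up associations under socio-economic
#'   confounding.
#' @param missing_rate Per-call genotype missingness rate.
#' @param migration_coupling Increase of log displacement per trait SD.
#' @param migration_dep_coupling Increase of log displacement per
#'   deprivation-index SD (confounding path for attenuation analyses).
#' @param map_extent_km,map_cell_km Size and resolution of the planar
#'   density raster on which residences are placed.
#' @param n_control_traits Number of pure-noise control traits to generate
#'   alongside the scenario trait.
#' @param seed Integer seed; identical `(config, seed)` gives a
#'   bit-identical cohort.
#'
#' @return An object of class `scenario_config` (a named list).
#' @export
#' @examples
#' cfg <- scenario_config("trait_to_disorder", n_individuals = 500,
#'                        n_snps = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
scenario_config <- function(scenario = c("null", "pleiotropy", "structure",
                                         "disorder_to_trait", "trait_to_disorder"),
                            n_individuals = 2000,
                            n_snps = 300,
                            ld_block_size = 10,
                            ld_rho = 0.5,
                            maf_range = c(0.05, 0.5),
                            n_causal = 30,
                            h2_liability = 0.3,
                            prevalence = 0.01,
                            n_subpops = 1,
                            fst = 0,
                            env_gradient = NULL,
                            trait_effect = 0.3,
                            h2_trait = 0.3,
                            misclassification_rate = 0,
                            medication_prob_slope = 2,
                            medication_trait_shift = 0,
                            deprivation_trait_effect = 0,
                            missing_rate = 0,
                            migration_coupling = 0,
                            migration_dep_coupling = 0,
                            map_extent_km = 500,
                            map_cell_km = 10,
                            n_control_traits = 0,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  n_individuals <- check_count(n_individuals, "n_individuals", 2L)
  n_snps <- check_count(n_snps, "n_snps")
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  n_causal <- check_count(n_causal, "n_causal", 0L)
  if (n_causal > n_snps) abort("`n_causal` must not exceed `n_snps`")
  check_prop(ld_rho, "ld_rho", 0, 1, hi_open = TRUE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  check_prop(h2_liability, "h2_liability")
  check_prop(h2_trait, "h2_trait")
  check_prop(prevalence, "prevalence", 0, 1, lo_open = TRUE, hi_open = TRUE)
  n_subpops <- check_count(n_subpops, "n_subpops")
  check_prop(fst, "fst", 0, 1, hi_open = TRUE)
  check_prop(misclassification_rate, "misclassification_rate")
  check_prop(missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  if (is.null(env_gradient)) {
    env_gradient <- if (n_subpops > 1) seq(-0.5, 0.5, length.out = n_subpops) else 0
  }
  if (length(env_gradient) != n_subpops) {
    env_gradient <- rep_len(env_gradient, n_subpops)
  }
  structure(
    list(scenario = scenario, n_individuals = n_individuals, n_snps = n_snps,
         ld_block_size = ld_block_size, ld_rho = ld_rho, maf_range = maf_range,
         n_causal = n_causal, h2_liability = h2_liability,
         prevalence = prevalence, n_subpops = n_subpops, fst = fst,
         env_gradient = env_gradient, trait_effect = trait_effect,
         h2_trait = h2_trait, misclassification_rate = misclassification_rate,
         medication_prob_slope = medication_prob_slope,
         medication_trait_shift = medication_trait_shift,
         deprivation_trait_effect = deprivation_trait_effect,
         missing_rate = missing_rate,
         migration_coupling = migration_coupling,
         migration_dep_coupling = migration_dep_coupling,
         map_extent_km = map_extent_km, map_cell_km = map_cell_km,
         n_control_traits = check_count(n_control_traits, "n_control_traits", 0L),
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> scenario:", x$scenario,
      sprintf("| n = %d, m = %d, h2 = %g, prevalence = %g, seed = %d\n",
              x$n_individuals, x$n_snps, x$h2_liability, x$prevalence, x$seed))
  invisible(x)
}
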