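#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic-data generator: cohort and
#' panel dimensions, LD structure, allele frequencies, genetic and
#' lifestyle effect sizes, disease incidence, and the master seed.
#' Defaults emulate a large European-ancestry biobank cohort in which
#' rheumatoid arthritis has prevalence about 1.3%: roughly 71% of
#' participants are regularly active, 61% are non-smokers, 78% have a
#' moderate BMI, the per-SD polygenic odds ratio is 1.4, and the three
#' healthy-lifestyle indicators carry protective odds ratios of
#' 0.70-0.75.
#'
#' @param n_individuals Number of individuals in the target cohort.
#' @param n_variants Number of variants in the genotype panel.
#' @param block_size Variants per LD block.  Blocks never straddle
#'   chromosomes.
#' @param ld_rho Latent adjacent-variant correlation within a block, in
#'   `[0, 1)`.  Correlation decays as `ld_rho^distance` (AR(1)).
#' @param maf_range Length-2 numeric, the range minor allele frequencies
#'   are drawn from (uniformly), within `(0.02, 0.5]`.
#' @param n_causal Number of causal variants.
#' @param causal_log_or Per-allele log odds ratio assigned to each causal
#'   variant before rescaling (scalar or length `n_causal`).  Relative
#'   sizes matter; the absolute scale is set by `or_per_sd`.
#' @param or_per_sd Target odds ratio per standard deviation of the true
#'   polygenic score.  Set `NULL` to use `causal_log_or` unscaled.
#' @param discovery_n Discovery GWAS sample size driving summary-statistic
#'   sampling noise.  `Inf` gives noise-free summary statistics.
#' @param discovery_case_fraction Case fraction of the discovery GWAS,
#'   used in the binary-trait standard-error approximation.
#' @param lifestyle_prevalences Named probabilities of the five healthy
#'   indicators (`no_smoking`, `regular_activity`, `moderate_bmi`,
#'   `no_alcohol`, `healthy_diet`) after applying the derivation rules.
#' @param lifestyle_log_or Named log odds ratios of the healthy indicators
#'   on disease (negative = protective).
#' @param lifestyle_correlation Optional 5x5 latent correlation matrix
#'   across the five indicators (rows/columns in the order above);
#'   `NULL` samples them independently.
#' @param baseline_prevalence Probability of prevalent (baseline) disease
#'   for an individual with average risk.
#' @param baseline_hazard Incident-disease baseline hazard, per
#'   person-year.
#' @param censor_year_range Length-2 numeric, administrative censoring
#'   drawn uniformly over this many years of follow-up.
#' @param interaction_log_or Coefficient of the product of the
#'   standardized true score and the count of unhealthy factors (0-3);
#'   0 gives a purely multiplicative (log-additive) model.
#' @param missing_rate Probability a dosage is missing.
#' @param seed Master integer seed; every generator stage derives its own
#'   substream from it.
#'
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_variants = 40, seed = 7)
#' cfg$or_per_sd
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 2000,
                       block_size = 20,
                       ld_rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_causal = 60,
                       causal_log_or = 0.1,
                       or_per_sd = 1.4,
                       discovery_n = 50000,
                       discovery_case_fraction = 0.25,
                       lifestyle_prevalences = c(
                         no_smoking = 0.61, regular_activity = 0.71,
                         moderate_bmi = 0.781, no_alcohol = 0.06,
                         healthy_diet = 0.337
                       ),
                       lifestyle_log_or = c(
                         no_smoking = log(0.70), regular_activity = log(0.75),
                         moderate_bmi = log(0.72), no_alcohol = 0,
                         healthy_diet = 0
                       ),
                       lifestyle_correlation = NULL,
                       baseline_prevalence = 0.0035,
                       baseline_hazard = 7.7e-4,
                       censor_year_range = c(10, 14),
                       interaction_log_or = 0,
                       missing_rate = 0,
                       seed = 1234) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_variants <- check_count(n_variants, "n_variants")
  block_size <- check_count(block_size, "block_size")
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_variants) abort("`n_causal` must be <= `n_variants`")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1) {
    abort("`ld_rho` must lie in [0, 1)")
  }
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
    maf_range[1] <= 0.02 || maf_range[2] > 0.5) {
    abort("`maf_range` must be an increasing pair within (0.02, 0.5]")
  }
  check_prob(lifestyle_prevalences, "lifestyle_prevalences")
  check_prob(baseline_prevalence, "baseline_prevalence")
  if (baseline_hazard < 0) abort("`baseline_hazard` must be >= 0")
  if (length(censor_year_range) != 2L ||
    censor_year_range[1] > censor_year_range[2] || censor_year_range[1] <= 0) {
    abort("`censor_year_range` must be an increasing positive pair")
  }
  if (!(is.finite(discovery_n) || is.infinite(discovery_n)) ||
    discovery_n <= 0) {
    abort("`discovery_n` must be positive (possibly Inf)")
  }
  check_prob(discovery_case_fraction, "discovery_case_fraction")
  check_prob(missing_rate, "missing_rate", open = FALSE)
  factors <- c(
    "no_smoking", "regular_activity", "moderate_bmi", "no_alcohol",
    "healthy_diet"
  )
  if (!all(factors %in% names(lifestyle_prevalences))) {
    abort("`lifestyle_prevalences` must name all five lifestyle factors")
  }
  if (!all(factors %in% names(lifestyle_log_or))) {
    abort("`lifestyle_log_or` must name all five lifestyle factors")
  }
  if (!is.null(lifestyle_correlation)) {
    lc <- as.matrix(lifestyle_correlation)
    if (!identical(dim(lc), c(5L, 5L)) || any(abs(lc - t(lc)) > 1e-10)) {
      abort("`lifestyle_correlation` must be a symmetric 5x5 matrix")
    }
    lifestyle_correlation <- lc
  }
  if (!is.null(or_per_sd) && or_per_sd <= 0) abort("`or_per_sd` must be > 0")

  structure(
    list(
      n_individuals = n_individuals, n_variants = n_variants,
      block_size = block_size, ld_rho = ld_rho, maf_range = maf_range,
      n_causal = n_causal, causal_log_or = causal_log_or,
      or_per_sd = or_per_sd, discovery_n = discovery_n,
      discovery_case_fraction = discovery_case_fraction,
      lifestyle_prevalences = lifestyle_prevalences[factors],
      lifestyle_log_or = lifestyle_log_or[factors],
      lifestyle_correlation = lifestyle_correlation,
      baseline_prevalence = baseline_prevalence,
      baseline_hazard = baseline_hazard,
      censor_year_range = censor_year_range,
      interaction_log_or = interaction_log_or,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d individuals x %d variants (blocks of %d, ld_rho %.2f)\n",
    x$n_individuals, x$n_variants, x$block_size, x$ld_rho
  ))
  cat(sprintf(
    "  %d causal variants, OR per score SD %s; seed %d\n",
    x$n_causal, ifelse(is.null(x$or_per_sd), "unscaled", format(x$or_per_sd)),
    x$seed
  ))
  invisible(x)
}
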