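#' Simulate prevalent and incident disease for a cohort
#'
#' Builds the linear predictor
#' `eta = log(true_or_per_sd) * z + sum_f gamma_f L_f (+ interaction)`,
#' where `z` is the standardized true polygenic score, `L_f` are the
#' healthy-lifestyle indicators derived from the raw fields, and the
#' optional interaction term is `interaction_log_or * z * (3 - index)`.
#' Prevalent (baseline) disease is Bernoulli with
#' `logit P = alpha + eta`, `alpha` solved so the cohort-average
#' prevalence equals `config$baseline_prevalence`.  Incident disease
#' times for the remainder are exponential with rate
#' `baseline_hazard * exp(eta)` under uniform administrative censoring
#' over `censor_year_range`.  Demographic covariates (age, sex, Townsend
#' deprivation index, genotyping batch, assessment centre, 10 genetic
#' PCs) are simulated independently of disease, as pure adjustment
#' variables.
#'
#' @param panel A [simulate_panel()] result.
#' @param lifestyle Raw lifestyle tibble from [simulate_lifestyle()].
#' @param truth The matching [ground_truth()].
#' @param config The matching [sim_config()].
#' @return A cohort tibble: `iid`, `status` (ever-diagnosed 0/1),
#'   `onset` (`"baseline"` / `"follow-up"` / `NA`), `time` (follow-up
#'   years; 0 for prevalent cases), `event` (incident event flag),
#'   covariates `age`, `sex`, `tdi`, `batch`, `center`, `PC1`-`PC10`.
#' @export
simulate_disease <- function(panel, lifestyle, truth, config) {
  stopifnot(
    inherits(panel, "genotype_panel"), inherits(truth, "ground_truth"),
    inherits(config, "sim_config")
  )
  n <- nrow(panel$dosages)
  if (nrow(lifestyle) != n) {
    abort("`lifestyle` rows must match panel individuals")
  }

  profile <- derive_lifestyle(lifestyle)
  flags <- cbind(
    no_smoking = profile$no_smoking,
    regular_activity = profile$regular_activity,
    moderate_bmi = profile$moderate_bmi,
    no_alcohol = profile$no_alcohol,
    healthy_diet = profile$healthy_diet
  )
  gamma <- truth$true_lifestyle_effects[colnames(flags)]
  eta_ls <- as.numeric(flags %*% gamma)

  g <- true_score(panel, truth$true_betas)
  z <- if (sd(g) > 0) (g - mean(g)) / sd(g) else rep(0, n)
  eta <- log(truth$true_or_per_sd) * z + eta_ls
  if (config$interaction_log_or != 0) {
    eta <- eta + config$interaction_log_or * z * (3 - profile$lifestyle_index)
  }

  withr::with_seed(stage_seed(config$seed, "disease"), {
    alpha <- calibrate_intercept(eta, config$baseline_prevalence)
    prevalent <- rbinom(n, 1, plogis(alpha + eta)) == 1

    h <- config$baseline_hazard * exp(eta)
    t_event <- if (config$baseline_hazard > 0) rexp(n, h) else rep(Inf, n)
    censor <- runif(n, config$censor_year_range[1], config$censor_year_range[2])
    event <- !prevalent & t_event <= censor
    time <- ifelse(prevalent, 0, pmin(t_event, censor))

    tibble::tibble(
      iid = panel$individuals$iid,
      status = as.integer(prevalent | event),
      onset = dplyr::case_when(
        prevalent ~ "baseline",
        event ~ "follow-up",
        .default = NA_character_
      ),
      time = time,
      event = as.integer(event),
      age = round(rnorm(n, 56.3, 8)),
      sex = factor(ifelse(runif(n) < 0.535, "female", "male")),
      tdi = rnorm(n, -1.65, 2.89),
      batch = factor(sample(paste0("b", 1:3), n, replace = TRUE)),
      center = factor(sample(paste0("c", 1:5), n, replace = TRUE))
    ) |>
      dplyr::bind_cols(
        tibble::as_tibble(
          matrix(rnorm(n * 10), n, 10,
            dimnames = list(NULL, paste0("PC", 1:10))
          )
        )
      )
  })
}

# alpha such that mean(plogis(alpha + eta)) hits the target prevalence.
calibrate_intercept <- function(eta, target) {
  r <- max(abs(eta), 0)
  uniroot(
    function(a) mean(plogis(a + eta)) - target,
    lower = qlogis(target) - r - 10,
    upper = qlogis(target) + r + 10,
    tol = 1e-10
  )$root
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_panel()], [ground_truth()],
#' [simulate_summary_stats()], [simulate_lifestyle()] and
#' [simulate_disease()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `panel`, `truth`, `sumstats`,
#'   `lifestyle`, `cohort`.
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   n_individuals = 300, n_variants = 40,
#'   n_causal = 5, seed = 42
#' ))
#' names(sim)
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_panel(config)
  truth <- ground_truth(panel, config)
  sumstats <- simulate_summary_stats(panel, truth, config)
  lifestyle <- simulate_lifestyle(config)
  cohort <- simulate_disease(panel, lifestyle, truth, config)
  list(
    config = config, panel = panel, truth = truth, sumstats = sumstats,
    lifestyle = lifestyle, cohort = cohort
  )
}
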