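#' Simulate raw lifestyle fields
#'
#' Emits the raw behavioural fields (smoking status and years since
#' quitting, drinking frequency and status, weekly activity minutes and
#' active days, six diet-component frequency scores, numeric BMI) such
#' that applying the derivation rules of [derive_lifestyle()] recovers
#' the configured healthy-indicator prevalences up to sampling error.
#' Each factor is driven by its own latent uniform; the five latents are
#' independent unless `config$lifestyle_correlation` supplies a Gaussian
#' copula correlation matrix.
#'
#' BMI is log-normal with the log-mean centred between the moderate-BMI
#' bounds and the log-SD solved so that `P(18.5 <= BMI < 24)` equals the
#' configured prevalence exactly.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (defaults to `config$n_individuals`).
#' @return A tibble of raw fields, one row per individual.
#' @export
simulate_lifestyle <- function(config, n = config$n_individuals) {
  stopifnot(inherits(config, "sim_config"))
  n <- check_count(n, "n")
  prev <- config$lifestyle_prevalences
  check_prob(prev, "lifestyle_prevalences")

  withr::with_seed(stage_seed(config$seed, "lifestyle"), {
    u <- lifestyle_latents(n, config$lifestyle_correlation)

    smoke <- sim_smoking(u[, "no_smoking"], prev[["no_smoking"]], n)
    act <- sim_activity(u[, "regular_activity"], prev[["regular_activity"]], n)
    alco <- sim_alcohol(u[, "no_alcohol"], prev[["no_alcohol"]], n)
    diet <- sim_diet(u[, "healthy_diet"], prev[["healthy_diet"]], n)
    bmi <- sim_bmi(u[, "moderate_bmi"], prev[["moderate_bmi"]])

    tibble::tibble(
      smoking_status = smoke$status,
      years_since_quit = smoke$years_since_quit,
      drink_frequency = alco$frequency,
      drinker_status = alco$status,
      vigorous_min_wk = act$vigorous,
      moderate_min_wk = act$moderate,
      active_days_wk = act$days,
      diet
    ) |>
      dplyr::mutate(bmi = bmi)
  })
}

# Latent uniforms for the five factors, optionally copula-correlated.
lifestyle_latents <- function(n, corr) {
  factors <- c(
    "no_smoking", "regular_activity", "moderate_bmi", "no_alcohol",
    "healthy_diet"
  )
  if (is.null(corr)) {
    u <- matrix(runif(n * 5), n, 5)
  } else {
    ch <- chol(corr)
    z <- matrix(rnorm(n * 5), n, 5) %*% ch
    u <- pnorm(z)
  }
  colnames(u) <- factors
  u
}

# Non-smokers are never-smokers plus former smokers quit >= 30 years.
# The healthy indicator fires iff u < prev, split 70% never-smokers and
# 30% long-quit former smokers.
sim_smoking <- function(u, q, n) {
  p_never <- 0.7 * q
  healthy <- u < q
  long_quit <- healthy & u >= p_never
  status <- ifelse(healthy & !long_quit, "never", NA)
  status[long_quit] <- "former"
  # Unhealthy remainder: current smokers and short-quit former smokers.
  bad <- !healthy
  status[bad] <- ifelse(runif(sum(bad)) < 0.7, "current", "former")
  years <- rep(NA_real_, n)
  years[long_quit] <- runif(sum(long_quit), 30, 50)
  short_quit <- bad & status == "former"
  years[short_quit] <- runif(sum(short_quit), 0, 29.5)
  list(status = status, years_since_quit = years)
}

# Regular activity: >= 75 vigorous min/wk, or >= 150 moderate, or an
# equivalent combination (2*vigorous + moderate >= 150), or both
# intensities on >= 5 days/wk.
sim_activity <- function(u, q, n) {
  active <- u < q
  vig <- mod <- numeric(n)
  days <- integer(n)
  na <- sum(active)
  mode <- sample(1:3, na, replace = TRUE, prob = c(0.45, 0.35, 0.2))
  vig_a <- mod_a <- numeric(na)
  vig_a[mode == 1] <- runif(sum(mode == 1), 80, 300)
  mod_a[mode == 1] <- runif(sum(mode == 1), 0, 100)
  mod_a[mode == 2] <- runif(sum(mode == 2), 155, 400)
  vig_a[mode == 3] <- runif(sum(mode == 3), 40, 70)
  mod_a[mode == 3] <- 150 - 2 * vig_a[mode == 3] + runif(sum(mode == 3), 5, 100)
  vig[active] <- vig_a
  mod[active] <- mod_a
  days[active] <- sample(0:7, na, replace = TRUE)
  ni <- sum(!active)
  vig[!active] <- runif(ni, 0, 60)
  mod[!active] <- pmax(0, 149 - 2 * vig[!active]) * runif(ni)
  days[!active] <- sample(0:4, ni, replace = TRUE)
  list(vigorous = vig, moderate = mod, days = days)
}

# Alcohol consumption = drinking more than once per month while a
# current drinker; the healthy indicator is its negation.
sim_alcohol <- function(u, q, n) {
  no_alc <- u < q
  freq <- status <- character(n)
  nn <- sum(no_alc)
  status[no_alc] <- sample(c("never", "former", "current"), nn,
    replace = TRUE, prob = c(0.5, 0.2, 0.3)
  )
  freq[no_alc] <- ifelse(status[no_alc] == "never", "never",
    sample(c("less than monthly", "monthly"), nn, replace = TRUE)
  )
  nd <- sum(!no_alc)
  status[!no_alc] <- "current"
  freq[!no_alc] <- sample(c("weekly", "daily"), nd,
    replace = TRUE, prob = c(0.7, 0.3)
  )
  list(frequency = freq, status = status)
}

# Six ordinal component scores (0-6).  A healthy diet means >= 4 of 6
# components on the healthy side of the cohort median (high fruit /
# vegetables / whole grains / fish, low red / processed meat).  Scores
# are generated with the median pinned at 3: healthy-direction draws sit
# strictly past 3, others at or short of it.
sim_diet <- function(u, q, n) {
  healthy <- u < q
  k <- integer(n)
  k[healthy] <- sample(4:6, sum(healthy), replace = TRUE,
    prob = c(0.5, 0.35, 0.15)
  )
  k[!healthy] <- sample(0:3, sum(!healthy), replace = TRUE,
    prob = c(0.1, 0.25, 0.35, 0.3)
  )
  comp <- c(
    "diet_fruit", "diet_vegetables", "diet_whole_grains", "diet_fish",
    "diet_red_meat", "diet_processed_meat"
  )
  # which components are on the healthy side, uniformly at random
  hmat <- matrix(FALSE, n, 6)
  for (i in seq_len(n)) {
    if (k[i] > 0) hmat[i, sample.int(6, k[i])] <- TRUE
  }
  out <- matrix(0L, n, 6, dimnames = list(NULL, comp))
  for (j in 1:6) {
    meat <- j >= 5
    good <- hmat[, j]
    hi <- sample(4:6, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    lo <- sample(0:3, n, replace = TRUE, prob = c(0.1, 0.2, 0.25, 0.45))
    out[, j] <- if (meat) ifelse(good, lo, hi + 0L) else ifelse(good, hi, lo)
  }
  tibble::as_tibble(out)
}

sim_bmi <- function(u, q) {
  low <- 18.5
  high <- 24
  center <- (log(low) + log(high)) / 2
  half <- (log(high) - log(low)) / 2
  sdlog <- half / qnorm((1 + q) / 2)
  exp(qnorm(u) * sdlog + center)
}
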