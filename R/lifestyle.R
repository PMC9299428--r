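#' Derive the healthy-lifestyle indicators and index
#'
#' Turns raw behavioural fields into the five binary healthy-lifestyle
#' indicators and composes the three-factor index (no smoking, regular
#' physical activity, moderate BMI) and its category: 0-1 indicators =
#' unfavorable, 2 = moderate, 3 = favorable.  Diet and alcohol are
#' derived but deliberately excluded from the index; they are available
#' for five-factor sensitivity analyses.
#'
#' Rows with a missing value in any of the three index factors get a
#' missing index and category (and are reported via a message); they
#' should be excluded from index-based analyses.
#'
#' @param data Tibble of raw fields as produced by
#'   [simulate_lifestyle()]: `smoking_status`, `years_since_quit`,
#'   `drink_frequency`, `drinker_status`, `vigorous_min_wk`,
#'   `moderate_min_wk`, `active_days_wk`, the six `diet_*` scores, `bmi`.
#' @param bmi_bounds Moderate-BMI interval, default `c(18.5, 24)`; use
#'   `c(18.5, 25)` for the wider sensitivity definition.
#' @param bmi_closed_upper If `TRUE` the upper BMI bound is included
#'   (closed interval); default half-open.
#' @param smoking_rule `"quit30"` (never-smokers plus former smokers quit
#'   at least 30 years) or `"no_current"` (everyone but current smokers),
#'   the sensitivity definition.
#' @param diet_k Number of the 6 diet components that must sit on the
#'   healthy side of the cohort median, default 4.
#' @param diet_reference Optional named numeric of reference cutpoints
#'   for the diet components; defaults to the cohort medians.
#' @return The input with columns `no_smoking`, `no_alcohol`,
#'   `regular_activity`, `healthy_diet`, `moderate_bmi` (logical),
#'   `lifestyle_index` (0-3) and `lifestyle_category` (factor
#'   favorable/moderate/unfavorable) appended.
#' @examples
#' raw <- simulate_lifestyle(sim_config(seed = 1), n = 200)
#' derive_lifestyle(raw) |> dplyr::count(lifestyle_category)
#' @export
derive_lifestyle <- function(data,
                             bmi_bounds = c(18.5, 24),
                             bmi_closed_upper = FALSE,
                             smoking_rule = c("quit30", "no_current"),
                             diet_k = 4,
                             diet_reference = NULL) {
  smoking_rule <- match.arg(smoking_rule)
  out <- data |>
    dplyr::mutate(
      no_smoking = derive_no_smoking(.data$smoking_status,
        .data$years_since_quit,
        rule = smoking_rule
      ),
      no_alcohol = derive_no_alcohol(
        .data$drink_frequency, .data$drinker_status
      ),
      regular_activity = derive_regular_activity(
        .data$vigorous_min_wk, .data$moderate_min_wk, .data$active_days_wk
      ),
      moderate_bmi = derive_moderate_bmi(.data$bmi,
        low = bmi_bounds[1], high = bmi_bounds[2],
        closed_upper = bmi_closed_upper
      )
    )
  out$healthy_diet <- derive_healthy_diet(
    dplyr::select(data, dplyr::starts_with("diet_")),
    k = diet_k, reference = diet_reference
  )
  idx <- lifestyle_index(
    out$no_smoking, out$regular_activity, out$moderate_bmi
  )
  out$lifestyle_index <- idx$index
  out$lifestyle_category <- idx$category
  n_miss <- sum(is.na(idx$index))
  if (n_miss > 0) {
    inform(paste0(
      n_miss, " individual(s) with missing index factors; excluded from",
      " index-based analyses"
    ))
  }
  out
}

#' Healthy smoking indicator
#'
#' Never-smokers, and former smokers who quit at least 30 years ago,
#' count as non-smokers.  A former smoker with unknown quit time gets
#' `NA`.  The `"no_current"` rule is the sensitivity definition where
#' only current smokers are flagged unhealthy.
#'
#' @param status Character, one of `"never"`, `"former"`, `"current"`.
#' @param years_since_quit Years since quitting (former smokers).
#' @param rule `"quit30"` (default) or `"no_current"`.
#' @return Logical vector.
#' @export
derive_no_smoking <- function(status, years_since_quit,
                              rule = c("quit30", "no_current")) {
  rule <- match.arg(rule)
  bad <- !status %in% c("never", "former", "current") & !is.na(status)
  if (any(bad)) abort("invalid smoking status")
  if (rule == "no_current") {
    return(status != "current")
  }
  dplyr::case_when(
    status == "never" ~ TRUE,
    status == "current" ~ FALSE,
    status == "former" ~ years_since_quit >= 30,
    .default = NA
  )
}

#' Regular physical activity indicator
#'
#' At least 75 vigorous minutes per week, or 150 moderate minutes, or an
#' equivalent combination (2 x vigorous + moderate >= 150 minutes), or
#' both intensities practised on at least 5 days per week.
#'
#' @param vigorous_min_wk,moderate_min_wk Weekly minutes.
#' @param active_days_wk Days per week with activity of both kinds.
#' @return Logical vector.
#' @export
derive_regular_activity <- function(vigorous_min_wk, moderate_min_wk,
                                    active_days_wk = 0) {
  vigorous_min_wk >= 75 |
    moderate_min_wk >= 150 |
    (2 * vigorous_min_wk + moderate_min_wk) >= 150 |
    (vigorous_min_wk > 0 & moderate_min_wk > 0 & active_days_wk >= 5)
}

#' Moderate-BMI indicator
#'
#' Default half-open interval `[18.5, 24)` kg/m^2; the upper bound is
#' configurable (e.g. 25 for the sensitivity definition) and may be made
#' inclusive.
#'
#' @param bmi Body-mass index, kg/m^2.
#' @param low,high Interval bounds.
#' @param closed_upper Include the upper bound?
#' @return Logical vector.
#' @export
derive_moderate_bmi <- function(bmi, low = 18.5, high = 24,
                                closed_upper = FALSE) {
  if (closed_upper) bmi >= low & bmi <= high else bmi >= low & bmi < high
}

#' No-alcohol indicator
#'
#' Alcohol consumption means drinking more than once per month while
#' currently a drinker; the indicator is its negation.
#'
#' @param drink_frequency Character; `"weekly"` and `"daily"` count as
#'   more than once per month.
#' @param drinker_status One of `"never"`, `"former"`, `"current"`.
#' @return Logical vector.
#' @export
derive_no_alcohol <- function(drink_frequency, drinker_status) {
  !(drink_frequency %in% c("weekly", "daily") & drinker_status == "current")
}

#' Healthy-diet indicator
#'
#' A diet is healthy when at least `k` of the 6 components sit on the
#' healthy side of the reference cutpoint: above it for fruit,
#' vegetables, whole grains and fish; below it for red and processed
#' meat.  Cutpoints default to the cohort medians.
#'
#' @param components Data frame with columns `diet_fruit`,
#'   `diet_vegetables`, `diet_whole_grains`, `diet_fish`,
#'   `diet_red_meat`, `diet_processed_meat`.
#' @param k Required number of healthy components (default 4).
#' @param reference Optional named cutpoints; defaults to medians.
#' @return Logical vector; `NA` where all components are missing.
#' @export
derive_healthy_diet <- function(components, k = 4, reference = NULL) {
  comp <- c(
    "diet_fruit", "diet_vegetables", "diet_whole_grains", "diet_fish",
    "diet_red_meat", "diet_processed_meat"
  )
  if (!all(comp %in% names(components))) {
    abort("`components` must contain the six diet_* columns")
  }
  x <- as.matrix(components[comp])
  if (is.null(reference)) {
    reference <- apply(x, 2, median, na.rm = TRUE)
  }
  healthy_dir <- cbind(
    x[, 1:4, drop = FALSE] > rep(reference[1:4], each = nrow(x)),
    x[, 5:6, drop = FALSE] < rep(reference[5:6], each = nrow(x))
  )
  n_healthy <- rowSums(healthy_dir, na.rm = TRUE)
  all_missing <- rowSums(!is.na(x)) == 0
  ifelse(all_missing, NA, n_healthy >= k)
}

#' Three-factor lifestyle index and category
#'
#' @param no_smoking,regular_activity,moderate_bmi Logical indicators.
#' @return List with `index` (integer 0-3, `NA` if any factor missing)
#'   and `category` (ordered factor favorable < moderate < unfavorable
#'   reversed: levels are favorable, moderate, unfavorable).
#' @export
lifestyle_index <- function(no_smoking, regular_activity, moderate_bmi) {
  idx <- as.integer(no_smoking) + as.integer(regular_activity) +
    as.integer(moderate_bmi)
  category <- dplyr::case_when(
    idx == 3L ~ "favorable",
    idx == 2L ~ "moderate",
    idx <= 1L ~ "unfavorable"
  )
  list(
    index = idx,
    category = factor(category, levels = c(
      "favorable", "moderate", "unfavorable"
    ))
  )
}
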