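#' Compute raw polygenic risk scores
#'
#' The unnormalized weighted sum `PRS_i = sum_k X_ik * beta_k` over the
#' selected variants, with missing dosages mean-imputed as twice the
#' allele frequency before summation.  Scores are deliberately not
#' divided by the number of variants or alleles.
#'
#' @param panel `genotype_panel` holding the dosages (weights must
#'   already be harmonized to the panel's counted alleles, see
#'   [harmonize_alleles()]).
#' @param weights Summary-statistics tibble with `SNP` and `BETA`,
#'   typically one threshold's selection.
#' @param label Optional threshold label stored with the scores.
#' @return Tibble with `iid` and `raw`; attributes `n_variants` and
#'   `label`.
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   n_individuals = 50, n_variants = 10,
#'   n_causal = 3, seed = 9
#' ))
#' prs_score(sim$panel, sim$sumstats)
#' @export
prs_score <- function(panel, weights, label = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(weights) == 0) abort("weight set is empty: need >= 1 variant")
  idx <- match(weights$SNP, panel$variants$id)
  if (anyNA(idx)) abort("weights refer to variants absent from the panel")
  x <- panel$dosages[, idx, drop = FALSE]
  if (anyNA(x)) {
    imp <- rep(2 * panel$variants$maf[idx], each = nrow(x))
    x <- ifelse(is.na(x), imp, x)
  }
  out <- tibble::tibble(
    iid = panel$individuals$iid,
    raw = as.numeric(x %*% weights$BETA)
  )
  attr(out, "n_variants") <- nrow(weights)
  attr(out, "label") <- label
  out
}

#' Standardize polygenic scores
#'
#' Centres and scales the raw scores to mean 0, SD 1.  The reference
#' population defaults to every individual (train and test together);
#' pass `reference_ids` to standardize against a subset while
#' transforming everyone.
#'
#' @param scores Tibble from [prs_score()].
#' @param reference_ids Optional `iid` subset defining the mean/SD.
#' @return `scores` with a `z` column appended.
#' @export
prs_standardize <- function(scores, reference_ids = NULL) {
  ref <- if (is.null(reference_ids)) {
    scores$raw
  } else {
    scores$raw[scores$iid %in% reference_ids]
  }
  s <- sd(ref)
  if (!is.finite(s) || s == 0) {
    abort("degenerate scores: zero variance in the reference population")
  }
  dplyr::mutate(scores, z = (.data$raw - mean(ref)) / s)
}

#' Assign genetic risk groups by score quartile
#'
#' Low = bottom quartile, intermediate = quartiles 2-3, high = top
#' quartile, cut at the 25th and 75th empirical percentiles (type-7
#' quantiles).  Individuals exactly at a cut point go to the lower
#' group.  Assignment depends only on score ranks.
#'
#' @param scores Tibble with a `z` (preferred) or `raw` score column.
#' @return `scores` with a `genetic_risk` factor
#'   (low/intermediate/high).
#' @examples
#' s <- tibble::tibble(iid = letters[1:8], raw = 1:8, z = scale(1:8)[, 1])
#' assign_risk_groups(s)$genetic_risk
#' @export
assign_risk_groups <- function(scores) {
  x <- score_column(scores)
  if (length(x) < 4) abort("need at least 4 individuals for quartile groups")
  qs <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  if (qs[1] == qs[2]) {
    warn("tied scores: quartile cut points coincide; groups degenerate")
  }
  grp <- dplyr::case_when(
    x <= qs[1] ~ "low",
    x <= qs[2] ~ "intermediate",
    .default = "high"
  )
  dplyr::mutate(scores, genetic_risk = factor(grp,
    levels = c("low", "intermediate", "high")
  ))
}

#' Assign score deciles
#'
#' Ten equal-probability bins cut at the type-7 decile quantiles; values
#' exactly at a cut point go to the lower bin.  Invariant under any
#' monotone transform of the scores.
#'
#' @param scores Tibble with a `z` or `raw` score column.
#' @return `scores` with an integer `decile` column (1-10).
#' @export
assign_deciles <- function(scores) {
  x <- score_column(scores)
  if (length(x) < 10) abort("need at least 10 individuals for deciles")
  cuts <- quantile(x, seq(0.1, 0.9, by = 0.1), type = 7, names = FALSE)
  dec <- rowSums(outer(x, cuts, `>`)) + 1L
  dplyr::mutate(scores, decile = as.integer(dec))
}

score_column <- function(scores) {
  if ("z" %in% names(scores)) {
    return(scores$z)
  }
  if ("raw" %in% names(scores)) {
    return(scores$raw)
  }
  abort("`scores` must contain a `z` or `raw` column")
}
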