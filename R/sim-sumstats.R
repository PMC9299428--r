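#' Simulate discovery GWAS summary statistics
#'
#' Samples per-variant effect estimates analytically rather than by
#' simulating a discovery cohort: each estimate is drawn from
#' `Normal(marginal beta, se^2)` with the binary-trait standard-error
#' approximation `se = 1 / sqrt(2 N p (1 - p) phi (1 - phi))`, where `N`
#' is the discovery sample size, `p` the allele frequency and `phi` the
#' discovery case fraction.  The marginal beta of a non-causal variant
#' tagged by LD is the linear projection `sum_j r_ij beta_j` over causal
#' variants in the same block, with `r` the realized dosage correlation
#' of the panel.  Two-sided Wald p-values come from `beta_hat / se`.
#' With `discovery_n = Inf` estimates equal the marginal betas and
#' p-values collapse to 0 (tagged) or 1 (null).
#'
#' @param panel A [simulate_panel()] result (LD reference for the
#'   marginal-beta projection).
#' @param truth The matching [ground_truth()].
#' @param config The matching [sim_config()].
#' @return A tibble with columns `SNP`, `CHR`, `BP`, `A1`, `A2`, `BETA`,
#'   `SE`, `P`, sorted by (chromosome, position), with the discovery case
#'   fraction recorded in attribute `case_fraction`.
#' @export
simulate_summary_stats <- function(panel, truth, config) {
  stopifnot(
    inherits(panel, "genotype_panel"), inherits(truth, "ground_truth"),
    inherits(config, "sim_config")
  )
  v <- panel$variants
  m <- nrow(v)
  phi <- config$discovery_case_fraction
  se <- se_binary_trait(config$discovery_n, v$maf, phi)

  beta_disc <- truth$discovery_betas
  marg <- numeric(m)
  causal_idx <- which(beta_disc != 0)
  for (b in unique(v$block[causal_idx])) {
    cols <- which(v$block == b)
    cc <- intersect(cols, causal_idx)
    r <- suppressWarnings(
      cor(panel$dosages[, cols, drop = FALSE],
        panel$dosages[, cc, drop = FALSE],
        use = "pairwise.complete.obs"
      )
    )
    r[!is.finite(r)] <- 0
    marg[cols] <- as.numeric(r %*% beta_disc[cc])
  }

  if (is.infinite(config$discovery_n)) {
    beta_hat <- marg
    se <- rep(0, m)
    p <- ifelse(marg == 0, 1, 0)
  } else {
    beta_hat <- withr::with_seed(
      stage_seed(config$seed, "sumstats"),
      rnorm(m, marg, se)
    )
    p <- 2 * pnorm(-abs(beta_hat / se))
  }

  out <- tibble::tibble(
    SNP = v$id, CHR = v$chrom, BP = v$pos, A1 = v$a1, A2 = v$a2,
    BETA = beta_hat, SE = se, P = p
  )
  out <- dplyr::arrange(out, as.integer(.data$CHR), .data$BP)
  attr(out, "case_fraction") <- phi
  out
}

#' Binary-trait GWAS standard-error approximation
#'
#' `se = 1 / sqrt(2 N p (1 - p) phi (1 - phi))` for an additive
#' log-odds effect at allele frequency `p` with `N` samples of which a
#' fraction `phi` are cases.
#'
#' @param n Discovery sample size.
#' @param maf Allele frequency (vectorized).
#' @param case_fraction Case fraction `phi`.
#' @return Standard errors, same length as `maf`.
#' @export
se_binary_trait <- function(n, maf, case_fraction) {
  1 / sqrt(2 * n * maf * (1 - maf) * case_fraction * (1 - case_fraction))
}
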