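#' Per-variant SNP-by-lifestyle interaction scan
#'
#' For every variant in the panel, fits a logistic model of the binary
#' outcome on dosage, the lifestyle variable, their product, and the
#' covariates, and reports the Wald test of the product term.  Variants
#' whose fit does not converge, or whose product term is aliased, are
#' reported with a missing p-value and a flag rather than dropped.  Raw
#' p-values are reported (with an optional Bonferroni column); output is
#' sorted by ascending p.
#'
#' @param panel `genotype_panel`.
#' @param data Cohort data frame aligned with the panel rows, holding
#'   `outcome`, `lifestyle` and covariate columns.
#' @param lifestyle Name of the (numeric or 0/1) lifestyle column.
#' @param outcome Name of the binary outcome column, default "status".
#' @param covariates Character vector of adjustment columns.
#' @param bonferroni Add a Bonferroni-adjusted column? Default TRUE.
#' @return Tibble, one row per variant: `id`, `beta_interaction`,
#'   `se`, `statistic`, `p.value`, `converged` (+ `p.bonferroni`).
#' @export
snp_lifestyle_scan <- function(panel, data, lifestyle, outcome = "status",
                               covariates = NULL, bonferroni = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(data) != nrow(panel$dosages)) {
    abort("`data` rows must align with panel individuals")
  }
  y <- data[[outcome]]
  ls <- as.numeric(data[[lifestyle]])
  z_cov <- if (length(covariates) > 0) {
    model.matrix(build_formula("", covariates), data = data)[, -1, drop = FALSE]
  } else {
    NULL
  }
  base <- cbind(`(Intercept)` = 1, lifestyle = ls, z_cov)

  m <- ncol(panel$dosages)
  res <- purrr::map(seq_len(m), function(k) {
    g <- panel$dosages[, k]
    if (anyNA(g)) g <- ifelse(is.na(g), 2 * panel$variants$maf[k], g)
    x <- cbind(base, dosage = g, interaction = g * ls)
    ok <- complete.cases(x) & !is.na(y)
    fit <- tryCatch(
      suppressWarnings(
        stats::glm.fit(x[ok, , drop = FALSE], y[ok], family = binomial())
      ),
      error = function(e) NULL
    )
    bad <- is.null(fit) || !fit$converged ||
      fit$rank < ncol(x) || is.na(coef(fit)["interaction"])
    if (bad) {
      return(tibble::tibble(
        beta_interaction = NA_real_, se = NA_real_,
        statistic = NA_real_, p.value = NA_real_, converged = FALSE
      ))
    }
    w <- fit$weights
    xtwx <- crossprod(x[ok, , drop = FALSE] * sqrt(w))
    vc <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(vc)) {
      return(tibble::tibble(
        beta_interaction = NA_real_, se = NA_real_,
        statistic = NA_real_, p.value = NA_real_, converged = FALSE
      ))
    }
    b <- coef(fit)[["interaction"]]
    se <- sqrt(vc["interaction", "interaction"])
    tibble::tibble(
      beta_interaction = b, se = se, statistic = b / se,
      p.value = 2 * pnorm(-abs(b / se)), converged = TRUE
    )
  })
  out <- dplyr::bind_cols(
    tibble::tibble(id = panel$variants$id),
    dplyr::bind_rows(res)
  )
  if (bonferroni) {
    out$p.bonferroni <- stats::p.adjust(out$p.value, method = "bonferroni")
  }
  dplyr::arrange(out, .data$p.value)
}
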