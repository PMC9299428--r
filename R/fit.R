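#' Fit a multivariable logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least
#' squares via [stats::glm()]) returning a tidy-able `prsj_fit`.  Effects
#' are reported as odds ratios with Wald confidence intervals.  Aliased
#' (rank-deficient) columns are dropped with a warning; perfect
#' separation raises an explicit error.
#'
#' @param data Data frame with the outcome and terms; rows with missing
#'   values in the model variables are dropped (complete-case).
#' @param formula Model formula with a binary (0/1) outcome.
#' @param conf_level Confidence level, default 0.95.
#' @return A `prsj_fit` object; see [tidy.prsj_fit()] and
#'   [glance.prsj_fit()].
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.3), x = rnorm(200))
#' tidy(fit_logistic(d, y ~ x))
#' @export
fit_logistic <- function(data, formula, conf_level = 0.95) {
  model <- withCallingHandlers(
    glm(formula, family = binomial(), data = data,
      control = list(epsilon = 1e-10, maxit = 25)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
        conditionMessage(w)
      )) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(model)
  aliased <- is.na(cf)
  if (any(aliased)) {
    warn(paste0(
      "aliased column(s) dropped: ",
      paste(names(cf)[aliased], collapse = ", ")
    ))
  }
  # Separation: diverging estimates with exploding standard errors.
  keep <- names(cf)[!aliased]
  se <- sqrt(diag(vcov(model)))[keep]
  big <- abs(cf[keep]) > 10 & se > 10
  if (any(big)) {
    abort(paste0(
      "perfect separation detected for term(s): ",
      paste(keep[big], collapse = ", ")
    ), class = "prsjoint_separation")
  }
  if (!model$converged) warn("IRLS did not converge within 25 iterations")
  new_prsj_fit(model, "odds-ratio", conf_level)
}

#' Fit a multivariable Cox proportional-hazards regression
#'
#' Partial-likelihood Cox fit with the Efron tie correction, reporting
#' hazard ratios with Wald confidence intervals.  Follow-up runs from
#' baseline to the first of event, loss, or administrative censoring, as
#' encoded in the `(time, event)` pair of the survival outcome.
#'
#' @param data Data frame with time, event and covariate columns.
#' @param formula Formula whose left side is `survival::Surv(time,
#'   event)`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `prsj_fit` object.
#' @export
fit_cox <- function(data, formula, conf_level = 0.95) {
  diverged <- FALSE
  model <- withCallingHandlers(
    survival::coxph(formula, data = data, ties = "efron", model = TRUE),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (model$nevent == 0) abort("no events: Cox model undefined")
  if (diverged) {
    abort("monotone partial likelihood: a coefficient diverges",
      class = "prsjoint_divergence"
    )
  }
  if (anyNA(coef(model))) {
    abort(paste0(
      "zero-information (aliased or constant) column(s): ",
      paste(names(coef(model))[is.na(coef(model))], collapse = ", ")
    ))
  }
  new_prsj_fit(model, "hazard-ratio", conf_level)
}

new_prsj_fit <- function(model, scale, conf_level) {
  structure(
    list(model = model, effect_scale = scale, conf_level = conf_level),
    class = c(
      if (scale == "odds-ratio") "prsj_logit" else "prsj_cox",
      "prsj_fit"
    )
  )
}

#' @export
print.prsj_fit <- function(x, ...) {
  cat(sprintf(
    "<prsj_fit> %s scale, %d observations\n", x$effect_scale,
    stats::nobs(x$model)
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a prsj_fit
#'
#' One row per model term, with the exponentiated effect (odds or hazard
#' ratio), its log-scale standard error, Wald statistic, p-value and
#' confidence interval.
#'
#' @param x A `prsj_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy prsj_fit
#' @export
tidy.prsj_fit <- function(x, ...) {
  cf <- coef(x$model)
  cf <- cf[!is.na(cf)]
  se <- sqrt(diag(vcov(x$model)))[names(cf)]
  ci <- wald_ci(cf, se, x$conf_level)
  z <- cf / se
  tibble::tibble(
    term = names(cf),
    estimate = unname(exp(cf)),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    conf.low = unname(exp(ci$low)),
    conf.high = unname(exp(ci$high))
  )
}

#' Model-level summary of a prsj_fit
#'
#' @param x A `prsj_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `converged`, `effect_scale`,
#'   and `auc` (in-sample, logistic fits only).
#' @method glance prsj_fit
#' @export
glance.prsj_fit <- function(x, ...) {
  m <- x$model
  if (inherits(m, "coxph")) {
    tibble::tibble(
      n = m$n, n_events = m$nevent,
      converged = TRUE,
      effect_scale = x$effect_scale, auc = NA_real_
    )
  } else {
    y <- m$y
    tibble::tibble(
      n = stats::nobs(m), n_events = sum(y),
      converged = m$converged,
      effect_scale = x$effect_scale,
      auc = auc_mw(stats::fitted(m), y)
    )
  }
}

#' @export
coef.prsj_fit <- function(object, ...) coef(object$model)

#' @export
vcov.prsj_fit <- function(object, ...) vcov(object$model)

#' Standard covariate adjustment set
#'
#' The usual confounder block for biobank risk models: age, sex,
#' deprivation index, genotyping batch, assessment centre and the top 10
#' genetic principal components.
#'
#' @param n_pcs Number of principal components, default 10.
#' @return Character vector of covariate names.
#' @export
covariate_terms <- function(n_pcs = 10) {
  c("age", "sex", "tdi", "batch", "center", paste0("PC", seq_len(n_pcs)))
}

# Build "lhs ~ a + b + ..." from term strings.
build_formula <- function(lhs, terms) {
  as.formula(paste(lhs, "~", paste(terms, collapse = " + ")))
}
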