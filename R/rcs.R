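#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power
#' parameterization: for knots `t_1 < ... < t_k` the columns are the
#' linear term plus `k - 2` restricted cubic terms
#' \deqn{f_j(x) = \frac{(x-t_j)_+^3 -
#'   (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1}) +
#'   (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})}{(t_k-t_1)^2},}
#' which is linear beyond the boundary knots (all curvature vanishes
#' outside them).  Default knots sit at conventional quantiles of `x`:
#' 10/50/90 for 3 knots, 5/35/65/95 for 4, 5/27.5/50/72.5/95 for 5.
#'
#' @param x Numeric vector.
#' @param n_knots Number of knots (3-5), default 4; ignored when `knots`
#'   is given.
#' @param knots Optional explicit knot vector (strictly increasing),
#'   e.g. to evaluate the basis of a fitted model at new `x`.
#' @return Matrix `length(x) x (k - 1)` with columns `rcs1..rcs(k-1)`
#'   and the knots in attribute `"knots"`.
#' @examples
#' b <- rcs_basis(rnorm(100))
#' attr(b, "knots")
#' @export
rcs_basis <- function(x, n_knots = 4, knots = NULL) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      abort("`n_knots` must be 3, 4 or 5")
    )
    knots <- quantile(x, probs, type = 7, names = FALSE)
  }
  k <- length(knots)
  if (k < 3 || any(diff(knots) <= 0)) {
    abort("knots must be strictly increasing (>= 3 distinct values)")
  }
  pos3 <- function(u) pmax(u, 0)^3
  scale2 <- (knots[k] - knots[1])^2
  basis <- matrix(0, length(x), k - 1)
  basis[, 1] <- x
  for (j in seq_len(k - 2)) {
    basis[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      pos3(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])) / scale2
  }
  colnames(basis) <- paste0("rcs", seq_len(k - 1))
  attr(basis, "knots") <- knots
  basis
}

#' Fit a restricted-cubic-spline dose-response curve
#'
#' Logistic (or Cox) regression of the outcome on a restricted cubic
#' spline of `x` plus covariates, with predictions expressed relative to
#' a reference point (default the median of `x`), the usual display for
#' a continuous score vs disease-risk curve.
#'
#' @param data Data frame.
#' @param x Name of the continuous exposure column.
#' @param outcome Name of the binary outcome column.
#' @param covariates Character vector of adjustment columns (optional).
#' @param n_knots Number of spline knots, default 4.
#' @param ref Reference value of `x`; default its median.
#' @return Tibble of class `prsj_rcs`: `x`, `estimate` (OR vs `ref`),
#'   `conf.low`, `conf.high`; the fitted `prsj_fit` in attribute
#'   `"fit"`.
#' @export
rcs_curve <- function(data, x, outcome = "status", covariates = NULL,
                      n_knots = 4, ref = NULL) {
  xv <- data[[x]]
  basis <- rcs_basis(xv, n_knots = n_knots)
  df <- dplyr::bind_cols(
    data[c(outcome, covariates)],
    tibble::as_tibble(basis)
  )
  fit <- fit_logistic(
    df, build_formula(outcome, c(colnames(basis), covariates))
  )
  ref <- ref %||% median(xv, na.rm = TRUE)
  grid <- seq(min(xv), max(xv), length.out = 200)
  gb <- rcs_basis(grid, knots = attr(basis, "knots"))
  rb <- rcs_basis(ref, knots = attr(basis, "knots"))
  d <- gb - rep(rb, each = nrow(gb))
  cf <- coef(fit$model)[colnames(basis)]
  vc <- vcov(fit$model)[colnames(basis), colnames(basis)]
  lp <- as.numeric(d %*% cf)
  se <- sqrt(rowSums((d %*% vc) * d))
  ci <- wald_ci(lp, se)
  out <- tibble::tibble(
    x = grid, estimate = exp(lp),
    conf.low = exp(ci$low), conf.high = exp(ci$high)
  )
  class(out) <- c("prsj_rcs", class(out))
  attr(out, "fit") <- fit
  attr(out, "ref") <- ref
  out
}
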