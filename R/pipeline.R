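#' Split a cohort into training and test sets
#'
#' Simple random sample without replacement: the training set has
#' `floor(fraction * N)` individuals.  Deterministic given the seed.
#'
#' @param ids Vector of individual ids.
#' @param fraction Training fraction in (0, 1), default 0.2.
#' @param seed Integer sampling seed, default 1234.
#' @return Tibble with `iid` and `set` (`"train"` / `"test"`);
#'   attributes `fraction` and `seed`.
#' @examples
#' table(split_cohort(1:100, 0.2, seed = 1)$set)
#' @export
split_cohort <- function(ids, fraction = 0.2, seed = 1234) {
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must be in (0, 1)")
  n <- length(ids)
  n_train <- floor(fraction * n)
  train_idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  out <- tibble::tibble(
    iid = ids,
    set = factor(
      ifelse(seq_len(n) %in% train_idx, "train", "test"),
      levels = c("train", "test")
    )
  )
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Select the best-performing PRS threshold on training data
#'
#' Fits the covariate-adjusted logistic model of the outcome on each
#' candidate standardized score, in the training set only.  The primary
#' selection criterion is the smallest score-term p-value; exact ties
#' break by the larger AUC of the score-plus-covariates model, then by
#' candidate order.  The full per-threshold table is returned so the
#' choice is auditable; no candidate is silently dropped.
#'
#' @param train Training-set data frame with the outcome and covariates.
#' @param candidates Named list of score tibbles (one per threshold,
#'   each with `iid` and `z`), e.g. built from [apply_thresholds()] and
#'   [prs_score()].
#' @param outcome Binary outcome column name, default "status".
#' @param covariates Character vector of adjustment columns.
#' @return List of class `prs_selection`: `best` (label), `table`
#'   (tibble: `label`, `n_variants`, `or`, `conf.low`, `conf.high`,
#'   `p.value`, `auc`).
#' @export
select_best_prs <- function(train, candidates, outcome = "status",
                            covariates = NULL) {
  if (length(candidates) < 1) abort("need at least one candidate score")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    abort("`candidates` must be a named list")
  }
  rows <- purrr::imap(candidates, function(sc, label) {
    d <- dplyr::inner_join(train, sc[c("iid", "z")], by = "iid")
    fit <- fit_logistic(d, build_formula(outcome, c("z", covariates)))
    td <- tidy(fit)
    zr <- td[td$term == "z", ]
    tibble::tibble(
      label = label,
      n_variants = attr(sc, "n_variants") %||% NA_integer_,
      or = zr$estimate, conf.low = zr$conf.low, conf.high = zr$conf.high,
      p.value = zr$p.value,
      auc = glance(fit)$auc
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (all(tab$p.value >= 0.05)) {
    warn("no candidate score reaches p < 0.05; selecting the best anyway")
  }
  best_p <- min(tab$p.value)
  cand <- which(tab$p.value == best_p)
  if (length(cand) > 1) {
    cand <- cand[tab$auc[cand] == max(tab$auc[cand])]
    if (length(cand) > 1) {
      inform("tied candidates; keeping the first in threshold order")
    }
  }
  structure(
    list(best = tab$label[cand[1]], table = tab),
    class = "prs_selection"
  )
}

#' @export
print.prs_selection <- function(x, ...) {
  cat(sprintf("<prs_selection> best threshold: %s\n", x$best))
  print(x$table, ...)
  invisible(x)
}

#' Joint genetic-by-lifestyle risk grid
#'
#' Cross-classifies individuals by genetic risk group (low /
#' intermediate / high) and lifestyle category (favorable / moderate /
#' unfavorable) and estimates, against the low-genetic-risk +
#' favorable-lifestyle reference cell, the covariate-adjusted odds ratio
#' (logistic, case-control) and hazard ratio (Cox, prospective) of each
#' of the other 8 cells.  Baseline-prevalent cases are excluded from the
#' prospective fit (and this is asserted).  Per-genetic-stratum
#' Cochran-Armitage trend tests across lifestyle categories are
#' attached.
#'
#' @param data Data frame with `status`, `time`, `event`, `onset`, a
#'   `genetic_risk` factor, a `lifestyle_category` factor, and
#'   covariates.
#' @param covariates Character vector of adjustment columns.
#' @param cox Also fit the prospective Cox model? Default TRUE.
#' @return Tibble of class `joint_grid`, one row per cell:
#'   `genetic_risk`, `lifestyle_category`, `n`, `cases`, `or`,
#'   `or.conf.low`, `or.conf.high`, `or.p`, `hr`, `hr.conf.low`,
#'   `hr.conf.high`, `hr.p` (reference cell: estimates 1, CIs `NA`).
#'   Attribute `"trend"` holds the per-stratum trend tests.
#' @export
joint_analysis <- function(data, covariates = NULL, cox = TRUE) {
  need <- c("status", "genetic_risk", "lifestyle_category")
  if (!all(need %in% names(data))) {
    abort("`data` must contain status, genetic_risk, lifestyle_category")
  }
  d <- dplyr::filter(
    data,
    !is.na(.data$genetic_risk), !is.na(.data$lifestyle_category)
  )
  d$cell <- interaction(d$genetic_risk, d$lifestyle_category,
    sep = ":", lex.order = TRUE
  )
  counts <- dplyr::count(d, .data$genetic_risk, .data$lifestyle_category,
    .drop = FALSE
  )
  if (any(counts$n == 0)) {
    empty <- counts[counts$n == 0, ]
    abort(paste0(
      "empty joint cell(s): ",
      paste(empty$genetic_risk, empty$lifestyle_category,
        sep = ":", collapse = ", "
      )
    ))
  }
  d$cell <- stats::relevel(factor(d$cell), ref = "low:favorable")

  logit <- fit_logistic(d, build_formula("status", c("cell", covariates)))
  or_tab <- cell_estimates(logit, "cell")

  hr_tab <- NULL
  if (cox) {
    prosp <- dplyr::filter(d, is.na(.data$onset) | .data$onset != "baseline")
    stopifnot(!any(prosp$onset == "baseline", na.rm = TRUE))
    cx <- fit_cox(prosp, build_formula(
      "survival::Surv(time, event)", c("cell", covariates)
    ))
    hr_tab <- cell_estimates(cx, "cell")
  }

  cases <- dplyr::summarise(
    dplyr::group_by(d, .data$genetic_risk, .data$lifestyle_category),
    n = dplyr::n(), cases = sum(.data$status), .groups = "drop"
  )
  grid <- cases |>
    dplyr::mutate(cell = paste(.data$genetic_risk, .data$lifestyle_category,
      sep = ":"
    )) |>
    dplyr::left_join(or_tab, by = "cell") |>
    dplyr::rename(
      or = "estimate", or.conf.low = "conf.low",
      or.conf.high = "conf.high", or.p = "p.value"
    )
  if (!is.null(hr_tab)) {
    grid <- grid |>
      dplyr::left_join(hr_tab, by = "cell") |>
      dplyr::rename(
        hr = "estimate", hr.conf.low = "conf.low",
        hr.conf.high = "conf.high", hr.p = "p.value"
      )
  }
  ref <- grid$cell == "low:favorable"
  grid$or[ref] <- 1
  if (!is.null(hr_tab)) grid$hr[ref] <- 1
  grid$cell <- NULL

  trend <- d |>
    dplyr::group_by(.data$genetic_risk) |>
    dplyr::group_modify(function(g, key) {
      tab <- g |>
        dplyr::count(.data$lifestyle_category, wt = NULL) |>
        dplyr::left_join(
          dplyr::count(g[g$status == 1, ], .data$lifestyle_category,
            name = "cases"
          ),
          by = "lifestyle_category"
        )
      tab$cases[is.na(tab$cases)] <- 0L
      cochran_armitage_trend(tab$cases, tab$n - tab$cases)
    }) |>
    dplyr::ungroup()

  class(grid) <- c("joint_grid", class(grid))
  attr(grid, "trend") <- trend
  grid
}

# Pull the cell-indicator rows out of a tidy fit, keyed by cell label.
cell_estimates <- function(fit, prefix) {
  td <- tidy(fit)
  td <- td[startsWith(td$term, prefix), ]
  td$cell <- sub(paste0("^", prefix), "", td$term)
  td[c("cell", "estimate", "conf.low", "conf.high", "p.value")]
}

#' Table-1-style cohort summary
#'
#' Stratified counts with percentages recomputed from the counts (one
#' decimal).  Denominators: the full cohort for the case, control and
#' incident-case rows; cases for the onset-period and case-sex rows;
#' controls for the control-sex and lifestyle rows.
#'
#' @param cohort Data frame with `status` (0/1) and optionally `onset`,
#'   `sex`, lifestyle indicator columns, `genetic_risk`.
#' @return Tibble: `variable`, `level`, `count`, `denominator`, `pct`.
#' @examples
#' cohort_summary(data.frame(status = c(1, 0, 0, 0)))
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort("empty cohort")
  n <- nrow(cohort)
  cases <- sum(cohort$status == 1)
  if (cases == 0) warn("degenerate summary: no cases")
  pct <- function(count, denom) {
    ifelse(denom > 0, round(100 * count / denom, 1), NA_real_)
  }
  rows <- list(
    tibble::tibble(
      variable = "status", level = c("control", "case"),
      count = c(n - cases, cases), denominator = n
    )
  )
  if ("onset" %in% names(cohort)) {
    onset <- cohort$onset[cohort$status == 1]
    rows <- c(rows, list(tibble::tibble(
      variable = c("status", "onset", "onset"),
      level = c("incident case", "baseline", "follow-up"),
      count = c(
        sum(cohort$onset == "follow-up", na.rm = TRUE),
        sum(onset == "baseline", na.rm = TRUE),
        sum(onset == "follow-up", na.rm = TRUE)
      ),
      denominator = c(n, cases, cases)
    )))
  }
  if ("sex" %in% names(cohort)) {
    for (grp in c("case", "control")) {
      sub <- cohort$sex[cohort$status == (grp == "case")]
      rows <- c(rows, list(tibble::tibble(
        variable = paste0("sex (", grp, "s)"),
        level = c("female", "male"),
        count = c(sum(sub == "female"), sum(sub == "male")),
        denominator = length(sub)
      )))
    }
  }
  ls_cols <- intersect(
    c(
      "regular_activity", "no_smoking", "no_alcohol", "healthy_diet",
      "moderate_bmi"
    ),
    names(cohort)
  )
  for (cc in ls_cols) {
    for (grp in c("control", "case")) {
      sub <- cohort[[cc]][cohort$status == (grp == "case")]
      rows <- c(rows, list(tibble::tibble(
        variable = paste0(cc, " (", grp, "s)"), level = "yes",
        count = sum(sub, na.rm = TRUE), denominator = length(sub)
      )))
    }
  }
  if ("genetic_risk" %in% names(cohort)) {
    for (grp in c("control", "case")) {
      sub <- cohort$genetic_risk[cohort$status == (grp == "case")]
      rows <- c(rows, list(tibble::tibble(
        variable = paste0("genetic_risk (", grp, "s)"),
        level = levels(cohort$genetic_risk),
        count = as.integer(table(sub)),
        denominator = length(sub)
      )))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$pct <- pct(out$count, out$denominator)
  out
}
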