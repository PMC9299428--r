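#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in case proportions across ordered exposure
#' groups.  The signed statistic is positive when proportions increase
#' with the scores; the two-sided p-value comes from the standard-normal
#' reference.  With two groups the squared statistic equals the 2x2
#' Pearson chi-square.
#'
#' @param cases,controls Per-group counts, same ordered length >= 2.
#' @param scores Group scores; default `0, 1, 2, ...`.
#' @return Tibble with `statistic` (Z), `p.value`.
#' @examples
#' cochran_armitage_trend(c(10, 20, 40), c(90, 80, 60))
#' @export
cochran_armitage_trend <- function(cases, controls, scores = NULL) {
  if (length(cases) != length(controls) || length(cases) < 2) {
    abort("`cases` and `controls` must align with >= 2 groups")
  }
  n_i <- cases + controls
  if (any(n_i == 0)) abort("empty group: all groups need observations")
  scores <- scores %||% (seq_along(cases) - 1)
  n <- sum(n_i)
  r <- sum(cases)
  pbar <- r / n
  num <- sum(scores * (cases - n_i * pbar))
  v <- pbar * (1 - pbar) * (sum(n_i * scores^2) - sum(n_i * scores)^2 / n)
  z <- if (v > 0) num / sqrt(v) else 0
  tibble::tibble(statistic = z, p.value = 2 * pnorm(-abs(z)))
}
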