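#' Variant quality-control filter
#'
#' Retains variants with minor allele frequency strictly above
#' `maf_min`, Hardy-Weinberg equilibrium p-value strictly above
#' `hwe_p_min`, and call rate at least `call_rate_min`, preserving
#' variant order.  MAF, HWE and call rate are computed from the panel's
#' hard-call dosages.  Applying the filter twice is a no-op.
#'
#' @param panel A `genotype_panel`.
#' @param maf_min MAF threshold (exclusive), default 0.02.
#' @param hwe_p_min HWE p-value threshold (exclusive), default 1e-7.
#' @param call_rate_min Minimum per-variant call rate, default 0.95.
#' @return The filtered `genotype_panel`, with a `qc` tibble attribute
#'   recording per-variant statistics and the kept flag.
#' @export
qc_panel <- function(panel, maf_min = 0.02, hwe_p_min = 1e-7,
                     call_rate_min = 0.95) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (ncol(panel$dosages) == 0) abort("empty panel")
  thr <- c(maf_min, hwe_p_min, call_rate_min)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1)) {
    abort("QC thresholds must lie in [0, 1]")
  }
  x <- panel$dosages
  call_rate <- colMeans(!is.na(x))
  af <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  counts <- genotype_counts(x)
  hwe <- hardy_weinberg_chi2(counts[, 1], counts[, 2], counts[, 3])

  keep <- unname(
    maf > maf_min & hwe$p.value > hwe_p_min & call_rate >= call_rate_min
  )
  qc <- tibble::tibble(
    id = panel$variants$id, maf = unname(maf), hwe_p = hwe$p.value,
    call_rate = unname(call_rate), kept = keep
  )
  out <- subset_panel(panel, keep)
  attr(out, "qc") <- qc
  out
}

genotype_counts <- function(x) {
  cbind(
    colSums(x == 0, na.rm = TRUE),
    colSums(x == 1, na.rm = TRUE),
    colSums(x == 2, na.rm = TRUE)
  )
}

subset_panel <- function(panel, keep) {
  structure(
    list(
      individuals = panel$individuals,
      variants = panel$variants[keep, , drop = FALSE],
      dosages = panel$dosages[, keep, drop = FALSE],
      seed = panel$seed
    ),
    class = "genotype_panel"
  )
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test comparing observed
#' genotype counts to the expectations `p^2`, `2pq`, `q^2` at the sample
#' allele frequency.  Vectorized over the three count vectors.
#' Monomorphic sites (expected heterozygote count zero) return a zero
#' statistic and p-value 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (dosage 0 / 1 / 2).
#' @return Tibble with `statistic` and `p.value`.
#' @examples
#' hardy_weinberg_chi2(25, 50, 25) # exact HWE: statistic 0
#' @export
hardy_weinberg_chi2 <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (any(n == 0)) abort("total genotype count must be > 0")
  q <- (2 * n_bb + n_ab) / (2 * n)
  p <- 1 - q
  e <- cbind(n * p^2, n * 2 * p * q, n * q^2)
  o <- cbind(n_aa, n_ab, n_bb)
  dev <- (o - e)^2 / e
  dev[e == 0] <- 0
  stat <- rowSums(dev)
  tibble::tibble(statistic = stat, p.value = pchisq(stat, df = 1,
    lower.tail = FALSE
  ))
}
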