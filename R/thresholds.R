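#' Default clumping and thresholding settings
#'
#' The conventional conservative instrument-selection settings: clump at
#' r-squared 0.001 within a 1 Mb window, then threshold at five
#' descending p-value cut-offs from 5e-4 to 5e-8.
#'
#' @return Named list with `r2_threshold`, `window_bp`, `p_cutoffs`.
#' @export
clump_defaults <- function() {
  list(
    r2_threshold = 0.001,
    window_bp = 1e6,
    p_cutoffs = c(5e-4, 5e-5, 5e-6, 5e-7, 5e-8)
  )
}

#' Apply p-value thresholds to clumped summary statistics
#'
#' For each cut-off `c` retains the variants with `P < c`.  Cut-offs are
#' sorted descending; the retained sets are therefore nested (each
#' stricter set is a subset of the looser one).
#'
#' @param stats Summary-statistics tibble (after clumping), with `SNP`
#'   and `P`.
#' @param p_cutoffs Numeric vector of thresholds, default
#'   `clump_defaults()$p_cutoffs`.
#' @return Tibble with one row per cut-off: `cutoff`, `label`
#'   (e.g. `"5e-07"`), `n_variants`, and list-column `ids`.
#' @examples
#' stats <- tibble::tibble(SNP = c("a", "b"), P = c(1e-9, 1e-5))
#' apply_thresholds(stats, c(5e-4, 5e-8))
#' @export
apply_thresholds <- function(stats, p_cutoffs = clump_defaults()$p_cutoffs) {
  if (any(p_cutoffs <= 0 | p_cutoffs > 1)) abort("cut-offs must be in (0, 1]")
  p_cutoffs <- sort(unique(p_cutoffs), decreasing = TRUE)
  tibble::tibble(
    cutoff = p_cutoffs,
    label = format(p_cutoffs, scientific = TRUE, trim = TRUE),
    ids = purrr::map(p_cutoffs, \(cc) stats$SNP[stats$P < cc]),
    n_variants = lengths(ids)
  ) |>
    dplyr::relocate("n_variants", .before = "ids")
}

#' Exclude variants in the MHC region
#'
#' Removes variants on the major-histocompatibility-complex chromosome
#' segment (default chr6:28,477,797-33,448,354, 1-based inclusive), the
#' strongest and most LD-complex autoimmune-risk locus cluster, for
#' MHC-free score sensitivity analyses.
#'
#' @param stats Summary-statistics tibble with `CHR` and `BP`.
#' @param mhc_chrom Chromosome label, default `"6"`.
#' @param mhc_start,mhc_end Window bounds (inclusive).
#' @return `stats` without the MHC variants.
#' @export
exclude_mhc <- function(stats, mhc_chrom = "6", mhc_start = 28477797,
                        mhc_end = 33448354) {
  if (mhc_start > mhc_end) abort("`mhc_start` must be <= `mhc_end`")
  inside <- stats$CHR == as.character(mhc_chrom) &
    stats$BP >= mhc_start & stats$BP <= mhc_end
  stats[!inside, , drop = FALSE]
}

#' Harmonize summary-statistic alleles to a genotype panel
#'
#' Aligns effect alleles with the panel's counted allele: where the
#' summary statistics report the effect for the panel's other allele the
#' beta sign is flipped; variants whose allele pair does not match the
#' panel are dropped with a warning.  Files are assumed to be on the
#' same strand, so A/T and C/G (strand-ambiguous) pairs are treated like
#' any other.
#'
#' @param stats Summary-statistics tibble with `SNP`, `A1`, `A2`, `BETA`.
#' @param panel `genotype_panel` whose `a1` is the counted allele.
#' @return `stats` restricted to matchable variants, `BETA` oriented to
#'   the panel's counted allele.
#' @export
harmonize_alleles <- function(stats, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  idx <- match(stats$SNP, v$id)
  present <- !is.na(idx)
  same <- present & stats$A1 == v$a1[idx] & stats$A2 == v$a2[idx]
  flipped <- present & stats$A1 == v$a2[idx] & stats$A2 == v$a1[idx]
  drop <- !(same | flipped)
  if (any(drop)) {
    warn(paste0(
      sum(drop), " variant(s) dropped during allele harmonization",
      " (absent from panel or mismatched allele pair)"
    ))
  }
  out <- stats[!drop, , drop = FALSE]
  flip_kept <- flipped[!drop]
  out$BETA[flip_kept] <- -out$BETA[flip_kept]
  if (any(flip_kept)) {
    tmp <- out$A1[flip_kept]
    out$A1[flip_kept] <- out$A2[flip_kept]
    out$A2[flip_kept] <- tmp
  }
  out
}
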