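#' Squared dosage correlation (LD r-squared)
#'
#' Squared Pearson correlation of two dosage vectors (composite LD on
#' unphased hard calls), with pairwise-complete handling of missing
#' entries.  Symmetric; a constant vector makes LD undefined and raises
#' an error (clumping treats that case as r-squared 0).
#'
#' @param x,y Dosage vectors of equal length (>= 2).
#' @return Squared correlation in `[0, 1]`.
#' @examples
#' ld_r2(c(0, 1, 2, 1), c(2, 1, 0, 1)) # perfect negative LD: 1
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("`x` and `y` must have equal length >= 2")
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("LD undefined for a constant dosage vector", class = "prsjoint_ld_undefined")
  }
  cor(x[ok], y[ok])^2
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the unassigned variant with the
#' smallest p-value as an index variant, then drop every unassigned
#' variant on the same chromosome within `window_bp` of it whose dosage
#' r-squared with the index reaches `r2_threshold`.  P-value ties break
#' by (chromosome, position).  The window is `+/- window_bp` from the
#' index position.  Variants present in `stats` but absent from the
#' panel are dropped with a warning.
#'
#' @param stats Summary-statistics tibble with columns `SNP`, `CHR`,
#'   `BP`, `P` (e.g. from [simulate_summary_stats()] or
#'   [read_summary_stats()]).
#' @param panel `genotype_panel` serving as the LD reference.
#' @param r2_threshold r-squared above which a neighbour is absorbed,
#'   default 0.001.
#' @param window_bp Physical window, default 1e6 (1 Mb).
#' @return Character vector of index variant ids, in selection order.
#'   No two retained variants within the window share r-squared at or
#'   above the threshold (asserted before returning).
#' @export
ld_clump <- function(stats, panel, r2_threshold = 0.001, window_bp = 1e6) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!(r2_threshold > 0 && r2_threshold < 1) || window_bp <= 0) {
    abort("invalid clumping configuration")
  }
  missing <- setdiff(stats$SNP, panel$variants$id)
  if (length(missing) > 0) {
    warn(paste0(
      length(missing), " variant(s) in summary stats absent from the LD",
      " reference; dropped"
    ))
    stats <- stats[!stats$SNP %in% missing, , drop = FALSE]
  }
  if (nrow(stats) == 0) {
    return(character(0))
  }

  col <- match(stats$SNP, panel$variants$id)
  ord <- order(stats$P, as.integer(stats$CHR), stats$BP)
  chr <- stats$CHR
  bp <- stats$BP
  assigned <- logical(nrow(stats))
  index <- integer(0)

  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index <- c(index, i)
    nb <- which(!assigned & chr == chr[i] & abs(bp - bp[i]) <= window_bp)
    if (length(nb) == 0) next
    xi <- panel$dosages[, col[i]]
    r2 <- vapply(nb, function(j) {
      tryCatch(ld_r2(xi, panel$dosages[, col[j]]),
        prsjoint_ld_undefined = function(e) 0
      )
    }, numeric(1))
    assigned[nb[r2 >= r2_threshold]] <- TRUE
  }

  ids <- stats$SNP[index]
  assert_clump_independence(stats[index, ], panel, r2_threshold, window_bp)
  ids
}

# Post-hoc invariant: no two survivors on the same chromosome within the
# window may reach the r2 threshold.
assert_clump_independence <- function(kept, panel, r2_threshold, window_bp) {
  if (nrow(kept) < 2) {
    return(invisible(TRUE))
  }
  col <- match(kept$SNP, panel$variants$id)
  for (i in seq_len(nrow(kept) - 1)) {
    for (j in (i + 1):nrow(kept)) {
      if (kept$CHR[i] == kept$CHR[j] &&
        abs(kept$BP[i] - kept$BP[j]) <= window_bp) {
        r2 <- tryCatch(
          ld_r2(panel$dosages[, col[i]], panel$dosages[, col[j]]),
          prsjoint_ld_undefined = function(e) 0
        )
        if (r2 >= r2_threshold) {
          abort("clump independence violated (internal error)")
        }
      }
    }
  }
  invisible(TRUE)
}
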