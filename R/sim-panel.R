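#' Simulate an LD-structured genotype dosage panel
#'
#' Draws hard-call dosages (0/1/2 copies of the counted allele) for
#' `n_individuals` x `n_variants` under a Gaussian copula: within each LD
#' block a latent AR(1) Gaussian vector with adjacent correlation
#' `ld_rho` is thresholded at the Hardy-Weinberg genotype quantiles of
#' each variant's drawn allele frequency, so marginal genotype
#' frequencies are p^2 / 2pq / q^2 and dosage correlation decays
#' approximately as `ld_rho^distance` within a block.  Blocks are
#' assigned to chromosomes 1-22 round-robin (never straddling a
#' chromosome) with physical spans well under 1 Mb; chromosome 6 blocks
#' are placed from 29 Mb so that some variants fall inside the MHC
#' window (28,477,797-33,448,354) used by [exclude_mhc()].
#'
#' @param config A [sim_config()].
#' @return A `genotype_panel`: list with `individuals` (tibble of `iid`),
#'   `variants` (tibble of `id`, `chrom`, `pos`, `a1`, `a2`, `maf`), and
#'   `dosages` (integer matrix, individuals x variants, `NA` where a
#'   missingness rate is configured).  Dosages count copies of `a1`.
#' @examples
#' panel <- simulate_panel(sim_config(n_individuals = 100, n_variants = 20,
#'   block_size = 5, seed = 1))
#' dim(panel$dosages)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_variants
  bs <- config$block_size

  n_blocks <- ceiling(m / bs)
  block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  idx_on_chrom <- stats::ave(seq_len(n_blocks), chrom_of_block,
    FUN = seq_along
  ) - 1L
  # 5 kb spacing keeps any block of <= 100 variants under 1 Mb wide.
  block_start <- ifelse(chrom_of_block == 6L, 29e6, 1e6) +
    idx_on_chrom * 2e6
  pos <- block_start[block_of] +
    (stats::ave(seq_len(m), block_of, FUN = seq_along) - 1L) * 5000

  drawn <- withr::with_seed(stage_seed(config$seed, "panel"), {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    out <- matrix(NA_integer_, n, m)
    for (b in seq_len(n_blocks)) {
      cols <- which(block_of == b)
      z <- matrix(rnorm(n * length(cols)), n, length(cols))
      if (config$ld_rho > 0 && length(cols) > 1) {
        w <- sqrt(1 - config$ld_rho^2)
        for (j in 2:length(cols)) {
          z[, j] <- config$ld_rho * z[, j - 1] + w * z[, j]
        }
      }
      u <- pnorm(z)
      p <- maf[cols]
      c0 <- rep((1 - p)^2, each = n)
      c1 <- rep((1 - p)^2 + 2 * p * (1 - p), each = n)
      out[, cols] <- (u > c0) + (u > c1)
    }
    if (config$missing_rate > 0) {
      out[runif(n * m) < config$missing_rate] <- NA_integer_
    }
    list(maf = maf, dosages = out)
  })

  variants <- tibble::tibble(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = as.character(chrom_of_block[block_of]),
    pos = as.integer(pos),
    a1 = "A", a2 = "G",
    maf = drawn$maf,
    block = block_of
  )
  dos <- drawn$dosages
  iid <- sprintf("id%06d", seq_len(n))
  dimnames(dos) <- list(iid, variants$id)

  structure(
    list(
      individuals = tibble::tibble(iid = iid),
      variants = variants,
      dosages = dos,
      seed = config$seed
    ),
    class = "genotype_panel"
  )
}

#' Construct a genotype panel from a dosage matrix
#'
#' Assembles the container used by the QC, clumping and scoring
#' functions from an individuals-by-variants dosage matrix and variant
#' metadata.
#'
#' @param dosages Numeric/integer matrix, individuals x variants,
#'   values in `[0, 2]` (`NA` allowed).
#' @param variants Tibble/data frame with columns `id`, `chrom`, `pos`,
#'   `a1`, `a2` and optionally `maf` (computed from the dosages when
#'   absent).  Row order must match the matrix columns.
#' @param iid Individual ids; default `row.names(dosages)` or generated.
#' @return A `genotype_panel`.
#' @examples
#' x <- matrix(c(0, 1, 2, 1, 0, 1), nrow = 3)
#' v <- tibble::tibble(
#'   id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
#'   a1 = "A", a2 = "G"
#' )
#' genotype_panel(x, v)
#' @export
genotype_panel <- function(dosages, variants, iid = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    abort("`variants` rows must match dosage columns")
  }
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% names(variants))) {
    abort("`variants` must contain id, chrom, pos, a1, a2")
  }
  if (anyDuplicated(variants$id)) abort("variant ids must be unique")
  variants <- tibble::as_tibble(variants)
  variants$chrom <- as.character(variants$chrom)
  if (!"maf" %in% names(variants)) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    variants$maf <- pmin(af, 1 - af)
  }
  iid <- iid %||% rownames(dosages) %||% sprintf("id%06d", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(iid, variants$id)
  structure(
    list(
      individuals = tibble::tibble(iid = iid),
      variants = variants,
      dosages = dosages,
      seed = NA
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d variants (seed %s)\n",
    nrow(x$dosages), ncol(x$dosages), format(x$seed)
  ))
  invisible(x)
}

#' Ground truth of a simulated cohort
#'
#' Chooses `n_causal` causal variants, assigns them per-allele effects,
#' and, when `config$or_per_sd` is set, rescales the effect vector so
#' that one standard deviation of the realized true score carries exactly
#' `log(or_per_sd)` on the log-odds scale.
#'
#' @param panel A [simulate_panel()] result (the realized panel fixes the
#'   score SD used for rescaling).
#' @param config The matching [sim_config()].
#' @param discovery_beta Optional per-variant effect vector used only for
#'   discovery summary statistics (length `n_variants`), allowing
#'   discovery/target effect heterogeneity.  Defaults to the target
#'   effects.
#' @return A `ground_truth` list: `causal_variant_ids`, `true_betas`
#'   (length `n_variants`, zero off the causal set), `discovery_betas`,
#'   `true_lifestyle_effects`, `true_or_per_sd`.
#' @export
ground_truth <- function(panel, config, discovery_beta = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  m <- config$n_variants
  betas <- numeric(m)
  causal <- withr::with_seed(
    stage_seed(config$seed, "truth"),
    sort(sample.int(m, config$n_causal))
  )
  betas[causal] <- rep_len(config$causal_log_or, config$n_causal)

  or_per_sd <- config$or_per_sd
  if (!is.null(or_per_sd) && config$n_causal > 0) {
    g <- true_score(panel, betas)
    s <- sd(g)
    if (s > 0) betas <- betas * log(or_per_sd) / s
  } else if (config$n_causal > 0) {
    or_per_sd <- exp(sd(true_score(panel, betas)))
  } else {
    or_per_sd <- 1
  }

  if (!is.null(discovery_beta)) {
    stopifnot(length(discovery_beta) == m)
  }
  structure(
    list(
      causal_variant_ids = panel$variants$id[causal],
      true_betas = betas,
      discovery_betas = discovery_beta %||% betas,
      true_lifestyle_effects = config$lifestyle_log_or,
      true_or_per_sd = or_per_sd
    ),
    class = "ground_truth"
  )
}

# Raw true score X.beta with mean imputation of missing dosages.
true_score <- function(panel, betas) {
  x <- panel$dosages
  if (anyNA(x)) {
    imp <- rep(2 * panel$variants$maf, each = nrow(x))
    x <- ifelse(is.na(x), imp, x)
  }
  as.numeric(x %*% betas)
}
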