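test_that("Hardy-Weinberg chi-square matches hand-computed values", {
  expect_equal(hardy_weinberg_chi2(25, 50, 25)$statistic, 0)
  expect_equal(hardy_weinberg_chi2(25, 50, 25)$p.value, 1)
  # all-heterozygote table: (0-25)^2/25 + (100-50)^2/50 + (0-25)^2/25
  expect_equal(hardy_weinberg_chi2(0, 100, 0)$statistic, 100)
  expect_equal(hardy_weinberg_chi2(36, 48, 16)$statistic, 0)
  expect_error(hardy_weinberg_chi2(-1, 5, 5), ">= 0")
  expect_error(hardy_weinberg_chi2(0, 0, 0), "> 0")
  # monomorphic: degenerate expected counts handled
  expect_equal(hardy_weinberg_chi2(10, 0, 0)$statistic, 0)
})

test_that("QC filter applies strict MAF, HWE and call-rate rules", {
  # variant 1: MAF exactly 0.02 -> removed under the strict inequality
  n <- 1000
  v1 <- c(rep(1L, 40), rep(0L, 960)) # 40 heterozygotes: MAF exactly 0.02
  v2 <- rep(0L, n) # monomorphic
  v3 <- withr::with_seed(2, rbinom(n, 2, 0.3)) # clean
  v4 <- c(rep(1L, 500), rep(NA_integer_, 500)) # low call rate + HWE failure
  panel <- make_panel(cbind(v1, v2, v3, v4))
  kept <- qc_panel(panel, maf_min = 0.02, hwe_p_min = 1e-7,
    call_rate_min = 0.95
  )
  expect_identical(kept$variants$id, "v003")
  qc <- attr(kept, "qc")
  expect_identical(qc$kept, c(FALSE, FALSE, TRUE, FALSE))

  # a panel where everything passes comes back unchanged, and the
  # filter is idempotent
  clean <- make_panel(withr::with_seed(3, matrix(rbinom(n * 4, 2, 0.3), n)))
  once <- qc_panel(clean)
  expect_identical(once$dosages, clean$dosages)
  twice <- qc_panel(once)
  expect_identical(twice$dosages, once$dosages)
  expect_error(qc_panel(clean, maf_min = -0.1), "thresholds")
})

test_that("ld_r2 equals the textbook Pearson formula and is symmetric", {
  withr::with_seed(10, {
    x <- as.numeric(rbinom(200, 2, 0.3))
    y <- round(pmin(pmax(x + rnorm(200), 0), 2))
  })
  manual <- (sum((x - mean(x)) * (y - mean(y))))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld_r2(x, y), manual, tolerance = 1e-12)
  expect_equal(ld_r2(x, y), ld_r2(y, x), tolerance = 1e-12)
  expect_equal(ld_r2(x, x), 1.0)
  expect_equal(ld_r2(x, 2 - x), 1.0)
  expect_error(ld_r2(rep(1, 10), x[1:10]), class = "prsjoint_ld_undefined")
  expect_error(ld_r2(x, y[1:10]), "equal length")
  # pairwise-complete missing handling
  xm <- x
  xm[1:5] <- NA
  expect_equal(ld_r2(xm, y), cor(xm, y, use = "pairwise.complete.obs")^2)
})

test_that("clumping keeps the smallest-p variant of a correlated pair", {
  withr::with_seed(4, {
    base <- rbinom(400, 2, 0.4)
  })
  panel <- make_panel(cbind(base, base), pos = c(1000000L, 1500000L))
  stats <- tibble::tibble(
    SNP = c("v001", "v002"), CHR = "1", BP = c(1000000L, 1500000L),
    P = c(1e-6, 1e-8)
  )
  expect_identical(ld_clump(stats, panel, 0.5, 1e6), "v002")
})

test_that("clumping matches the exhaustive greedy oracle on simulated blocks", {
  for (seed in c(1, 2, 3)) {
    cfg <- sim_config(
      n_individuals = 300, n_variants = 80, block_size = 16,
      ld_rho = 0.7, n_causal = 10, seed = seed
    )
    p <- simulate_panel(cfg)
    tr <- ground_truth(p, cfg)
    ss <- simulate_summary_stats(p, tr, cfg)
    for (r2 in c(0.01, 0.2)) {
      got <- ld_clump(ss, p, r2_threshold = r2, window_bp = 1e6)
      want <- oracle_clump(ss, p, r2, 1e6)
      expect_identical(got, want)
    }
  }
})

test_that("clump warns about and drops variants missing from the panel", {
  withr::with_seed(5, d <- matrix(rbinom(200 * 3, 2, 0.3), 200))
  panel <- make_panel(d)
  stats <- tibble::tibble(
    SNP = c("v001", "v002", "v003", "ghost"),
    CHR = "1", BP = c(10000L, 20000L, 30000L, 40000L),
    P = c(0.5, 1e-4, 0.2, 1e-9)
  )
  expect_warning(kept <- ld_clump(stats, panel, 0.9, 1e6), "absent")
  expect_false("ghost" %in% kept)
})

test_that("threshold grids are nested and match a brute-force filter", {
  withr::with_seed(6, {
    stats <- tibble::tibble(
      SNP = sprintf("s%03d", 1:200),
      P = 10^runif(200, -10, 0)
    )
  })
  grid <- apply_thresholds(stats)
  expect_identical(grid$cutoff, sort(clump_defaults()$p_cutoffs,
    decreasing = TRUE
  ))
  for (i in seq_len(nrow(grid))) {
    expect_setequal(grid$ids[[i]], stats$SNP[stats$P < grid$cutoff[i]])
    if (i > 1) expect_true(all(grid$ids[[i]] %in% grid$ids[[i - 1]]))
  }
  # counting example: cutoffs {5e-4, 5e-8} over p {1e-9, 1e-6, 1e-4}
  small <- tibble::tibble(SNP = c("a", "b", "c"), P = c(1e-9, 1e-6, 1e-4))
  g2 <- apply_thresholds(small, c(5e-4, 5e-8))
  expect_identical(g2$n_variants, c(3L, 1L))
  # empty input
  g3 <- apply_thresholds(small[0, ])
  expect_true(all(g3$n_variants == 0L))
})

test_that("MHC exclusion uses 1-based inclusive bounds on chromosome 6", {
  stats <- tibble::tibble(
    SNP = c("in1", "edge_low", "below", "other_chr", "edge_high"),
    CHR = c("6", "6", "6", "7", "6"),
    BP = c(30000000L, 28477797L, 28477796L, 30000000L, 33448354L),
    P = 0.5
  )
  out <- exclude_mhc(stats)
  expect_setequal(out$SNP, c("below", "other_chr"))
  expect_error(exclude_mhc(stats, mhc_start = 10, mhc_end = 5), "<=")
})

test_that("allele harmonization flips swapped strands and drops mismatches", {
  withr::with_seed(7, d <- matrix(rbinom(100 * 3, 2, 0.4), 100))
  panel <- make_panel(d) # a1 = A, a2 = G
  stats <- tibble::tibble(
    SNP = c("v001", "v002", "v003"),
    A1 = c("A", "G", "C"), A2 = c("G", "A", "T"),
    BETA = c(0.5, 0.5, 0.5)
  )
  expect_warning(h <- harmonize_alleles(stats, panel), "dropped")
  expect_setequal(h$SNP, c("v001", "v002"))
  expect_equal(h$BETA[h$SNP == "v001"], 0.5)
  expect_equal(h$BETA[h$SNP == "v002"], -0.5)
  expect_identical(h$A1[h$SNP == "v002"], "A")
})
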