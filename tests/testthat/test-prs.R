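test_that("scoring is the plain weighted dosage sum", {
  panel <- make_panel(matrix(c(1, 2, 0, 1, 2, 0), nrow = 3))
  w <- tibble::tibble(SNP = c("v001", "v002"), BETA = c(0.5, -0.25))
  s <- prs_score(panel, w)
  # first individual: 0.5*1 + (-0.25)*1; dosages by column: v001 = (1,2,0)
  expect_equal(s$raw, c(0.5 * 1 - 0.25 * 1, 0.5 * 2 - 0.25 * 2, 0))
  expect_identical(attr(s, "n_variants"), 2L)

  zero <- make_panel(matrix(0, nrow = 4, ncol = 2))
  expect_equal(prs_score(zero, w)$raw, rep(0, 4))
  expect_error(prs_score(panel, w[0, ]), "empty")
  expect_error(
    prs_score(panel, tibble::tibble(SNP = "nope", BETA = 1)),
    "absent"
  )
})

test_that("scoring matches a brute-force double loop on a random panel", {
  withr::with_seed(20, {
    d <- matrix(rbinom(5 * 3, 2, 0.4), 5, 3)
    betas <- rnorm(3)
  })
  panel <- make_panel(d)
  w <- tibble::tibble(SNP = panel$variants$id, BETA = betas)
  got <- prs_score(panel, w)$raw
  want <- numeric(5)
  for (i in 1:5) {
    for (k in 1:3) want[i] <- want[i] + d[i, k] * betas[k]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("scoring is linear in the weights", {
  withr::with_seed(21, d <- matrix(rbinom(50 * 4, 2, 0.3), 50, 4))
  panel <- make_panel(d)
  ids <- panel$variants$id
  w1 <- tibble::tibble(SNP = ids, BETA = rnorm(4))
  w2 <- tibble::tibble(SNP = ids, BETA = rnorm(4))
  comb <- tibble::tibble(SNP = ids, BETA = 2 * w1$BETA - 3 * w2$BETA)
  expect_equal(
    prs_score(panel, comb)$raw,
    2 * prs_score(panel, w1)$raw - 3 * prs_score(panel, w2)$raw,
    tolerance = 1e-10
  )
})

test_that("MHC-excluded score equals full score minus MHC-only score", {
  withr::with_seed(22, d <- matrix(rbinom(60 * 6, 2, 0.3), 60, 6))
  panel <- make_panel(d,
    chrom = c("6", "6", "6", "2", "2", "2"),
    pos = as.integer(c(29e6, 30e6, 34e6, 1e6, 2e6, 3e6))
  )
  stats <- tibble::tibble(
    SNP = panel$variants$id, CHR = panel$variants$chrom,
    BP = panel$variants$pos, BETA = rnorm(6)
  )
  non_mhc <- exclude_mhc(stats)
  mhc_only <- stats[!stats$SNP %in% non_mhc$SNP, ]
  expect_equal(
    prs_score(panel, non_mhc)$raw,
    prs_score(panel, stats)$raw - prs_score(panel, mhc_only)$raw,
    tolerance = 1e-10
  )
})

test_that("standardization yields exact moments and preserves ranks", {
  s <- tibble::tibble(iid = c("a", "b", "c"), raw = c(1, 2, 3))
  z <- prs_standardize(s)
  expect_equal(z$z, c(-1, 0, 1))
  withr::with_seed(23, s2 <- tibble::tibble(
    iid = as.character(1:500), raw = rexp(500)
  ))
  z2 <- prs_standardize(s2)
  expect_lt(abs(mean(z2$z)), 1e-8)
  expect_lt(abs(sd(z2$z) - 1), 1e-8)
  expect_identical(rank(z2$z), rank(z2$raw))
  expect_error(
    prs_standardize(tibble::tibble(iid = "a", raw = c(2, 2, 2))),
    "degenerate"
  )
  # reference-subset standardization transforms everyone
  zr <- prs_standardize(s2, reference_ids = as.character(1:250))
  ref <- zr$z[1:250]
  expect_lt(abs(mean(ref)), 1e-8)
  expect_lt(abs(sd(ref) - 1), 1e-8)
})

test_that("risk groups cut at quartiles with ties going low", {
  s <- tibble::tibble(iid = letters[1:8], raw = as.numeric(1:8))
  g <- assign_risk_groups(s)$genetic_risk
  expect_identical(
    as.character(g),
    c("low", "low", rep("intermediate", 4), "high", "high")
  )
  expect_error(
    assign_risk_groups(tibble::tibble(iid = "a", raw = 1)),
    "at least 4"
  )
  expect_warning(
    tied <- assign_risk_groups(tibble::tibble(
      iid = letters[1:6], raw = rep(2, 6)
    )),
    "tied"
  )
  expect_true(all(tied$genetic_risk == "low"))

  withr::with_seed(24, big <- tibble::tibble(
    iid = as.character(1:10000), raw = rnorm(10000)
  ))
  gr <- table(assign_risk_groups(big)$genetic_risk) / 10000
  expect_equal(as.numeric(gr), c(0.25, 0.50, 0.25), tolerance = 0.005)
})

test_that("deciles are balanced and rank-invariant", {
  s <- tibble::tibble(iid = as.character(1:10), raw = as.numeric(1:10))
  expect_identical(assign_deciles(s)$decile, 1:10)
  withr::with_seed(25, u <- tibble::tibble(
    iid = as.character(1:100000), raw = runif(100000)
  ))
  d1 <- assign_deciles(u)$decile
  expect_true(all(abs(table(d1) / 1e5 - 0.1) < 0.005))
  # monotone transform leaves the assignment unchanged
  u2 <- dplyr::mutate(u, raw = exp(3 * raw) - 1)
  expect_identical(assign_deciles(u2)$decile, d1)
})
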