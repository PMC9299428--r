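test_that("saturated 2x2 logistic fit reproduces the cross-product ratio", {
  d <- tibble::tibble(
    exposed = rep(c(1, 1, 0, 0), c(20, 80, 10, 90)),
    y = rep(c(1, 0, 1, 0), c(20, 80, 10, 90))
  )
  td <- tidy(fit_logistic(d, y ~ exposed))
  expect_equal(td$estimate[td$term == "exposed"], 2.25, tolerance = 1e-6)
})

test_that("intercept-only logistic fit returns the log-odds of the mean", {
  d <- tibble::tibble(y = rep(c(1, 0), c(30, 70)))
  fit <- fit_logistic(d, y ~ 1)
  expect_equal(unname(coef(fit)), log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("logistic deviance matches an independent optimizer", {
  d <- make_binary_cohort(400, seed = 30)
  fit <- fit_logistic(d, y ~ x + l)
  nll <- function(b) {
    eta <- b[1] + b[2] * d$x + b[3] * d$l
    -sum(d$y * eta - log1p(exp(eta)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
    control = list(reltol = 1e-14)
  )
  expect_equal(fit$model$deviance, 2 * opt$value, tolerance = 1e-6)
})

test_that("separation and aliasing are surfaced explicitly", {
  d <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)), y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(d, y ~ x), class = "prsjoint_separation")
  d2 <- make_binary_cohort(100, seed = 31)
  d2$x2 <- d2$x * 2
  expect_warning(
    suppressWarnings(fit_logistic(d2, y ~ x + x2), classes = "simpleWarning"),
    "aliased"
  )
})

test_that("six-subject Cox fit matches brute-force partial likelihood", {
  d <- tibble::tibble(
    time = c(1.1, 2.3, 3.7, 4.1, 5.9, 7.3),
    event = c(1, 1, 0, 1, 1, 0),
    x = c(1, 0, 1, 1, 0, 0)
  )
  fit <- fit_cox(d, survival::Surv(time, event) ~ x)
  beta_hat <- unname(coef(fit))
  beta_oracle <- oracle_cox_beta(d$time, d$event, d$x)
  expect_equal(beta_hat, beta_oracle, tolerance = 1e-6)
  # rank invariance: doubling the times changes nothing
  d2 <- dplyr::mutate(d, time = time * 2)
  expect_equal(unname(coef(fit_cox(d2, survival::Surv(time, event) ~ x))),
    beta_hat,
    tolerance = 1e-10
  )
})

test_that("degenerate Cox inputs raise the documented errors", {
  d <- tibble::tibble(
    time = c(1, 2, 3, 4), event = c(1, 1, 0, 1), const = 1,
    x = c(0, 1, 0, 1)
  )
  expect_error(
    fit_cox(d, survival::Surv(time, event) ~ const),
    "zero-information"
  )
  d0 <- dplyr::mutate(d, event = 0)
  expect_error(fit_cox(d0, survival::Surv(time, event) ~ x), "no events")
})

test_that("logistic OR and Cox HR agree for a rare outcome", {
  n <- 200000
  withr::with_seed(33, {
    x <- rbinom(n, 1, 0.3)
    h <- 5e-4 * exp(log(1.5) * x)
    t_ev <- rexp(n, h)
    cens <- runif(n, 10, 14)
    d <- tibble::tibble(
      x = x, time = pmin(t_ev, cens), event = as.integer(t_ev <= cens)
    )
  })
  expect_lt(mean(d$event), 0.01)
  or <- tidy(fit_logistic(d, event ~ x))$estimate[2]
  hr <- tidy(fit_cox(d, survival::Surv(time, event) ~ x))$estimate[1]
  expect_lt(abs(or / hr - 1), 0.15)
})

test_that("AUC equals brute-force concordance, including ties", {
  expect_equal(auc_mw(c(0.2, 0.8, 0.4, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_mw(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mw(1:5, rep(1, 5)), "both classes")
  withr::with_seed(34, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      s <- sample(seq(0, 1, 0.05), n, replace = TRUE) # force ties
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      expect_identical(auc_mw(s, y), oracle_auc(s, y))
    }
  })
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(38, {
    s <- rnorm(300)
    y <- rbinom(300, 1, plogis(s))
  })
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(auc_mw(s, y), ref, tolerance = 1e-12)
})

test_that("restricted cubic spline basis is linear beyond the boundary knots", {
  withr::with_seed(35, x <- rnorm(500))
  b <- rcs_basis(x, n_knots = 4)
  k <- attr(b, "knots")
  expect_length(k, 4)
  expect_identical(dim(b), c(500L, 3L))
  expect_equal(k, quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7,
    names = FALSE
  ))
  # below the first knot every nonlinear column vanishes
  lo <- seq(min(x) - 2, k[1] - 0.01, length.out = 50)
  blo <- rcs_basis(lo, knots = k)
  expect_true(all(abs(blo[, -1]) < 1e-12))
  # numerical curvature outside the boundary knots is zero
  for (side in list(
    seq(k[4] + 0.1, k[4] + 3, length.out = 100),
    seq(k[1] - 3, k[1] - 0.1, length.out = 100)
  )) {
    bb <- rcs_basis(side, knots = k)
    d2 <- diff(diff(bb[, 2]))
    expect_lt(max(abs(d2)), 1e-8)
  }
  expect_error(rcs_basis(x, knots = c(1, 1, 2)), "strictly increasing")
})

test_that("spline fit is invariant to affine transforms of the exposure", {
  d <- make_binary_cohort(800, seed = 36)
  b1 <- rcs_basis(d$x, n_knots = 4)
  f1 <- glm(d$y ~ b1, family = binomial())
  b2 <- rcs_basis(3 * d$x + 5, knots = 3 * attr(b1, "knots") + 5)
  f2 <- glm(d$y ~ b2, family = binomial())
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-8)
})

test_that("rcs_curve returns an OR curve anchored at the reference", {
  d <- make_binary_cohort(1500, seed = 37)
  cur <- rcs_curve(d, x = "x", outcome = "y")
  ref <- attr(cur, "ref")
  at_ref <- which.min(abs(cur$x - ref))
  expect_lt(abs(cur$estimate[at_ref] - 1), 0.05)
  expect_true(all(cur$conf.low <= cur$estimate + 1e-12))
})

test_that("trend test matches prop.trend.test and the 2x2 chi-square", {
  cases <- c(10, 25, 40)
  controls <- c(190, 175, 160)
  got <- cochran_armitage_trend(cases, controls)
  ref <- suppressWarnings(
    stats::prop.trend.test(cases, cases + controls, score = 0:2)
  )
  expect_equal(got$statistic^2, unname(ref$statistic), tolerance = 1e-10)
  expect_gt(got$statistic, 0) # increasing proportions -> positive Z
  # two groups: squared statistic equals the Pearson chi-square
  g2 <- cochran_armitage_trend(c(12, 30), c(88, 70))
  chi <- stats::prop.test(c(12, 30), c(100, 100), correct = FALSE)
  expect_equal(g2$statistic^2, unname(chi$statistic), tolerance = 1e-10)
  # flat proportions: Z = 0, p = 1
  flat <- cochran_armitage_trend(c(10, 20, 30), c(90, 180, 270))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
  expect_error(cochran_armitage_trend(c(1, 0), c(0, 0)), "empty group")
})

test_that("RERI/AP formula arithmetic and null behaviour", {
  # exp(b_gl) = 2.5, exp(b_g) = exp(b_l) = 1.5 -> RERI 0.5, AP 0.2
  pt <- prsjoint:::reri_ap_point(log(1.5), log(1.5), log(2.5))
  expect_equal(pt$reri, 0.5, tolerance = 1e-12)
  expect_equal(pt$ap, 0.2, tolerance = 1e-12)
  null <- prsjoint:::reri_ap_point(0, 0, 0)
  expect_equal(null$reri, 0)
  expect_equal(null$ap, 0)
})

test_that("RERI/AP from a saturated fit equals the 2x2x2 closed form", {
  counts <- array(
    c(
      930, 40, 230, 35, 320, 45, 80, 38
    ),
    dim = c(2, 2, 2),
    dimnames = list(c("control", "case"), c("g0", "g1"), c("l0", "l1"))
  )
  d <- tidyr::expand_grid(status = 0:1, g = 0:1, l = 0:1) |>
    dplyr::rowwise() |>
    dplyr::mutate(n = counts[status + 1, g + 1, l + 1]) |>
    dplyr::ungroup() |>
    tidyr::uncount(n) |>
    dplyr::mutate(
      g_only = as.integer(g & !l), l_only = as.integer(!g & l),
      g_and_l = as.integer(g & l)
    )
  fit <- fit_logistic(d, status ~ g_only + l_only + g_and_l)
  est <- reri_ap(fit, "g_only", "l_only", "g_and_l")
  want <- oracle_reri_2x2x2(aperm(counts, c(1, 2, 3)))
  expect_equal(est$estimate[est$term == "reri"], want$reri,
    tolerance = 1e-8
  )
  expect_equal(est$estimate[est$term == "ap"], want$ap, tolerance = 1e-8)
  # bootstrap CIs agree in location with the delta CIs
  boot <- reri_ap(fit, "g_only", "l_only", "g_and_l",
    method = "bootstrap", n_boot = 200
  )
  expect_equal(boot$estimate, est$estimate, tolerance = 1e-12)
  expect_true(all(boot$conf.low < boot$estimate),
    info = "percentile interval brackets the point estimate"
  )
  expect_error(reri_ap(fit, "g_only", "l_only", "nope"), "not found")
})

test_that("the SNP-by-lifestyle scan is complete, calibrated and robust", {
  cfg <- sim_config(
    n_individuals = 3000, n_variants = 40, block_size = 1,
    n_causal = 1, or_per_sd = 1, baseline_prevalence = 0.15,
    lifestyle_log_or = c(
      no_smoking = 0, regular_activity = 0, moderate_bmi = 0,
      no_alcohol = 0, healthy_diet = 0
    ),
    seed = 40
  )
  sim <- simulate_cohort(cfg)
  prof <- derive_lifestyle(sim$lifestyle)
  d <- dplyr::mutate(sim$cohort,
    unfavorable = as.integer(prof$lifestyle_category == "unfavorable")
  )
  scan <- snp_lifestyle_scan(sim$panel, d, lifestyle = "unfavorable")
  expect_identical(nrow(scan), 40L) # one row per variant, none dropped
  expect_true(all(diff(scan$p.value[!is.na(scan$p.value)]) >= 0))
  # no true interactions anywhere: p-values should look uniform
  ks <- suppressWarnings(
    stats::ks.test(scan$p.value[scan$converged], "punif")
  )
  expect_gt(ks$p.value, 0.01)
  # a degenerate constant variant is flagged, not fatal
  pan2 <- sim$panel
  pan2$dosages[, 1] <- 1L
  scan2 <- snp_lifestyle_scan(pan2, d, lifestyle = "unfavorable")
  row1 <- scan2[scan2$id == pan2$variants$id[1], ]
  expect_false(row1$converged)
  expect_true(is.na(row1$p.value))
})
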