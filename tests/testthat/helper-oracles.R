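# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive reimplementation (brute force,
# closed form, or a reference package) kept separate from the package's
# own code paths.

# Exhaustive greedy clumping oracle: literal restatement of the rule
# with no indexing tricks, O(k^2) r2 evaluations.
oracle_clump <- function(stats, panel, r2_threshold, window_bp) {
  remaining <- stats
  kept <- character(0)
  while (nrow(remaining) > 0) {
    o <- order(remaining$P, as.integer(remaining$CHR), remaining$BP)
    idx <- o[1]
    kept <- c(kept, remaining$SNP[idx])
    xi <- panel$dosages[, match(remaining$SNP[idx], panel$variants$id)]
    drop <- logical(nrow(remaining))
    drop[idx] <- TRUE
    for (j in seq_len(nrow(remaining))) {
      if (j == idx) next
      if (remaining$CHR[j] != remaining$CHR[idx]) next
      if (abs(remaining$BP[j] - remaining$BP[idx]) > window_bp) next
      xj <- panel$dosages[, match(remaining$SNP[j], panel$variants$id)]
      r2 <- if (sd(xi) == 0 || sd(xj) == 0) 0 else cor(xi, xj)^2
      if (r2 >= r2_threshold) drop[j] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# Brute-force pairwise AUC: loop over all case/control pairs.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) {
    for (b in ct) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cs) * length(ct))
}

# Written-out Cox partial likelihood for untied data, one binary
# covariate; maximized numerically.
oracle_cox_beta <- function(time, event, x) {
  nll <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    -ll
  }
  stats::optimize(nll, c(-10, 10), tol = 1e-10)$minimum
}

# Closed-form RERI/AP from a saturated 2x2x2 table of counts
# (case/control x G x L), odds ratios vs the G=0, L=0 cell.
oracle_reri_2x2x2 <- function(counts) {
  or <- function(g, l) {
    (counts["case", g, l] * counts["control", "g0", "l0"]) /
      (counts["control", g, l] * counts["case", "g0", "l0"])
  }
  reri <- or("g1", "l1") - or("g1", "l0") - or("g0", "l1") + 1
  list(reri = reri, ap = reri / or("g1", "l1"))
}

# Small deterministic panel from an explicit dosage matrix; positions
# spaced 10 kb on one chromosome unless given.
make_panel <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  genotype_panel(
    dosages,
    tibble::tibble(
      id = sprintf("v%03d", seq_len(m)),
      chrom = chrom %||% rep("1", m),
      pos = pos %||% as.integer(seq_len(m) * 10000),
      a1 = "A", a2 = "G"
    )
  )
}

# Random small cohort for model tests.
make_binary_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    l <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-2 + 0.8 * x + 0.5 * l))
    tibble::tibble(y = y, x = x, l = l)
  })
}

`%||%` <- rlang::`%||%`
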