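test_that("without covariates the burden beta is the carrier mean difference", {
  set.seed(2)
  for (i in 1:10) {
    carrier <- c(rep(1L, 15), rep(0L, 185))
    y <- rnorm(200) + 0.3 * carrier
    fit <- burdenFit(carrier, y)
    expect_equal(fit$beta,
                 mean(y[carrier == 1]) - mean(y[carrier == 0]),
                 tolerance = 1e-10)
  }
})

test_that("burden fit recovers a known effect and flags tiny genes", {
  set.seed(31)
  nrep <- 20
  betas <- ses <- numeric(nrep)
  for (r in seq_len(nrep)) {
    n <- 5000
    carrier <- rbinom(n, 1, 0.01)
    X <- cbind(age = rnorm(n), pc1 = rnorm(n))
    y <- 0.5 * carrier + 0.05 * X[, 1] + rnorm(n)
    fit <- burdenFit(carrier, y, X)
    betas[r] <- fit$beta
    ses[r] <- fit$se
  }
  expect_lt(abs(mean(betas) - 0.5), 3 * mean(ses) / sqrt(nrep))

  ## all-zero carrier vector -> excluded, not fitted
  fit0 <- burdenFit(rep(0L, 100), rnorm(100))
  expect_true(fit0$excluded)
  expect_true(is.na(fit0$p))
})

test_that("collinear covariates are dropped with a warning", {
  set.seed(4)
  carrier <- c(rep(1L, 20), rep(0L, 80))
  X <- cbind(a = rnorm(100))
  X <- cbind(X, b = 2 * X[, "a"])
  expect_warning(fit <- burdenFit(carrier, rnorm(100), X), "collinear")
  expect_false(is.na(fit$beta))
})

test_that("exome-wide significance is strict and calibrated for power", {
  ## p exactly at the threshold is not significant
  cs <- list(list(carriers = matrix(rep(c(rep(1L, 12), rep(0L, 88)), 1),
                                    1, 100,
                                    dimnames = list("G", sprintf("s%d", 1:100))),
                  info = data.frame(gene = "G", mask = "PTV",
                                    n_carriers = 12L, excluded = FALSE)))
  y <- setNames(rnorm(100), sprintf("s%d", 1:100))
  res <- exomewideScan(cs, y, threshold = 1)
  expect_false(any(res$p == 1 & res$significant))

  ## a 1-SD effect with ~60 carriers in n = 20,000 is detected at 1.64e-6
  set.seed(77)
  hits <- logical(15)
  for (r in 1:15) {
    n <- 20000
    carrier <- rbinom(n, 1, 0.003)
    y <- setNames(1.0 * carrier + rnorm(n), sprintf("s%d", 1:n))
    cs <- list(list(carriers = matrix(carrier, 1, n,
                                      dimnames = list("G", names(y))),
                    info = data.frame(gene = "G", mask = "PTV",
                                      n_carriers = sum(carrier),
                                      excluded = FALSE)))
    hits[r] <- exomewideScan(cs, y, threshold = 1.64e-6)$significant
  }
  expect_gte(mean(hits), 0.95)

  ## empty carrier sets give an empty table when a threshold is supplied
  empty <- exomewideScan(list(), y, threshold = 0.05)
  expect_identical(nrow(empty), 0L)
})

test_that("BH candidate scan matches the brute-force step-up", {
  res <- data.frame(gene = c("A", "B", "C", "D"), mask = "PTV",
                    analysis = "fetal", stratum = "all", n = 100L,
                    n_carriers = 10L, beta = 0.1, se = 0.05,
                    p = c(0.01, 0.02, 0.03, 0.5))
  out <- bhCandidateScan(res, c("A", "B", "C", "D"))
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.5))
  ## m = 1 identity
  expect_equal(bhCandidateScan(res[3, ], "C")$q, 0.03)
  ## all p = 1: no discoveries
  res$p <- 1
  expect_false(any(bhCandidateScan(res, res$gene)$discovery))
  ## restriction to proximal genes
  expect_identical(nrow(bhCandidateScan(res, "Z")), 0L)

  set.seed(12)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("conditioning on an independent sentinel does not attenuate", {
  set.seed(21)
  n <- 20000
  carrier <- rbinom(n, 1, 0.005)
  sentinel <- rbinom(n, 2, 0.3)
  X <- cbind(age = rnorm(n))
  y <- 0.4 * carrier + 0.1 * sentinel + 0.05 * X[, 1] + rnorm(n)
  fit <- conditionalFit(carrier, y, X, cbind(sentinel))
  expect_equal(fit$beta_conditional, fit$beta_marginal, tolerance = 0.05)
  expect_lt(abs(fit$attenuation_pct), 10)
  expect_false(fit$attenuated)
  ## attenuation arithmetic: 0.30 -> 0.26 is 13.3%, attenuated
  expect_equal(100 * (0.30 - 0.26) / 0.30, 13.3, tolerance = 0.05)
  expect_equal(fit$attenuation_pct,
               100 * (fit$beta_marginal - fit$beta_conditional) /
                 fit$beta_marginal)
})

test_that("a sentinel tagging the carrier haplotype attenuates the burden", {
  set.seed(22)
  n <- 20000
  carrier <- rbinom(n, 1, 0.01)
  ## the sentinel tags the carrier haplotype and carries part of the signal
  sentinel <- carrier + rbinom(n, 1, 0.3)
  y <- 0.3 * carrier + 0.25 * sentinel + rnorm(n)
  fit <- conditionalFit(carrier, y, NULL, cbind(sentinel))
  expect_true(abs(fit$attenuation_pct) > 10)
  expect_true(fit$attenuated)
})

test_that("the family-wise error of the null exome scan is controlled", {
  ## 100 null cohorts x 200 genes x 2 masks at the Bonferroni threshold
  ## for 400 tests: expect any-hit cohorts ~ Binomial(100, ~0.05)
  set.seed(61)
  n_coh <- 100
  n_genes <- 200
  any_hit <- logical(n_coh)
  thr <- 0.05 / (2 * n_genes)
  for (r in seq_len(n_coh)) {
    n <- 1500
    carriers <- matrix(rbinom(n_genes * n, 1, 0.012), n_genes, n,
                       dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                       sprintf("s%d", seq_len(n))))
    y <- setNames(rnorm(n), colnames(carriers))
    info <- data.frame(gene = rownames(carriers), mask = "PTV",
                       n_carriers = rowSums(carriers), excluded = FALSE)
    cs <- list(list(carriers = carriers, info = info),
               list(carriers = carriers,
                    info = transform(info, mask = "MissensePTV")))
    res <- exomewideScan(cs, y, threshold = thr)
    any_hit[r] <- any(res$significant, na.rm = TRUE)
  }
  expect_lte(sum(any_hit), 10)
})
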