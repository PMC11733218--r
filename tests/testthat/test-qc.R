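test_that("call-level depth/quality thresholds are strict", {
  ## SNV at the boundary (DP 7, GQ 20) passes; below either cutoff fails
  expect_identical(filterCalls(1L, 7L, 20L, FALSE), 1L)
  expect_true(is.na(filterCalls(1L, 6L, 55L, FALSE)))
  expect_true(is.na(filterCalls(1L, 30L, 19L, FALSE)))
  ## indels need DP 10
  expect_true(is.na(filterCalls(1L, 9L, 60L, TRUE)))
  expect_identical(filterCalls(2L, 10L, 20L, TRUE), 2L)
  ## matrix form recycles the per-variant indel flag down columns
  gt <- matrix(1L, 2, 3)
  dp <- matrix(9L, 2, 3)
  gq <- matrix(60L, 2, 3)
  out <- filterCalls(gt, dp, gq, c(FALSE, TRUE))
  expect_identical(out[1, ], rep(1L, 3))
  expect_true(all(is.na(out[2, ])))
})

test_that("allele-balance p-values match closed forms and are symmetric", {
  expect_equal(alleleBalanceTest(10L, 20L), 1.0)
  ## all-reference het call: p = 2 * (1/2)^20
  expect_equal(alleleBalanceTest(0L, 20L), 2 * 0.5^20)
  expect_true(alleleBalanceTest(0L, 20L) <= 1e-3)
  ## frozen brute-force sum over outcomes as extreme or more
  expect_equal(alleleBalanceTest(5L, 20L), 0.0413894653, tolerance = 1e-8)
  expect_true(alleleBalanceTest(5L, 20L) > 1e-3)

  set.seed(42)
  n <- sample(1:80, 60, replace = TRUE)
  k <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  expect_equal(alleleBalanceTest(k, n), alleleBalanceTest(n - k, n))

  expect_error(alleleBalanceTest(3L, 10L, dosage = 2L), "heterozygous")
  expect_error(alleleBalanceTest(0L, 0L), "depth")
})

test_that("variant missingness drops strictly above 50 percent", {
  gt50 <- matrix(c(rep(NA_integer_, 50), rep(0L, 50)), 1)
  gt51 <- matrix(c(rep(NA_integer_, 51), rep(0L, 49)), 1)
  gt0 <- matrix(0L, 1, 100)
  expect_true(variantMissingness(gt50))
  expect_false(variantMissingness(gt51))
  expect_true(variantMissingness(gt0))
  expect_error(variantMissingness(matrix(integer(), 1, 0)), "no samples")
})

test_that("AD~DP slope is 1 on perfect data and 0 in the spurious limit", {
  set.seed(7)
  dp <- 2L * (rpois(200, 15) + 1L)   # even depths keep het AD exact
  gt <- sample(c(0L, 1L, 2L), 200, replace = TRUE)
  ad_perfect <- as.integer(round(gt / 2 * dp))
  expect_equal(adDpSlope(gt, dp, ad_perfect), 1.0, tolerance = 1e-12)
  ## all alternate reads absent across het and hom-alt calls
  expect_equal(adDpSlope(gt, dp, rep(0L, 200)), 0.0, tolerance = 1e-12)
  ## degenerate design: every expected value identical
  expect_true(is.na(adDpSlope(rep(1L, 5), rep(20L, 5), c(8L, 9L, 10L, 11L, 12L))))
})

test_that("het alternate-read probability p yields slope ~ 2p", {
  ## rare-variant genotype mix: hom-ref background plus het carriers
  set.seed(11)
  n <- 40000
  gt <- c(rep(0L, n - 1000L), rep(1L, 1000L))
  dp <- rpois(n, 30) + 1L
  p <- ifelse(gt == 1L, 0.2, 0.002)
  ad <- rbinom(n, dp, p)
  s <- adDpSlope(gt, dp, ad)
  expect_equal(s, 0.4, tolerance = 0.03)
  expect_true(s < 0.5)                       # dropped by the filter
})

test_that("MAF boundary: 19 het carriers in 10,000 pass, 20 fail", {
  m19 <- computeMaf(c(rep(1L, 19), rep(0L, 9981)))
  m20 <- computeMaf(c(rep(1L, 20), rep(0L, 9980)))
  expect_equal(m19, 9.5e-4)
  expect_equal(m20, 1e-3)
  th <- qcThresholds()
  expect_true(m19 < th$maf_max)
  expect_false(m20 < th$maf_max)            # strict inequality
  expect_equal(computeMaf(rep(0L, 100)), 0) # monomorphic kept by this rule
  expect_error(computeMaf(rep(NA_integer_, 5)), "all-missing")
  ## folded above 0.5 alternate frequency
  expect_equal(computeMaf(c(rep(2L, 99), 1L)), 0.005)
})

test_that("the QC pipeline log is reproducible and ordered", {
  coh <- simulateDuos(null_cohort_config(seed = 5))
  a <- runGenotypeQc(genotypeCalls(coh))
  b <- runGenotypeQc(genotypeCalls(coh))
  expect_identical(a$log, b$log)
  expect_identical(a$log$step,
                   c("call_depth_gq", "allele_balance",
                     "variant_missingness", "rare_maf"))
  expect_identical(a$log$n_after, a$log$n_before - a$log$n_removed)
  ## slope + aascore steps appear in replication-style runs
  calls2 <- genotypeCalls(coh)
  SummarizedExperiment::rowData(calls2)$aascore <- 0.95
  full <- runGenotypeQc(calls2, slope_filter = TRUE, aascore_filter = TRUE)
  expect_identical(full$log$step,
                   c("call_depth_gq", "allele_balance",
                     "variant_missingness", "ad_dp_slope", "aascore",
                     "rare_maf"))
})

test_that("the slope filter drops a skewed variant the balance test keeps", {
  ## two variants x 60 samples: variant 1 well-behaved (het AD = DP/2,
  ## slope 1); variant 2 skewed with het AD = 6 of DP 30 (allele-balance
  ## p ~ 1.4e-3 > 1e-3, so calls survive, but slope = 0.4 < 0.5)
  gt <- rbind(c(rep(1L, 20), rep(0L, 30), rep(2L, 10)),
              c(rep(1L, 20), rep(0L, 40)))
  dp <- matrix(30L, 2, 60)
  ad <- rbind(c(rep(15L, 20), rep(0L, 30), rep(30L, 10)),
              c(rep(6L, 20), rep(0L, 40)))
  calls <- make_calls(gt, dp = dp, ad = ad)
  qc <- runGenotypeQc(calls, slope_filter = TRUE, rare_filter = FALSE)
  expect_equal(qc$report$slope, c(1.0, 0.4), tolerance = 1e-12)
  expect_identical(qc$report$decision, c("keep", "drop_slope"))
  expect_identical(nrow(qc$calls), 1L)
})
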