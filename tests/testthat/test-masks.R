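ann_row <- function(cls = "missense", cadd = NA_real_, loftee = FALSE,
                    miter = NA_real_, clin = NA_character_,
                    id = "1:100:A:T") {
  data.frame(variant_id = id, gene = "G", consequence_class = cls,
             loftee_high_confidence = loftee, cadd = cadd, miter = miter,
             aascore = NA_real_, clinical_class = clin)
}

test_that("mask qualification boundaries are inclusive as stated", {
  mp <- maskMissensePTV()
  expect_true(qualifyVariants(ann_row("missense", cadd = 25.0), mp))
  expect_false(qualifyVariants(ann_row("missense", cadd = 24.999), mp))
  ## PTVs require the high-confidence flag
  expect_true(qualifyVariants(ann_row("PTV", loftee = TRUE), mp))
  expect_false(qualifyVariants(ann_row("PTV", loftee = FALSE), maskPTV()))
  ## MITER <= -2 is inclusive and missense-only
  mm <- burdenMask("MITER", includePtv = FALSE, miterMax = -2)
  expect_true(qualifyVariants(ann_row("missense", miter = -2.0), mm))
  expect_false(qualifyVariants(ann_row("missense", miter = -1.9), mm))
  expect_false(qualifyVariants(ann_row("PTV", miter = -3, loftee = TRUE),
                               mm))
  ## clinical mask
  mc <- burdenMask("path", includePtv = FALSE,
                   clinicalClasses = c("pathogenic", "likely_pathogenic"))
  expect_true(qualifyVariants(ann_row(clin = "likely_pathogenic"), mc))
  expect_false(qualifyVariants(ann_row(clin = "vus"), mc))
  ## the REGENIE-style variant admits inframe indels at CADD >= 25
  expect_true(qualifyVariants(ann_row("inframe", cadd = 26),
                              maskRegenieMissensePTV()))
  expect_false(qualifyVariants(ann_row("inframe", cadd = 26),
                               maskMissensePTV()))
  ## exclusion list wins over any criterion
  mx <- maskPTV(excludedVariants = "1:100:A:T")
  expect_false(qualifyVariants(ann_row("PTV", loftee = TRUE), mx))
  ## a mask needs at least one active criterion
  expect_error(burdenMask("empty", includePtv = FALSE))
})

test_that("carrier collapse resolves partial missingness to evidence", {
  expect_identical(collapseCarriers(matrix(c(0L, 1L, 0L), 3, 1)), 1L)
  expect_identical(collapseCarriers(matrix(c(0L, NA, 0L), 3, 1)), 0L)
  expect_identical(collapseCarriers(matrix(NA_integer_, 3, 1)),
                   NA_integer_)
  expect_identical(collapseCarriers(matrix(c(2L, NA), 2, 1)), 1L)
})

test_that("carrier collapse agrees with the brute-force scan oracle", {
  set.seed(99)
  for (i in 1:300) {
    v <- sample(1:8, 1)
    s <- sample(1:20, 1)
    gt <- matrix(sample(c(0L, 1L, 2L, NA), v * s, replace = TRUE,
                        prob = c(0.6, 0.2, 0.05, 0.15)), v, s)
    expect_identical(unname(collapseCarriers(gt)), oracle_collapse(gt))
  }
})

test_that("relaxing the CADD cutoff never loses carriers", {
  set.seed(5)
  for (i in 1:20) {
    nv <- 12
    vt <- data.frame(
      variant_id = sprintf("1:%d:A:T", seq_len(nv)),
      gene = sample(c("A", "B"), nv, replace = TRUE),
      consequence_class = sample(c("PTV", "missense", "synonymous"), nv,
                                 replace = TRUE),
      loftee_high_confidence = sample(c(TRUE, FALSE), nv, replace = TRUE),
      cadd = runif(nv, 0, 40), miter = NA_real_, aascore = NA_real_,
      clinical_class = NA_character_, is_indel = FALSE,
      chrom = "1", pos = seq_len(nv), ref = "A", alt = "T")
    gt <- matrix(sample(c(0L, 1L, NA), nv * 30, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)), nv, 30)
    calls <- make_calls(gt, variants = vt)
    strict <- buildCarrierSets(calls, burdenMask("s", caddMin = 30),
                               min_carriers = 1)
    loose <- buildCarrierSets(calls, burdenMask("l", caddMin = 20),
                              min_carriers = 1)
    for (g in strict$info$gene) {
      n_strict <- strict$info$n_carriers[strict$info$gene == g]
      n_loose <- loose$info$n_carriers[loose$info$gene == g]
      expect_gte(n_loose, n_strict)
    }
  }
})

test_that("leaving out a zero-carrier variant leaves the set unchanged", {
  gt <- rbind(c(1L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L))
  vt <- data.frame(variant_id = c("1:1:A:T", "1:2:A:T"), gene = "G",
                   consequence_class = "PTV",
                   loftee_high_confidence = TRUE, cadd = 40,
                   miter = NA_real_, aascore = NA_real_,
                   clinical_class = NA_character_, is_indel = FALSE,
                   chrom = "1", pos = 1:2, ref = "A", alt = "T")
  calls <- make_calls(gt, variants = vt)
  full <- buildCarrierSets(calls, maskPTV(), min_carriers = 1)
  loo <- buildCarrierSets(calls, maskPTV(excludedVariants = "1:2:A:T"),
                          min_carriers = 1)
  expect_identical(full$carriers["G", ], loo$carriers["G", ])
})

test_that("genes below the carrier floor are flagged excluded", {
  gt <- rbind(c(rep(1L, 3), rep(0L, 27)))
  calls <- make_calls(gt)
  cs <- buildCarrierSets(calls, maskPTV(), min_carriers = 10)
  expect_identical(cs$info$n_carriers, 3L)
  expect_true(cs$info$excluded)
})

test_that("threshold arithmetic follows 0.05 over the summed counts", {
  expect_equal(exomeWideThreshold(c(1)), 0.05)
  expect_equal(exomeWideThreshold(c(100, 100)), 2.5e-4)
  expect_error(exomeWideThreshold(c(0, 0)), "no testable genes")
})
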