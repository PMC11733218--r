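test_that("identical seed and config give byte-identical outputs", {
  cfg <- duoSimConfig(600, list(geneSimSpec("G1", n_variants = 3,
                                            carrier_freq = 0.003)),
                      seed = 42)
  a <- simulateDuos(cfg)
  b <- simulateDuos(cfg)
  expect_identical(dosages(genotypeCalls(a)), dosages(genotypeCalls(b)))
  expect_identical(sampleTable(a), sampleTable(b))
  da <- tempfile(); db <- tempfile()
  writeCohort(a, da); writeCohort(b, db)
  for (f in c("cohort.vcf", "phenotypes.tsv", "annotations.tsv",
              "truth.tsv"))
    expect_identical(readLines(file.path(da, f)),
                     readLines(file.path(db, f)))
})

test_that("cohort dimensions and the no-power warning", {
  cfg <- duoSimConfig(100, list(geneSimSpec("G1", n_variants = 5,
                                            carrier_freq = 0.004)),
                      seed = 1)
  coh <- suppressWarnings(simulateDuos(cfg))
  d <- tempfile()
  writeCohort(coh, d)
  vcf <- readLines(file.path(d, "cohort.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  expect_length(body, 5L)                          # 5 records
  header <- strsplit(grep("^#CHROM", vcf, value = TRUE), "\t")[[1]]
  expect_length(header, 9L + 200L)                 # mothers + children
  ## E[carriers] = 0.4 < 1 -> warning
  expect_warning(simulateDuos(cfg), "expected carrier count")
  ## non-empty output directory is refused without force
  expect_error(writeCohort(coh, d), "not empty")
  expect_silent(writeCohort(coh, d, force = TRUE))
})

test_that("write -> read round trip preserves every call field", {
  cfg <- duoSimConfig(300, list(geneSimSpec("G1", n_variants = 4,
                                            carrier_freq = 0.004,
                                            n_background = 2)),
                      seed = 9)
  coh <- simulateDuos(cfg)
  d <- tempfile()
  writeCohort(coh, d)
  back <- readCohortVcf(file.path(d, "cohort.vcf"))
  calls <- genotypeCalls(coh)
  expect_identical(unname(dosages(back)), unname(dosages(calls)))
  expect_identical(unname(readDepth(back)), unname(readDepth(calls)))
  expect_identical(unname(genotypeQuality(back)),
                   unname(genotypeQuality(calls)))
  expect_identical(unname(altReads(back)), unname(altReads(calls)))
  ann <- readAnnotations(file.path(d, "annotations.tsv"))
  expect_identical(ann$variant_id, variantTable(calls)$variant_id)
  ph <- readPhenotypes(file.path(d, "phenotypes.tsv"))
  expect_identical(ph$sample_id, sampleTable(coh)$sample_id)
})

test_that("spurious-variant reads match the configured skew", {
  cfg <- duoSimConfig(
    6000, list(geneSimSpec("G1", n_variants = 2, carrier_freq = 0.01,
                           variant_freq = 0.005)),
    spurious = list(list(gene = "G1", variant = 2,
                         het_alt_read_prob = 0.1)),
    missing_rate = 0, seed = 10)
  coh <- simulateDuos(cfg)
  calls <- genotypeCalls(coh)
  gt <- dosages(calls); ad <- altReads(calls); dp <- readDepth(calls)
  het2 <- gt[2, ] == 1L
  expect_lt(abs(mean(ad[2, het2] / dp[2, het2]) - 0.1), 0.02)
  het1 <- gt[1, ] == 1L
  expect_lt(abs(mean(ad[1, het1] / dp[1, het1]) - 0.5), 0.02)
})

test_that("mother-child carrier correlation is 0.5 under transmission", {
  ## 20 rare variants pooled: child carrier implies one carrier parent,
  ## the mother with probability 1/2, so corr ~ 0.5
  cfg <- duoSimConfig(
    100000, list(geneSimSpec("G1", n_variants = 20, carrier_freq = 0.08,
                             variant_freq = 0.004)),
    missing_rate = 0, seed = 11)
  coh <- simulateDuos(cfg)
  gt <- dosages(genotypeCalls(coh))
  role <- SummarizedExperiment::colData(genotypeCalls(coh))$role
  mom <- gt[, role == "mother"] >= 1L
  kid <- gt[, role == "child"] >= 1L
  cors <- vapply(seq_len(nrow(gt)), function(v)
    cor(as.numeric(mom[v, ]), as.numeric(kid[v, ])), numeric(1))
  expect_equal(mean(cors), 0.5, tolerance = 0.02)

  ## symmetry: aggregate carrier frequency matches between generations
  expect_equal(mean(colSums(kid) > 0), mean(colSums(mom) > 0),
               tolerance = 0.1)
})

test_that("marginal slopes recover the projected effects", {
  ## beta_fetal = 0.5, beta_maternal = 0: the marginal maternal slope
  ## converges to 0.25 = beta_fetal / 2 under the r = 0.5 structure
  set.seed(12)
  nrep <- 30
  bF <- bM <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- duoSimConfig(20000,
                        list(geneSimSpec("G1", n_variants = 4,
                                         carrier_freq = 0.004,
                                         beta_fetal = 0.5)),
                        seed = 5000 + r)
    coh <- simulateDuos(cfg)
    calls <- genotypeCalls(coh)
    cc <- metadata(calls)$carrier_child[1, ]
    cm <- metadata(calls)$carrier_mother[1, ]
    z <- standardise(metadata(calls)$bw_kg)
    bF[r] <- burdenFit(cc, z)$beta
    bM[r] <- burdenFit(cm, z)$beta
  }
  expect_lt(abs(mean(bF) - 0.5), 3 * sd(bF) / sqrt(nrep))
  expect_lt(abs(mean(bM) - 0.25), 3 * sd(bM) / sqrt(nrep))
})

test_that("overlapping panels give mothers their own birth weight", {
  cfg <- duoSimConfig(500, list(geneSimSpec("G1", n_variants = 2,
                                            carrier_freq = 0.004)),
                      overlap_fraction = 0.2, seed = 13)
  coh <- simulateDuos(cfg)
  st <- sampleTable(coh)
  moms <- st[startsWith(st$sample_id, "M"), ]
  expect_identical(sum(nzchar(moms$own_bw_reports)), 100L)
})

test_that("invalid configurations are rejected", {
  expect_error(duoSimConfig(0, list(geneSimSpec("G"))), "positive")
  expect_error(geneSimSpec("G", n_variants = 0), "n_variants")
  expect_error(geneSimSpec("G", carrier_freq = 0.2, n_variants = 2),
               "carrier frequency")
  expect_error(geneSimSpec("G", beta_fetal = Inf), "finite")
  expect_error(duoSimConfig(10, list(geneSimSpec("G")),
                            missing_rate = 1.5), "probabilities")
})
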