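## Fixtures and independent brute-force oracles shared across test files.

## Write a small VCF from parallel record strings and return the path.
write_vcf_fixture <- function(records, samples,
                              ad_number = "1", ad_type = "Integer") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##contig=<ID=2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("##FORMAT=<ID=AD,Number=", ad_number, ",Type=", ad_type,
           ",Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

## Minimal GenotypeCalls built in code.
make_calls <- function(gt, dp = NULL, gq = NULL, ad = NULL,
                       variants = NULL) {
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1L)
  if (is.null(colnames(gt)))
    colnames(gt) <- sprintf("s%02d", seq_len(ncol(gt)))
  if (is.null(dp)) dp <- matrix(30L, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(60L, nrow(gt), ncol(gt))
  if (is.null(ad)) {
    ad <- gt
    ad[!is.na(gt)] <- as.integer(round(gt[!is.na(gt)] / 2 *
                                         dp[!is.na(gt)]))
  }
  dimnames(dp) <- dimnames(gq) <- dimnames(ad) <- dimnames(gt)
  if (is.null(variants))
    variants <- data.frame(
      variant_id = sprintf("1:%d:A:T", 100L * seq_len(nrow(gt))),
      chrom = "1", pos = 100L * seq_len(nrow(gt)), ref = "A", alt = "T",
      gene = "G1", consequence_class = "PTV",
      loftee_high_confidence = TRUE, cadd = 40, miter = NA_real_,
      aascore = NA_real_, clinical_class = NA_character_,
      is_indel = FALSE)
  GenotypeCalls(gt, dp, gq, ad, variants = variants)
}

## Brute-force oracle for the two-sided binomial p at prob 1/2:
## explicit sum over outcomes at most as likely as the observed one.
oracle_binom_p <- function(k, n) {
  obs <- choose(n, k) * 0.5^n
  total <- 0
  for (j in 0:n) {
    pj <- choose(n, j) * 0.5^n
    if (pj <= obs * (1 + 1e-07)) total <- total + pj
  }
  min(1, total)
}

## Brute-force per-sample carrier collapse.
oracle_collapse <- function(gt) {
  out <- integer(ncol(gt))
  for (s in seq_len(ncol(gt))) {
    col <- gt[, s]
    if (all(is.na(col))) out[s] <- NA_integer_
    else if (any(col >= 1L, na.rm = TRUE)) out[s] <- 1L
    else out[s] <- 0L
  }
  out
}

## Brute-force Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

## Brute-force AD~DP slope via stats::lm on the expected counts.
oracle_slope <- function(gt, dp, ad) {
  ok <- !is.na(gt) & !is.na(dp) & !is.na(ad) & dp >= 1
  expected <- (gt[ok] / 2) * dp[ok]
  if (length(unique(expected)) < 2L) return(NA_real_)
  unname(coef(lm(ad[ok] ~ expected))[2])
}

## Tiny null cohort config used by several calibration tests.
null_cohort_config <- function(n_duos = 3000, carrier_freq = 0.005,
                               n_variants = 2, seed = 1) {
  duoSimConfig(n_duos,
               list(geneSimSpec("NULLGENE", n_variants = n_variants,
                                carrier_freq = carrier_freq)),
               seed = seed)
}
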