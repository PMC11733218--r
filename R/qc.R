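## Genotype-call and variant-level quality control.
##
## Pipeline order is fixed: call-level depth/quality filters, then the
## heterozygous allele-balance test, then variant missingness, then the
## optional AD~DP slope and AAscore filters (replication-cohort style),
## then the rare-variant MAF filter.  Every step logs
## (n_before, n_removed, n_after).

#' QC thresholds
#'
#' Default values: SNV calls need depth >= 7 and genotype quality >= 20
#' (indels: depth >= 10); heterozygous SNVs with a two-sided exact binomial
#' allele-balance p <= 1e-3 are set missing; variants with > 50\% missing
#' genotypes are dropped; the AD~DP slope filter (when enabled) drops
#' variants with slope < 0.5; the AAscore filter (when enabled) requires
#' AAscore > 0.8; the rare filter keeps MAF < 0.001.  All comparisons are
#' strict as stated.
#'
#' @param snv_min_depth,snv_min_gq,indel_min_depth,indel_min_gq call-level
#'   cutoffs (calls strictly below are set missing).
#' @param allele_balance_p_max het calls with binomial p at or below this
#'   are set missing.
#' @param variant_max_missing variants with missing fraction strictly above
#'   this are dropped.
#' @param adslope_min variants with AD~DP slope strictly below this are
#'   dropped (when the slope filter is on).
#' @param aascore_min variants need AAscore strictly above this (when the
#'   AAscore filter is on).
#' @param maf_max variants with MAF at or above this are dropped by the
#'   rare filter.
#' @return a \code{QcThresholds} list.
#' @export
qcThresholds <- function(snv_min_depth = 7, snv_min_gq = 20,
                         indel_min_depth = 10, indel_min_gq = 20,
                         allele_balance_p_max = 1e-3,
                         variant_max_missing = 0.5,
                         adslope_min = 0.5, aascore_min = 0.8,
                         maf_max = 0.001) {
  th <- as.list(environment())
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  if (maf_max >= 0.5) stop("maf_max must be below 0.5")
  structure(th, class = "QcThresholds")
}

#' Call-level depth / genotype-quality filter
#'
#' Sets a dosage missing iff (SNV and (DP < 7 or GQ < 20)) or (indel and
#' (DP < 10 or GQ < 20)); thresholds are strict "<", so DP = 7, GQ = 20
#' passes for an SNV.  Calls with missing DP or GQ are set missing.
#'
#' @param gt,dp,gq dosage / depth / quality vectors or matrices.
#' @param is_indel logical, recycled along rows for matrices.
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return the filtered dosage object.
#' @export
filterCalls <- function(gt, dp, gq, is_indel, thresholds = qcThresholds()) {
  min_dp <- ifelse(is_indel, thresholds$indel_min_depth,
                   thresholds$snv_min_depth)
  min_gq <- ifelse(is_indel, thresholds$indel_min_gq, thresholds$snv_min_gq)
  ## for matrices the length-V vectors recycle down columns
  fail <- is.na(dp) | is.na(gq) | dp < min_dp | gq < min_gq
  gt[fail & !is.na(gt)] <- NA_integer_
  gt
}

#' Heterozygous allele-balance binomial test
#'
#' Two-sided exact binomial probability of the observed alternate-read
#' count under Binomial(depth, 1/2), the expected 50/50 allele balance of a
#' true heterozygote.  Two-sidedness follows the minimum-likelihood
#' convention (sum of outcome probabilities no larger than the observed
#' one's), matching \code{\link[stats]{binom.test}}.  The test is symmetric:
#' p(k, n) = p(n - k, n).
#'
#' @param alt_reads,depth integer vectors; \code{depth} must be >= 1.
#' @param dosage optional; when supplied, every call must be heterozygous
#'   (dosage 1) or an error is raised.
#' @return vector of p-values.
#' @export
alleleBalanceTest <- function(alt_reads, depth, dosage = NULL) {
  if (!is.null(dosage) && any(dosage != 1L, na.rm = TRUE))
    stop("allele-balance test applies to heterozygous calls only")
  if (any(depth < 1, na.rm = TRUE))
    stop("allele-balance test needs depth >= 1")
  p <- rep(NA_real_, length(alt_reads))
  ok <- which(!is.na(alt_reads) & !is.na(depth))
  ## one pmf evaluation per distinct depth
  for (n in unique(depth[ok])) {
    i <- ok[depth[ok] == n]
    pmf <- dbinom(0:n, n, 0.5)
    p[i] <- vapply(alt_reads[i], function(k)
      min(1, sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-07)])), numeric(1))
  }
  p
}

#' Variant missingness filter
#'
#' @param gt dosage matrix (variants x samples), after call-level filters.
#' @param thresholds a \code{\link{qcThresholds}}.
#' @return logical vector: keep iff missing fraction <= 50\% (drop is
#'   strict ">").
#' @export
variantMissingness <- function(gt, thresholds = qcThresholds()) {
  if (ncol(gt) == 0L) stop("no samples")
  rowMeans(is.na(gt)) <= thresholds$variant_max_missing
}

#' AD~DP slope of a variant
#'
#' Regresses observed alternate-read counts on their genotype-expected
#' values (dosage/2 x depth) by ordinary least squares with intercept.  A
#' well-behaved variant has slope 1 (and intercept 0); spurious variants
#' fall toward 0, and the caller drops the variant iff slope < 0.5.  With a
#' degenerate design (all expected values equal) the slope is undefined and
#' \code{NA} is returned; such variants are flagged not-evaluable and
#' retained with a warning by \code{\link{runGenotypeQc}}.
#'
#' @param gt,dp,ad per-sample dosage, depth and alternate reads of one
#'   variant.
#' @return the OLS slope, or \code{NA} if not evaluable.
#' @export
adDpSlope <- function(gt, dp, ad) {
  ok <- !is.na(gt) & !is.na(dp) & !is.na(ad) & dp >= 1
  if (sum(ok) < 3L) return(NA_real_)
  expected <- (gt[ok] / 2) * dp[ok]
  if (length(unique(expected)) < 2L) return(NA_real_)
  x <- expected - mean(expected)
  sum(x * ad[ok]) / sum(x * x)
}

#' Minor allele frequency from post-QC dosages
#'
#' \code{maf = min(f, 1 - f)} with f the alternate-allele frequency among
#' non-missing dosages.  The rare filter keeps a variant iff
#' \code{maf < maf_max} (strict).
#'
#' @param gt dosage vector or matrix (variants x samples).
#' @return MAF per variant.
#' @export
computeMaf <- function(gt) {
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1L)
  n_obs <- rowSums(!is.na(gt))
  if (any(n_obs == 0L))
    stop("all-missing variant; run the missingness filter first")
  f <- rowSums(gt, na.rm = TRUE) / (2 * n_obs)
  pmin(f, 1 - f)
}

#' Run the genotype QC pipeline
#'
#' Applies, in order: call-level depth/GQ filters; the heterozygous-SNV
#' allele-balance filter; the variant missingness filter; optionally the
#' AD~DP slope and AAscore filters (replication-cohort style QC, off by
#' default); and optionally the rare-variant MAF filter.  MAF is computed
#' within the cohort after call-level QC and stored in \code{rowData}.
#'
#' @param calls a \linkS4class{GenotypeCalls} whose \code{rowData} has
#'   \code{is_indel} (and \code{aascore} if that filter is on).
#' @param thresholds a \code{\link{qcThresholds}}.
#' @param slope_filter,aascore_filter enable the replication-style variant
#'   filters.
#' @param rare_filter apply the MAF < 0.1\% restriction.
#' @return list with \code{calls} (filtered), \code{report} (per input
#'   variant: missingness, maf, slope, decision) and \code{log} (per step:
#'   n_before, n_removed, n_after; counts are calls for call-level steps and
#'   variants thereafter).
#' @export
runGenotypeQc <- function(calls, thresholds = qcThresholds(),
                          slope_filter = FALSE, aascore_filter = FALSE,
                          rare_filter = TRUE) {
  log <- .emptyLog()
  gt <- dosages(calls)
  dp <- readDepth(calls)
  gq <- genotypeQuality(calls)
  ad <- altReads(calls)
  vt <- variantTable(calls)
  is_indel <- if ("is_indel" %in% colnames(vt)) vt$is_indel else
    nchar(vt$ref) != 1L | nchar(vt$alt) != 1L

  n_calls <- sum(!is.na(gt))
  gt2 <- filterCalls(gt, dp, gq, is_indel, thresholds)
  log <- .logStep(log, "call_depth_gq", n_calls, n_calls - sum(!is.na(gt2)))

  ## allele balance: heterozygous SNV calls only (is_indel recycles)
  het <- which(!is.na(gt2) & gt2 == 1L & !is_indel &
                 !is.na(dp) & dp >= 1 & !is.na(ad))
  ab_p <- rep(NA_real_, length(gt2))
  if (length(het))
    ab_p[het] <- alleleBalanceTest(ad[het], dp[het])
  ab_fail <- which(!is.na(ab_p) & ab_p <= thresholds$allele_balance_p_max)
  n_before <- sum(!is.na(gt2))
  gt2[ab_fail] <- NA_integer_
  log <- .logStep(log, "allele_balance", n_before, length(ab_fail))

  report <- data.frame(variant_id = vt$variant_id,
                       missingness = rowMeans(is.na(gt2)),
                       maf = NA_real_, slope = NA_real_,
                       decision = "keep", stringsAsFactors = FALSE)

  keep <- variantMissingness(gt2, thresholds)
  report$decision[!keep] <- "drop_missingness"
  log <- .logStep(log, "variant_missingness", nrow(gt2), sum(!keep))

  if (slope_filter) {
    idx <- which(keep)
    slopes <- vapply(idx, function(i)
      adDpSlope(gt2[i, ], dp[i, ], ad[i, ]), numeric(1))
    report$slope[idx] <- slopes
    not_eval <- idx[is.na(slopes)]
    if (length(not_eval)) {
      warning(length(not_eval),
              " variant(s) not evaluable for the AD~DP slope; retained")
      report$decision[not_eval] <- "keep_slope_not_evaluable"
    }
    drop <- idx[!is.na(slopes) & slopes < thresholds$adslope_min]
    report$decision[drop] <- "drop_slope"
    keep[drop] <- FALSE
    log <- .logStep(log, "ad_dp_slope", length(idx), length(drop))
  }
  if (aascore_filter) {
    if (!"aascore" %in% colnames(vt))
      stop("AAscore filter requested but no aascore annotation")
    idx <- which(keep)
    drop <- idx[is.na(vt$aascore[idx]) |
                  vt$aascore[idx] <= thresholds$aascore_min]
    report$decision[drop] <- "drop_aascore"
    keep[drop] <- FALSE
    log <- .logStep(log, "aascore", length(idx), length(drop))
  }

  maf <- rep(NA_real_, nrow(gt2))
  maf[keep] <- computeMaf(gt2[keep, , drop = FALSE])
  report$maf <- maf
  if (rare_filter) {
    idx <- which(keep)
    drop <- idx[maf[idx] >= thresholds$maf_max]
    report$decision[drop] <- "drop_maf"
    keep[drop] <- FALSE
    log <- .logStep(log, "rare_maf", length(idx), length(drop))
  }

  out <- calls
  assay(out, "GT") <- gt2
  out <- out[keep, ]
  rowData(out)$maf <- maf[keep]
  list(calls = out, report = report, log = log)
}
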