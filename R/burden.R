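## Covariate-adjusted carrier burden association.

#' Fit one gene burden association
#'
#' Ordinary least squares of the standardised phenotype on the per-gene
#' carrier indicator plus covariates; the burden effect is the carrier
#' coefficient (SD units per carrier), with a two-sided p-value from the t
#' reference at residual degrees of freedom.  Samples with missing carrier
#' status, phenotype or covariates are dropped; genes with fewer than
#' \code{min_carriers} carriers among the fitted samples are flagged
#' excluded and not fitted.  Collinear covariate columns are dropped with a
#' warning.
#'
#' @param carrier integer 0/1/NA carrier vector.
#' @param bw_sd standardised phenotype, aligned to \code{carrier}.
#' @param covariates numeric covariate matrix (no intercept column), or
#'   \code{NULL}.
#' @param min_carriers reporting floor (default 10).
#' @return one-row data.frame: n, n_carriers, beta, se, p, excluded.
#' @export
burdenFit <- function(carrier, bw_sd, covariates = NULL,
                      min_carriers = 10L) {
  if (is.null(covariates))
    covariates <- matrix(numeric(0), length(carrier), 0)
  ok <- !is.na(carrier) & !is.na(bw_sd) &
    stats::complete.cases(covariates)
  n <- sum(ok)
  n_carr <- sum(carrier[ok] == 1L)
  if (n_carr < min_carriers)
    return(data.frame(n = n, n_carriers = n_carr, beta = NA_real_,
                      se = NA_real_, p = NA_real_, excluded = TRUE))
  X <- cbind(`(Intercept)` = 1, carrier = carrier[ok],
             covariates[ok, , drop = FALSE])
  fit <- .olsStats(X, bw_sd[ok])
  i <- match("carrier", fit$term)
  data.frame(n = n, n_carriers = n_carr, beta = fit$estimate[i],
             se = fit$se[i], p = fit$p[i], excluded = FALSE)
}

#' Exome-wide burden scan over carrier sets
#'
#' Fits every gene under every supplied mask, derives the Bonferroni
#' exome-wide threshold from the testable gene counts
#' (\code{\link{countTests}}), and flags significance at \code{p <
#' threshold} (strict).
#'
#' @param carrier_sets list of \code{\link{buildCarrierSets}} outputs, one
#'   per mask.
#' @param bw_sd named standardised phenotype vector (names = sample ids;
#'   samples outside the carrier matrices are ignored).
#' @param covariates covariate matrix with rownames = sample ids.
#' @param analysis,stratum labels recorded in the results.
#' @param min_carriers reporting floor.
#' @param threshold significance threshold; by default derived from the
#'   carrier sets themselves.
#' @return data.frame of burden results (one row per gene x mask) with a
#'   \code{significant} flag; the threshold is kept in
#'   \code{attr(, "threshold")}.
#' @export
exomewideScan <- function(carrier_sets, bw_sd, covariates = NULL,
                          analysis = "fetal", stratum = "all",
                          min_carriers = 10L, threshold = NULL) {
  if (is.null(threshold))
    threshold <- countTests(carrier_sets, min_carriers)$threshold
  rows <- list()
  for (cs in carrier_sets) {
    ids <- intersect(colnames(cs$carriers), names(bw_sd))
    Xc <- if (is.null(covariates)) NULL else
      covariates[ids, , drop = FALSE]
    for (g in rownames(cs$carriers)) {
      fit <- burdenFit(cs$carriers[g, ids], bw_sd[ids], Xc, min_carriers)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(gene = g, mask = cs$info$mask[1],
                         analysis = analysis, stratum = stratum), fit)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), mask = character(),
               analysis = character(), stratum = character(),
               n = integer(), n_carriers = integer(), beta = numeric(),
               se = numeric(), p = numeric(), excluded = logical())
  res$significant <- !is.na(res$p) & res$p < threshold
  attr(res, "threshold") <- threshold
  res
}

#' Benjamini-Hochberg scan of GWAS-proximal candidate genes
#'
#' Restricts a burden result table to genes proximal to GWAS signals (see
#' \code{\link{mapProximal}}) and applies the Benjamini-Hochberg step-up
#' procedure over the restricted set; discoveries are flagged at
#' \code{q <= 0.05}.
#'
#' @param results burden result data.frame with \code{gene} and \code{p}.
#' @param proximal_genes character vector of gene symbols within the
#'   proximity window.
#' @param fdr discovery level (default 0.05).
#' @return the restricted table with \code{q} and \code{discovery} columns
#'   (empty table if nothing is proximal).
#' @export
bhCandidateScan <- function(results, proximal_genes, fdr = 0.05) {
  res <- results[results$gene %in% proximal_genes & !is.na(results$p), ,
                 drop = FALSE]
  if (!nrow(res)) {
    res$q <- numeric(0)
    res$discovery <- logical(0)
    return(res)
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$discovery <- res$q <= fdr
  res
}

#' Conditional analysis on GWAS sentinel genotypes
#'
#' Residualises the phenotype on the covariates, then fits the residuals on
#' carrier status alone (marginal) and on carrier status plus the sentinel
#' dosages (conditional).  Attenuation is
#' \code{100 * (beta_marginal - beta_conditional) / beta_marginal};
#' the association is flagged attenuated iff |attenuation| > 10\%.
#'
#' @param carrier 0/1/NA carrier vector.
#' @param bw_sd standardised phenotype.
#' @param covariates covariate matrix or \code{NULL}.
#' @param sentinels matrix of sentinel dosages (samples x signals), aligned
#'   to \code{carrier}.
#' @return one-row data.frame: beta_marginal, beta_conditional,
#'   attenuation_pct, attenuated.
#' @export
conditionalFit <- function(carrier, bw_sd, covariates, sentinels) {
  sentinels <- as.matrix(sentinels)
  ok <- !is.na(carrier) & !is.na(bw_sd) &
    stats::complete.cases(sentinels) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  y <- bw_sd[ok]
  if (!is.null(covariates)) {
    Xc <- cbind(1, covariates[ok, , drop = FALSE])
    y <- y - Xc %*% qr.coef(qr(Xc), y)
  }
  car <- carrier[ok]
  if (length(unique(car)) < 2L)
    stop("carrier status is constant among the usable samples")
  bm <- .olsStats(cbind(1, carrier = car), y)
  bm <- bm$estimate[bm$term == "carrier"]
  Xs <- cbind(1, carrier = car, sentinels[ok, , drop = FALSE])
  bc <- .olsStats(Xs, y)
  if (!"carrier" %in% bc$term)
    stop("carrier collinear with the sentinel genotypes")
  bc <- bc$estimate[bc$term == "carrier"]
  if (bm == 0) {
    warning("marginal beta is zero; attenuation undefined")
    att <- NA_real_
  } else att <- 100 * (bm - bc) / bm
  data.frame(beta_marginal = bm, beta_conditional = bc,
             attenuation_pct = att,
             attenuated = !is.na(att) & abs(att) > 10)
}

#' Run a fetal or maternal burden analysis on a duo cohort
#'
#' End-to-end convenience wrapper: genotype QC (optional), phenotype
#' derivation and standardisation for the requested analysis panel
#' (children's own birth weight for fetal; mothers' offspring birth weight
#' for maternal), covariate construction, carrier collapsing under each
#' mask, and the exome-wide scan.
#'
#' @param cohort a \linkS4class{DuoCohort}.
#' @param analysis \code{"fetal"} or \code{"maternal"}.
#' @param masks list of \linkS4class{BurdenMask}.
#' @param stratum \code{"all"}, \code{"female"} or \code{"male"} (children
#'   only; the maternal panel is all-female).
#' @param qc run \code{\link{runGenotypeQc}} first (discovery-style
#'   flags: slope and AAscore filters off).
#' @param style phenotype derivation rules (see
#'   \code{\link{deriveBirthWeights}}).
#' @param min_carriers reporting floor.
#' @return burden result data.frame as from \code{\link{exomewideScan}}.
#' @export
runBurdenAnalysis <- function(cohort, analysis = c("fetal", "maternal"),
                              masks = defaultMasks(), stratum = "all",
                              qc = TRUE, style = "discovery",
                              min_carriers = 10L) {
  analysis <- match.arg(analysis)
  calls <- genotypeCalls(cohort)
  if (qc) calls <- runGenotypeQc(calls)$calls
  samples <- sampleTable(cohort)
  role <- if (analysis == "fetal") "child" else "mother"
  panel_ids <- rownames(colData(calls))[colData(calls)$role == role]
  panel <- samples[match(panel_ids, samples$sample_id), , drop = FALSE]
  if (analysis == "fetal" && stratum != "all")
    panel <- panel[panel$sex == stratum, , drop = FALSE]

  bw <- deriveBirthWeights(panel, analysis, style)
  bw_sd <- setNames(rep(NA_real_, nrow(bw)), bw$sample_id)
  obs <- !is.na(bw$bw_kg)
  bw_sd[obs] <- standardise(bw$bw_kg[obs])
  keep <- names(bw_sd)[obs]
  X <- buildCovariates(panel[match(keep, panel$sample_id), , drop = FALSE],
                       analysis, stratum)
  sets <- lapply(masks, function(m)
    buildCarrierSets(calls[, keep], m, min_carriers))
  exomewideScan(sets, bw_sd[keep], X, analysis = analysis,
                stratum = stratum, min_carriers = min_carriers)
}
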