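## Simulation studies validating the estimator properties end to end:
## parameter recovery of the WLM deconvolution, and null calibration of the
## burden and dimorphism tests.  Both are deterministic given a seed.

#' WLM parameter-recovery study
#'
#' Repeatedly simulates a fetal panel (children of \code{n_duos} duos
#' reporting their own birth weight) and an independent maternal panel (the
#' mothers of a second, disjoint set of \code{n_duos} duos reporting their
#' first child's birth weight), runs the marginal burden analyses through
#' the standard pipeline (phenotype derivation, standardisation, carrier
#' collapsing under the Missense+PTV mask, covariate-adjusted fit) and
#' applies \code{\link{wlmAdjust}}.  Under the transmission model the
#' marginal estimates converge to \code{beta_fetal + beta_maternal/2} and
#' \code{beta_maternal + beta_fetal/2}, while the adjusted estimates
#' recover the true effects.
#'
#' @param nrep number of replicate cohort pairs.
#' @param n_duos duos per panel.
#' @param carrier_freq aggregate carrier frequency of the causal gene.
#' @param n_variants qualifying variants in the causal gene.
#' @param beta_fetal,beta_maternal true effects (SD units).
#' @param seed integer seed for the whole study.
#' @param qc run genotype QC inside each replicate (slower; the QC filters
#'   are validated separately and barely touch clean simulated reads).
#' @return data.frame with one row per replicate: marginal and adjusted
#'   estimates and their standard errors.
#' @export
wlmRecoveryStudy <- function(nrep = 300, n_duos = 50000,
                             carrier_freq = 0.002, n_variants = 2,
                             beta_fetal = 0.4, beta_maternal = -0.2,
                             seed = 1, qc = FALSE) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, 2L * nrep)
  gene <- geneSimSpec("GENE1", n_variants = n_variants,
                      carrier_freq = carrier_freq,
                      beta_fetal = beta_fetal,
                      beta_maternal = beta_maternal)
  mask <- list(maskMissensePTV())
  out <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    cohA <- simulateDuos(duoSimConfig(n_duos, list(gene),
                                      seed = seeds[2L * r - 1L]))
    cohB <- simulateDuos(duoSimConfig(n_duos, list(gene),
                                      seed = seeds[2L * r]))
    fetal <- runBurdenAnalysis(cohA, "fetal", masks = mask, qc = qc)
    maternal <- runBurdenAnalysis(cohB, "maternal", masks = mask, qc = qc)
    adj <- wlmAdjustResults(fetal, maternal)
    out[[r]] <- data.frame(
      beta_fetal_marginal = adj$beta_fetal, se_fetal = adj$se_fetal,
      beta_maternal_marginal = adj$beta_maternal,
      se_maternal = adj$se_maternal,
      beta_fetal_adj = adj$beta_fetal_adj,
      beta_maternal_adj = adj$beta_maternal_adj)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- c(beta_fetal = beta_fetal,
                          beta_maternal = beta_maternal)
  res
}

#' Null calibration study of the burden and dimorphism tests
#'
#' Simulates replicate duo cohorts around a gene with no fetal or maternal
#' effect, fits the covariate-adjusted burden test in the children
#' (sex-combined and sex-stratified) and the summary-statistic dimorphism
#' test between the strata, and returns the per-replicate p-values.  Under
#' the null both should be uniform.
#'
#' @param nrep replicates.
#' @param n_duos duos per cohort.
#' @param carrier_freq aggregate carrier frequency of the null gene.
#' @param min_carriers carrier floor for the stratified fits; replicates
#'   where a stratum falls below it yield \code{NA} heterogeneity p.
#' @param seed integer seed.
#' @return data.frame with \code{p_burden} and \code{p_het} per replicate.
#' @export
nullCalibrationStudy <- function(nrep = 1000, n_duos = 6000,
                                 carrier_freq = 0.008, min_carriers = 10L,
                                 seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, nrep)
  gene <- geneSimSpec("NULLGENE", n_variants = 2,
                      carrier_freq = carrier_freq)
  p_burden <- p_het <- rep(NA_real_, nrep)
  for (r in seq_len(nrep)) {
    coh <- simulateDuos(duoSimConfig(n_duos, list(gene),
                                     seed = seeds[r]))
    calls <- genotypeCalls(coh)
    carrier <- metadata(calls)$carrier_child[1, ]
    z <- standardise(metadata(calls)$bw_kg)
    st <- sampleTable(coh)
    kids <- st[match(names(metadata(calls)$bw_kg), st$sample_id), ]
    X <- buildCovariates(kids, "fetal", "all")
    p_burden[r] <- burdenFit(carrier, z, X, min_carriers)$p
    fem <- kids$sex == "female"
    ff <- burdenFit(carrier[fem], z[fem],
                    buildCovariates(kids[fem, ], "fetal", "female"),
                    min_carriers)
    fm <- burdenFit(carrier[!fem], z[!fem],
                    buildCovariates(kids[!fem, ], "fetal", "male"),
                    min_carriers)
    if (!ff$excluded && !fm$excluded)
      p_het[r] <- dimorphismTest(ff$beta, ff$se, fm$beta, fm$se)$p_het
  }
  data.frame(p_burden = p_burden, p_het = p_het)
}
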