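## Weighted-linear-model deconvolution of marginal fetal and maternal
## burden estimates, dimorphism and direction-consistency tests.
##
## Structural model: with a mother-child genotype correlation of 0.5, the
## marginal estimates project the true conditional effects as
##   E[bF_hat] = bf + bm/2,   E[bM_hat] = bm + bf/2,
## so the inversion is bf_adj = (4 bF - 2 bM)/3, bm_adj = (4 bM - 2 bF)/3.

#' WLM adjustment of marginal fetal/maternal estimates
#'
#' Converts marginal fetal and maternal burden estimates into approximately
#' conditional ones under the r = 0.5 mother-child genotype correlation.
#' Variances propagate as \code{var(bf_adj) = (16 seF^2 + 4 seM^2 - 16
#' cov)/9} (and symmetrically), with \code{cov} the covariance between the
#' two marginal estimates -- zero for independent fetal and maternal
#' panels, the default.  Adjusted p-values are two-sided normal.
#'
#' @param beta_f,se_f marginal fetal estimate and SE.
#' @param beta_m,se_m marginal maternal estimate and SE.
#' @param overlap_cov covariance between the two marginal estimates
#'   (sample-overlap term; default 0).
#' @param alpha classification level (default 0.05).
#' @return data.frame with \code{beta_fetal_adj}, \code{se_fetal_adj},
#'   \code{p_fetal_adj}, the maternal counterparts, and a
#'   \code{classification} in \{fetal_only, maternal_only, both,
#'   unclassified\} (p < alpha on the adjusted estimates).
#' @examples
#' wlmAdjust(0.3, 0.06, 0.15, 0.06)  # pure fetal marginal projection
#' @export
wlmAdjust <- function(beta_f, se_f, beta_m, se_m, overlap_cov = 0,
                      alpha = 0.05) {
  stopifnot(all(se_f > 0), all(se_m > 0),
            all(is.finite(c(beta_f, beta_m))))
  bf_adj <- (4 * beta_f - 2 * beta_m) / 3
  bm_adj <- (4 * beta_m - 2 * beta_f) / 3
  vf <- (16 * se_f^2 + 4 * se_m^2 - 16 * overlap_cov) / 9
  vm <- (16 * se_m^2 + 4 * se_f^2 - 16 * overlap_cov) / 9
  if (any(vf <= 0) || any(vm <= 0))
    stop("overlap_cov yields non-positive adjusted variance")
  se_fa <- sqrt(vf)
  se_ma <- sqrt(vm)
  p_fa <- 2 * pnorm(-abs(bf_adj / se_fa))
  p_ma <- 2 * pnorm(-abs(bm_adj / se_ma))
  data.frame(beta_fetal_adj = bf_adj, se_fetal_adj = se_fa,
             p_fetal_adj = p_fa, beta_maternal_adj = bm_adj,
             se_maternal_adj = se_ma, p_maternal_adj = p_ma,
             classification = classifyWlm(p_fa, p_ma, alpha))
}

#' Classify a gene from adjusted p-values
#'
#' \code{fetal_only} iff the adjusted fetal p < alpha and the adjusted
#' maternal p >= alpha; \code{maternal_only} symmetrically; \code{both}
#' iff both are below alpha; \code{unclassified} otherwise.
#'
#' @param p_fetal_adj,p_maternal_adj adjusted p-values.
#' @param alpha level (default 0.05).
#' @return character vector of classifications.
#' @export
classifyWlm <- function(p_fetal_adj, p_maternal_adj, alpha = 0.05) {
  f <- p_fetal_adj < alpha
  m <- p_maternal_adj < alpha
  ifelse(f & m, "both",
         ifelse(f, "fetal_only",
                ifelse(m, "maternal_only", "unclassified")))
}

#' Sexual-dimorphism test from sex-stratified estimates
#'
#' Two-sample comparison of female and male effect estimates on summary
#' statistics: \code{z = (bF - bM) / sqrt(seF^2 + seM^2)}, two-sided p from
#' the normal reference (the large-sample form of the two-sample t-test).
#' Dimorphic iff p < 0.05.
#'
#' @param beta_female,se_female,beta_male,se_male stratified estimates.
#' @return data.frame with \code{p_het} and \code{dimorphic}.
#' @export
dimorphismTest <- function(beta_female, se_female, beta_male, se_male) {
  stopifnot(all(se_female > 0), all(se_male > 0))
  z <- (beta_female - beta_male) / sqrt(se_female^2 + se_male^2)
  p <- 2 * pnorm(-abs(z))
  data.frame(beta_female = beta_female, se_female = se_female,
             beta_male = beta_male, se_male = se_male,
             p_het = p, dimorphic = p < 0.05)
}

#' Exact sign test of directional consistency
#'
#' Two-sided exact binomial test of k direction-concordant effects out of
#' n at probability 1/2 (minimum-likelihood two-sided convention, as
#' \code{\link[stats]{binom.test}}).
#'
#' @param k number of concordant pairs.
#' @param n number of pairs.
#' @return the p-value.
#' @examples
#' signTest(10, 11)  # 0.0117
#' @export
signTest <- function(k, n) {
  if (n == 0) stop("sign test needs n >= 1")
  stopifnot(k >= 0, k <= n)
  stats::binom.test(k, n, p = 0.5)$p.value
}

#' WLM-adjust a pair of marginal result tables
#'
#' Joins fetal and maternal burden results by gene and mask and applies
#' \code{\link{wlmAdjust}} row-wise.
#'
#' @param fetal,maternal burden result data.frames (columns gene, mask,
#'   beta, se).
#' @param overlap_cov,alpha passed to \code{\link{wlmAdjust}}.
#' @return merged data.frame with marginal and adjusted columns.
#' @export
wlmAdjustResults <- function(fetal, maternal, overlap_cov = 0,
                             alpha = 0.05) {
  ## unfitted rows (carrier floor not met) cannot be adjusted
  fetal <- fetal[!is.na(fetal$se), , drop = FALSE]
  maternal <- maternal[!is.na(maternal$se), , drop = FALSE]
  merged <- merge(fetal[, c("gene", "mask", "n_carriers", "beta", "se")],
                  maternal[, c("gene", "mask", "beta", "se")],
                  by = c("gene", "mask"),
                  suffixes = c("_fetal", "_maternal"))
  if (!nrow(merged)) stop("no gene x mask keys in common")
  cbind(merged, wlmAdjust(merged$beta_fetal, merged$se_fetal,
                          merged$beta_maternal, merged$se_maternal,
                          overlap_cov, alpha))
}
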