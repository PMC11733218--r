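#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

## Required assays of a GenotypeCalls object, in canonical order.
.REQUIRED_ASSAYS <- c("GT", "DP", "GQ", "AD")

.CONSEQUENCE_LEVELS <- c("PTV", "missense", "synonymous", "inframe", "other")
.CLINICAL_LEVELS <- c("pathogenic", "likely_pathogenic", "vus", "benign")

#' GenotypeCalls: per-sample genotype calls with read-level evidence
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one row per
#' biallelic variant and one column per sample, with four integer assays:
#' \describe{
#'   \item{GT}{allele dosage 0/1/2, \code{NA} = missing call}
#'   \item{DP}{total read depth}
#'   \item{GQ}{genotype quality}
#'   \item{AD}{alternate-allele read count, \code{AD <= DP}}
#' }
#' \code{rowData} carries the variant annotations (see
#' \code{\link{variantTable}}): \code{variant_id} ("chrom:pos:ref:alt"),
#' \code{gene}, \code{consequence_class} (one of PTV, missense, synonymous,
#' inframe, other), \code{loftee_high_confidence}, \code{cadd}, and the
#' optional \code{miter}, \code{aascore}, \code{clinical_class}, \code{maf}
#' columns. Positions are 1-based throughout.
#'
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  msg <- character()
  missing_assays <- setdiff(.REQUIRED_ASSAYS, assayNames(object))
  if (length(missing_assays))
    msg <- c(msg, paste0("missing assay(s): ",
                         paste(missing_assays, collapse = ", ")))
  if (!length(msg)) {
    ad <- assay(object, "AD")
    dp <- assay(object, "DP")
    bad <- !is.na(ad) & !is.na(dp) & ad > dp
    if (any(bad))
      msg <- c(msg, "AD exceeds DP for some calls")
    gt <- assay(object, "GT")
    if (length(gt) && !all(is.na(gt))) {
      rng <- range(gt, na.rm = TRUE)
      if (rng[1] < 0L || rng[2] > 2L)
        msg <- c(msg, "GT must be 0, 1, 2 or NA")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCalls object
#'
#' @param GT,DP,GQ,AD integer matrices, variants x samples. \code{GT} is the
#'   allele dosage (0/1/2, \code{NA} missing); \code{AD} is the
#'   alternate-allele read count.
#' @param variants \code{DataFrame} or data.frame of per-variant annotations
#'   (one row per row of \code{GT}).
#' @param samples optional \code{DataFrame} of per-column metadata.
#' @return a \linkS4class{GenotypeCalls} object.
#' @examples
#' gt <- matrix(c(0L, 1L), 1, 2, dimnames = list("1:100:A:T", c("s1", "s2")))
#' gc <- GenotypeCalls(gt, gt + 19L, gt * 0L + 50L, gt * 10L,
#'                     variants = data.frame(variant_id = "1:100:A:T"))
#' dosages(gc)
#' @export
GenotypeCalls <- function(GT, DP, GQ, AD, variants = NULL, samples = NULL) {
  storage.mode(GT) <- "integer"
  storage.mode(DP) <- "integer"
  storage.mode(GQ) <- "integer"
  storage.mode(AD) <- "integer"
  se <- SummarizedExperiment(
    assays = SimpleList(GT = GT, DP = DP, GQ = GQ, AD = AD))
  if (!is.null(variants)) rowData(se) <- DataFrame(variants)
  if (!is.null(samples)) colData(se) <- DataFrame(samples,
                                                  row.names = colnames(GT))
  new("GenotypeCalls", se)
}

#' DuoCohort: a simulated mother-child cohort with known truth
#'
#' Container for the output of \code{\link{simulateDuos}}: read-level
#' genotype calls for mothers and children (\code{calls}), the phenotype and
#' covariate table (\code{samples}; one row per individual, birth-weight
#' reports encoded as in \code{\link{readPhenotypes}}), and the \code{truth}
#' table of true per-gene fetal and maternal effects (SD units).
#'
#' @slot calls a \linkS4class{GenotypeCalls}; \code{colData} columns
#'   \code{role} ("mother"/"child") and \code{duo_id} link the pairs.
#' @slot samples data.frame of sample records.
#' @slot truth data.frame with columns \code{gene}, \code{beta_fetal},
#'   \code{beta_maternal}, \code{carrier_freq}.
#' @export
setClass("DuoCohort",
         representation(calls = "GenotypeCalls",
                        samples = "data.frame",
                        truth = "data.frame"))

setValidity("DuoCohort", function(object) {
  msg <- character()
  cd <- colData(object@calls)
  if (!all(c("role", "duo_id") %in% colnames(cd)))
    msg <- c(msg, "calls colData must have 'role' and 'duo_id'")
  if (!all(object@samples$sample_id %in% rownames(cd)))
    msg <- c(msg, "sample table contains ids absent from the calls")
  if (!all(c("gene", "beta_fetal", "beta_maternal") %in%
           colnames(object@truth)))
    msg <- c(msg, "truth table must have gene, beta_fetal, beta_maternal")
  if (length(msg)) msg else TRUE
})

#' BurdenMask: a variant collapsing mask
#'
#' A qualifying rule for rare variants entering a per-gene carrier burden.
#' A variant qualifies if it is not explicitly excluded and satisfies at
#' least one active criterion:
#' \itemize{
#'   \item \code{includePtv}: consequence class PTV flagged high-confidence;
#'   \item \code{caddMin}: CADD score at or above the cutoff for a
#'     consequence class in \code{caddClasses} (default missense; the
#'     REGENIE-style variant also admits inframe indels);
#'   \item \code{miterMax}: missense with experimental MITER score at or
#'     below the cutoff (lipodystrophy-level is <= -2);
#'   \item \code{clinicalClasses}: clinical classification in the given set.
#' }
#' @export
setClass("BurdenMask",
         representation(name = "character",
                        includePtv = "logical",
                        caddMin = "numeric",
                        caddClasses = "character",
                        miterMax = "numeric",
                        clinicalClasses = "character",
                        excludedVariants = "character"))

setValidity("BurdenMask", function(object) {
  active <- object@includePtv || length(object@caddMin) ||
    length(object@miterMax) || length(object@clinicalClasses)
  if (!active)
    return("mask has no active inclusion criterion")
  if (length(object@clinicalClasses) &&
      !all(object@clinicalClasses %in% .CLINICAL_LEVELS))
    return("unknown clinical class")
  TRUE
})

#' @param name mask label used in result tables.
#' @param includePtv include high-confidence protein-truncating variants.
#' @param caddMin CADD cutoff (inclusive, \code{>=}) or \code{NULL}.
#' @param caddClasses consequence classes eligible under the CADD criterion.
#' @param miterMax MITER cutoff (inclusive, \code{<=}) or \code{NULL}.
#' @param clinicalClasses clinical classes admitted, or \code{NULL}.
#' @param excludedVariants variant ids excluded (leave-one-out support).
#' @rdname BurdenMask-class
#' @examples
#' maskPTV()
#' maskMissensePTV()
#' burdenMask("GCK_pathogenic", includePtv = FALSE,
#'            clinicalClasses = c("pathogenic", "likely_pathogenic"))
#' @export
burdenMask <- function(name, includePtv = TRUE, caddMin = NULL,
                       caddClasses = "missense", miterMax = NULL,
                       clinicalClasses = NULL,
                       excludedVariants = character()) {
  new("BurdenMask", name = name, includePtv = includePtv,
      caddMin = as.numeric(caddMin), caddClasses = caddClasses,
      miterMax = as.numeric(miterMax),
      clinicalClasses = as.character(clinicalClasses),
      excludedVariants = excludedVariants)
}

#' @rdname BurdenMask-class
#' @export
maskPTV <- function(excludedVariants = character()) {
  burdenMask("PTV", includePtv = TRUE, excludedVariants = excludedVariants)
}

#' @rdname BurdenMask-class
#' @export
maskMissensePTV <- function(excludedVariants = character()) {
  burdenMask("MissensePTV", includePtv = TRUE, caddMin = 25,
             excludedVariants = excludedVariants)
}

#' @rdname BurdenMask-class
#' @export
maskRegenieMissensePTV <- function(excludedVariants = character()) {
  burdenMask("MissensePTV_inframe", includePtv = TRUE, caddMin = 25,
             caddClasses = c("missense", "inframe"),
             excludedVariants = excludedVariants)
}

#' Default discovery masks: PTV and Missense+PTV (CADD >= 25)
#' @return list of \linkS4class{BurdenMask}
#' @export
defaultMasks <- function() list(maskPTV(), maskMissensePTV())
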