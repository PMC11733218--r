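## Variant collapsing masks and per-gene carrier "dummy genotypes".

#' Which variants qualify under a mask?
#'
#' A variant qualifies iff it is not in the mask's exclusion list and
#' satisfies at least one active criterion: high-confidence PTV (when
#' \code{includePtv}); a consequence class in \code{caddClasses} with
#' CADD >= \code{caddMin} (inclusive); missense with MITER <=
#' \code{miterMax} (inclusive); or a clinical class in
#' \code{clinicalClasses}.  Missing annotation fields never qualify.
#'
#' @param variants data.frame of variant annotations
#'   (\code{\link{variantTable}}).
#' @param mask a \linkS4class{BurdenMask}.
#' @return logical vector along the rows of \code{variants}.
#' @export
qualifyVariants <- function(variants, mask) {
  cls <- variants$consequence_class
  q <- rep(FALSE, nrow(variants))
  if (mask@includePtv)
    q <- q | (!is.na(cls) & cls == "PTV" &
                !is.na(variants$loftee_high_confidence) &
                variants$loftee_high_confidence)
  if (length(mask@caddMin))
    q <- q | (!is.na(cls) & cls %in% mask@caddClasses &
                !is.na(variants$cadd) & variants$cadd >= mask@caddMin)
  if (length(mask@miterMax) && "miter" %in% colnames(variants))
    q <- q | (!is.na(cls) & cls == "missense" &
                !is.na(variants$miter) & variants$miter <= mask@miterMax)
  if (length(mask@clinicalClasses) &&
      "clinical_class" %in% colnames(variants))
    q <- q | (!is.na(variants$clinical_class) &
                variants$clinical_class %in% mask@clinicalClasses)
  q & !(variants$variant_id %in% mask@excludedVariants)
}

#' Collapse qualifying variants to a carrier indicator
#'
#' Per sample over the qualifying variants of one gene: carrier 1 iff any
#' dosage >= 1; carrier 0 iff at least one dosage is observed and all
#' observed dosages are 0; missing iff every qualifying dosage is missing.
#' Observed non-carrier evidence thus dominates partial missingness.
#'
#' @param gt dosage matrix (qualifying variants x samples) with >= 1 row.
#' @return integer vector of per-sample carrier status (0/1/NA).
#' @export
collapseCarriers <- function(gt) {
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1L)
  if (nrow(gt) == 0L) stop("no qualifying variants")
  any_carr <- colSums(gt >= 1L, na.rm = TRUE) > 0L
  any_obs <- colSums(!is.na(gt)) > 0L
  out <- rep(NA_integer_, ncol(gt))
  out[any_obs] <- 0L
  out[any_carr] <- 1L
  if (!is.null(colnames(gt))) names(out) <- colnames(gt)
  out
}

#' Build per-gene carrier sets under a mask
#'
#' @param calls a \linkS4class{GenotypeCalls} (post-QC).
#' @param mask a \linkS4class{BurdenMask}.
#' @param min_carriers genes with fewer carriers are flagged excluded
#'   (default 10, the reporting floor).
#' @return list with \code{carriers} (genes x samples integer matrix),
#'   \code{info} (data.frame gene, mask, n_carriers, excluded) and
#'   \code{qualifying} (named list of qualifying variant ids per gene).
#'   Genes with no qualifying variant are omitted.
#' @export
buildCarrierSets <- function(calls, mask, min_carriers = 10L) {
  vt <- variantTable(calls)
  q <- qualifyVariants(vt, mask)
  genes <- unique(vt$gene[q])
  genes <- genes[!is.na(genes)]
  gt <- dosages(calls)
  carriers <- matrix(NA_integer_, length(genes), ncol(gt),
                     dimnames = list(genes, colnames(gt)))
  qual_ids <- vector("list", length(genes))
  names(qual_ids) <- genes
  for (g in genes) {
    rows <- which(q & vt$gene == g)
    carriers[g, ] <- collapseCarriers(gt[rows, , drop = FALSE])
    qual_ids[[g]] <- vt$variant_id[rows]
  }
  n_carr <- as.integer(rowSums(carriers == 1L, na.rm = TRUE))
  list(carriers = carriers,
       info = data.frame(gene = genes, mask = maskName(mask),
                         n_carriers = n_carr,
                         excluded = n_carr < min_carriers),
       qualifying = qual_ids)
}

#' Exome-wide Bonferroni threshold from testable gene counts
#'
#' \code{0.05 / sum(counts)}, where each count is the number of genes with
#' at least \code{min_carriers} carriers under one mask.  With the study's
#' discovery counts, \code{exomeWideThreshold(c(16735, 13684))} gives
#' 1.64e-6 and \code{exomeWideThreshold(c(17745, 13968))} gives 1.58e-6.
#'
#' @param counts_per_mask integer vector of testable gene counts, one per
#'   mask.
#' @param alpha family-wise level (default 0.05).
#' @return the significance threshold.
#' @export
exomeWideThreshold <- function(counts_per_mask, alpha = 0.05) {
  total <- sum(counts_per_mask)
  if (total <= 0) stop("no testable genes")
  alpha / total
}

#' Count testable genes across masks and derive the threshold
#'
#' @param carrier_sets list of \code{\link{buildCarrierSets}} outputs (one
#'   per mask).
#' @param min_carriers carrier floor for testability.
#' @param alpha family-wise level.
#' @return list with per-mask \code{counts} and the Bonferroni
#'   \code{threshold}.
#' @export
countTests <- function(carrier_sets, min_carriers = 10L, alpha = 0.05) {
  counts <- vapply(carrier_sets, function(cs)
    sum(cs$info$n_carriers >= min_carriers), integer(1))
  names(counts) <- vapply(carrier_sets, function(cs)
    cs$info$mask[1], character(1))
  list(counts = counts,
       threshold = exomeWideThreshold(counts, alpha))
}
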