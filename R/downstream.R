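## GWAS-signal proximity mapping and replication bookkeeping.

#' Map GWAS signals to proximal genes
#'
#' A signal is proximal to a gene iff it lies on the same chromosome within
#' the closed interval \code{[start - window, end + window]} (1-based
#' inclusive coordinates; 300 kb by default).  Distance is 0 when the
#' signal falls inside the gene span, otherwise
#' \code{max(start - pos, pos - end)}.  \code{is_nearest_gene} flags, per
#' signal, the gene(s) at minimal distance among all supplied genes.
#' Candidate pairs are found with \code{GenomicRanges::findOverlaps}.
#'
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @param signals data.frame with \code{signal_id}, \code{chrom},
#'   \code{pos}.
#' @param window proximity window in bp (default 300000; must be > 0).
#' @return data.frame of hits: gene, signal_id, distance,
#'   is_nearest_gene.
#' @export
mapProximal <- function(genes, signals, window = 300000L) {
  if (window <= 0) stop("window must be positive")
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  sig_gr <- GenomicRanges::GRanges(
    signals$chrom, IRanges::IRanges(signals$pos, width = 1L))
  cand <- GenomicRanges::findOverlaps(sig_gr, gene_gr,
                                      maxgap = as.integer(window))
  si <- S4Vectors::queryHits(cand)
  gi <- S4Vectors::subjectHits(cand)
  dist <- pmax(0L, genes$start[gi] - signals$pos[si],
               signals$pos[si] - genes$end[gi])
  keep <- dist <= window
  si <- si[keep]; gi <- gi[keep]; dist <- dist[keep]

  ## nearest gene per signal over all supplied genes (any distance)
  nearest <- vapply(seq_len(nrow(signals)), function(i) {
    same <- which(genes$chrom == signals$chrom[i])
    if (!length(same)) return(NA_real_)
    min(pmax(0L, genes$start[same] - signals$pos[i],
             signals$pos[i] - genes$end[same]))
  }, numeric(1))

  out <- data.frame(gene = genes$gene[gi],
                    signal_id = signals$signal_id[si],
                    distance = dist,
                    is_nearest_gene = dist == nearest[si])
  out[order(out$signal_id, out$distance, out$gene), , drop = FALSE]
}

#' Direction concordance between discovery and replication results
#'
#' Joins two burden result tables by gene and mask, counts pairs whose
#' effect estimates agree in sign, and summarises directional consistency
#' with the exact \code{\link{signTest}}.  Pairs with a beta of exactly
#' zero carry no direction and are dropped from the count with a warning.
#'
#' @param discovery,replication burden result data.frames (gene, mask,
#'   beta).
#' @return list with \code{table} (per-pair concordance), \code{k}
#'   concordant, \code{n} counted pairs, and the sign-test \code{p}.
#' @export
replicationTable <- function(discovery, replication) {
  merged <- merge(discovery[, c("gene", "mask", "beta")],
                  replication[, c("gene", "mask", "beta")],
                  by = c("gene", "mask"),
                  suffixes = c("_discovery", "_replication"))
  if (!nrow(merged)) stop("no gene x mask keys in common")
  zero <- merged$beta_discovery == 0 | merged$beta_replication == 0
  if (any(zero))
    warning(sum(zero), " pair(s) with beta exactly 0 dropped from the ",
            "sign test")
  merged$concordant <- ifelse(zero, NA,
                              sign(merged$beta_discovery) ==
                                sign(merged$beta_replication))
  k <- sum(merged$concordant, na.rm = TRUE)
  n <- sum(!is.na(merged$concordant))
  list(table = merged, k = k, n = n,
       p = if (n > 0) signTest(k, n) else NA_real_)
}
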