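## Readers/writers for the external formats: VCF (via vcfR),
## and TSV tables for annotations, phenotypes, GWAS signals, genes, results.

#' Read genotype calls from a VCF file
#'
#' Reads a biallelic VCF v4.2 (multiallelics pre-split and left-normalised)
#' whose FORMAT carries GT, DP, GQ and AD, and returns a
#' \linkS4class{GenotypeCalls} object.  Parsing is done with
#' \pkg{vcfR}, which handles cohort-scale sample counts.  Any genotype
#' other than 0/0, 0/1, 1/0 or 1/1 (phased or unphased) maps to missing.
#' The AD field is taken as the alternate-allele read count: for the
#' standard comma-separated per-allele form the last (alternate) entry is
#' used; a single integer is used directly.
#'
#' @param path path to a VCF file.
#' @param sample_subset optional character vector of sample names to keep.
#' @return a \linkS4class{GenotypeCalls}; \code{rowData} holds
#'   \code{variant_id}, \code{chrom}, \code{pos} (1-based), \code{ref},
#'   \code{alt} and \code{is_indel}.
#' @export
readCohortVcf <- function(path, sample_subset = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  fmt <- unique(unlist(strsplit(unname(vcf@gt[, "FORMAT"]), ":",
                                fixed = TRUE)))
  needed <- c("GT", "DP", "GQ", "AD")
  if (!all(needed %in% fmt))
    stop("VCF FORMAT must provide GT, DP, GQ and AD; missing: ",
         paste(setdiff(needed, fmt), collapse = ", "))
  alts <- unname(fix[, "ALT"])
  if (any(grepl(",", alts, fixed = TRUE)))
    stop("multiallelic record(s) found; split multiallelics first")
  chrom <- unname(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  refs <- unname(fix[, "REF"])
  vid <- paste(chrom, pos, refs, alts, sep = ":")

  gt_chr <- vcfR::extract.gt(vcf, "GT")
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
               dimnames = dimnames(gt_chr))
  gt[gt_chr %in% c("0/0", "0|0")] <- 0L
  gt[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_chr %in% c("1/1", "1|1")] <- 2L

  int_assay <- function(key) {
    m <- vcfR::extract.gt(vcf, key)
    storage.mode(m) <- "integer"
    m
  }
  ad_chr <- vcfR::extract.gt(vcf, "AD")
  ## comma-separated per-allele AD: keep the final (alternate) entry
  ad <- matrix(as.integer(sub(".*,", "", ad_chr)), nrow(ad_chr),
               dimnames = dimnames(ad_chr))

  calls <- GenotypeCalls(
    GT = gt, DP = int_assay("DP"), GQ = int_assay("GQ"), AD = ad,
    variants = DataFrame(variant_id = vid, chrom = chrom, pos = pos,
                         ref = refs, alt = alts,
                         is_indel = nchar(refs) != 1L | nchar(alts) != 1L))
  rownames(calls) <- vid
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, colnames(calls))
    if (length(missing_s))
      stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "))
    calls <- calls[, sample_subset]
  }
  calls
}

#' Read a variant annotation table
#'
#' TSV with header; one row per \code{variant_id}.  Recognised columns:
#' \code{variant_id}, \code{gene}, \code{consequence_class} (PTV, missense,
#' synonymous, inframe, other), \code{loftee_high_confidence} (logical or
#' HC/LC), \code{cadd}, and optional \code{miter}, \code{aascore},
#' \code{clinical_class}, \code{gnomad_ac}.  Missing optional columns (or
#' empty cells) yield \code{NA} fields.
#'
#' @param path TSV path.
#' @return data.frame keyed by \code{variant_id}.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  req <- c("variant_id", "gene", "consequence_class")
  if (!all(req %in% colnames(ann)))
    stop("annotation table must have columns: ",
         paste(req, collapse = ", "))
  if (anyDuplicated(ann$variant_id))
    stop("duplicate variant_id in annotation table: ",
         paste(unique(ann$variant_id[duplicated(ann$variant_id)]),
               collapse = ", "))
  bad <- !is.na(ann$consequence_class) &
    !ann$consequence_class %in% .CONSEQUENCE_LEVELS
  if (any(bad))
    stop("unknown consequence_class: ",
         paste(unique(ann$consequence_class[bad]), collapse = ", "))
  if ("loftee_high_confidence" %in% colnames(ann) &&
      !is.logical(ann$loftee_high_confidence))
    ann$loftee_high_confidence <- ann$loftee_high_confidence %in%
      c("HC", "TRUE", "true", "1")
  for (col in c("cadd", "miter", "aascore")) {
    if (!col %in% colnames(ann)) {
      ann[[col]] <- NA_real_
    } else if (!is.numeric(ann[[col]])) {
      suppressWarnings(num <- as.numeric(ann[[col]]))
      if (any(is.na(num) & !is.na(ann[[col]])))
        stop("non-numeric ", col, " value(s) in annotation table")
      ann[[col]] <- num
    }
  }
  if (!"loftee_high_confidence" %in% colnames(ann))
    ann$loftee_high_confidence <- NA
  if (!"clinical_class" %in% colnames(ann))
    ann$clinical_class <- NA_character_
  ann
}

#' Attach annotations to genotype calls
#'
#' Joins an annotation table onto the \code{rowData} of a
#' \linkS4class{GenotypeCalls} by \code{variant_id}.  Annotation rows whose
#' variant id is absent from the calls are dropped with a logged count;
#' variants without an annotation row keep \code{NA} annotation fields.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param annotations data.frame from \code{\link{readAnnotations}}.
#' @return the annotated \linkS4class{GenotypeCalls}.
#' @export
annotateVariants <- function(calls, annotations) {
  vid <- rowData(calls)$variant_id
  unknown <- !annotations$variant_id %in% vid
  if (any(unknown)) {
    message(sum(unknown),
            " annotation row(s) with unknown variant_id dropped")
    annotations <- annotations[!unknown, , drop = FALSE]
  }
  idx <- match(vid, annotations$variant_id)
  keep <- setdiff(colnames(annotations), "variant_id")
  for (col in keep)
    rowData(calls)[[col]] <- annotations[[col]][idx]
  calls
}

## ---- phenotype tables -----------------------------------------------------

## Birth-weight report lists are encoded as semicolon-separated entries,
## "value:unit:visit" for own reports and "value:unit:source" for offspring
## reports, e.g. "3.2:kg:1;3.4:kg:2".  Empty string = no reports.
.encodeReports <- function(reports, id_order, tag_col) {
  if (!nrow(reports)) return(rep("", length(id_order)))
  f <- factor(reports$sample_id, levels = id_order)
  o <- order(f)
  enc <- sprintf("%.6g:%s:%s", reports$value[o], reports$unit[o],
                 as.character(reports[[tag_col]][o]))
  fo <- as.integer(f[o])
  counts <- tabulate(fo, nbins = length(id_order))
  m <- matrix(NA_character_, length(id_order), max(counts))
  m[cbind(fo, sequence(counts[counts > 0L]))] <- enc
  out <- m[, 1L]
  out[is.na(out)] <- ""
  for (k in seq_len(ncol(m))[-1L]) {
    has <- !is.na(m[, k])
    out[has] <- paste(out[has], m[has, k], sep = ";")
  }
  out
}

.decodeReports <- function(encoded, sample_ids, tag_col) {
  nz <- which(!is.na(encoded) & nzchar(encoded))
  if (!length(nz)) {
    out <- data.frame(sample_id = character(), value = numeric(),
                      unit = character(), tag = character())
    names(out)[4] <- tag_col
    return(out)
  }
  parts <- strsplit(encoded[nz], ";", fixed = TRUE)
  n_rep <- lengths(parts)
  fields <- strsplit(unlist(parts), ":", fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop("malformed report entry; expected value:unit:",
         if (tag_col == "visit") "visit" else "source")
  fm <- matrix(unlist(fields), nrow = 3L)
  out <- data.frame(
    sample_id = rep(sample_ids[nz], n_rep),
    value = as.numeric(fm[1L, ]),
    unit = fm[2L, ],
    tag = fm[3L, ])
  names(out)[4] <- tag_col
  out
}

#' Read a phenotype/covariate table
#'
#' TSV schema (one row per sample): \code{sample_id}, \code{sex}
#' (female/male), \code{age}, \code{year_of_birth}, \code{pc1}..\code{pc10},
#' \code{wes_batch}, \code{multiple_birth} (logical), optional
#' \code{mothers_diabetes}, \code{age_first_birth}, and the encoded report
#' columns \code{own_bw_reports} ("value:unit:visit" entries separated by
#' ";") and \code{offspring_bw_reports} ("value:unit:source", source
#' hospital or self_report).  Values are stored as reported; pound-unit
#' entries are converted at derivation time, not at read time.
#'
#' @param path TSV path.
#' @return data.frame of sample records.
#' @seealso \code{\link{bwReports}} to expand the encoded report columns.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA"))
  req <- c("sample_id", "sex", "multiple_birth")
  if (!all(req %in% colnames(ph)))
    stop("phenotype table must have columns: ", paste(req, collapse = ", "))
  if (!all(ph$sex %in% c("female", "male")))
    stop("unknown sex code: ",
         paste(unique(setdiff(ph$sex, c("female", "male"))), collapse = ", "))
  for (col in c("own_bw_reports", "offspring_bw_reports")) {
    if (!col %in% colnames(ph)) ph[[col]] <- ""
    ph[[col]][is.na(ph[[col]])] <- ""
    vals <- .decodeReports(ph[[col]], ph$sample_id, "tag")$value
    if (any(!is.na(vals) & vals <= 0))
      stop("non-positive birth weight report in ", col)
  }
  ph
}

#' @rdname readPhenotypes
#' @param samples data.frame of sample records.
#' @export
writePhenotypes <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expand encoded birth-weight report columns to a long table
#'
#' @param samples data.frame of sample records.
#' @param type \code{"own"} (value:unit:visit) or \code{"offspring"}
#'   (value:unit:source).
#' @return long data.frame with one row per report.
#' @export
bwReports <- function(samples, type = c("own", "offspring")) {
  type <- match.arg(type)
  if (type == "own")
    .decodeReports(samples$own_bw_reports, samples$sample_id, "visit")
  else
    .decodeReports(samples$offspring_bw_reports, samples$sample_id, "source")
}

## ---- results tables -------------------------------------------------------

.RESULT_CORE <- c("gene", "mask", "analysis", "stratum", "n", "n_carriers",
                  "beta", "se", "p")

#' Write / read burden result tables
#'
#' The results TSV carries \code{gene}, \code{mask}, \code{analysis},
#' \code{stratum}, \code{n}, \code{n_carriers}, \code{beta}, \code{se},
#' \code{p}, and any further columns present (significance flags,
#' WLM-adjusted estimates and classification).  \code{readResults} of a file
#' written by \code{writeResults} is the identity on the table.
#'
#' @param results data.frame of burden results.
#' @param path TSV path.
#' @export
writeResults <- function(results, path) {
  missing_cols <- setdiff(.RESULT_CORE, colnames(results))
  if (length(missing_cols))
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a GWAS signal table
#'
#' TSV with columns \code{signal_id}, \code{chrom}, \code{pos} (1-based)
#' followed by one column per sample carrying genotype dosages in [0, 2].
#'
#' @param path TSV path.
#' @return list with \code{signals} (data.frame signal_id/chrom/pos) and
#'   \code{dosages} (signals x samples matrix).
#' @export
readGwasSignals <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("signal_id", "chrom", "pos")
  if (!all(req %in% colnames(tab)))
    stop("signal table must have columns: ", paste(req, collapse = ", "))
  sample_cols <- setdiff(colnames(tab), req)
  dos <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(dos) <- tab$signal_id
  if (length(dos) && (min(dos, na.rm = TRUE) < 0 ||
                      max(dos, na.rm = TRUE) > 2))
    stop("signal dosages must lie in [0, 2]")
  list(signals = tab[, req], dosages = dos)
}

#' Read gene coordinates (symbol, chrom, start, end; 1-based inclusive)
#' @param path TSV path.
#' @export
readGeneCoordinates <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% colnames(tab)))
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  if (any(tab$end < tab$start)) stop("gene end before start")
  tab
}
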