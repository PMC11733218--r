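#' @rdname GenotypeCalls-class
#' @param object,x a \linkS4class{GenotypeCalls} or \linkS4class{DuoCohort}.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("genotypeQuality",
           function(x) standardGeneric("genotypeQuality"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("altReads", function(x) standardGeneric("altReads"))

#' @rdname GenotypeCalls-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname DuoCohort-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname DuoCohort-class
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname DuoCohort-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname BurdenMask-class
#' @param x a \linkS4class{BurdenMask}.
#' @export
setGeneric("maskName", function(x) standardGeneric("maskName"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("dosages", "GenotypeCalls", function(x) assay(x, "GT"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("readDepth", "GenotypeCalls", function(x) assay(x, "DP"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("genotypeQuality", "GenotypeCalls",
          function(x) assay(x, "GQ"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("altReads", "GenotypeCalls", function(x) assay(x, "AD"))

#' @rdname GenotypeCalls-class
#' @export
setMethod("variantTable", "GenotypeCalls",
          function(x) as.data.frame(rowData(x)))

#' @rdname DuoCohort-class
#' @export
setMethod("genotypeCalls", "DuoCohort", function(x) x@calls)

#' @rdname DuoCohort-class
#' @export
setMethod("sampleTable", "DuoCohort", function(x) x@samples)

#' @rdname DuoCohort-class
#' @export
setMethod("truthTable", "DuoCohort", function(x) x@truth)

#' @rdname BurdenMask-class
#' @export
setMethod("maskName", "BurdenMask", function(x) x@name)

setMethod("show", "GenotypeCalls", function(object) {
  cat("GenotypeCalls:", nrow(object), "variants x", ncol(object),
      "samples\n")
  gt <- assay(object, "GT")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(gt))), "\n")
  callNextMethod()
})

setMethod("show", "DuoCohort", function(object) {
  cd <- colData(object@calls)
  cat("DuoCohort:", sum(cd$role == "child"), "children,",
      sum(cd$role == "mother"), "mothers;",
      nrow(object@calls), "variants across",
      length(unique(rowData(object@calls)$gene)), "gene(s)\n")
  cat("  truth: betas in [",
      paste(range(c(object@truth$beta_fetal, object@truth$beta_maternal)),
            collapse = ", "), "] SD\n")
})

setMethod("show", "BurdenMask", function(object) {
  crit <- character()
  if (object@includePtv) crit <- c(crit, "high-confidence PTV")
  if (length(object@caddMin))
    crit <- c(crit, paste0(paste(object@caddClasses, collapse = "/"),
                           " CADD >= ", object@caddMin))
  if (length(object@miterMax))
    crit <- c(crit, paste0("missense MITER <= ", object@miterMax))
  if (length(object@clinicalClasses))
    crit <- c(crit, paste0("clinical {",
                           paste(object@clinicalClasses, collapse = ","),
                           "}"))
  cat("BurdenMask '", object@name, "': ",
      paste(crit, collapse = " OR "), "\n", sep = "")
  if (length(object@excludedVariants))
    cat("  excluding", length(object@excludedVariants), "variant(s)\n")
})
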