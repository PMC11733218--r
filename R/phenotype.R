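## Birth-weight phenotype derivation and covariate construction.

#' @importFrom data.table as.data.table setnames :=
NULL

#' Derive cleaned birth-weight phenotypes
#'
#' Derives one birth weight in kg per sample from the report lists, for the
#' fetal analysis (own birth weight) or the maternal analysis (offspring
#' birth weight, women only).  Pound reports are converted to kg
#' (x 0.45359237).  For the maternal analysis under the default
#' (\code{"discovery"}) rules, hospital-source reports are preferentially
#' retained when present; repeated reports are averaged; a sample is
#' excluded (NA, with a reason) when it is from a multiple birth, when
#' reports differ by more than 1 kg (strictly; the \code{"regenie"} rules
#' exclude at >= 1 kg), or when the averaged value is < 1 or >= 7 kg.
#' Under the \code{"regenie"} rules offspring weight uses self-reports
#' only.  Derivation is idempotent and insensitive to report order.
#'
#' @param samples data.frame of sample records
#'   (see \code{\link{readPhenotypes}}).
#' @param analysis \code{"fetal"} or \code{"maternal"}.
#' @param style \code{"discovery"} (default) or \code{"regenie"}.
#' @return data.frame \code{sample_id}, \code{bw_kg} (NA = excluded) with
#'   attributes \code{exclusions} (sample_id, reason; reasons partition the
#'   removed set) and \code{log}.
#' @export
deriveBirthWeights <- function(samples,
                               analysis = c("fetal", "maternal"),
                               style = c("discovery", "regenie")) {
  analysis <- match.arg(analysis)
  style <- match.arg(style)
  if (analysis == "maternal")
    samples <- samples[samples$sex == "female", , drop = FALSE]
  rep_long <- if (analysis == "fetal") bwReports(samples, "own")
              else bwReports(samples, "offspring")
  if (any(rep_long$value <= 0)) stop("non-positive birth weight report")

  dt <- as.data.table(rep_long)
  if (nrow(dt)) {
    dt[, kg := ifelse(unit == "lb", value * KG_PER_LB, value)]
    if (analysis == "maternal") {
      if (style == "discovery") {
        hosp_ids <- unique(dt$sample_id[dt$source == "hospital"])
        dt <- dt[!(sample_id %in% hosp_ids) | source == "hospital"]
      } else {
        dt <- dt[source == "self_report"]
      }
    }
    agg <- dt[, list(bw = mean(kg), spread = max(kg) - min(kg)),
              by = sample_id]
  } else {
    agg <- data.table::data.table(sample_id = character(), bw = numeric(),
                                  spread = numeric())
  }

  idx <- match(samples$sample_id, agg$sample_id)
  bw <- agg$bw[idx]
  spread <- agg$spread[idx]
  discrepant <- !is.na(spread) &
    (if (style == "discovery") spread > 1 else spread >= 1)

  reason <- rep(NA_character_, nrow(samples))
  reason[is.na(bw)] <- "no_reports"
  reason[is.na(reason) & samples$multiple_birth] <- "multiple_birth"
  reason[is.na(reason) & discrepant] <- "discrepant_reports"
  reason[is.na(reason) & (bw < 1 | bw >= 7)] <- "extreme_value"
  bw[!is.na(reason)] <- NA_real_

  log <- .emptyLog()
  n <- nrow(samples)
  for (r in c("no_reports", "multiple_birth", "discrepant_reports",
              "extreme_value")) {
    log <- .logStep(log, r, n, sum(reason == r, na.rm = TRUE))
    n <- n - sum(reason == r, na.rm = TRUE)
  }
  out <- data.frame(sample_id = samples$sample_id, bw_kg = bw)
  attr(out, "exclusions") <- data.frame(
    sample_id = samples$sample_id[!is.na(reason)],
    reason = reason[!is.na(reason)])
  attr(out, "log") <- log
  out
}

#' Standardise a phenotype to z-scores
#'
#' \code{(x - mean) / sd} over the non-missing values of the analysis
#' cohort, using the sample standard deviation.  The result has mean 0 and
#' variance 1.
#'
#' @param x numeric vector (NAs passed through).
#' @return z-scored vector.
#' @export
standardise <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) stop("need >= 2 non-missing values")
  s <- sd(obs)
  if (s == 0) stop("zero variance; cannot standardise")
  (x - mean(obs)) / s
}

#' Build the covariate model matrix for an analysis
#'
#' Fetal analysis: reporter age, age squared, sex (sex-combined runs only),
#' the 10 principal components and sequencing batch.  Maternal analysis:
#' age at first birth (falling back to year of birth when mostly missing),
#' the 10 principal components and batch.  Ages are centred before
#' squaring.  Factors are expanded to treatment-coded dummies; no intercept
#' column is included.
#'
#' @param samples data.frame of sample records.
#' @param analysis \code{"fetal"} or \code{"maternal"}.
#' @param stratum \code{"all"}, \code{"female"} or \code{"male"}; sex is a
#'   covariate only when \code{"all"} and the analysis is fetal.
#' @return numeric matrix with rownames \code{sample_id}.
#' @export
buildCovariates <- function(samples, analysis = c("fetal", "maternal"),
                            stratum = c("all", "female", "male")) {
  analysis <- match.arg(analysis)
  stratum <- match.arg(stratum)
  pcs <- as.matrix(samples[, paste0("pc", 1:10)])
  batch <- factor(samples$wes_batch)
  bdum <- if (nlevels(batch) > 1L)
    stats::model.matrix(~batch)[, -1L, drop = FALSE] else NULL
  if (analysis == "fetal") {
    age_c <- samples$age - mean(samples$age)
    base <- cbind(age = age_c, age2 = age_c^2)
    if (stratum == "all")
      base <- cbind(base, sex_male = as.numeric(samples$sex == "male"))
  } else {
    afb <- samples$age_first_birth
    if (mean(is.na(afb)) > 0.5) {
      base <- cbind(year_of_birth = samples$year_of_birth -
                      mean(samples$year_of_birth))
    } else {
      afb[is.na(afb)] <- mean(afb, na.rm = TRUE)
      base <- cbind(age_first_birth = afb - mean(afb))
    }
  }
  X <- if (is.null(bdum)) cbind(base, pcs) else cbind(base, pcs, bdum)
  rownames(X) <- samples$sample_id
  X
}
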