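## Mother-child duo cohort simulator with read-level data and known truth.
##
## Transmission model: for each rare variant, mother and father carrier
## status are independent Bernoulli draws; a carrier parent transmits the
## rare allele with probability 1/2; the child dosage is the sum of the two
## transmissions.  For rare variants a carrier child has exactly one carrier
## parent, which is the mother with probability 1/2 -- this is what makes
## the child-mother carrier correlation ~0.5 rather than imposing it.
## Fathers are simulated but never emitted.

#' Specify one simulated gene
#'
#' @param gene gene symbol.
#' @param n_variants number of qualifying (causal-class) variants.
#' @param carrier_freq aggregate carrier frequency of the qualifying
#'   variants; per-variant frequency defaults to
#'   \code{carrier_freq / n_variants} and must lie in (0, 0.005].
#' @param beta_fetal,beta_maternal true fetal and maternal effects of
#'   carrier status on the SD-scale phenotype.
#' @param fraction_ptv fraction of qualifying variants that are
#'   protein-truncating (LOFTEE high-confidence); the rest are missense
#'   with CADD >= 25.
#' @param cadd_min,cadd_scale missense CADD scores are drawn as
#'   \code{cadd_min + Exp(cadd_scale)}.
#' @param variant_freq optional per-variant carrier frequency overriding the
#'   aggregate default.
#' @param n_background number of non-qualifying (synonymous, low-CADD)
#'   variants simulated alongside, for exercising mask logic.
#' @return a \code{GeneSimSpec} list.
#' @export
geneSimSpec <- function(gene, n_variants = 8L, carrier_freq = 0.002,
                        beta_fetal = 0, beta_maternal = 0,
                        fraction_ptv = 0.5, cadd_min = 25, cadd_scale = 4,
                        variant_freq = NULL, n_background = 0L) {
  if (n_variants < 1L) stop("n_variants must be >= 1")
  if (is.null(variant_freq)) variant_freq <- carrier_freq / n_variants
  if (any(variant_freq <= 0) || any(variant_freq > 0.005))
    stop("per-variant carrier frequency must lie in (0, 0.005]")
  if (!is.finite(beta_fetal) || !is.finite(beta_maternal))
    stop("betas must be finite")
  structure(list(gene = gene, n_variants = as.integer(n_variants),
                 carrier_freq = carrier_freq, variant_freq = variant_freq,
                 beta_fetal = beta_fetal, beta_maternal = beta_maternal,
                 fraction_ptv = fraction_ptv, cadd_min = cadd_min,
                 cadd_scale = cadd_scale,
                 n_background = as.integer(n_background)),
            class = "GeneSimSpec")
}

#' Configure a duo cohort simulation
#'
#' Defaults emulate the statistical structure of a biobank exome study of
#' birth weight: rare carriers (per-variant MAF below 0.1\%), ~30x short-read
#' depth with binomial allele sampling at heterozygous sites, a standardised
#' phenotype with additive fetal and maternal carrier effects plus small
#' covariate effects, and self-/hospital-reported birth weight with repeat
#' visits, occasional pound units, multiple births and missing reports.
#'
#' @param n_duos number of mother-child pairs.
#' @param genes list of \code{\link{geneSimSpec}}.
#' @param noise_sd residual SD of the latent phenotype (SD units).
#' @param covariate_effects SD-scale effects: \code{sex_female} (on the
#'   child's phenotype), \code{age} per year and \code{age2} per squared
#'   year of reporter age (centred at 55), \code{pc} per unit of each of the
#'   10 principal components, \code{batch} for the second sequencing batch.
#' @param depth_mean mean Poisson read depth.
#' @param het_alt_read_prob alternate-read probability at heterozygous
#'   calls (0.5 for a well-behaved variant).
#' @param hom_alt_read_prob,ref_alt_read_prob alternate-read probabilities
#'   for hom-alt (~1) and hom-ref (~0) calls.
#' @param gq_mean,gq_sd genotype-quality distribution (truncated to 0..99).
#' @param missing_rate genotype missingness rate.
#' @param spurious list of \code{list(gene=, variant=, het_alt_read_prob=)}
#'   entries overriding the het alternate-read probability of single
#'   variants, to emulate spurious calls (AD~DP slope ~ 2p).
#' @param bw_mean_kg,bw_sd_kg location/scale mapping the latent SD-scale
#'   phenotype to kilograms.
#' @param report_sd_kg visit-to-visit reporting noise.
#' @param second_visit_prob,lb_report_prob,hospital_report_prob,
#'   self_report_prob,report_missing_prob,multiple_birth_prob report
#'   generation rates.
#' @param overlap_fraction fraction of mothers who additionally appear in
#'   the fetal panel with an own-birth-weight report (default 0:
#'   independent panels, matching the error-propagation assumption of
#'   \code{\link{wlmAdjust}}).
#' @param seed integer seed governing all randomness.
#' @return a \code{DuoSimConfig} list.
#' @export
duoSimConfig <- function(n_duos, genes, noise_sd = 1,
                         covariate_effects = list(sex_female = -0.12,
                                                  age = 0.002, age2 = 0,
                                                  pc = 0.01, batch = 0.02),
                         depth_mean = 30, het_alt_read_prob = 0.5,
                         hom_alt_read_prob = 0.99,
                         ref_alt_read_prob = 0.002,
                         gq_mean = 60, gq_sd = 15, missing_rate = 0.01,
                         spurious = list(),
                         bw_mean_kg = 3.4, bw_sd_kg = 0.55,
                         report_sd_kg = 0.05, second_visit_prob = 0.15,
                         lb_report_prob = 0.05,
                         hospital_report_prob = 0.3,
                         self_report_prob = 0.95,
                         report_missing_prob = 0.02,
                         multiple_birth_prob = 0.015,
                         overlap_fraction = 0, seed = 1L) {
  if (n_duos <= 0) stop("n_duos must be positive")
  if (inherits(genes, "GeneSimSpec")) genes <- list(genes)
  probs <- c(het_alt_read_prob, hom_alt_read_prob, ref_alt_read_prob,
             missing_rate, second_visit_prob, lb_report_prob,
             hospital_report_prob, self_report_prob, report_missing_prob,
             multiple_birth_prob, overlap_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(as.list(environment()), class = "DuoSimConfig")
}

## Variant table for a config: qualifying variants first within each gene,
## then background.  PTVs alternate stop-gained SNVs and frameshift indels.
.simVariantTable <- function(config) {
  tabs <- lapply(seq_along(config$genes), function(g) {
    sp <- config$genes[[g]]
    nq <- sp$n_variants
    nb <- sp$n_background
    n <- nq + nb
    n_ptv <- round(sp$fraction_ptv * nq)
    cls <- c(rep("PTV", n_ptv), rep("missense", nq - n_ptv),
             rep("synonymous", nb))
    is_fs <- cls == "PTV" & (seq_len(n) %% 2L == 0L)
    pos <- g * 1000000L + (seq_len(n) - 1L) * 100L
    data.frame(
      gene = sp$gene, chrom = "1", pos = pos,
      ref = ifelse(is_fs, "AC", "A"), alt = "A",
      consequence_class = cls,
      loftee_high_confidence = cls == "PTV",
      cadd = ifelse(cls == "missense",
                    sp$cadd_min + stats::rexp(n, 1 / sp$cadd_scale),
                    ifelse(cls == "PTV", 40, 1)),
      miter = NA_real_, aascore = NA_real_, clinical_class = NA_character_,
      carrier_freq = rep(sp$variant_freq, length.out = n),
      qualifying = c(rep(TRUE, nq), rep(FALSE, nb)))
  })
  tab <- do.call(rbind, tabs)
  tab$alt[tab$ref == "A"] <- "T"
  tab$variant_id <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  tab
}

#' Simulate a mother-child duo cohort
#'
#' See \code{\link{duoSimConfig}} for the generating model.  The child's
#' latent phenotype is
#' \code{sum_genes(beta_fetal * carrier_child + beta_maternal *
#' carrier_mother) + covariate terms + Normal(0, noise_sd)}, recorded both
#' as the child's own birth weight and as the mother's offspring
#' birth-weight report (in kg on the \code{bw_mean_kg}/\code{bw_sd_kg}
#' scale).  Read depth is Poisson; alternate reads are binomial with
#' genotype-class probabilities.  Identical seed and config give identical
#' output.
#'
#' @param config a \code{\link{duoSimConfig}}.
#' @param seed overrides \code{config$seed} when given.
#' @return a \linkS4class{DuoCohort}.  True per-gene carrier indicators are
#'   kept in \code{metadata(genotypeCalls(cohort))} as
#'   \code{carrier_child} / \code{carrier_mother} (genes x duos matrices).
#' @export
simulateDuos <- function(config, seed = NULL) {
  stopifnot(inherits(config, "DuoSimConfig"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_duos
  vt <- .simVariantTable(config)
  V <- nrow(vt)
  qv <- vt$carrier_freq

  exp_carriers <- vapply(config$genes,
                         function(sp) n * sp$carrier_freq, numeric(1))
  if (any(exp_carriers < 1))
    warning("expected carrier count < 1 for gene(s): ",
            paste(vapply(config$genes, `[[`, character(1), "gene")
                  [exp_carriers < 1], collapse = ", "),
            " (no power)")

  ## carrier draws and transmission
  mom <- matrix(rbinom(V * n, 1L, qv), V, n)
  dad <- matrix(rbinom(V * n, 1L, qv), V, n)
  child <- matrix(rbinom(V * n, 1L, 0.5), V, n) * mom +
    matrix(rbinom(V * n, 1L, 0.5), V, n) * dad

  gene_idx <- match(vt$gene, unique(vt$gene))
  q_rows <- which(vt$qualifying)
  rows_by_gene <- split(q_rows, gene_idx[q_rows])
  agg <- function(m) {
    out <- matrix(0L, length(rows_by_gene), ncol(m))
    for (i in seq_along(rows_by_gene)) {
      rows <- rows_by_gene[[i]]
      out[i, ] <- if (length(rows) == 1L) (m[rows, ] >= 1L) + 0L else
        (colSums(m[rows, , drop = FALSE] >= 1L) > 0L) + 0L
    }
    out
  }
  carrier_child <- agg(child)
  carrier_mom <- agg(mom)
  rownames(carrier_child) <- rownames(carrier_mom) <- unique(vt$gene)

  ## covariates; mothers occupy rows 1..n, children n+1..2n
  child_ids <- sprintf("C%06d", seq_len(n))
  mom_ids <- sprintf("M%06d", seq_len(n))
  ce <- config$covariate_effects
  m2 <- 2L * n
  i_k <- n + seq_len(n)
  sex <- c(rep("female", n), sample(c("female", "male"), n, replace = TRUE))
  age <- round(runif(m2, 40, 70))
  pcs <- matrix(rnorm(10 * m2), m2,
                dimnames = list(NULL, paste0("pc", 1:10)))
  samples <- data.frame(
    sample_id = c(mom_ids, child_ids), sex = sex, age = age,
    year_of_birth = 2022L - age, pcs,
    wes_batch = sample(c("b1", "b2"), m2, replace = TRUE),
    multiple_birth = rbinom(m2, 1, config$multiple_birth_prob) == 1,
    age_first_birth = c(round(runif(n, 18, 40)), rep(NA_real_, n)),
    mothers_diabetes = c(rbinom(n, 1, 0.05) == 1, rep(NA, n)))

  betas_f <- vapply(config$genes, `[[`, numeric(1), "beta_fetal")
  betas_m <- vapply(config$genes, `[[`, numeric(1), "beta_maternal")
  gen_eff <- drop(crossprod(carrier_child, betas_f)) +
    drop(crossprod(carrier_mom, betas_m))
  cov_eff <- ce$sex_female * (sex[i_k] == "female") +
    ce$age * (age[i_k] - 55) + ce$age2 * (age[i_k] - 55)^2 +
    ce$pc * rowSums(pcs[i_k, , drop = FALSE]) +
    ce$batch * (samples$wes_batch[i_k] == "b2")
  z <- gen_eff + cov_eff + rnorm(n, 0, config$noise_sd)
  bw_kg <- config$bw_mean_kg + config$bw_sd_kg * z

  ## reads over all emitted samples (mothers then children)
  gt <- cbind(mom, child)
  colnames(gt) <- c(mom_ids, child_ids)
  rownames(gt) <- vt$variant_id
  N <- length(gt)
  dp <- matrix(rpois(N, config$depth_mean), V)
  het_p <- rep(config$het_alt_read_prob, V)
  for (sp in config$spurious) {
    rows <- which(vt$gene == sp$gene & vt$qualifying)
    het_p[rows[sp$variant]] <- sp$het_alt_read_prob
  }
  p_alt <- matrix(config$ref_alt_read_prob, V, 2L * n)
  i_het <- which(gt == 1L)
  p_alt[i_het] <- het_p[(i_het - 1L) %% V + 1L]
  p_alt[gt == 2L] <- config$hom_alt_read_prob
  ad <- matrix(rbinom(N, dp, p_alt), V)
  gq_v <- as.integer(round(rnorm(N, config$gq_mean, config$gq_sd)))
  gq_v[gq_v < 0L] <- 0L
  gq_v[gq_v > 99L] <- 99L
  gq <- matrix(gq_v, V)
  miss <- matrix(runif(N) < config$missing_rate, V)
  gt[miss] <- NA_integer_
  dp[miss] <- NA_integer_
  gq[miss] <- NA_integer_
  ad[miss] <- NA_integer_
  dimnames(dp) <- dimnames(gq) <- dimnames(ad) <- dimnames(gt)

  ## birth-weight reports; visit-1 rows precede visit-2 rows and the report
  ## encoder's grouping sort is stable, so no explicit sort is needed
  rep_val <- function(v, sd_kg) {
    x <- v + rnorm(length(v), 0, sd_kg)
    x[x < 0.05] <- 0.05
    x
  }
  v1 <- rep_val(bw_kg, config$report_sd_kg)
  in_lb <- runif(n) < config$lb_report_prob
  v1[in_lb] <- v1[in_lb] / KG_PER_LB
  second <- which(runif(n) < config$second_visit_prob)
  own <- data.frame(
    sample_id = c(child_ids, child_ids[second]),
    value = c(v1, rep_val(bw_kg[second], config$report_sd_kg)),
    unit = c(ifelse(in_lb, "lb", "kg"), rep("kg", length(second))),
    visit = rep(c(1L, 2L), c(n, length(second))))
  own <- own[runif(nrow(own)) >= config$report_missing_prob, ]

  has_self <- which(runif(n) < config$self_report_prob)
  has_hosp <- which(runif(n) < config$hospital_report_prob)
  off <- data.frame(
    sample_id = c(mom_ids[has_self], mom_ids[has_hosp]),
    value = c(rep_val(bw_kg[has_self], 2 * config$report_sd_kg),
              rep_val(bw_kg[has_hosp], 0.3 * config$report_sd_kg)),
    unit = "kg",
    source = rep(c("self_report", "hospital"),
                 c(length(has_self), length(has_hosp))))

  samples$own_bw_reports <- ""
  samples$offspring_bw_reports <- ""
  samples$own_bw_reports[match(child_ids, samples$sample_id)] <-
    .encodeReports(own, child_ids, "visit")
  samples$offspring_bw_reports[match(mom_ids, samples$sample_id)] <-
    .encodeReports(off, mom_ids, "source")

  ## optional overlap: some mothers also report their own birth weight
  k_over <- floor(config$overlap_fraction * n)
  if (k_over > 0) {
    idx <- seq_len(k_over)
    grandma <- (carrier_mom[, idx, drop = FALSE] *
                  matrix(rbinom(nrow(carrier_mom) * k_over, 1, 0.5),
                         nrow(carrier_mom))) >= 1L
    z_own <- drop(crossprod(carrier_mom[, idx, drop = FALSE], betas_f)) +
      drop(crossprod(grandma + 0L, betas_m)) +
      ce$sex_female + rnorm(k_over, 0, config$noise_sd)
    v_own <- config$bw_mean_kg + config$bw_sd_kg * z_own
    samples$own_bw_reports[match(mom_ids[idx], samples$sample_id)] <-
      paste0(format(rep_val(v_own, config$report_sd_kg), trim = TRUE,
                    digits = 15), ":kg:1")
  }

  variants <- vt[, c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence_class", "loftee_high_confidence", "cadd",
                     "miter", "aascore", "clinical_class", "qualifying")]
  variants$is_indel <- nchar(variants$ref) != 1L |
    nchar(variants$alt) != 1L
  calls <- GenotypeCalls(gt, dp, gq, ad, variants = variants,
                         samples = DataFrame(
                           sample_id = colnames(gt),
                           role = rep(c("mother", "child"), each = n),
                           duo_id = rep(seq_len(n), 2L),
                           row.names = colnames(gt)))
  metadata(calls)$carrier_child <- carrier_child
  metadata(calls)$carrier_mother <- carrier_mom
  metadata(calls)$bw_kg <- setNames(bw_kg, child_ids)

  truth <- data.frame(
    gene = vapply(config$genes, `[[`, character(1), "gene"),
    beta_fetal = betas_f, beta_maternal = betas_m,
    carrier_freq = vapply(config$genes, `[[`, numeric(1), "carrier_freq"))
  new("DuoCohort", calls = calls, samples = samples, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits \code{cohort.vcf} (VCF v4.2, FORMAT GT:DP:GQ:AD with AD as the
#' alternate-allele read count), \code{phenotypes.tsv},
#' \code{annotations.tsv} and \code{truth.tsv}, all readable by the package
#' readers with no loss on dosage, DP, GQ or AD.
#'
#' @param cohort a \linkS4class{DuoCohort}.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return \code{out_dir}, invisibly.
#' @export
writeCohort <- function(cohort, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- genotypeCalls(cohort)
  writeCallsVcf(calls, file.path(out_dir, "cohort.vcf"))
  writePhenotypes(sampleTable(cohort), file.path(out_dir, "phenotypes.tsv"))
  ann <- variantTable(calls)
  ann <- ann[, intersect(c("variant_id", "gene", "consequence_class",
                           "loftee_high_confidence", "cadd", "miter",
                           "aascore", "clinical_class", "qualifying"),
                         colnames(ann))]
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truthTable(cohort), file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Write genotype calls as VCF v4.2
#'
#' Fixed-schema emitter for \linkS4class{GenotypeCalls}: biallelic records
#' in row order, FORMAT \code{GT:DP:GQ:AD} with AD declared
#' \code{Number=1} as the alternate-allele read count.  Output is
#' deterministic (no timestamps), so identical cohorts give byte-identical
#' files.
#'
#' @param calls a \linkS4class{GenotypeCalls}.
#' @param path output path.
#' @export
writeCallsVcf <- function(calls, path) {
  vt <- variantTable(calls)
  gt <- dosages(calls)
  gts <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt))
  gts[is.na(gt)] <- "./."
  fmt_int <- function(m) {
    s <- matrix(as.character(m), nrow(m))
    s[is.na(m)] <- "."
    s
  }
  body <- matrix(paste(gts, fmt_int(readDepth(calls)),
                       fmt_int(genotypeQuality(calls)),
                       fmt_int(altReads(calls)), sep = ":"), nrow(gt))
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(vt$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("##FORMAT=<ID=AD,Number=1,Type=Integer,",
           "Description=\"Alternate allele read count\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"),
    paste(vt$chrom, vt$pos, vt$variant_id, vt$ref, vt$alt, ".", "PASS",
          ".", "GT:DP:GQ:AD",
          apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
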