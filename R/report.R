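## Pipeline orchestration: load -> preflight -> harmonize -> allele checks
## -> effect checks -> instrument checks, aggregated into a QcReport with a
## single recommended disposition. Stages lacking their reference inputs
## degrade to "not assessable" instead of failing.

#' Run the full QC pipeline on one summary-statistics set
#'
#' Executes the stages in fixed order: rsid resolution and pre-QC
#' exclusions; effect-scale normalization (absolute-risk effects are
#' rescaled to log odds ratios when a prevalence is configured); effect
#' allele direction check against top hits; effect allele frequency checks
#' against top hits and the consensus-MAF reference (with data set level
#' pattern classification and per-superpopulation correlations);
#' expected-vs-reported effect regression, deviation-vs-quality summaries,
#' P-Z consistency and extreme-effect flags; LD clumping with index-SNP
#' novelty assessment.
#'
#' Disposition policy: \code{exclude-recommended} only on systematic
#' evidence -- a systematic effect-allele flip against the top hits, or an
#' irreconcilable P-Z relationship. A frequency-pattern verdict of
#' \code{systematic_flip} or \code{maf_coded}, a flagged slope, a flagged
#' P-Z correlation, high allele conflicts, extreme effects or novel index
#' SNPs give \code{investigate} with targeted recommendations (e.g. "set
#' the effect allele frequency to missing" for a MAF-coded frequency
#' column). Otherwise \code{pass}.
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @param tophits top-hits reference data.frame or NULL.
#' @param mafRef consensus-MAF reference data.frame or NULL.
#' @param ld LD pair data.frame or NULL.
#' @param knownHits known-hits data.frame or NULL.
#' @param config threshold list, see \code{\link{qcDefaults}}.
#' @param samePublication is the test set the same publication as the
#'   top-hits reference?
#' @param population superpopulation for the MAF comparison
#'   (\code{"consensus"} or a reference column name).
#' @param positionLookup,aliasTable optional rsid-resolution tables.
#' @param seed recorded in the report metadata (the pipeline itself is
#'   deterministic).
#' @return A \code{\link{QcReport-class}}.
#' @export
runFullQc <- function(sset, tophits = NULL, mafRef = NULL, ld = NULL,
                      knownHits = NULL, config = qcDefaults(),
                      samePublication = FALSE, population = "consensus",
                      positionLookup = NULL, aliasTable = NULL,
                      seed = NA_integer_) {
  flags <- list()
  verdicts <- list()
  recommendations <- character(0)
  plot_data <- list()

  ## preflight
  rs <- assignRsids(sset, positionLookup, aliasTable)
  ex <- applyExclusions(rs$table, macMin = config$mac_min,
                        ciLevel = config$ci_level)
  sset <- ex$table
  filters <- rbind(rs$log, ex$log)

  ## scale normalization
  d <- ssData(sset)
  linear <- !is.na(d$scale) & d$scale == "linear_risk"
  if (any(linear)) {
    if (!is.na(config$prevalence)) {
      tr <- transformLinearToLogOR(d$beta[linear], d$se[linear],
                                   config$prevalence)
      d$beta[linear] <- tr$beta
      d$se[linear] <- tr$se
      d$scale[linear] <- "log_odds"
      sset <- setSS(sset, d)
      recommendations <- c(recommendations, sprintf(
        "%d absolute-risk effect(s) rescaled to log odds ratios at prevalence %.4g",
        sum(linear), config$prevalence))
    } else {
      recommendations <- c(recommendations, paste(
        "records on the linear (absolute-risk) scale present but no",
        "prevalence configured: effect sizes are not comparable to log",
        "odds ratios"))
    }
  }

  ## allele metadata checks
  dir_res <- checkDirectionVsTopHits(sset, tophits, samePublication, config)
  flags$direction <- dir_res$flags
  verdicts$direction <- dir_res$verdict
  plot_data$direction <- dir_res$data

  eaf_res <- checkEafVsTopHits(sset, tophits, config)
  flags$eaf <- eaf_res$flags
  plot_data$eaf <- eaf_res$data

  maf_res <- if (!is.null(mafRef) && nrow(mafRef) > 0) {
    checkMafVsReference(sset, mafRef, population, config)
  } else list(flags = emptyFlags(), data = NULL)
  flags$maf <- maf_res$flags
  plot_data$maf <- maf_res$data
  freq_verdict <- if (!is.null(maf_res$data)) {
    classifyFrequencyPattern(maf_res$data$recoded, maf_res$data$ref_maf,
                             config)
  } else {
    .verdictRow("maf_vs_reference", "ambiguous", NA_real_, NA_real_, 0L,
                "no MAF reference or no overlapping SNPs")
  }
  verdicts$frequency <- freq_verdict
  ancestry_r <- ancestryCorrelations(maf_res$data,
                                     minSnps = config$min_pattern_snps)

  ## effect-size checks
  comparisons <- buildEffectComparisons(sset)
  slope <- fitExpectedVsReported(comparisons, config$slope_range,
                                 config$min_slope_snps)
  dev <- deviationVsQuality(comparisons, sset, config$info_min,
                            config$min_slope_snps)
  flags$lowinfo <- dev$flags
  d <- ssData(sset)
  pz <- pzConsistency(d$beta, d$se, d$pval, rMin = config$pz_min,
                      irreconcilableR = config$pz_irreconcilable,
                      outlierZ = config$pz_outlier_z,
                      outlierP = config$pz_outlier_p,
                      minPoints = config$min_pz_snps)
  flags$extreme <- flagExtremeEffects(sset, config$extreme_logor)
  plot_data$expected <- if (isTRUE(slope$assessable)) slope$data else NULL
  plot_data$pz <- if (isTRUE(pz$assessable)) pz$data else NULL

  ## instrument checks
  instrument <- list(assessable = FALSE)
  if (!is.null(ld) || any(!is.na(d$pval))) {
    clump <- ldClump(sset, ld, pThreshold = config$clump_p,
                     r2Threshold = config$clump_r2,
                     kbWindow = config$clump_kb)
    instrument <- list(assessable = TRUE, clump = clump,
                       n_index = nrow(clump$index_snps))
    if (!is.null(knownHits) && nrow(clump$index_snps) > 0) {
      novelty <- compareIndexToKnown(clump, knownHits,
                                     bpWindow = config$known_bp_window)
      instrument$novelty <- novelty$status
      instrument$flagged <- novelty$flagged
      instrument$n_novel <- sum(novelty$status$status == "novel")
    }
  }

  all_flags <- do.call(rbind, c(flags, list(emptyFlags())))
  rownames(all_flags) <- NULL
  all_verdicts <- do.call(rbind, verdicts)
  rownames(all_verdicts) <- NULL

  ## disposition
  direction_flip <-
    dir_res$verdict$classification == "systematic_flip"
  pz_broken <- isTRUE(pz$irreconcilable)
  investigate <- FALSE
  if (direction_flip) {
    recommendations <- c(recommendations, paste(
      "systematic effect-direction conflict with the top-hits reference:",
      "the effect allele column likely refers to the non-effect allele;",
      "exclusion recommended"))
  }
  if (pz_broken) {
    recommendations <- c(recommendations, paste(
      "reported P-values are irreconcilable with beta/SE z-scores;",
      "exclusion recommended"))
  }
  if (freq_verdict$classification == "systematic_flip") {
    investigate <- TRUE
    recommendations <- c(recommendations, paste(
      "reported effect allele frequency corresponds to the non-effect",
      "allele; recode the frequency column or set it to missing"))
  }
  if (freq_verdict$classification == "maf_coded") {
    investigate <- TRUE
    recommendations <- c(recommendations, paste(
      "reported effect allele frequency column is a minor allele",
      "frequency; set the effect allele frequency to missing"))
  }
  if (isTRUE(slope$assessable) && isTRUE(slope$flagged)) {
    investigate <- TRUE
    recommendations <- c(recommendations, sprintf(
      paste("expected-vs-reported slope %.3f outside [%g, %g]: check",
            "effect-size scale, sample sizes and post-GWAS filtering"),
      slope$slope, config$slope_range[1], config$slope_range[2]))
  }
  if (isTRUE(pz$assessable) && isTRUE(pz$flagged) && !pz_broken) {
    investigate <- TRUE
    recommendations <- c(recommendations, sprintf(
      "P-Z correlation %.4f below %g: check reported P-values", pz$r,
      config$pz_min))
  }
  if (nrow(all_flags) && any(all_flags$level == "high")) investigate <- TRUE
  if (nrow(flags$extreme)) {
    investigate <- TRUE
    recommendations <- c(recommendations, sprintf(
      "%d SNP(s) with |log OR| > %g: check for unstable estimates",
      nrow(flags$extreme), config$extreme_logor))
  }
  if (isTRUE(instrument$flagged)) {
    investigate <- TRUE
    recommendations <- c(recommendations, sprintf(
      paste("%d clump index SNP(s) absent from the known-hits reference:",
            "possible false positives from unfiltered variants"),
      instrument$n_novel %||% NA_integer_))
  }
  disposition <- if (direction_flip || pz_broken) "exclude-recommended"
    else if (investigate) "investigate" else "pass"

  metadata <- list(
    trait_name = traitName(sset), trait_type = traitType(sset),
    ancestry = ancestry(sset), publication_id = sset@publicationId,
    n_records = nRecords(sset), max_n = maxN(sset),
    n_cases_total = sset@nCasesTotal, n_controls_total = sset@nControlsTotal,
    same_publication = samePublication, population = population,
    position_base = "1-based",
    pct_deviation_denominator = "expected",
    seed = seed,
    thresholds = config,
    ancestry_correlations = as.list(ancestry_r))

  new("QcReport", metadata = metadata, filters = filters,
      flags = all_flags, verdicts = all_verdicts, slope = slope, pz = pz,
      deviation = dev[c("assessable", "correlations")],
      instrument = instrument, recommendations = recommendations,
      disposition = disposition, plotData = plot_data)
}

#' Serialize a QcReport to a JSON-ready list
#'
#' Sections: \code{metadata, filters, flags, slopes, correlations,
#' classifications, instrument, recommendations, disposition}. The shipped
#' schema (\code{inst/schema/qc_report_schema.json}) describes the layout;
#' \code{\link{validateReportJSON}} checks conformity.
#'
#' @param report a \code{\link{QcReport-class}}.
#' @return Nested list suitable for \code{jsonlite::write_json}.
#' @export
reportToJSON <- function(report) {
  cor_list <- list(
    pz = if (isTRUE(report@pz$assessable)) report@pz$r else NA_real_,
    deviation_vs_quality =
      if (isTRUE(report@deviation$assessable))
        as.list(report@deviation$correlations) else NULL,
    ancestry = report@metadata$ancestry_correlations)
  list(
    metadata = report@metadata[setdiff(names(report@metadata),
                                       "ancestry_correlations")],
    filters = report@filters,
    flags = report@flags,
    slopes = report@slope[setdiff(names(report@slope), "data")],
    correlations = cor_list,
    classifications = report@verdicts,
    pz = report@pz[setdiff(names(report@pz), "data")],
    instrument = if (isTRUE(report@instrument$assessable)) {
      list(n_index = report@instrument$n_index,
           params = report@instrument$clump$params,
           index_snps = report@instrument$clump$index_snps,
           novelty = report@instrument$novelty,
           flagged = report@instrument$flagged)
    } else list(assessable = FALSE),
    recommendations = report@recommendations,
    disposition = report@disposition)
}

#' Validate a report JSON structure against the shipped schema
#'
#' Lightweight structural validation: checks that the required top-level
#' sections exist, that the disposition is an allowed value, and that flag
#' rows carry the required fields with allowed levels.
#'
#' @param x parsed JSON (list) or a path to a report JSON file.
#' @return TRUE, or stops with a description of the violation.
#' @export
validateReportJSON <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("schema", "qc_report_schema.json", package = "sumstatQC"),
    simplifyVector = TRUE)
  required <- schema$required
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("report JSON lacks section(s): ",
                         paste(miss, collapse = ", "))
  if (!x$disposition %in% .DISPOSITIONS) {
    stop("invalid disposition: ", x$disposition)
  }
  for (fl in x$flags) {
    f_miss <- setdiff(c("check", "rsid", "level", "reason"), names(fl))
    if (length(f_miss)) stop("flag lacks field(s): ",
                             paste(f_miss, collapse = ", "))
    if (!fl$level %in% c("none", "moderate", "high")) {
      stop("invalid flag level: ", fl$level)
    }
  }
  TRUE
}

#' Map a disposition to a CLI exit status
#'
#' \code{pass} = 0, \code{investigate} = 2, \code{exclude-recommended} = 3.
#' (1 is reserved for errors.) The status is a pure function of the
#' disposition.
#'
#' @param disposition disposition string.
#' @return Integer exit status.
#' @export
dispositionStatus <- function(disposition) {
  switch(disposition,
         "pass" = 0L, "investigate" = 2L, "exclude-recommended" = 3L,
         stop("unknown disposition: ", disposition))
}
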