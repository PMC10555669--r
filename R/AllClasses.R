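#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyFilterLog <- function() {
  data.frame(rule = character(0), rsid = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

emptyFlags <- function() {
  data.frame(check = character(0), rsid = character(0),
             level = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

emptyVerdicts <- function() {
  data.frame(check = character(0), classification = character(0),
             conflict_fraction = numeric(0), correlation = numeric(0),
             n_compared = integer(0), note = character(0),
             stringsAsFactors = FALSE)
}

## Canonical column set of a summary-statistics table. Every SumStatSet
## carries all of these (missing ones filled with NA) so downstream checks
## never have to test for column existence.
.SUMSTAT_COLS <- c(
  "rsid", "chr", "pos", "effect_allele", "other_allele", "eaf", "beta",
  "se", "pval", "n", "n_cases", "n_controls", "info", "hwe_p", "het_p",
  "n_studies", "scale"
)

.SCALE_LEVELS <- c("log_odds", "linear_risk", "sd_units", "unknown")

.NUMERIC_COLS <- c(
  "pos", "eaf", "beta", "se", "pval", "n", "n_cases", "n_controls",
  "info", "hwe_p", "het_p", "n_studies"
)

#' Container for one GWAS summary-statistics data set
#'
#' A \code{SumStatSet} holds one record per SNP association together with the
#' study-level metadata the QC checks need (trait type, declared ancestry,
#' declared sample sizes) and the provenance of every field (which raw column
#' it was read from). The container is deliberately permissive: records that
#' violate field-level expectations (e.g. an allele frequency above 0.5 for
#' the declared minor allele) are exactly what the QC pipeline exists to
#' find, so only structural requirements are enforced here.
#'
#' @slot data data.frame with the canonical columns \code{rsid, chr, pos,
#'   effect_allele, other_allele, eaf, beta, se, pval, n, n_cases,
#'   n_controls, info, hwe_p, het_p, n_studies, scale}.
#' @slot traitName character(1) trait label.
#' @slot traitType \code{"continuous"} or \code{"binary"}.
#' @slot ancestry declared ancestry label (e.g. \code{"EUR"}).
#' @slot publicationId publication identifier or \code{NA}.
#' @slot maxN declared maximum total sample size.
#' @slot nCasesTotal,nControlsTotal declared study-level case/control counts
#'   (binary traits; \code{NA} otherwise).
#' @slot provenance named list mapping canonical fields to raw column names.
#'
#' @exportClass SumStatSet
setClass("SumStatSet",
  representation(
    data = "data.frame",
    traitName = "character",
    traitType = "character",
    ancestry = "character",
    publicationId = "character",
    maxN = "numeric",
    nCasesTotal = "numeric",
    nControlsTotal = "numeric",
    provenance = "list"
  ),
  prototype(
    traitName = "unnamed trait", traitType = "continuous",
    ancestry = "unknown", publicationId = NA_character_,
    maxN = NA_real_, nCasesTotal = NA_real_, nControlsTotal = NA_real_,
    provenance = list()
  )
)

setValidity("SumStatSet", function(object) {
  msgs <- character(0)
  missing_cols <- setdiff(.SUMSTAT_COLS, names(object@data))
  if (length(missing_cols)) {
    msgs <- c(msgs, paste("missing canonical columns:",
                          paste(missing_cols, collapse = ", ")))
  }
  if (!object@traitType %in% c("continuous", "binary")) {
    msgs <- c(msgs, "traitType must be 'continuous' or 'binary'")
  }
  if ("scale" %in% names(object@data)) {
    bad <- setdiff(unique(stats::na.omit(object@data$scale)), .SCALE_LEVELS)
    if (length(bad)) {
      msgs <- c(msgs, paste("unknown scale value(s):", paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SumStatSet
#'
#' @param data data.frame holding at least some canonical columns; missing
#'   canonical columns are added as NA, extra columns are kept.
#' @param traitName,traitType,ancestry,publicationId study metadata.
#' @param maxN,nCasesTotal,nControlsTotal declared sample sizes. When omitted
#'   for a binary trait they are inferred from the per-record maxima.
#' @param provenance named list mapping canonical field -> raw column name.
#' @return A \code{\link{SumStatSet-class}} object.
#' @export
SumStatSet <- function(data, traitName = "unnamed trait",
                       traitType = c("continuous", "binary"),
                       ancestry = "unknown", publicationId = NA_character_,
                       maxN = NA_real_, nCasesTotal = NA_real_,
                       nControlsTotal = NA_real_, provenance = list()) {
  traitType <- match.arg(traitType)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (cc in setdiff(.SUMSTAT_COLS, names(data))) {
    data[[cc]] <- rep(if (cc %in% .NUMERIC_COLS) NA_real_ else
      NA_character_, nrow(data))
  }
  if (all(is.na(data$scale))) {
    data$scale <- rep("unknown", nrow(data))
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  if (is.na(maxN) && any(!is.na(num_or_na(data$n)))) {
    maxN <- max(num_or_na(data$n), na.rm = TRUE)
  }
  if (traitType == "binary") {
    if (is.na(nCasesTotal) && any(!is.na(num_or_na(data$n_cases)))) {
      nCasesTotal <- max(num_or_na(data$n_cases), na.rm = TRUE)
    }
    if (is.na(nControlsTotal) && any(!is.na(num_or_na(data$n_controls)))) {
      nControlsTotal <- max(num_or_na(data$n_controls), na.rm = TRUE)
    }
  }
  new("SumStatSet",
      data = data[, c(.SUMSTAT_COLS, setdiff(names(data), .SUMSTAT_COLS)),
                  drop = FALSE],
      traitName = traitName, traitType = traitType, ancestry = ancestry,
      publicationId = as.character(publicationId),
      maxN = as.numeric(maxN), nCasesTotal = as.numeric(nCasesTotal),
      nControlsTotal = as.numeric(nControlsTotal), provenance = provenance)
}

#' @rdname SumStatSet
#' @param object,x a \code{SumStatSet}.
#' @export
setGeneric("ssData", function(x) standardGeneric("ssData"))

#' @rdname SumStatSet
#' @export
setMethod("ssData", "SumStatSet", function(x) x@data)

#' @rdname SumStatSet
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname SumStatSet
#' @export
setMethod("nRecords", "SumStatSet", function(x) nrow(x@data))

#' @rdname SumStatSet
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))

#' @rdname SumStatSet
#' @export
setMethod("traitType", "SumStatSet", function(x) x@traitType)

#' @rdname SumStatSet
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname SumStatSet
#' @export
setMethod("traitName", "SumStatSet", function(x) x@traitName)

#' @rdname SumStatSet
#' @export
setGeneric("ancestry", function(x) standardGeneric("ancestry"))

#' @rdname SumStatSet
#' @export
setMethod("ancestry", "SumStatSet", function(x) x@ancestry)

#' @rdname SumStatSet
#' @export
setGeneric("maxN", function(x) standardGeneric("maxN"))

#' @rdname SumStatSet
#' @export
setMethod("maxN", "SumStatSet", function(x) x@maxN)

## replace the record table, keeping metadata
setSS <- function(x, data) {
  x@data <- data
  x
}

setMethod("show", "SumStatSet", function(object) {
  d <- object@data
  cat("SumStatSet:", object@traitName,
      sprintf("(%s, %s)\n", object@traitType, object@ancestry))
  cat("  records:", nrow(d), "\n")
  if (object@traitType == "binary") {
    cat(sprintf("  declared cases/controls: %s / %s\n",
                format(object@nCasesTotal), format(object@nControlsTotal)))
  } else {
    cat("  declared max N:", format(object@maxN), "\n")
  }
  sc <- table(d$scale, useNA = "ifany")
  cat("  scale:", paste(sprintf("%s (%d)", names(sc), sc), collapse = ", "), "\n")
  n_show <- min(5L, nrow(d))
  if (n_show > 0) {
    print(utils::head(d[, c("rsid", "chr", "pos", "effect_allele",
                            "other_allele", "eaf", "beta", "se", "pval")],
                      n_show))
    if (nrow(d) > n_show) cat("  ...", nrow(d) - n_show, "more records\n")
  }
  invisible(NULL)
})

## ---------------------------------------------------------------------------

.DISPOSITIONS <- c("pass", "investigate", "exclude-recommended")

#' Aggregated quality-control report
#'
#' The result of \code{\link{runFullQc}}: graded conflict flags, data set
#' level pattern verdicts, the expected-vs-reported slope fit, the P-Z
#' consistency summary, instrument (clumping) results, the preflight filter
#' log and a single recommended disposition.
#'
#' The disposition is \code{"exclude-recommended"} only when a systematic
#' verdict is present: a systematic effect-allele flip against the top-hits
#' reference, or an irreconcilable P-Z relationship.
#'
#' @slot metadata list of inputs, thresholds and seeds used.
#' @slot filters data.frame preflight filter log (rule, rsid, detail).
#' @slot flags data.frame of graded conflict flags (check, rsid, level, reason).
#' @slot verdicts data.frame of data set level pattern classifications.
#' @slot slope list: expected-vs-reported OLS fit.
#' @slot pz list: P-Z consistency summary.
#' @slot deviation list: percentage-deviation vs quality-metric summaries.
#' @slot instrument list: clumping result and index-SNP novelty statuses.
#' @slot recommendations character vector of recommended actions.
#' @slot disposition one of \code{"pass"}, \code{"investigate"},
#'   \code{"exclude-recommended"}.
#' @slot plotData list of scatter-plot data frames used by
#'   \code{\link{renderPlots}}.
#'
#' @exportClass QcReport
setClass("QcReport",
  representation(
    metadata = "list",
    filters = "data.frame",
    flags = "data.frame",
    verdicts = "data.frame",
    slope = "list",
    pz = "list",
    deviation = "list",
    instrument = "list",
    recommendations = "character",
    disposition = "character",
    plotData = "list"
  ),
  prototype(
    metadata = list(), filters = emptyFilterLog(), flags = emptyFlags(),
    verdicts = emptyVerdicts(), slope = list(assessable = FALSE),
    pz = list(assessable = FALSE), deviation = list(assessable = FALSE),
    instrument = list(assessable = FALSE),
    recommendations = character(0), disposition = "pass", plotData = list()
  )
)

setValidity("QcReport", function(object) {
  msgs <- character(0)
  if (!object@disposition %in% .DISPOSITIONS) {
    msgs <- c(msgs, paste("disposition must be one of:",
                          paste(.DISPOSITIONS, collapse = ", ")))
  }
  if (identical(object@disposition, "exclude-recommended")) {
    v <- object@verdicts
    systematic <- nrow(v) > 0 &&
      any(v$classification == "systematic_flip" &
            v$check == "direction_vs_tophits")
    irreconcilable <- isTRUE(object@pz$irreconcilable)
    if (!systematic && !irreconcilable) {
      msgs <- c(msgs, paste("exclude-recommended requires a systematic",
                            "direction flip or an irreconcilable P-Z check"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname QcReport
#' @param x a \code{QcReport}.
#' @export
setGeneric("disposition", function(x) standardGeneric("disposition"))

#' @rdname QcReport
#' @export
setMethod("disposition", "QcReport", function(x) x@disposition)

#' @rdname QcReport
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname QcReport
#' @export
setMethod("qcFlags", "QcReport", function(x) x@flags)

#' @rdname QcReport
#' @export
setGeneric("qcVerdicts", function(x) standardGeneric("qcVerdicts"))

#' @rdname QcReport
#' @export
setMethod("qcVerdicts", "QcReport", function(x) x@verdicts)

#' @rdname QcReport
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname QcReport
#' @export
setMethod("filterLog", "QcReport", function(x) x@filters)

#' @rdname QcReport
#' @export
setGeneric("slopeFit", function(x) standardGeneric("slopeFit"))

#' @rdname QcReport
#' @export
setMethod("slopeFit", "QcReport", function(x) x@slope)

#' @rdname QcReport
#' @export
setGeneric("recommendations", function(x) standardGeneric("recommendations"))

#' @rdname QcReport
#' @export
setMethod("recommendations", "QcReport", function(x) x@recommendations)

setMethod("show", "QcReport", function(object) {
  cat("QcReport for:", object@metadata$trait_name %||% "unknown trait", "\n")
  cat("  disposition:", object@disposition, "\n")
  if (nrow(object@flags)) {
    tab <- table(object@flags$check, object@flags$level)
    cat("  flags:\n")
    print(tab)
  } else {
    cat("  flags: none\n")
  }
  if (nrow(object@verdicts)) {
    for (i in seq_len(nrow(object@verdicts))) {
      v <- object@verdicts[i, ]
      cat(sprintf("  %s: %s (conflict fraction %.3f, r = %s, n = %d)\n",
                  v$check, v$classification, v$conflict_fraction,
                  ifelse(is.na(v$correlation), "NA",
                         sprintf("%.3f", v$correlation)), v$n_compared))
    }
  }
  if (isTRUE(object@slope$assessable)) {
    cat(sprintf("  expected-vs-reported slope: %.3f%s (n = %d)\n",
                object@slope$slope,
                if (isTRUE(object@slope$flagged)) " [FLAGGED]" else "",
                object@slope$n))
  }
  if (isTRUE(object@pz$assessable)) {
    cat(sprintf("  P-Z correlation: %.6f%s\n", object@pz$r,
                if (isTRUE(object@pz$flagged)) " [FLAGGED]" else ""))
  }
  if (length(object@recommendations)) {
    cat("  recommendations:\n")
    for (r in object@recommendations) cat("   -", r, "\n")
  }
  invisible(NULL)
})
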