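## Readers and writers for the delimited-text formats the pipeline consumes:
## summary statistics, catalogue-style top hits, the consensus-MAF reference,
## LD tables and the cleaned outputs. All parsing is done by data.table::fread
## (TSV/CSV, optionally gzipped); this file only maps columns, normalizes
## missing-value tokens and enforces loader invariants.

.MISSING_TOKENS <- c("", "NA", "NaN", ".")

## coerce a raw column to numeric; counts unparsable cells and maps the
## accepted missing tokens to NA
.parseNumeric <- function(x, raw_name) {
  if (is.numeric(x)) return(list(x = as.numeric(x), bad = 0L, missing = sum(is.na(x))))
  x <- as.character(x)
  miss <- x %in% .MISSING_TOKENS | is.na(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    warning(sum(bad), " unparsable numeric cell(s) in column '", raw_name,
            "' set to missing", call. = FALSE)
  }
  list(x = out, bad = sum(bad), missing = sum(miss))
}

.OPTIONAL_FIELDS <- c("rsid", "chr", "pos", "other_allele", "eaf", "beta",
                      "se", "pval", "n", "n_cases", "n_controls", "info",
                      "hwe_p", "het_p", "n_studies", "scale",
                      "ci_lower", "ci_upper")

#' Read a GWAS summary-statistics file into a SumStatSet
#'
#' Loads a delimited text file (TSV/CSV, optionally gzipped) with an explicit
#' column map. Nothing is filtered at load time: the record count of the
#' returned object equals the data-row count of the file, rows keep file
#' order, and every mapped field records the raw column it came from.
#' Ambiguous headers (e.g. \code{A1}/\code{A2}) are never guessed at; they
#' must be mapped explicitly, because silently guessing the effect allele is
#' precisely the error mode this pipeline exists to detect.
#'
#' Canonical fields: \code{rsid, chr, pos, effect_allele, other_allele, eaf,
#' beta, se, pval, n, n_cases, n_controls, info, hwe_p, het_p, n_studies,
#' scale}, plus \code{ci_lower}/\code{ci_upper} which are carried along for
#' standard-error inference (\code{\link{inferSE}}). Positions are treated as
#' 1-based. Missing-value tokens accepted in numeric columns: empty string,
#' \code{NA}, \code{NaN}, \code{.}.
#'
#' @param path file path.
#' @param columnMap named character vector mapping canonical field -> raw
#'   column header. Raw headers that already match canonical names are picked
#'   up automatically. Must cover at least \code{rsid} or
#'   (\code{chr} and \code{pos}); \code{effect_allele}; \code{beta}; and one
#'   of \code{se}, \code{pval} or \code{ci_lower}+\code{ci_upper}.
#' @param traitName,traitType,ancestry,publicationId study metadata.
#' @param nTotal,nCasesTotal,nControlsTotal declared study-level sample
#'   sizes; fall back to the per-record maxima when omitted.
#' @param scale declared effect-size scale applied to all records when the
#'   file has no scale column: one of \code{"log_odds"},
#'   \code{"linear_risk"}, \code{"sd_units"}, \code{"unknown"}.
#' @return A \code{\link{SumStatSet-class}}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(rsid = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'              other_allele = c("G", "T"), Effect = c(0.1, -0.2),
#'              se = c(0.05, 0.07), eaf = c(0.3, 0.4)),
#'   f, sep = "\t", row.names = FALSE, quote = FALSE)
#' ss <- readSumStats(f, columnMap = c(beta = "Effect"),
#'                    traitName = "toy", traitType = "continuous",
#'                    nTotal = 1000)
#' nRecords(ss)
#' @export
readSumStats <- function(path, columnMap = character(0),
                         traitName = "unnamed trait",
                         traitType = c("continuous", "binary"),
                         ancestry = "unknown",
                         publicationId = NA_character_,
                         nTotal = NA_real_, nCasesTotal = NA_real_,
                         nControlsTotal = NA_real_,
                         scale = c("unknown", "log_odds", "linear_risk",
                                   "sd_units")) {
  traitType <- match.arg(traitType)
  scale <- match.arg(scale)
  raw <- as.data.frame(data.table::fread(path, na.strings = .MISSING_TOKENS,
                                         showProgress = FALSE))
  columnMap <- vapply(columnMap, as.character, character(1))

  ## resolve canonical field -> raw header, explicit map first, then identity
  fields <- c("effect_allele", .OPTIONAL_FIELDS)
  resolved <- character(0)
  for (f in fields) {
    if (f %in% names(columnMap)) {
      if (!columnMap[[f]] %in% names(raw)) {
        stop("configuration error: mapped column '", columnMap[[f]],
             "' for field '", f, "' not present in ", path)
      }
      resolved[f] <- columnMap[[f]]
    } else if (f %in% names(raw)) {
      resolved[f] <- f
    }
  }

  have <- names(resolved)
  if (!"effect_allele" %in% have) {
    stop("configuration error: required field 'effect_allele' is not mapped")
  }
  if (!("rsid" %in% have || all(c("chr", "pos") %in% have))) {
    stop("configuration error: need 'rsid' or both 'chr' and 'pos'")
  }
  if (!"beta" %in% have) {
    stop("configuration error: required field 'beta' is not mapped")
  }
  if (!("se" %in% have || "pval" %in% have ||
        all(c("ci_lower", "ci_upper") %in% have))) {
    stop("configuration error: need 'se', or 'pval', or a confidence ",
         "interval ('ci_lower' + 'ci_upper') to derive it")
  }

  n_rows <- nrow(raw)
  out <- list()
  char_fields <- c("rsid", "chr", "effect_allele", "other_allele", "scale")
  for (f in c(.SUMSTAT_COLS, "ci_lower", "ci_upper")) {
    if (f %in% have) {
      col <- raw[[resolved[[f]]]]
      if (f %in% char_fields) {
        out[[f]] <- as.character(col)
      } else {
        out[[f]] <- .parseNumeric(col, resolved[[f]])$x
      }
    } else {
      out[[f]] <- rep(if (f %in% char_fields) NA_character_ else NA_real_,
                      n_rows)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)

  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  if (all(is.na(out$scale))) out$scale <- scale

  bad_eaf <- !is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1)
  if (any(bad_eaf)) {
    warning(sum(bad_eaf), " record(s) with eaf outside [0, 1] set to missing",
            call. = FALSE)
    out$eaf[bad_eaf] <- NA_real_
  }
  bad_se <- !is.na(out$se) & out$se <= 0
  if (any(bad_se)) {
    warning(sum(bad_se), " record(s) with non-positive se set to missing",
            call. = FALSE)
    out$se[bad_se] <- NA_real_
  }

  provenance <- as.list(resolved)
  SumStatSet(out, traitName = traitName, traitType = traitType,
             ancestry = ancestry, publicationId = publicationId,
             maxN = nTotal, nCasesTotal = nCasesTotal,
             nControlsTotal = nControlsTotal, provenance = provenance)
}

#' Read a catalogue-style top-hits reference table
#'
#' Expected columns: \code{rsid, effect_allele, other_allele, beta, se, eaf,
#' pval, ancestry, publication_id} (\code{se} optional). Records missing the
#' effect size, the effect allele frequency or either allele are dropped, and
#' palindromic (A/T or C/G) records are dropped, since their strand cannot be
#' resolved for a direction comparison. Drop counts are attached as the
#' \code{"dropped"} attribute and reported via a message.
#'
#' @param path file path (TSV/CSV, optionally gzipped).
#' @return data.frame of retained top hits.
#' @export
readTopHits <- function(path) {
  raw <- as.data.frame(data.table::fread(path, na.strings = .MISSING_TOKENS,
                                         showProgress = FALSE))
  needed <- c("rsid", "effect_allele", "other_allele", "beta", "eaf", "pval")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("top-hits file lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"se" %in% names(raw)) raw$se <- NA_real_
  if (!"ancestry" %in% names(raw)) raw$ancestry <- NA_character_
  if (!"publication_id" %in% names(raw)) raw$publication_id <- NA_character_
  raw$effect_allele <- toupper(as.character(raw$effect_allele))
  raw$other_allele <- toupper(as.character(raw$other_allele))
  for (f in c("beta", "se", "eaf", "pval")) {
    raw[[f]] <- .parseNumeric(raw[[f]], f)$x
  }

  incomplete <- is.na(raw$beta) | is.na(raw$eaf) |
    is.na(raw$effect_allele) | is.na(raw$other_allele)
  palindromic <- !incomplete &
    isPalindromic(raw$effect_allele, raw$other_allele)
  keep <- !incomplete & !palindromic
  dropped <- c(incomplete = sum(incomplete), palindromic = sum(palindromic))
  if (any(dropped > 0)) {
    message("readTopHits: dropped ", dropped[["incomplete"]],
            " incomplete and ", dropped[["palindromic"]],
            " palindromic record(s)")
  }
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no usable top hits after filtering; downstream comparisons ",
            "will report 'not assessable'", call. = FALSE)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read a consensus minor-allele-frequency reference table
#'
#' The reference emulates a set of SNPs with the same minor allele across all
#' superpopulations and a minor allele frequency between 0.1 and 0.35 in each.
#' Expected columns: \code{rsid, minor_allele, major_allele} plus one numeric
#' MAF column per superpopulation (any names, e.g. \code{EUR, EAS, AFR, AMR,
#' SAS, GLOBAL}). Records violating the invariants (any population MAF above
#' 0.5 -- which would mean the minor allele differs in that population -- or
#' outside [0.1, 0.35]) are rejected with a per-record log entry.
#'
#' @param path file path.
#' @return data.frame of accepted records; rejected records (with a reason)
#'   are attached as the \code{"rejected"} attribute.
#' @export
readMafReference <- function(path) {
  raw <- as.data.frame(data.table::fread(path, na.strings = .MISSING_TOKENS,
                                         showProgress = FALSE))
  needed <- c("rsid", "minor_allele", "major_allele")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("MAF reference lacks column(s): ", paste(miss, collapse = ", "))
  }
  pop_cols <- setdiff(names(raw), needed)
  for (p in pop_cols) raw[[p]] <- .parseNumeric(raw[[p]], p)$x
  pop_cols <- pop_cols[vapply(raw[pop_cols], is.numeric, logical(1))]
  if (length(pop_cols) == 0) {
    stop("MAF reference has no per-population MAF columns")
  }
  raw$minor_allele <- toupper(as.character(raw$minor_allele))
  raw$major_allele <- toupper(as.character(raw$major_allele))

  mafs <- as.matrix(raw[pop_cols])
  over_half <- rowSums(mafs > 0.5, na.rm = TRUE) > 0
  out_of_band <- rowSums(mafs < 0.1 | mafs > 0.35, na.rm = TRUE) > 0
  any_missing <- rowSums(is.na(mafs)) > 0
  reason <- rep(NA_character_, nrow(raw))
  reason[any_missing] <- "missing MAF in at least one population"
  reason[out_of_band & is.na(reason)] <- "MAF outside [0.1, 0.35]"
  reason[over_half] <- "MAF > 0.5: minor allele not shared across populations"
  reject <- !is.na(reason)
  if (any(reject)) {
    message("readMafReference: rejected ", sum(reject), " record(s)")
  }
  rejected <- data.frame(rsid = raw$rsid[reject], reason = reason[reject],
                         stringsAsFactors = FALSE)
  out <- raw[!reject, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  attr(out, "populations") <- pop_cols
  out
}

#' Read a pairwise LD table
#'
#' Three columns: \code{rsid_a, rsid_b, r2}. Pairs are treated as symmetric
#' at lookup; absent pairs are treated as r-squared 0 (independent).
#'
#' @param path file path.
#' @return data.frame with columns \code{rsid_a, rsid_b, r2}.
#' @export
readLdTable <- function(path) {
  ld <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  miss <- setdiff(c("rsid_a", "rsid_b", "r2"), names(ld))
  if (length(miss)) {
    stop("LD table lacks column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !is.na(ld$r2) & (ld$r2 < 0 | ld$r2 > 1)
  if (any(bad)) stop("LD table contains r2 outside [0, 1]")
  ld
}

#' Write the QC outputs for one data set
#'
#' Emits the cleaned summary-statistics table (TSV with canonical headers),
#' the flag table (TSV), the aggregate report (JSON) and the diagnostic plots.
#' Re-reading the cleaned TSV with \code{\link{readSumStats}} reproduces the
#' table field-for-field.
#'
#' @param report a \code{\link{QcReport-class}}.
#' @param sset the (cleaned) \code{\link{SumStatSet-class}} to write.
#' @param outdir output directory, created if needed.
#' @param plots logical; also render the diagnostic panels.
#' @return Invisibly, a named character vector of the files written.
#' @export
writeOutputs <- function(report, sset, outdir, plots = TRUE) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output dir: ", outdir)
  }
  files <- c(
    sumstats = file.path(outdir, "cleaned_sumstats.tsv"),
    flags = file.path(outdir, "qc_flags.tsv"),
    report = file.path(outdir, "qc_report.json")
  )
  d <- ssData(sset)[, .SUMSTAT_COLS, drop = FALSE]
  data.table::fwrite(d, files[["sumstats"]], sep = "\t", na = "NA",
                     quote = FALSE)
  data.table::fwrite(qcFlags(report), files[["flags"]], sep = "\t",
                     na = "NA", quote = FALSE)
  jsonlite::write_json(reportToJSON(report), files[["report"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  if (plots) {
    plot_files <- renderPlots(report, outdir)
    files <- c(files, plot_files)
  }
  invisible(files)
}
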