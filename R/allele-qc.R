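## Metadata checks on the effect allele and effect allele frequency columns:
## direction-of-effect comparison against catalogue-style top hits, frequency
## comparison against top hits, recoded-frequency comparison against a
## consensus-MAF reference, data set level pattern classification, and
## descriptive per-superpopulation frequency correlations.

.flagRow <- function(check, rsid, level, reason) {
  data.frame(check = check, rsid = rsid, level = level, reason = reason,
             stringsAsFactors = FALSE)
}

.verdictRow <- function(check, classification, conflict_fraction,
                        correlation, n_compared, note = "") {
  data.frame(check = check, classification = classification,
             conflict_fraction = conflict_fraction,
             correlation = correlation, n_compared = as.integer(n_compared),
             note = note, stringsAsFactors = FALSE)
}

## merge a SumStatSet with a top-hits table on rsid and harmonize to the
## top-hit effect allele; returns one row per comparable pair
.pairWithTopHits <- function(sset, tophits) {
  d <- ssData(sset)
  th <- tophits[!duplicated(tophits$rsid), , drop = FALSE]
  idx <- match(d$rsid, th$rsid)
  use <- !is.na(idx)
  if (!any(use)) return(NULL)
  d <- d[use, , drop = FALSE]
  th <- th[idx[use], , drop = FALSE]
  h <- suppressWarnings(harmonizeAlleles(
    d$effect_allele, d$other_allele, d$beta, d$eaf,
    th$effect_allele, th$other_allele))
  data.frame(
    rsid = d$rsid, action = h$action,
    beta_test = h$beta, eaf_test = h$eaf, se_test = d$se, p_test = d$pval,
    beta_ref = th$beta, se_ref = th$se, eaf_ref = th$eaf, p_ref = th$pval,
    publication_ref = th$publication_id, stringsAsFactors = FALSE)
}

#' Check effect directions against catalogue-style top hits
#'
#' For every SNP shared with the top-hits reference (after harmonization to
#' the same effect allele; palindromic and irreconcilable pairs are
#' excluded), a conflict is declared when the harmonized test effect and the
#' reference effect have opposite signs. The conflict is \code{high} when
#' the association P-value is below \code{p_both_threshold} (default 1e-4)
#' in \emph{both} data sets, and \code{moderate} otherwise -- weak
#' associations can flip sign by chance in small studies. If the test data
#' set and the reference hits come from the same publication, every conflict
#' is \code{high} regardless of P-values.
#'
#' The data set verdict classifies the pattern: \code{systematic_flip} when
#' at least \code{pattern_flip_fraction} of at least
#' \code{min_direction_snps} comparable SNPs conflict and at least half of
#' the conflicts are high (strong evidence that the effect allele column
#' refers to the non-effect allele); \code{consistent} when at most
#' \code{pattern_consistent_fraction} conflict; otherwise \code{ambiguous}.
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @param tophits top-hits data.frame (see \code{\link{readTopHits}}).
#' @param samePublication logical: does the test data set correspond to the
#'   same publication as the reference hits?
#' @param config threshold list, see \code{\link{qcDefaults}}.
#' @return list with \code{flags} (conflict flags), \code{verdict}
#'   (one-row data.frame) and \code{data} (per-pair scatter data).
#' @export
checkDirectionVsTopHits <- function(sset, tophits, samePublication = FALSE,
                                    config = qcDefaults()) {
  pairs <- if (is.null(tophits) || nrow(tophits) == 0) NULL else
    .pairWithTopHits(sset, tophits)
  empty_verdict <- .verdictRow("direction_vs_tophits", "ambiguous",
                               NA_real_, NA_real_, 0L,
                               "no comparable SNPs")
  if (is.null(pairs)) {
    return(list(flags = emptyFlags(), verdict = empty_verdict, data = NULL))
  }
  ok <- pairs$action != "incompatible" & !is.na(pairs$beta_test) &
    !is.na(pairs$beta_ref) & pairs$beta_test != 0 & pairs$beta_ref != 0
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  if (n == 0) {
    return(list(flags = emptyFlags(), verdict = empty_verdict, data = NULL))
  }

  conflict <- sign(pairs$beta_test) != sign(pairs$beta_ref)
  strong_both <- !is.na(pairs$p_test) & !is.na(pairs$p_ref) &
    pairs$p_test < config$p_both_threshold &
    pairs$p_ref < config$p_both_threshold
  level <- ifelse(strong_both | samePublication, "high", "moderate")
  reason <- ifelse(
    samePublication & conflict,
    "opposite effect directions; same publication, so graded high",
    sprintf(paste0("opposite effect directions (test beta %.4g, reference ",
                   "beta %.4g); p_test = %.3g, p_ref = %.3g (high requires ",
                   "both < %g)"),
            pairs$beta_test, pairs$beta_ref, pairs$p_test, pairs$p_ref,
            config$p_both_threshold))
  flags <- if (any(conflict)) {
    .flagRow("direction_vs_tophits", pairs$rsid[conflict],
             level[conflict], reason[conflict])
  } else emptyFlags()

  frac <- mean(conflict)
  z_test <- pairs$beta_test / pairs$se_test
  z_ref <- ifelse(is.na(pairs$se_ref), pairs$beta_ref,
                  pairs$beta_ref / pairs$se_ref)
  r <- if (n >= 3 && stats::sd(z_test) > 0 && stats::sd(z_ref) > 0)
    stats::cor(z_test, z_ref) else NA_real_
  high_frac <- if (any(conflict)) mean(level[conflict] == "high") else 0
  classification <-
    if (n < config$min_direction_snps) "ambiguous"
    else if (frac <= config$pattern_consistent_fraction) "consistent"
    else if (frac >= config$pattern_flip_fraction && high_frac >= 0.5)
      "systematic_flip"
    else "ambiguous"
  note <- if (n < config$min_direction_snps)
    sprintf("only %d comparable SNPs (minimum %d)", n,
            config$min_direction_snps) else ""
  verdict <- .verdictRow("direction_vs_tophits", classification, frac, r, n,
                         note)
  pairs$z_test <- z_test
  pairs$z_ref <- z_ref
  pairs$conflict <- conflict
  pairs$level <- ifelse(conflict, level, "none")
  list(flags = flags, verdict = verdict, data = pairs)
}

#' Check effect allele frequencies against top hits
#'
#' After harmonizing to the same effect allele, a conflict is declared when
#' the effect allele frequency is not on the same side of 0.5 in both data
#' sets. The conflict is \code{high} when the minor allele frequency is at
#' or below \code{maf_high_bound} (default 0.4) in both data sets --
#' frequencies close to 0.5 can cross sides by chance -- and
#' \code{moderate} otherwise. Independently of sides, a difference of more
#' than \code{freq_diff_points} (default ten percentage points) between the
#' two frequencies is declared a \code{high} conflict. A frequency of
#' exactly 0.5 on either side is treated as having no side (level
#' \code{none}, with a note).
#'
#' @inheritParams checkDirectionVsTopHits
#' @return list with \code{flags} and \code{data} (per-pair frequencies).
#' @export
checkEafVsTopHits <- function(sset, tophits, config = qcDefaults()) {
  pairs <- if (is.null(tophits) || nrow(tophits) == 0) NULL else
    .pairWithTopHits(sset, tophits)
  if (is.null(pairs)) return(list(flags = emptyFlags(), data = NULL))
  ok <- pairs$action != "incompatible" & !is.na(pairs$eaf_test) &
    !is.na(pairs$eaf_ref)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) return(list(flags = emptyFlags(), data = NULL))

  et <- pairs$eaf_test
  er <- pairs$eaf_ref
  on_half <- et == 0.5 | er == 0.5
  opposite <- !on_half & ((et - 0.5) * (er - 0.5) < 0)
  maf_t <- pmin(et, 1 - et)
  maf_r <- pmin(er, 1 - er)
  both_low_maf <- maf_t <= config$maf_high_bound &
    maf_r <= config$maf_high_bound
  big_diff <- abs(et - er) > config$freq_diff_points

  level <- rep("none", nrow(pairs))
  reason <- rep("", nrow(pairs))
  level[opposite] <- ifelse(both_low_maf[opposite], "high", "moderate")
  reason[opposite] <- sprintf(
    paste0("EAF on opposite sides of 0.5 (test %.3f, reference %.3f); ",
           "MAF %.3f / %.3f (high requires both <= %g)"),
    et[opposite], er[opposite], maf_t[opposite], maf_r[opposite],
    config$maf_high_bound)
  up <- big_diff & !on_half
  level[up] <- "high"
  reason[up] <- paste0(
    ifelse(nchar(reason[up]) > 0, paste0(reason[up], "; "), ""),
    sprintf("frequencies differ by %.1f points (> %g-point bound)",
            100 * abs(et[up] - er[up]), 100 * config$freq_diff_points))
  reason[on_half] <- "EAF exactly 0.5: no side, not assessable"

  emit <- level != "none" | on_half
  flags <- if (any(emit)) {
    .flagRow("eaf_vs_tophits", pairs$rsid[emit], level[emit], reason[emit])
  } else emptyFlags()
  pairs$level <- level
  list(flags = flags, data = pairs)
}

## recode the frequencies of a SumStatSet to the reference minor allele;
## returns one row per overlapping, resolvable SNP
.recodedFrequencies <- function(sset, mafRef, population = "consensus") {
  d <- ssData(sset)
  pops <- attr(mafRef, "populations") %||%
    setdiff(names(mafRef), c("rsid", "minor_allele", "major_allele"))
  idx <- match(d$rsid, mafRef$rsid)
  use <- !is.na(idx)
  if (!any(use)) return(NULL)
  d <- d[use, , drop = FALSE]
  ref <- mafRef[idx[use], , drop = FALSE]
  recoded <- recodeToMinor(d$effect_allele, d$other_allele, d$eaf,
                           ref$minor_allele, ref$major_allele)
  ref_maf <- if (population %in% pops) {
    ref[[population]]
  } else {
    rowMeans(as.matrix(ref[pops]), na.rm = TRUE)  # consensus
  }
  out <- data.frame(rsid = d$rsid, recoded = recoded, ref_maf = ref_maf,
                    stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("maf_", p)]] <- ref[[p]]
  out[!is.na(out$recoded), , drop = FALSE]
}

#' Check recoded frequencies against the consensus-MAF reference
#'
#' Frequencies are recoded to the reference minor allele
#' (\code{\link{recodeToMinor}}); the recoded frequency of a correctly coded
#' data set should be a minor allele frequency, i.e. below 0.5. A conflict
#' is declared per SNP when the recoded frequency exceeds 0.5; it is
#' \code{high} at or above \code{maf_ref_high} (default 0.58, making
#' allowance for chance deviations) and \code{moderate} below. A recoded
#' frequency differing from the reference MAF by more than
#' \code{freq_diff_points} is also \code{high}; the final level is the
#' maximum over applicable rules.
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @param mafRef MAF reference (see \code{\link{readMafReference}}).
#' @param population superpopulation column to compare against, or
#'   \code{"consensus"} (mean over populations).
#' @param config threshold list.
#' @return list with \code{flags} and \code{data} (per-SNP recoded
#'   frequencies and reference MAFs; NULL when no rsids overlap).
#' @export
checkMafVsReference <- function(sset, mafRef, population = "consensus",
                                config = qcDefaults()) {
  rec <- .recodedFrequencies(sset, mafRef, population)
  if (is.null(rec) || nrow(rec) == 0) {
    return(list(flags = emptyFlags(), data = NULL))
  }
  conflict <- rec$recoded > 0.5
  high_freq <- rec$recoded >= config$maf_ref_high
  big_diff <- abs(rec$recoded - rec$ref_maf) > config$freq_diff_points
  level <- rep("none", nrow(rec))
  level[conflict] <- ifelse(high_freq[conflict], "high", "moderate")
  level[big_diff] <- "high"      # severity = max over rules
  reason <- sprintf(
    paste0("recoded minor-allele frequency %.3f vs reference MAF %.3f",
           " (conflict if > 0.5; high if >= %g or difference > %g points)"),
    rec$recoded, rec$ref_maf, config$maf_ref_high,
    100 * config$freq_diff_points)
  emit <- level != "none"
  flags <- if (any(emit)) {
    .flagRow("maf_vs_reference", rec$rsid[emit], level[emit], reason[emit])
  } else emptyFlags()
  rec$level <- level
  list(flags = flags, data = rec)
}

#' Classify the data set level frequency pattern
#'
#' Operationalizes the visual inspection of the recoded-frequency scatter
#' plot. With conflict fraction \code{f} (share of recoded frequencies above
#' 0.5) and Pearson correlation \code{r} between recoded and reference MAF:
#' \code{systematic_flip} when \code{f >= 0.8} and \code{r <= -0.5} (the
#' reported EAF corresponds to the non-effect allele across the vast
#' majority of SNPs); \code{maf_coded} when \code{0.3 <= f <= 0.7} and both
#' the non-conflicting subset and the reflected (1 - recoded) conflicting
#' subset correlate at least +0.5 with the reference (the reported column is
#' a minor allele frequency and the minor allele is not consistently the
#' effect allele); \code{consistent} when \code{f <= 0.05} and
#' \code{r >= 0.5}; otherwise \code{ambiguous}. Fewer than
#' \code{min_pattern_snps} (default 20) overlapping SNPs give
#' \code{ambiguous} with a note.
#'
#' @param recoded numeric vector of recoded minor-allele frequencies.
#' @param refMaf matched reference MAFs.
#' @param config threshold list.
#' @return One-row verdict data.frame (\code{check = "maf_vs_reference"}).
#' @export
classifyFrequencyPattern <- function(recoded, refMaf, config = qcDefaults()) {
  keep <- !is.na(recoded) & !is.na(refMaf)
  recoded <- recoded[keep]
  refMaf <- refMaf[keep]
  n <- length(recoded)
  if (n < config$min_pattern_snps) {
    return(.verdictRow("maf_vs_reference", "ambiguous", NA_real_, NA_real_,
                       n, sprintf("only %d overlapping SNPs (minimum %d)",
                                  n, config$min_pattern_snps)))
  }
  frac <- mean(recoded > 0.5)
  r <- if (stats::sd(recoded) > 0 && stats::sd(refMaf) > 0)
    stats::cor(recoded, refMaf) else NA_real_
  safe_cor <- function(x, y) {
    if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      stats::cor(x, y) else NA_real_
  }
  cls <- "ambiguous"
  if (!is.na(r) && frac >= config$pattern_flip_fraction &&
      r <= -config$pattern_cor_min) {
    cls <- "systematic_flip"
  } else if (frac >= config$pattern_mafcoded_range[1] &&
             frac <= config$pattern_mafcoded_range[2]) {
    conf <- recoded > 0.5
    r_ok <- safe_cor(recoded[!conf], refMaf[!conf])
    r_conf <- safe_cor(1 - recoded[conf], refMaf[conf])
    if (!is.na(r_ok) && !is.na(r_conf) &&
        r_ok >= config$pattern_cor_min && r_conf >= config$pattern_cor_min) {
      cls <- "maf_coded"
    }
  } else if (!is.na(r) && frac <= config$pattern_consistent_fraction &&
             r >= config$pattern_cor_min) {
    cls <- "consistent"
  }
  .verdictRow("maf_vs_reference", cls, frac, r, n)
}

#' Per-superpopulation frequency correlations
#'
#' Pearson correlation of the recoded test frequencies with each reference
#' superpopulation MAF column, sorted descending. Reported descriptively --
#' a markedly higher correlation with one superpopulation is information on
#' the ancestral background of the test data set -- and never used to
#' exclude.
#'
#' @param recodedData data.frame from \code{checkMafVsReference()$data}
#'   (columns \code{recoded} and \code{maf_<POP>}).
#' @param minSnps minimum overlapping SNPs (default 20); fewer returns an
#'   empty result.
#' @return Named numeric vector of correlations, descending (NA where the
#'   correlation is undefined, e.g. zero variance).
#' @export
ancestryCorrelations <- function(recodedData, minSnps = 20) {
  if (is.null(recodedData) || nrow(recodedData) < minSnps) {
    return(stats::setNames(numeric(0), character(0)))
  }
  pop_cols <- grep("^maf_", names(recodedData), value = TRUE)
  r <- vapply(pop_cols, function(p) {
    x <- recodedData$recoded
    y <- recodedData[[p]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < minSnps || stats::sd(x[keep]) == 0 ||
        stats::sd(y[keep]) == 0) return(NA_real_)
    stats::cor(x[keep], y[keep])
  }, numeric(1))
  names(r) <- sub("^maf_", "", pop_cols)
  r[order(-r, na.last = TRUE)]
}
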