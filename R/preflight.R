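## Pre-QC exclusions and field recovery: standard-error inference from
## confidence intervals or P-values, rsid resolution via local lookup tables,
## and the duplicate / triallelic / missing-data / minor-allele-count filters.
## Exclusions are logged, never fatal; conservation (input = retained +
## logged) holds by construction.

#' Infer standard errors from confidence intervals or P-values
#'
#' From a CI: \code{se = (high - low) / (2 * z)} with \code{z} the normal
#' quantile at \code{(1 + level) / 2}. From a P-value: \code{se = |beta| /
#' z_p} with \code{z_p} the two-sided normal quantile of \code{pval}; this is
#' undefined for \code{beta = 0}, in which case the result is missing (and
#' the record will later fall to the missing-SE exclusion). A CI is preferred
#' when both sources are available. Vectorized; elements with neither source
#' return missing.
#'
#' @param beta signed effect size(s).
#' @param ciLow,ciHigh confidence-interval bounds (optional).
#' @param level confidence level of the interval (default 0.95).
#' @param pval two-sided P-value(s) (optional).
#' @return Numeric vector of standard errors (NA where not derivable).
#' @examples
#' inferSE(0.5, ciLow = 0.304, ciHigh = 0.696)   # ~0.1
#' inferSE(0.2, pval = 0.0455)                    # ~0.1
#' @export
inferSE <- function(beta, ciLow = NULL, ciHigh = NULL, level = 0.95,
                    pval = NULL) {
  n <- length(beta)
  if (is.null(ciLow)) ciLow <- rep(NA_real_, n)
  if (is.null(ciHigh)) ciHigh <- rep(NA_real_, n)
  if (is.null(pval)) pval <- rep(NA_real_, n)
  stopifnot(length(ciLow) == n, length(ciHigh) == n, length(pval) == n)
  if (any(!is.na(pval) & (pval <= 0 | pval >= 1))) {
    stop("invalid input: pval must lie strictly in (0, 1)")
  }
  have_ci <- !is.na(ciLow) & !is.na(ciHigh)
  if (any(have_ci & ciHigh <= ciLow)) {
    stop("invalid input: ciHigh must exceed ciLow")
  }
  z_ci <- stats::qnorm((1 + level) / 2)
  se <- rep(NA_real_, n)
  se[have_ci] <- (ciHigh[have_ci] - ciLow[have_ci]) / (2 * z_ci)
  use_p <- !have_ci & !is.na(pval) & !is.na(beta) & beta != 0
  zp <- stats::qnorm(pval[use_p] / 2, lower.tail = FALSE)
  se[use_p] <- abs(beta[use_p]) / zp
  se
}

## fill missing standard errors of a SumStatSet in place, preferring CIs
.recoverSE <- function(sset, ciLevel = 0.95) {
  d <- ssData(sset)
  todo <- is.na(d$se)
  if (!any(todo)) return(sset)
  has_ci <- "ci_lower" %in% names(d) && "ci_upper" %in% names(d)
  lo <- if (has_ci) d$ci_lower[todo] else NULL
  hi <- if (has_ci) d$ci_upper[todo] else NULL
  pv <- d$pval[todo]
  pv[!is.na(pv) & (pv <= 0 | pv >= 1)] <- NA_real_
  d$se[todo] <- inferSE(d$beta[todo], ciLow = lo, ciHigh = hi,
                        level = ciLevel, pval = pv)
  setSS(sset, d)
}

#' Resolve rsids from positions and alias tables
#'
#' Records lacking an rsid are assigned one from a (chrom, pos) lookup; rsids
#' present in the alias table are rewritten to their canonical form (alias
#' identifiers arise from different genome builds carrying different rsids
#' for the same variant). Records that cannot be mapped -- no rsid and no
#' matching position, or a position mapping to more than one rsid -- are
#' excluded and logged under rule \code{unmappable_rsid}.
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @param positionLookup data.frame \code{chr, pos, rsid} or NULL.
#' @param aliasTable data.frame \code{alias, rsid} or NULL.
#' @return list with elements \code{table} (the updated SumStatSet) and
#'   \code{log} (data.frame \code{rule, rsid, detail}).
#' @export
assignRsids <- function(sset, positionLookup = NULL, aliasTable = NULL) {
  d <- ssData(sset)
  no_rsid <- is.na(d$rsid) | d$rsid %in% .MISSING_TOKENS
  reason <- rep(NA_character_, nrow(d))
  if (any(no_rsid)) {
    key_d <- paste(d$chr, d$pos, sep = ":")
    have_pos <- !is.na(d$chr) & !is.na(d$pos)
    if (!is.null(positionLookup)) {
      key <- paste(positionLookup$chr, positionLookup$pos, sep = ":")
      multi <- names(which(table(key) > 1))
      hit <- match(key_d, key)
      ambiguous <- no_rsid & have_pos & key_d %in% multi
      mapped <- no_rsid & have_pos & !ambiguous & !is.na(hit)
      d$rsid[mapped] <- positionLookup$rsid[hit[mapped]]
      reason[ambiguous] <- paste0("position ", key_d[ambiguous],
                                  " maps to multiple rsids")
      unmatched <- no_rsid & have_pos & !ambiguous & is.na(hit)
      reason[unmatched] <- paste0("position ", key_d[unmatched],
                                  " absent from lookup")
    }
    reason[no_rsid & !have_pos] <- "no rsid and no usable position"
  }
  drop <- !is.na(reason)
  log <- if (any(drop)) {
    data.frame(rule = "unmappable_rsid", rsid = NA_character_,
               detail = reason[drop], stringsAsFactors = FALSE)
  } else emptyFilterLog()
  d <- d[!drop, , drop = FALSE]
  if (!is.null(aliasTable) && nrow(d)) {
    hit <- match(d$rsid, aliasTable$alias)
    sub <- !is.na(hit)
    d$rsid[sub] <- aliasTable$rsid[hit[sub]]
  }
  rownames(d) <- NULL
  list(table = setSS(sset, d), log = log)
}

#' Apply the pre-QC exclusion rules
#'
#' Removes, in order: all records of any rsid observed with more than two
#' distinct alleles (\code{triallelic}) or appearing more than once with the
#' same allele pair (\code{duplicate}; every copy is removed, since keeping
#' an arbitrary copy risks silent errors); records with missing effect size
#' or standard error (\code{missing_beta_se}, after standard-error recovery
#' via \code{\link{inferSE}}); and, for binary traits, records whose minor
#' allele count \code{2 * N_group * min(eaf, 1 - eaf)} is below
#' \code{macMin} in either cases or controls (\code{low_mac}). The
#' real-valued count is compared, without rounding. Records with missing EAF
#' skip the MAC rule and are noted, not excluded. Per-record group counts
#' fall back to the table-level declared counts.
#'
#' Conservation holds: input records = retained records + log rows. The
#' operation is idempotent.
#'
#' @param sset a \code{\link{SumStatSet-class}} (rsids resolved).
#' @param macMin minor-allele-count threshold (default 50).
#' @param ciLevel confidence level assumed when recovering SEs from CIs.
#' @return list with \code{table} (filtered SumStatSet), \code{log}
#'   (data.frame \code{rule, rsid, detail}) and \code{notes} (data.frame of
#'   non-excluding observations, e.g. EAF missing so MAC not assessable).
#' @export
applyExclusions <- function(sset, macMin = 50, ciLevel = 0.95) {
  sset <- .recoverSE(sset, ciLevel = ciLevel)
  d <- ssData(sset)
  n_in <- nrow(d)
  logs <- list()
  notes <- list()

  ## duplicate / triallelic: group records by rsid
  allele_key <- paste(pmin(d$effect_allele, d$other_allele),
                      pmax(d$effect_allele, d$other_allele), sep = "/")
  rsid_count <- table(d$rsid)
  multi <- d$rsid %in% names(rsid_count)[rsid_count > 1]
  if (any(multi)) {
    split_alleles <- split(c(d$effect_allele[multi], d$other_allele[multi]),
                           rep(d$rsid[multi], 2))
    n_alleles <- vapply(split_alleles, function(a)
      length(unique(stats::na.omit(a))), integer(1))
    tri_rsids <- names(n_alleles)[n_alleles > 2]
    pair_key <- paste(d$rsid, allele_key)
    pair_dup <- pair_key %in% names(which(table(pair_key[multi]) > 1))
    is_tri <- multi & d$rsid %in% tri_rsids & !pair_dup
    is_dup <- multi & !is_tri
    if (any(is_tri)) {
      logs[[length(logs) + 1L]] <- data.frame(
        rule = "triallelic", rsid = d$rsid[is_tri],
        detail = paste0("rsid observed with >2 distinct alleles (",
                        allele_key[is_tri], ")"),
        stringsAsFactors = FALSE)
    }
    if (any(is_dup)) {
      logs[[length(logs) + 1L]] <- data.frame(
        rule = "duplicate", rsid = d$rsid[is_dup],
        detail = paste0("rsid appears ", as.integer(rsid_count[d$rsid[is_dup]]),
                        " times; all copies removed"),
        stringsAsFactors = FALSE)
    }
    d <- d[!multi, , drop = FALSE]
  }

  ## missing effect size or standard error (after recovery attempts)
  miss <- is.na(d$beta) | is.na(d$se)
  if (any(miss)) {
    logs[[length(logs) + 1L]] <- data.frame(
      rule = "missing_beta_se", rsid = d$rsid[miss],
      detail = ifelse(is.na(d$beta[miss]), "missing effect size",
                      "missing standard error (not derivable)"),
      stringsAsFactors = FALSE)
    d <- d[!miss, , drop = FALSE]
  }

  ## minor allele count, binary traits only
  if (traitType(sset) == "binary" && nrow(d)) {
    nca <- ifelse(is.na(d$n_cases), sset@nCasesTotal, d$n_cases)
    nco <- ifelse(is.na(d$n_controls), sset@nControlsTotal, d$n_controls)
    maf <- pmin(d$eaf, 1 - d$eaf)
    no_eaf <- is.na(d$eaf)
    no_counts <- is.na(nca) | is.na(nco)
    mac_cases <- 2 * nca * maf
    mac_controls <- 2 * nco * maf
    low <- !no_eaf & !no_counts &
      (mac_cases < macMin | mac_controls < macMin)
    if (any(low)) {
      logs[[length(logs) + 1L]] <- data.frame(
        rule = "low_mac", rsid = d$rsid[low],
        detail = sprintf("MAC cases %.1f / controls %.1f < %g",
                         mac_cases[low], mac_controls[low], macMin),
        stringsAsFactors = FALSE)
      d <- d[!low, , drop = FALSE]
      no_eaf <- no_eaf[!low]
      no_counts <- no_counts[!low]
    }
    skipped <- no_eaf | no_counts
    if (any(skipped)) {
      notes[[length(notes) + 1L]] <- data.frame(
        rsid = d$rsid[skipped],
        note = ifelse(no_eaf[skipped],
                      "EAF missing: MAC rule not assessable",
                      "group counts missing: MAC rule not assessable"),
        stringsAsFactors = FALSE)
    }
  }

  log <- if (length(logs)) do.call(rbind, logs) else emptyFilterLog()
  notes <- if (length(notes)) do.call(rbind, notes) else
    data.frame(rsid = character(0), note = character(0),
               stringsAsFactors = FALSE)
  rownames(d) <- NULL
  stopifnot(nrow(d) + nrow(log) == n_in)
  list(table = setSS(sset, d), log = log, notes = notes)
}
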