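## Instrument construction and validation: greedy LD clumping of the test
## data set, comparison of index SNPs to a known-hits table within a
## base-pair window, and proxy discovery. Local LD tables are sparse, so
## missing pairs are treated as r2 = 0 (independent).

## symmetric r2 lookup table from a pair list
.ldLookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  r2 <- c(ld$r2, ld$r2)
  keys <- c(paste(ld$rsid_a, ld$rsid_b, sep = "\r"),
            paste(ld$rsid_b, ld$rsid_a, sep = "\r"))
  stats::setNames(r2, keys)
}

.ldR2 <- function(lookup, a, b) {
  r2 <- unname(lookup[paste(a, b, sep = "\r")])
  r2[is.na(r2)] <- 0
  r2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-P unassigned SNP below \code{pThreshold} as
#' an index SNP and assigns to it every unassigned SNP on the same
#' chromosome within \code{kbWindow} kilobases (index-to-candidate,
#' inclusive) whose r-squared with the index is at least
#' \code{r2Threshold}. Ties in P are broken by (chromosome, position, rsid).
#' Every sub-threshold SNP ends up exactly once, as an index or as a member
#' of exactly one index. An empty result (no SNP below the threshold) is
#' valid.
#'
#' @param sset a \code{\link{SumStatSet-class}} with P-values and positions.
#' @param ld LD pair data.frame (\code{rsid_a, rsid_b, r2}); absent pairs
#'   count as r2 = 0.
#' @param pThreshold significance threshold for index selection.
#' @param r2Threshold clumping r-squared threshold (default 0.01).
#' @param kbWindow clumping window in kilobases (default 10000).
#' @return list of class \code{"ClumpResult"}: \code{index_snps} (data.frame
#'   \code{rsid, chr, pos, pval}, ascending P), \code{members} (named list
#'   index rsid -> clumped-away rsids) and \code{params}.
#' @export
ldClump <- function(sset, ld = NULL, pThreshold = 5e-8,
                    r2Threshold = 0.01, kbWindow = 10000) {
  d <- ssData(sset)
  cand <- d[!is.na(d$pval) & d$pval < pThreshold, , drop = FALSE]
  cand <- cand[order(cand$pval, cand$chr, cand$pos, cand$rsid), ,
               drop = FALSE]
  lookup <- .ldLookup(ld)
  assigned <- rep(FALSE, nrow(cand))
  index <- integer(0)
  members <- list()
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    assigned[i] <- TRUE
    index <- c(index, i)
    rest <- which(!assigned)
    if (length(rest)) {
      same_chr <- !is.na(cand$chr[rest]) & !is.na(cand$chr[i]) &
        cand$chr[rest] == cand$chr[i]
      within <- same_chr & !is.na(cand$pos[rest]) & !is.na(cand$pos[i]) &
        abs(cand$pos[rest] - cand$pos[i]) <= kbWindow * 1000
      r2 <- .ldR2(lookup, cand$rsid[i], cand$rsid[rest])
      take <- within & r2 >= r2Threshold
      if (any(take)) {
        members[[cand$rsid[i]]] <- cand$rsid[rest[take]]
        assigned[rest[take]] <- TRUE
      } else {
        members[[cand$rsid[i]]] <- character(0)
      }
    } else {
      members[[cand$rsid[i]]] <- character(0)
    }
  }
  structure(list(
    index_snps = data.frame(rsid = cand$rsid[index], chr = cand$chr[index],
                            pos = cand$pos[index], pval = cand$pval[index],
                            stringsAsFactors = FALSE),
    members = members,
    params = list(p_threshold = pThreshold, r2_threshold = r2Threshold,
                  kb_window = kbWindow,
                  window_convention = "index-to-candidate, inclusive")),
    class = "ClumpResult")
}

#' Compare clump index SNPs with a known-hits table
#'
#' An index SNP is \code{known} when its rsid appears in the known-hits
#' table, \code{near_known} when any known hit lies within \code{bpWindow}
#' base pairs on the same chromosome, and \code{novel} otherwise. Index SNPs
#' without a position get status \code{undetermined}. The data set is
#' flagged for further investigation when any index SNP is novel: apparent
#' hits absent from the catalogue are a signature of false positives from
#' unfiltered low-quality variants (though a larger-than-published study can
#' produce genuine novel hits).
#'
#' @param clump a \code{"ClumpResult"} from \code{\link{ldClump}}, or a
#'   data.frame with \code{rsid, chr, pos}.
#' @param knownHits data.frame \code{rsid, chr, pos}.
#' @param bpWindow window in base pairs (default 200000).
#' @return list with \code{status} (data.frame \code{rsid, status,
#'   nearest_known}) and \code{flagged} (any novel index SNP).
#' @export
compareIndexToKnown <- function(clump, knownHits, bpWindow = 200000) {
  idx <- if (inherits(clump, "ClumpResult")) clump$index_snps else clump
  n <- nrow(idx)
  status <- rep("novel", n)
  nearest <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (idx$rsid[i] %in% knownHits$rsid) {
      status[i] <- "known"
      nearest[i] <- idx$rsid[i]
      next
    }
    if (is.na(idx$pos[i]) || is.na(idx$chr[i])) {
      status[i] <- "undetermined"
      next
    }
    same <- !is.na(knownHits$chr) & knownHits$chr == idx$chr[i] &
      !is.na(knownHits$pos)
    if (any(same)) {
      dist <- abs(knownHits$pos[same] - idx$pos[i])
      if (min(dist) <= bpWindow) {
        status[i] <- "near_known"
        nearest[i] <- knownHits$rsid[same][which.min(dist)]
      }
    }
  }
  list(status = data.frame(rsid = idx$rsid, status = status,
                           nearest_known = nearest,
                           stringsAsFactors = FALSE),
       flagged = any(status %in% c("novel", "undetermined")))
}

#' Find proxy SNPs for a query rsid
#'
#' All SNPs in the LD table with r-squared at least \code{r2Min} (default
#' 0.8) with the query, sorted by descending r-squared; the query itself is
#' excluded. An rsid absent from the LD table returns an empty result with a
#' note attribute.
#'
#' @param rsid query rsid.
#' @param ld LD pair data.frame (\code{rsid_a, rsid_b, r2}).
#' @param r2Min minimum r-squared.
#' @return data.frame \code{rsid, r2}, descending r2.
#' @export
findProxies <- function(rsid, ld, r2Min = 0.8) {
  hit_a <- ld$rsid_a == rsid
  hit_b <- ld$rsid_b == rsid
  partners <- c(ld$rsid_b[hit_a], ld$rsid_a[hit_b])
  r2 <- c(ld$r2[hit_a], ld$r2[hit_b])
  if (length(partners) == 0) {
    out <- data.frame(rsid = character(0), r2 = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "note") <- paste0("rsid ", rsid, " absent from LD table")
    return(out)
  }
  keep <- !is.na(r2) & r2 >= r2Min & partners != rsid
  out <- data.frame(rsid = partners[keep], r2 = r2[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$rsid), , drop = FALSE]
  out <- out[order(-out$r2, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
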