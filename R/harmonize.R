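## Allele harmonization: orient test-data effect sizes and frequencies to a
## reference allele pair, detect palindromes, complement strands where a
## direct match fails, and recode frequencies to a reference minor allele.

.BASES <- c("A", "C", "G", "T")

#' Complement single-base alleles
#'
#' A<->T, C<->G. Tokens that are not a single base (indel codes, multi-base
#' strings) are returned unchanged: indels are carried through the pipeline
#' but excluded from strand logic.
#'
#' @param allele character vector of allele tokens.
#' @return Character vector of complemented alleles.
#' @export
complementAllele <- function(allele) {
  single <- !is.na(allele) & allele %in% .BASES
  out <- allele
  out[single] <- chartr("ACGT", "TGCA", allele[single])
  out
}

#' Is an allele pair palindromic?
#'
#' TRUE iff the unordered pair is {A,T} or {C,G}: such variants are their own
#' strand complement, so strand orientation cannot be resolved from the
#' alleles alone. Indel or multi-base tokens are never palindromic (a warning
#' is raised for them).
#'
#' @param a1,a2 allele vectors.
#' @return Logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  nonbase <- (!is.na(a1) & !a1 %in% .BASES) | (!is.na(a2) & !a2 %in% .BASES)
  if (any(nonbase)) {
    warning(sum(nonbase), " non-single-base allele pair(s) treated as ",
            "non-palindromic", call. = FALSE)
  }
  out <- !is.na(a1) & !is.na(a2) & a2 == complementAllele(a1) & !nonbase
  out
}

#' Harmonize test records to a reference allele pair
#'
#' Re-expresses test effect sizes and frequencies on the reference effect
#' allele. Matching is attempted directly first; strand complementing is
#' applied only when direct matching fails (minimizing spurious flips).
#' Actions: \code{none} (already aligned), \code{swap} (alleles swapped:
#' beta negated, eaf reflected to 1 - eaf), \code{strand_flip} (aligned
#' after complementing; values unchanged), \code{swap_and_flip},
#' \code{incompatible} (allele sets irreconcilable, or palindromic -- strand
#' unresolvable -- so the pair is excluded from downstream comparison).
#'
#' Harmonizing twice against the same reference is a no-op.
#'
#' @param testEffect,testOther test-data allele vectors.
#' @param beta,eaf test-data effect sizes and effect-allele frequencies.
#' @param refEffect,refOther reference allele vectors.
#' @return data.frame with columns \code{action, beta, eaf} (values
#'   re-expressed on the reference effect allele; NA for incompatible pairs).
#' @export
harmonizeAlleles <- function(testEffect, testOther, beta, eaf,
                             refEffect, refOther) {
  n <- length(testEffect)
  stopifnot(length(testOther) == n, length(refEffect) == n,
            length(refOther) == n)
  beta <- rep_len(as.numeric(beta), n)
  eaf <- rep_len(as.numeric(eaf), n)

  pal <- suppressWarnings(isPalindromic(testEffect, testOther))
  cE <- complementAllele(testEffect)
  cO <- complementAllele(testOther)

  direct <- testEffect == refEffect & testOther == refOther
  swapped <- testEffect == refOther & testOther == refEffect
  flipped <- cE == refEffect & cO == refOther
  swap_flip <- cE == refOther & cO == refEffect

  action <- rep("incompatible", n)
  action[flipped %in% TRUE] <- "strand_flip"
  action[swap_flip %in% TRUE] <- "swap_and_flip"
  action[direct %in% TRUE] <- "none"      # direct match takes precedence
  action[swapped %in% TRUE] <- "swap"
  action[pal %in% TRUE] <- "incompatible"
  action[is.na(testEffect) | is.na(testOther) |
           is.na(refEffect) | is.na(refOther)] <- "incompatible"

  out_beta <- beta
  out_eaf <- eaf
  sw <- action %in% c("swap", "swap_and_flip")
  out_beta[sw] <- -beta[sw]
  out_eaf[sw] <- 1 - eaf[sw]
  bad <- action == "incompatible"
  out_beta[bad] <- NA_real_
  out_eaf[bad] <- NA_real_

  data.frame(action = action, beta = out_beta, eaf = out_eaf,
             stringsAsFactors = FALSE)
}

#' Recode reported frequencies to a reference minor allele
#'
#' Returns the frequency of the reference minor allele implied by the test
#' data: \code{eaf} when the reported effect allele is the reference minor
#' allele, \code{1 - eaf} when it is the major allele (direct match or after
#' strand complement). Pairs whose alleles do not match the reference pair
#' return NA and are skipped by the frequency checks.
#'
#' @param effectAllele,otherAllele test-data alleles.
#' @param eaf reported effect-allele frequencies.
#' @param minorAllele,majorAllele reference alleles.
#' @return Numeric vector: frequency of the reference minor allele in the
#'   test data (NA where not resolvable).
#' @export
recodeToMinor <- function(effectAllele, otherAllele, eaf,
                          minorAllele, majorAllele) {
  n <- length(effectAllele)
  eaf <- rep_len(as.numeric(eaf), n)
  cE <- complementAllele(effectAllele)
  cO <- complementAllele(otherAllele)
  effect_is_minor <- (effectAllele == minorAllele & otherAllele == majorAllele)
  effect_is_major <- (effectAllele == majorAllele & otherAllele == minorAllele)
  need_flip <- !(effect_is_minor %in% TRUE) & !(effect_is_major %in% TRUE)
  effect_is_minor[need_flip] <-
    (cE == minorAllele & cO == majorAllele)[need_flip]
  effect_is_major[need_flip] <-
    (cE == majorAllele & cO == minorAllele)[need_flip]
  out <- rep(NA_real_, n)
  out[effect_is_minor %in% TRUE] <- eaf[effect_is_minor %in% TRUE]
  out[effect_is_major %in% TRUE] <- 1 - eaf[effect_is_major %in% TRUE]
  out
}
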