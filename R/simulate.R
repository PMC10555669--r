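## Fixture generator: additive-model GWAS summary statistics (continuous and
## case-control) with matching reference panels (catalogue-style top hits, a
## consensus-MAF reference, a known-hits table and a block-structured LD
## table), plus injection of each documented error mode with truth labels.
##
## Simulation is at summary level (no individual genotypes): the sampling
## distribution of a per-SNP estimate under an additive model is normal
## around the true effect with the analytic standard error, which is what
## every downstream check consumes. The individual-level Monte-Carlo mode
## (simulateLnOR) is retained as the oracle for the expected-log-OR solver.

.ERROR_MODES <- c("none", "flip_effect_allele", "eaf_is_noneffect",
                  "eaf_is_maf", "wrong_n", "linear_scale",
                  "unfiltered_lowqual", "scrambled_p",
                  "per_snp_n_variation")

## column-level errors corrupt the whole column; per-SNP errors hit a subset
.DEFAULT_FRACTION <- c(
  flip_effect_allele = 1.0, eaf_is_noneffect = 1.0, eaf_is_maf = 1.0,
  wrong_n = 1.0, linear_scale = 1.0,
  unfiltered_lowqual = 0.1, scrambled_p = 0.1, per_snp_n_variation = 0.1)

.newTruthLabels <- function(sset, effects, eaf_true) {
  structure(list(
    injected_error = "none",
    affected_rsids = character(0),
    true_effects = stats::setNames(effects, ssData(sset)$rsid),
    true_eaf = stats::setNames(eaf_true, ssData(sset)$rsid),
    params = list()), class = "TruthLabels")
}

## shared scaffolding: rsids, block-structured positions, allele pairs
.simScaffold <- function(nSnps, mafRange, blockSize = 5) {
  if (length(mafRange) != 2 || mafRange[1] >= mafRange[2] ||
      mafRange[1] <= 0 || mafRange[2] > 0.5) {
    stop("degenerate mafRange: need 0 < low < high <= 0.5")
  }
  rsid <- sprintf("rs%06d", seq_len(nSnps))
  block <- (seq_len(nSnps) - 1) %/% blockSize
  chr <- as.character(block %% 22 + 1)
  block_on_chr <- block %/% 22
  within <- (seq_len(nSnps) - 1) %% blockSize
  pos <- 1e6 + block_on_chr * 5e7 + within * 2e4
  pair <- t(vapply(seq_len(nSnps),
                   function(i) sample(.BASES, 2), character(2)))
  maf <- stats::runif(nSnps, mafRange[1], mafRange[2])
  eaf_true <- ifelse(stats::runif(nSnps) < 0.5, maf, 1 - maf)
  list(rsid = rsid, chr = chr, pos = pos, effect_allele = pair[, 1],
       other_allele = pair[, 2], maf = maf, eaf_true = eaf_true,
       block = block)
}

#' Simulate a continuous-trait GWAS summary-statistics set
#'
#' Per SNP: minor allele frequency uniform in \code{mafRange}; true
#' per-allele effect (SD units) normal with standard deviation
#' \code{effectSd}; per-SNP contributing sample size \code{n} times a
#' uniform fraction in \code{nFracRange} (meta-analyses rarely have every
#' cohort contributing to every SNP); estimate normal around the true
#' effect with the additive-model standard error
#' \code{1 / sqrt(2 maf (1 - maf) n)}; two-sided P-value from the z-score.
#' Fully reproducible from \code{seed}.
#'
#' @param nSnps number of SNPs (>= 1).
#' @param n nominal total sample size (>= 100).
#' @param mafRange range of the simulated minor allele frequency.
#' @param effectSd standard deviation of true effects (0 = null trait).
#' @param nFracRange range of the per-SNP contributing-sample fraction.
#' @param seed RNG seed.
#' @return list with \code{table} (a \code{\link{SumStatSet-class}}) and
#'   \code{labels} (truth labels, error \code{"none"}).
#' @export
simulateContinuousGwas <- function(nSnps = 200, n = 10000,
                                   mafRange = c(0.05, 0.5),
                                   effectSd = 0.05,
                                   nFracRange = c(0.15, 1),
                                   seed = 1) {
  stopifnot(nSnps >= 1, n >= 100)
  set.seed(seed)
  sc <- .simScaffold(nSnps, mafRange)
  frac <- stats::runif(nSnps, nFracRange[1], nFracRange[2])
  n_i <- round(frac * n)
  se <- 1 / sqrt(2 * sc$maf * (1 - sc$maf) * n_i)
  b_true <- stats::rnorm(nSnps, 0, effectSd)
  beta <- stats::rnorm(nSnps, b_true, se)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  eaf_obs <- pmin(pmax(
    sc$eaf_true + stats::rnorm(nSnps, 0,
                               sqrt(sc$eaf_true * (1 - sc$eaf_true) /
                                      (2 * n_i))), 0.001), 0.999)
  d <- data.frame(
    rsid = sc$rsid, chr = sc$chr, pos = sc$pos,
    effect_allele = sc$effect_allele, other_allele = sc$other_allele,
    eaf = eaf_obs, beta = beta, se = se, pval = pval, n = n_i,
    n_cases = NA_real_, n_controls = NA_real_,
    info = stats::runif(nSnps, 0.9, 1),
    hwe_p = stats::runif(nSnps), het_p = stats::runif(nSnps),
    n_studies = sample(3:12, nSnps, replace = TRUE),
    scale = "sd_units", stringsAsFactors = FALSE)
  sset <- SumStatSet(d, traitName = "simulated continuous trait",
                     traitType = "continuous", ancestry = "EUR",
                     publicationId = "SIMPUB1", maxN = n)
  labels <- .newTruthLabels(sset, b_true, sc$eaf_true)
  labels$params <- list(kind = "continuous", n = n, seed = seed,
                        maf = stats::setNames(sc$maf, sc$rsid),
                        block = sc$block)
  list(table = sset, labels = labels)
}

#' Simulate a case-control GWAS summary-statistics set
#'
#' Per SNP: true per-allele log odds ratio normal with standard deviation
#' \code{logorSd}; per-SNP case/control counts are the nominal counts times
#' a uniform contributing fraction in \code{nFracRange}; the reported
#' estimate is normal around the true log OR with the expected-information
#' standard error (\code{\link{lnorStandardError}}) at that SNP's minor
#' allele frequency and counts; scale is \code{log_odds}.
#'
#' @param nSnps number of SNPs.
#' @param nCases,nControls nominal case/control counts (>= 100).
#' @param mafRange,nFracRange as in \code{\link{simulateContinuousGwas}}.
#' @param logorSd standard deviation of true log odds ratios.
#' @param seed RNG seed.
#' @return list with \code{table} and \code{labels}.
#' @export
simulateBinaryGwas <- function(nSnps = 200, nCases = 5000, nControls = 5000,
                               mafRange = c(0.05, 0.5), logorSd = 0.15,
                               nFracRange = c(0.15, 1), seed = 1) {
  stopifnot(nSnps >= 1, nCases >= 100, nControls >= 100)
  set.seed(seed)
  sc <- .simScaffold(nSnps, mafRange)
  frac <- stats::runif(nSnps, nFracRange[1], nFracRange[2])
  nca <- round(frac * nCases)
  nco <- round(frac * nControls)
  b_true <- stats::rnorm(nSnps, 0, logorSd)
  se <- vapply(seq_len(nSnps), function(i) {
    lnorStandardError(b_true[i], sc$maf[i], nca[i], nco[i])
  }, numeric(1))
  beta <- stats::rnorm(nSnps, b_true, se)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  n_i <- nca + nco
  eaf_obs <- pmin(pmax(
    sc$eaf_true + stats::rnorm(nSnps, 0,
                               sqrt(sc$eaf_true * (1 - sc$eaf_true) /
                                      (2 * n_i))), 0.001), 0.999)
  d <- data.frame(
    rsid = sc$rsid, chr = sc$chr, pos = sc$pos,
    effect_allele = sc$effect_allele, other_allele = sc$other_allele,
    eaf = eaf_obs, beta = beta, se = se, pval = pval, n = n_i,
    n_cases = nca, n_controls = nco,
    info = stats::runif(nSnps, 0.9, 1),
    hwe_p = stats::runif(nSnps), het_p = stats::runif(nSnps),
    n_studies = sample(3:12, nSnps, replace = TRUE),
    scale = "log_odds", stringsAsFactors = FALSE)
  sset <- SumStatSet(d, traitName = "simulated cancer outcome",
                     traitType = "binary", ancestry = "EUR",
                     publicationId = "SIMPUB1",
                     maxN = nCases + nControls,
                     nCasesTotal = nCases, nControlsTotal = nControls)
  labels <- .newTruthLabels(sset, b_true, sc$eaf_true)
  labels$params <- list(kind = "binary", nCases = nCases,
                        nControls = nControls, seed = seed,
                        maf = stats::setNames(sc$maf, sc$rsid),
                        block = sc$block)
  list(table = sset, labels = labels)
}

#' Inject a documented error mode into a simulated data set
#'
#' Error modes (all documented failure modes of real collated GWAS summary
#' data):
#' \describe{
#'   \item{flip_effect_allele}{swap the allele labels \emph{without}
#'     negating the effect -- the classic mislabelled effect allele column.}
#'   \item{eaf_is_noneffect}{report \code{1 - eaf}: the frequency column
#'     refers to the non-effect allele.}
#'   \item{eaf_is_maf}{report \code{min(eaf, 1 - eaf)}: the frequency column
#'     is a minor allele frequency while the minor allele is not
#'     consistently the effect allele.}
#'   \item{wrong_n}{overwrite per-SNP case/control counts (or \code{n}) with
#'     the declared study-level maxima, as an analyst does when assuming the
#'     sample size is constant across SNPs.}
#'   \item{linear_scale}{multiply beta and se by \code{u (1 - u)} for a
#'     drawn prevalence \code{u}: the data were generated in a linear
#'     (mixed) model of a binary trait but are declared as log odds ratios.}
#'   \item{unfiltered_lowqual}{append SNPs with low imputation info
#'     (< 0.5), standard errors inflated by \code{1 / sqrt(info)} and
#'     correspondingly inflated effect estimates -- unfiltered low-quality
#'     variants.}
#'   \item{scrambled_p}{permute the P-values of a subset of records.}
#'   \item{per_snp_n_variation}{multiply the counts of a small subset by a
#'     random factor in [3, 10] -- a per-SNP sample-size reporting error.}
#' }
#' Column-level modes default to fraction 1 (they are all-or-nothing in
#' reality); per-SNP modes default to 0.1.
#'
#' @param sset a simulated \code{\link{SumStatSet-class}}.
#' @param labels its truth labels.
#' @param errorType one of the modes above.
#' @param fraction fraction of records affected (default per mode).
#' @param seed RNG seed.
#' @return list with the corrupted \code{table} and updated \code{labels}.
#' @export
injectError <- function(sset, labels, errorType, fraction = NULL, seed = 1) {
  errorType <- match.arg(errorType, setdiff(.ERROR_MODES, "none"))
  if (is.null(fraction)) fraction <- .DEFAULT_FRACTION[[errorType]]
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (errorType == "linear_scale" && traitType(sset) != "binary") {
    stop("linear_scale corruption applies to binary traits only")
  }
  set.seed(seed)
  d <- ssData(sset)
  n <- nrow(d)
  sel <- if (fraction >= 1) seq_len(n) else
    sort(sample(n, max(1, round(fraction * n))))
  params <- list(fraction = fraction, seed = seed)

  if (errorType == "flip_effect_allele") {
    ea <- d$effect_allele[sel]
    d$effect_allele[sel] <- d$other_allele[sel]
    d$other_allele[sel] <- ea
  } else if (errorType == "eaf_is_noneffect") {
    d$eaf[sel] <- 1 - d$eaf[sel]
  } else if (errorType == "eaf_is_maf") {
    d$eaf[sel] <- pmin(d$eaf[sel], 1 - d$eaf[sel])
  } else if (errorType == "wrong_n") {
    if (traitType(sset) == "binary") {
      d$n_cases[sel] <- sset@nCasesTotal
      d$n_controls[sel] <- sset@nControlsTotal
      d$n[sel] <- sset@nCasesTotal + sset@nControlsTotal
    } else {
      d$n[sel] <- maxN(sset)
    }
  } else if (errorType == "linear_scale") {
    u <- stats::runif(1, 0.01, 0.1)
    d$beta[sel] <- d$beta[sel] * u * (1 - u)
    d$se[sel] <- d$se[sel] * u * (1 - u)
    params$prevalence <- u
  } else if (errorType == "unfiltered_lowqual") {
    m <- max(1, round(fraction * n))
    extra <- .lowQualityRecords(sset, labels, m)
    d <- rbind(d[names(extra)], extra)
    sel <- n + seq_len(m)
  } else if (errorType == "scrambled_p") {
    if (length(sel) >= 2) d$pval[sel] <- d$pval[sample(sel)]
  } else if (errorType == "per_snp_n_variation") {
    fac <- stats::runif(length(sel), 3, 10)
    if (traitType(sset) == "binary") {
      d$n_cases[sel] <- round(d$n_cases[sel] * fac)
      d$n_controls[sel] <- round(d$n_controls[sel] * fac)
      d$n[sel] <- d$n_cases[sel] + d$n_controls[sel]
    } else {
      d$n[sel] <- round(d$n[sel] * fac)
    }
  }

  rownames(d) <- NULL
  labels$injected_error <- errorType
  labels$affected_rsids <- d$rsid[sel]
  labels$params <- utils::modifyList(labels$params, params)
  list(table = setSS(sset, d), labels = labels)
}

## appended false-positive records: low info, se inflated by 1/sqrt(info)
## relative to the analytic SE, estimates drawn at that inflated noise level
.lowQualityRecords <- function(sset, labels, m) {
  binary <- traitType(sset) == "binary"
  sc <- .simScaffold(m, c(0.05, 0.5))
  info <- stats::runif(m, 0.1, 0.5)
  if (binary) {
    nca <- rep(sset@nCasesTotal, m)
    nco <- rep(sset@nControlsTotal, m)
    se_model <- vapply(seq_len(m), function(i) {
      lnorStandardError(0, sc$maf[i], nca[i], nco[i])
    }, numeric(1))
    n_i <- nca + nco
  } else {
    n_i <- rep(maxN(sset), m)
    se_model <- 1 / sqrt(2 * sc$maf * (1 - sc$maf) * n_i)
    nca <- nco <- rep(NA_real_, m)
  }
  ## reported SE reflects the reduced effective sample (se_model / sqrt(info))
  ## but the estimates are unstable beyond it: the realized noise scales with
  ## 1 / info, which both inflates |beta| (false-positive hits) and makes the
  ## reported SE exceed the frequency/sample-size expectation
  se <- se_model / sqrt(info)
  beta <- stats::rnorm(m, 0, se_model / info)
  data.frame(
    rsid = sprintf("rs9%05d", seq_len(m)), chr = sc$chr, pos = sc$pos + 7,
    effect_allele = sc$effect_allele, other_allele = sc$other_allele,
    eaf = sc$eaf_true, beta = beta, se = se,
    pval = 2 * stats::pnorm(-abs(beta / se)),
    n = n_i, n_cases = nca, n_controls = nco, info = info,
    hwe_p = stats::runif(m), het_p = stats::runif(m),
    n_studies = 1, scale = if (binary) "log_odds" else "sd_units",
    stringsAsFactors = FALSE)
}

#' Build matching reference sets for a simulated data set
#'
#' Emulates the two external references of the QC protocol from the truth
#' labels of an \emph{uncorrupted} simulated table:
#' \itemize{
#'   \item catalogue-style top hits: the strongest true associations,
#'     re-estimated in an independent reference study
#'     \code{refSampleFactor} times the size of the test study (published
#'     catalogue hits typically come from the largest meta-analyses), with
#'     correct alleles, frequencies and directions; palindromic SNPs are
#'     excluded.
#'   \item a consensus-MAF reference restricted to SNPs with true minor
#'     allele frequency in [0.1, 0.35], with per-superpopulation MAFs (the
#'     column matching the simulated ancestry is exact; the others are
#'     perturbed within the band).
#'   \item a known-hits table (rsid, chr, pos) of the reference-study
#'     genome-wide-significant SNPs.
#'   \item a block-structured LD table: all within-block pairs get r2 drawn
#'     from U(0.5, 0.95); cross-block pairs are absent (r2 = 0).
#' }
#'
#' @param labels truth labels from a simulate call.
#' @param sset the uncorrupted \code{\link{SumStatSet-class}}.
#' @param nTopHits number of top hits to draw (truncated with a warning when
#'   fewer reference-significant SNPs exist).
#' @param seed RNG seed.
#' @param refSampleFactor size of the reference study relative to the test
#'   study.
#' @return list with \code{tophits}, \code{mafRef}, \code{knownHits},
#'   \code{ld} data.frames.
#' @export
makeReferenceSets <- function(labels, sset, nTopHits = 30, seed = 1,
                              refSampleFactor = 10) {
  set.seed(seed)
  d <- ssData(sset)
  b_true <- unname(labels$true_effects[d$rsid])
  eaf_true <- unname(labels$true_eaf[d$rsid])
  maf_true <- pmin(eaf_true, 1 - eaf_true)
  n <- nrow(d)
  binary <- traitType(sset) == "binary"

  if (binary) {
    nca_r <- refSampleFactor * sset@nCasesTotal
    nco_r <- refSampleFactor * sset@nControlsTotal
    se_ref <- vapply(seq_len(n), function(i) {
      lnorStandardError(b_true[i], maf_true[i], nca_r, nco_r)
    }, numeric(1))
    n_ref <- nca_r + nco_r
  } else {
    n_ref <- refSampleFactor * maxN(sset)
    se_ref <- 1 / sqrt(2 * maf_true * (1 - maf_true) * n_ref)
  }
  beta_ref <- stats::rnorm(n, b_true, se_ref)
  p_ref <- 2 * stats::pnorm(-abs(beta_ref / se_ref))
  eaf_ref <- pmin(pmax(
    eaf_true + stats::rnorm(n, 0, sqrt(eaf_true * (1 - eaf_true) /
                                         (2 * n_ref))), 0.001), 0.999)

  ## top hits: reference-significant, non-palindromic, strongest first
  pal <- suppressWarnings(isPalindromic(d$effect_allele, d$other_allele))
  strong <- which(!pal & p_ref < 5e-8)
  strong <- strong[order(p_ref[strong])]
  if (length(strong) < nTopHits) {
    warning("only ", length(strong), " reference-significant ",
            "non-palindromic SNPs available for ", nTopHits,
            " requested top hits", call. = FALSE)
  }
  th <- strong[seq_len(min(nTopHits, length(strong)))]
  tophits <- data.frame(
    rsid = d$rsid[th], effect_allele = d$effect_allele[th],
    other_allele = d$other_allele[th], beta = beta_ref[th],
    se = se_ref[th], eaf = eaf_ref[th], pval = p_ref[th],
    ancestry = ancestry(sset), publication_id = "REFPUB1",
    stringsAsFactors = FALSE)

  ## consensus-MAF reference
  in_band <- which(maf_true >= 0.1 & maf_true <= 0.35)
  pops <- c("AFR", "AMR", "EAS", "EUR", "SAS", "GLOBAL")
  own <- if (ancestry(sset) %in% pops) ancestry(sset) else "EUR"
  mafRef <- data.frame(
    rsid = d$rsid[in_band],
    minor_allele = ifelse(eaf_true[in_band] <= 0.5,
                          d$effect_allele[in_band], d$other_allele[in_band]),
    major_allele = ifelse(eaf_true[in_band] <= 0.5,
                          d$other_allele[in_band], d$effect_allele[in_band]),
    stringsAsFactors = FALSE)
  for (p in pops) {
    mafRef[[p]] <- if (p == own) {
      pmin(pmax(maf_true[in_band], 0.1), 0.35)
    } else {
      pmin(pmax(maf_true[in_band] + stats::rnorm(length(in_band), 0, 0.04),
                0.101), 0.349)
    }
  }
  attr(mafRef, "populations") <- pops

  knownHits <- data.frame(rsid = d$rsid[p_ref < 5e-8],
                          chr = d$chr[p_ref < 5e-8],
                          pos = d$pos[p_ref < 5e-8],
                          stringsAsFactors = FALSE)

  ## block LD: all pairs inside a block
  block <- labels$params$block
  ld_list <- lapply(split(seq_len(n), block), function(idx) {
    if (length(idx) < 2) return(NULL)
    pr <- t(utils::combn(idx, 2))
    data.frame(rsid_a = d$rsid[pr[, 1]], rsid_b = d$rsid[pr[, 2]],
               r2 = stats::runif(nrow(pr), 0.5, 0.95),
               stringsAsFactors = FALSE)
  })
  ld <- do.call(rbind, ld_list[!vapply(ld_list, is.null, logical(1))])
  rownames(ld) <- NULL

  list(tophits = tophits, mafRef = mafRef, knownHits = knownHits, ld = ld)
}

#' Write a complete simulated fixture bundle to disk
#'
#' Writes \code{sumstats.tsv}, \code{tophits.tsv}, \code{maf_reference.tsv},
#' \code{known_hits.tsv}, \code{ld.tsv} and \code{truth.json} into
#' \code{dir}. The bundle is byte-identical across runs with the same seed.
#'
#' @param dir output directory (created if needed).
#' @param sset simulated table; @param labels its truth labels;
#'   @param refs reference sets from \code{\link{makeReferenceSets}}.
#' @return Invisibly, the file paths written.
#' @export
writeFixtureBundle <- function(dir, sset, labels, refs) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    sumstats = file.path(dir, "sumstats.tsv"),
    tophits = file.path(dir, "tophits.tsv"),
    maf_reference = file.path(dir, "maf_reference.tsv"),
    known_hits = file.path(dir, "known_hits.tsv"),
    ld = file.path(dir, "ld.tsv"),
    truth = file.path(dir, "truth.json"))
  data.table::fwrite(ssData(sset)[, .SUMSTAT_COLS], files[["sumstats"]],
                     sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(refs$tophits, files[["tophits"]], sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(refs$mafRef, files[["maf_reference"]], sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(refs$knownHits, files[["known_hits"]], sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(refs$ld, files[["ld"]], sep = "\t", na = "NA",
                     quote = FALSE)
  truth <- list(
    injected_error = labels$injected_error,
    affected_rsids = labels$affected_rsids,
    true_effects = as.list(labels$true_effects),
    trait_type = traitType(sset),
    n_cases_total = sset@nCasesTotal, n_controls_total = sset@nControlsTotal,
    max_n = maxN(sset))
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(files)
}
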