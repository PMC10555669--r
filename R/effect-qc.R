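## Expected-vs-reported effect-size machinery.
##
## For a continuous trait the expected per-allele effect (in SD units) has a
## closed form in the z-score, minor allele frequency and sample size. For a
## binary trait the expected log odds ratio is obtained from a deterministic
## expected-information solver under an additive logistic model: genotype
## frequencies follow Hardy-Weinberg proportions, the intercept is pinned to
## the study case fraction, the standard error of the log OR comes from the
## inverse expected Fisher information, and the log OR solving
## b / SE(b) = z is found by monotone root bracketing. A Monte-Carlo
## logistic-regression simulation with the same inputs serves as the test
## oracle for this solver.

#' Expected per-allele effect for a continuous trait
#'
#' \deqn{\hat\beta = z / \sqrt{2 p (1 - p) (n + z^2)}}
#' where \code{p} is the minor allele frequency, \code{n} the sample size
#' and \code{z} the ratio of the reported effect size to its standard error.
#' The result is the standard-deviation change in the trait per copy of the
#' effect allele, assuming the z-score came from an additive model.
#' Antisymmetric in \code{z} and strictly decreasing in \code{n} for fixed
#' nonzero \code{z}.
#'
#' @param z z-score(s) (beta / se).
#' @param p minor allele frequency in (0, 1).
#' @param n sample size > 0.
#' @return Numeric vector of expected effects in SD units.
#' @examples
#' expectedBetaContinuous(5, 0.5, 10000)
#' @export
expectedBetaContinuous <- function(z, p, n) {
  if (any(!is.na(p) & (p <= 0 | p >= 1))) {
    stop("invalid input: p must lie strictly in (0, 1)")
  }
  if (any(!is.na(n) & n <= 0)) stop("invalid input: n must be positive")
  z / sqrt(2 * p * (1 - p) * (n + z^2))
}

## Solve the logistic intercept a so that the model-implied marginal case
## fraction equals phi, for per-allele log OR b and HWE genotype frequencies
## f at minor allele frequency maf. Newton with bisection fallback.
.solveIntercept <- function(b, maf, phi) {
  g <- 0:2
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  target <- function(a) sum(f * stats::plogis(a + b * g)) - phi
  a <- stats::qlogis(phi) - b * (2 * maf)  # start near the marginal logit
  for (i in 1:50) {
    mu <- stats::plogis(a + b * g)
    h <- sum(f * mu) - phi
    if (abs(h) < 1e-12) return(a)
    deriv <- sum(f * mu * (1 - mu))
    if (deriv < 1e-300) break
    a <- a - h / deriv
  }
  stats::uniroot(target, c(-80, 80), tol = 1e-12)$root
}

#' Expected standard error of a log odds ratio
#'
#' Standard error of the per-allele log OR under an additive logistic model
#' with Hardy-Weinberg genotype frequencies at minor allele frequency
#' \code{maf}, intercept pinned so the model-implied case fraction equals
#' \code{nCases / (nCases + nControls)}, via the inverse expected Fisher
#' information for (intercept, log OR) accumulated over genotypes with
#' weights \eqn{\mu_g (1 - \mu_g)}.
#'
#' @param b per-allele log odds ratio.
#' @param maf minor allele frequency in (0, 0.5).
#' @param nCases,nControls case and control counts.
#' @return Standard error of \code{b}.
#' @export
lnorStandardError <- function(b, maf, nCases, nControls) {
  if (is.na(maf) || maf <= 0 || maf >= 0.5) {
    stop("invalid input: maf must lie strictly in (0, 0.5)")
  }
  if (is.na(nCases) || is.na(nControls) || nCases <= 0 || nControls <= 0) {
    stop("invalid input: case and control counts must be positive")
  }
  N <- nCases + nControls
  phi <- nCases / N
  g <- 0:2
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  a <- .solveIntercept(b, maf, phi)
  mu <- stats::plogis(a + b * g)
  w <- f * mu * (1 - mu)
  i11 <- sum(w)
  i12 <- sum(w * g)
  i22 <- sum(w * g^2)
  det <- i11 * i22 - i12^2
  if (det <= 0) stop("expected information is singular")
  sqrt(i11 / det / N)
}

#' Expected log odds ratio from a z-score
#'
#' Deterministic solver: returns the per-allele log odds ratio \code{b}
#' whose expected z-score \code{b / SE(b)} (with \code{SE} from
#' \code{\link{lnorStandardError}}) equals the supplied z-score, found by
#' monotone root bracketing on |b| <= 20 to a tolerance of 1e-8 on z. The
#' sign of \code{b} equals the sign of \code{z}; \code{z = 0} returns
#' \code{(0, SE(0))} directly.
#'
#' @param z z-score (reported beta / se).
#' @param maf minor allele frequency in (0, 0.5).
#' @param nCases,nControls case and control counts.
#' @return list with \code{b} (expected log OR) and \code{se} (its expected
#'   standard error).
#' @examples
#' expectedLnOR(2, 0.3, 5000, 5000)
#' @export
expectedLnOR <- function(z, maf, nCases, nControls) {
  if (is.na(z)) return(list(b = NA_real_, se = NA_real_))
  se0 <- lnorStandardError(0, maf, nCases, nControls)
  if (z == 0) return(list(b = 0, se = se0))
  h <- function(b) b / lnorStandardError(b, maf, nCases, nControls) - z
  ## the root lies near z * SE(0); grow the bracket from there (b / SE(b)
  ## is monotone only over the plausible range -- the information collapses
  ## for extreme log ORs, so a fixed wide bracket can miss the sign change)
  hi <- sign(z) * min(max(2 * abs(z) * se0, 0.1), 20)
  while (sign(h(hi)) == sign(-z)) {
    if (abs(hi) >= 20) {
      stop("z inconsistent with counts: no log OR with |b| <= 20 attains it")
    }
    hi <- sign(z) * min(abs(hi) * 2, 20)
  }
  root <- stats::uniroot(h, sort(c(0, hi)), tol = 1e-12)
  b <- root$root
  se <- lnorStandardError(b, maf, nCases, nControls)
  ## polish until the fixed point holds to 1e-8 on z
  for (i in 1:20) {
    dev <- b / se - z
    if (abs(dev) < 1e-9) break
    b <- z * se
    se <- lnorStandardError(b, maf, nCases, nControls)
  }
  list(b = b, se = se)
}

## vectorized convenience wrapper over SNPs
.expectedLnORVec <- function(z, maf, nCases, nControls) {
  n <- length(z)
  b <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(z[i]) || is.na(maf[i]) || maf[i] <= 0 || maf[i] >= 0.5 ||
        is.na(nCases[i]) || is.na(nControls[i]) ||
        nCases[i] <= 0 || nControls[i] <= 0) next
    r <- expectedLnOR(z[i], maf[i], nCases[i], nControls[i])
    b[i] <- r$b
    se[i] <- r$se
  }
  list(b = b, se = se)
}

#' Monte-Carlo oracle for the expected log odds ratio
#'
#' Simulates individual-level case-control data under the same additive
#' logistic model as \code{\link{expectedLnOR}} (HWE genotypes, intercept
#' pinned to the case fraction, true per-allele log OR \code{b}) and fits a
#' logistic regression per replicate. Used as the independent oracle for the
#' deterministic solver and available as an optional simulation mode.
#'
#' @param b true per-allele log odds ratio.
#' @param maf minor allele frequency in (0, 0.5).
#' @param nCases,nControls target case/control counts (total N is their sum;
#'   realized counts vary binomially around the case fraction).
#' @param nReps number of replicates.
#' @param seed RNG seed (optional).
#' @return list with per-replicate \code{b_hat}, \code{se_hat}, \code{z_hat}
#'   vectors.
#' @export
simulateLnOR <- function(b, maf, nCases, nControls, nReps = 50,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nCases + nControls
  phi <- nCases / N
  g <- 0:2
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  a <- .solveIntercept(b, maf, phi)
  mu <- stats::plogis(a + b * g)
  b_hat <- se_hat <- rep(NA_real_, nReps)
  for (r in seq_len(nReps)) {
    ng <- as.vector(stats::rmultinom(1, N, f))
    cases <- stats::rbinom(3, ng, mu)
    fit <- stats::glm(cbind(cases, ng - cases) ~ g,
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    b_hat[r] <- cf["g", "Estimate"]
    se_hat[r] <- cf["g", "Std. Error"]
  }
  list(b_hat = b_hat, se_hat = se_hat, z_hat = b_hat / se_hat)
}

#' Rescale absolute-risk (linear-model) effects to log odds ratios
#'
#' Binary traits analysed in a linear (mixed) model yield effects on the
#' absolute-risk scale; dividing by \code{u (1 - u)}, with \code{u} the case
#' prevalence, converts them to the log odds ratio scale. The standard error
#' transforms identically. \code{transformLogORToLinear} is the exact
#' inverse.
#'
#' @param beta,se effect size(s) and standard error(s) on the absolute-risk
#'   scale.
#' @param u case prevalence in (0, 1).
#' @return list with rescaled \code{beta} and \code{se}.
#' @examples
#' transformLinearToLogOR(0.004, 0.001, u = 0.02)
#' @export
transformLinearToLogOR <- function(beta, se = NULL, u) {
  if (any(!is.na(u) & (u <= 0 | u >= 1))) {
    stop("invalid input: prevalence u must lie strictly in (0, 1)")
  }
  k <- u * (1 - u)
  list(beta = beta / k, se = if (is.null(se)) NULL else se / k)
}

#' @rdname transformLinearToLogOR
#' @export
transformLogORToLinear <- function(beta, se = NULL, u) {
  if (any(!is.na(u) & (u <= 0 | u >= 1))) {
    stop("invalid input: prevalence u must lie strictly in (0, 1)")
  }
  k <- u * (1 - u)
  list(beta = beta * k, se = if (is.null(se)) NULL else se * k)
}

#' Build per-SNP expected-vs-reported effect comparisons
#'
#' For each record with the needed fields, computes the expected effect on
#' the reported scale (\code{\link{expectedBetaContinuous}} for continuous
#' traits, \code{\link{expectedLnOR}} for binary traits), the z-score and
#' the percentage deviation \code{100 (reported - expected) / expected}
#' (missing when the expected effect is zero). The minor allele frequency
#' fed to the expectation is the reported EAF folded to
#' \code{min(eaf, 1 - eaf)}.
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @return data.frame with columns \code{rsid, reported, expected, z,
#'   pct_deviation}; records lacking eaf, se or sample sizes are dropped.
#' @export
buildEffectComparisons <- function(sset) {
  d <- ssData(sset)
  maf <- pmin(d$eaf, 1 - d$eaf)
  z <- d$beta / d$se
  if (traitType(sset) == "binary") {
    nca <- ifelse(is.na(d$n_cases), sset@nCasesTotal, d$n_cases)
    nco <- ifelse(is.na(d$n_controls), sset@nControlsTotal, d$n_controls)
    ok <- !is.na(z) & !is.na(maf) & maf > 0 & maf < 0.5 &
      !is.na(nca) & !is.na(nco) & nca > 0 & nco > 0
    expected <- rep(NA_real_, nrow(d))
    res <- .expectedLnORVec(z[ok], maf[ok], nca[ok], nco[ok])
    expected[ok] <- res$b
  } else {
    n <- ifelse(is.na(d$n), maxN(sset), d$n)
    ok <- !is.na(z) & !is.na(maf) & maf > 0 & maf < 1 & !is.na(n) & n > 0
    expected <- rep(NA_real_, nrow(d))
    expected[ok] <- expectedBetaContinuous(z[ok], maf[ok], n[ok])
  }
  out <- data.frame(rsid = d$rsid, reported = d$beta, expected = expected,
                    z = z, stringsAsFactors = FALSE)
  out$pct_deviation <- ifelse(
    !is.na(out$expected) & out$expected != 0,
    100 * (out$reported - out$expected) / out$expected, NA_real_)
  out[ok, , drop = FALSE]
}

#' Regress expected on reported effect sizes
#'
#' Ordinary least squares of the expected effect size (response) on the
#' reported effect size (predictor), with intercept. A slope above 1.20 or
#' below 0.8 is flagged as an unusual distribution of reported effect sizes
#' (scale conflicts, wrong sample sizes, unfiltered low-quality variants).
#' Linearity is assessed by reporting R-squared. Fewer than
#' \code{minPoints} finite comparisons make the fit not assessable.
#'
#' @param comparisons data.frame from \code{\link{buildEffectComparisons}}.
#' @param slopeRange flagging bounds, default \code{c(0.8, 1.20)}.
#' @param minPoints minimum comparisons, default 10.
#' @return list with \code{assessable, slope, intercept, n, r_squared,
#'   flagged} and the fitted \code{data}.
#' @export
fitExpectedVsReported <- function(comparisons,
                                  slopeRange = qcDefaults()$slope_range,
                                  minPoints = 10) {
  keep <- !is.na(comparisons$reported) & !is.na(comparisons$expected) &
    is.finite(comparisons$reported) & is.finite(comparisons$expected)
  cmp <- comparisons[keep, , drop = FALSE]
  if (nrow(cmp) < minPoints) {
    return(list(assessable = FALSE, n = nrow(cmp),
                note = sprintf("only %d comparisons (minimum %d)",
                               nrow(cmp), minPoints)))
  }
  fit <- stats::lm(expected ~ reported, data = cmp)
  slope <- unname(stats::coef(fit)[2])
  list(assessable = TRUE,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(cmp),
       # a perfect fit (identity input) is legitimate here
       r_squared = suppressWarnings(summary(fit)$r.squared),
       flagged = slope > slopeRange[2] || slope < slopeRange[1],
       slope_range = slopeRange,
       data = cmp)
}

#' Relate effect-size deviations to genotype-quality metrics
#'
#' Spearman correlation of the absolute percentage deviation between
#' expected and reported effects with each available quality metric
#' (imputation info score, Hardy-Weinberg P-value, between-study
#' heterogeneity P-value, number of contributing studies). A strong inverse
#' relationship with the info score indicates that unfiltered low-quality
#' variants drive the deviations. SNPs with info below \code{infoMin}
#' (default 0.8) are flagged \code{low_imputation_quality}.
#'
#' @param comparisons data.frame from \code{\link{buildEffectComparisons}}.
#' @param sset the \code{\link{SumStatSet-class}} supplying the metrics.
#' @param infoMin info-score flag threshold.
#' @param minPoints minimum paired observations per metric, default 10.
#' @return list with per-metric \code{correlations} (NA = not available or
#'   undefined), \code{flags} (low-info SNPs) and scatter \code{data}.
#' @export
deviationVsQuality <- function(comparisons, sset, infoMin = 0.8,
                               minPoints = 10) {
  d <- ssData(sset)
  idx <- match(comparisons$rsid, d$rsid)
  dev <- abs(comparisons$pct_deviation)
  metrics <- list(info = d$info[idx], hwe_p = d$hwe_p[idx],
                  het_p = d$het_p[idx], n_studies = d$n_studies[idx])
  correlations <- vapply(metrics, function(m) {
    keep <- !is.na(dev) & !is.na(m)
    if (sum(keep) < minPoints) return(NA_real_)
    if (stats::sd(m[keep]) == 0 || stats::sd(dev[keep]) == 0) return(NA_real_)
    stats::cor(dev[keep], m[keep], method = "spearman")
  }, numeric(1))
  low <- !is.na(metrics$info) & metrics$info < infoMin
  flags <- if (any(low)) {
    .flagRow("low_imputation_quality", comparisons$rsid[low], "moderate",
             sprintf("imputation info %.3f < %g", metrics$info[low], infoMin))
  } else emptyFlags()
  data <- data.frame(rsid = comparisons$rsid, abs_pct_deviation = dev,
                     info = metrics$info, hwe_p = metrics$hwe_p,
                     het_p = metrics$het_p, stringsAsFactors = FALSE)
  list(assessable = any(!is.na(correlations)),
       correlations = correlations, flags = flags, data = data)
}

#' P-value / z-score consistency check
#'
#' Compares z-scores inferred from the reported effect size and standard
#' error (\code{z_b = beta / se}) with z-scores inferred from the reported
#' P-value (\code{z_p}, the two-sided normal quantile carrying the sign of
#' beta). A Pearson correlation below \code{rMin} (default 0.99) flags the
#' data set; SNPs with a large \code{|z_b|} but a P-value near 1 are listed
#' as outliers. P-values of exactly zero are capped at the quantile of the
#' smallest representable positive double (noted in the result).
#'
#' @param beta,se,pval per-SNP vectors.
#' @param rMin flag threshold on the correlation.
#' @param irreconcilableR below this the relationship is treated as
#'   systematically broken (drives the exclude recommendation).
#' @param outlierZ,outlierP outlier rule: \code{|z_b| > outlierZ} and
#'   \code{pval > outlierP}.
#' @param minPoints minimum SNPs, default 10.
#' @return list with \code{assessable, r, flagged, irreconcilable, n,
#'   outliers} (data.frame) and scatter \code{data}.
#' @export
pzConsistency <- function(beta, se, pval, rMin = 0.99,
                          irreconcilableR = 0.90, outlierZ = 5,
                          outlierP = 0.9, minPoints = 10) {
  keep <- !is.na(beta) & !is.na(se) & !is.na(pval) & se > 0
  beta <- beta[keep]
  se <- se[keep]
  pval <- pval[keep]
  n <- length(beta)
  if (n < minPoints) {
    return(list(assessable = FALSE, n = n,
                note = sprintf("only %d SNPs (minimum %d)", n, minPoints)))
  }
  zero_p <- pval == 0
  pval_adj <- ifelse(zero_p, .Machine$double.xmin, pval)
  z_b <- beta / se
  z_mag <- stats::qnorm(log(pval_adj) - log(2), lower.tail = FALSE,
                        log.p = TRUE)
  z_p <- z_mag * ifelse(beta < 0, -1, 1)
  r <- if (stats::sd(z_b) > 0 && stats::sd(z_p) > 0)
    stats::cor(z_b, z_p) else NA_real_
  out_idx <- abs(z_b) > outlierZ & pval > outlierP
  outliers <- data.frame(z_b = z_b[out_idx], pval = pval[out_idx],
                         index = which(keep)[out_idx])
  list(assessable = TRUE, r = r, n = n,
       flagged = !is.na(r) && r < rMin,
       irreconcilable = !is.na(r) && r < irreconcilableR,
       zero_p_capped = sum(zero_p),
       outliers = outliers,
       data = data.frame(z_b = z_b, z_p = z_p))
}

#' Flag unusually large log odds ratios
#'
#' Flags every record on the log-odds scale with an absolute effect above
#' \code{bound} (default 1, i.e. an odds ratio beyond ~2.7 per allele --
#' implausibly large for a common-variant association and a typical
#' signature of unstable estimates).
#'
#' @param sset a \code{\link{SumStatSet-class}}.
#' @param bound absolute log-OR bound.
#' @return data.frame of flags (\code{check = "extreme_effect"}).
#' @export
flagExtremeEffects <- function(sset, bound = 1.0) {
  d <- ssData(sset)
  on_scale <- !is.na(d$scale) & d$scale == "log_odds"
  ext <- on_scale & !is.na(d$beta) & abs(d$beta) > bound
  if (!any(ext)) return(emptyFlags())
  .flagRow("extreme_effect", d$rsid[ext], "moderate",
           sprintf("|log OR| = %.3f > %g", abs(d$beta[ext]), bound))
}
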