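# build a paired test/top-hits fixture by hand: the test set and the
# reference carry the same alleles, so conflicts are fully controlled
pairedFixture <- function(z_test, z_ref, eaf_test = NULL, eaf_ref = NULL,
                          se = 0.05) {
  n <- length(z_test)
  if (is.null(eaf_test)) eaf_test <- runif(n, 0.1, 0.45)
  if (is.null(eaf_ref)) eaf_ref <- eaf_test
  alleles <- data.frame(
    ea = rep(c("A", "C", "G", "T"), length.out = n),
    oa = rep(c("G", "T", "A", "C"), length.out = n))
  ss <- toySet(n, beta = z_test * se, se = se,
               pval = 2 * pnorm(-abs(z_test)),
               eaf = eaf_test, effect_allele = alleles$ea,
               other_allele = alleles$oa)
  th <- data.frame(
    rsid = ssData(ss)$rsid, effect_allele = alleles$ea,
    other_allele = alleles$oa, beta = z_ref * se, se = se,
    eaf = eaf_ref, pval = 2 * pnorm(-abs(z_ref)),
    ancestry = "EUR", publication_id = "OTHERPUB",
    stringsAsFactors = FALSE)
  list(ss = ss, th = th)
}

test_that("direction conflicts are graded by two-sided significance", {
  fx <- pairedFixture(z_test = c(4.5, 1.0, 3.0),
                      z_ref = c(-4.2, -1.2, 2.5))
  res <- checkDirectionVsTopHits(fx$ss, fx$th)
  flags <- res$flags
  expect_equal(nrow(flags), 2)
  # p ~ 7e-6 and 2.7e-5: significant at 1e-4 in both -> high
  expect_equal(flags$level[flags$rsid == "rs1"], "high")
  # weak in both -> moderate
  expect_equal(flags$level[flags$rsid == "rs2"], "moderate")
  # concordant signs -> no flag
  expect_false("rs3" %in% flags$rsid)
  expect_equal(res$verdict$n_compared, 3L)
  expect_equal(res$verdict$conflict_fraction, 2 / 3, tolerance = 1e-12)
})

test_that("same-publication conflicts are always high", {
  fx <- pairedFixture(z_test = c(1.0, 0.8, 2, 1, 1.5),
                      z_ref = c(-1.2, -0.5, 2, 1, 1.5))
  res <- checkDirectionVsTopHits(fx$ss, fx$th, samePublication = TRUE)
  expect_true(all(res$flags$level == "high"))
  expect_equal(nrow(res$flags), 2)
})

test_that("an empty comparison set yields an ambiguous verdict", {
  ss <- toySet(3)
  th <- data.frame(rsid = "rs_absent", effect_allele = "A",
                   other_allele = "G", beta = 1, se = 0.1, eaf = 0.2,
                   pval = 1e-10, ancestry = "EUR", publication_id = "X",
                   stringsAsFactors = FALSE)
  res <- checkDirectionVsTopHits(ss, th)
  expect_equal(res$verdict$classification, "ambiguous")
  expect_equal(res$verdict$n_compared, 0L)
  res2 <- checkDirectionVsTopHits(ss, NULL)
  expect_equal(res2$verdict$n_compared, 0L)
})

test_that("EAF conflicts against top hits follow the side/MAF/10-point rules", {
  fx <- pairedFixture(z_test = rep(1, 4), z_ref = rep(1, 4),
                      eaf_test = c(0.30, 0.48, 0.30, 0.50),
                      eaf_ref = c(0.72, 0.53, 0.31, 0.60))
  res <- checkEafVsTopHits(fx$ss, fx$th)
  fl <- res$flags
  # opposite sides, both MAFs <= 0.4, difference > 10 points -> high
  expect_equal(fl$level[fl$rsid == "rs1"], "high")
  # opposite sides but both MAFs > 0.4 -> moderate
  expect_equal(fl$level[fl$rsid == "rs2"], "moderate")
  # same side, close -> no flag
  expect_false("rs3" %in% fl$rsid)
  # exactly 0.5: no side, level none with note
  expect_equal(fl$level[fl$rsid == "rs4"], "none")
  expect_match(fl$reason[fl$rsid == "rs4"], "no side")
})

test_that("the 10-point rule upgrades same-side frequency differences", {
  fx <- pairedFixture(z_test = 1, z_ref = 1, eaf_test = 0.15,
                      eaf_ref = 0.34)
  res <- checkEafVsTopHits(fx$ss, fx$th)
  expect_equal(res$flags$level, "high")
  expect_match(res$flags$reason, "points")
})

test_that("recoded-frequency conflicts are graded against the reference", {
  ref <- data.frame(rsid = c("rs1", "rs2", "rs3"),
                    minor_allele = c("A", "C", "G"),
                    major_allele = c("G", "T", "A"),
                    EUR = c(0.20, 0.30, 0.25),
                    stringsAsFactors = FALSE)
  attr(ref, "populations") <- "EUR"
  ss <- toySet(3, effect_allele = c("A", "C", "G"),
               other_allele = c("G", "T", "A"),
               eaf = c(0.62, 0.54, 0.22))
  res <- checkMafVsReference(ss, ref, population = "EUR")
  fl <- res$flags
  # 0.62 >= 0.58 -> high
  expect_equal(fl$level[fl$rsid == "rs1"], "high")
  # 0.54 in (0.5, 0.58) is moderate, but |0.54 - 0.30| > 0.10 -> high
  expect_equal(fl$level[fl$rsid == "rs2"], "high")
  # 0.22 vs 0.25 -> no flag
  expect_false("rs3" %in% fl$rsid)
})

test_that("severity never decreases when an upgrade rule applies", {
  set.seed(91)
  for (i in 1:30) {
    recoded <- runif(1, 0.45, 0.75)
    ref <- runif(1, 0.1, 0.35)
    ss <- toySet(1, effect_allele = "A", other_allele = "G", eaf = recoded)
    mref <- data.frame(rsid = "rs1", minor_allele = "A",
                       major_allele = "G", EUR = ref,
                       stringsAsFactors = FALSE)
    attr(mref, "populations") <- "EUR"
    fl <- checkMafVsReference(ss, mref, population = "EUR")$flags
    base <- if (recoded > 0.5)
      (if (recoded >= 0.58) "high" else "moderate") else "none"
    upgraded <- abs(recoded - ref) > 0.10
    want <- if (upgraded) "high" else base
    got <- if (nrow(fl)) fl$level else "none"
    expect_equal(got, want)
    # the max rule can only raise the base level
    expect_true(match(got, c("none", "moderate", "high")) >=
                  match(base, c("none", "moderate", "high")))
  }
})

test_that("flags are identical regardless of record order", {
  sim <- simulateBinaryGwas(nSnps = 60, seed = 3)
  refs <- suppressWarnings(makeReferenceSets(sim$labels, sim$table,
                                             seed = 4))
  flip <- injectError(sim$table, sim$labels, "flip_effect_allele")
  res1 <- checkDirectionVsTopHits(flip$table, refs$tophits)
  shuffled <- sumstatQC:::setSS(flip$table,
                                ssData(flip$table)[rev(seq_len(60)), ])
  res2 <- checkDirectionVsTopHits(shuffled, refs$tophits)
  f1 <- res1$flags[order(res1$flags$rsid), ]
  f2 <- res2$flags[order(res2$flags$rsid), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
  expect_equal(res1$verdict$conflict_fraction,
               res2$verdict$conflict_fraction)
})

test_that("frequency patterns classify flip, MAF-coded and consistent sets", {
  set.seed(8)
  ref_maf <- runif(80, 0.1, 0.35)
  # flipped column: recoded = 1 - MAF
  v1 <- classifyFrequencyPattern(1 - ref_maf + rnorm(80, 0, 0.01), ref_maf)
  expect_equal(v1$classification, "systematic_flip")
  expect_gte(v1$conflict_fraction, 0.8)
  expect_lte(v1$correlation, -0.5)
  # MAF-coded: half the SNPs reflected
  half <- rep(c(TRUE, FALSE), 40)
  rec <- ifelse(half, ref_maf, 1 - ref_maf) + rnorm(80, 0, 0.01)
  v2 <- classifyFrequencyPattern(rec, ref_maf)
  expect_equal(v2$classification, "maf_coded")
  # consistent
  v3 <- classifyFrequencyPattern(ref_maf + rnorm(80, 0, 0.01), ref_maf)
  expect_equal(v3$classification, "consistent")
  # too few SNPs -> ambiguous with note
  v4 <- classifyFrequencyPattern(ref_maf[1:10], ref_maf[1:10])
  expect_equal(v4$classification, "ambiguous")
  expect_match(v4$note, "minimum")
})

test_that("ancestry correlations rank the matching superpopulation first", {
  set.seed(12)
  n <- 60
  eur <- runif(n, 0.1, 0.35)
  eas <- pmin(pmax(eur + rnorm(n, 0, 0.08), 0.1), 0.35)
  rec <- data.frame(rsid = sprintf("rs%d", 1:n),
                    recoded = eur + rnorm(n, 0, 0.01),
                    ref_maf = eur, maf_EUR = eur, maf_EAS = eas)
  r <- ancestryCorrelations(rec)
  expect_equal(names(r)[1], "EUR")
  expect_gt(r["EUR"], r["EAS"])
  # identical column -> r = 1
  rec2 <- rec
  rec2$recoded <- eur
  expect_equal(unname(ancestryCorrelations(rec2)["EUR"]), 1.0)
  # constant test frequencies -> undefined, reported missing
  rec3 <- rec
  rec3$recoded <- 0.2
  expect_true(all(is.na(ancestryCorrelations(rec3))))
})
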