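test_that("simulation is deterministic in the seed", {
  a <- simulateBinaryGwas(nSnps = 40, seed = 123)
  b <- simulateBinaryGwas(nSnps = 40, seed = 123)
  expect_identical(ssData(a$table), ssData(b$table))
  expect_identical(a$labels$true_effects, b$labels$true_effects)
  c <- simulateBinaryGwas(nSnps = 40, seed = 124)
  expect_false(identical(ssData(a$table)$beta, ssData(c$table)$beta))
  r1 <- suppressWarnings(makeReferenceSets(a$labels, a$table, seed = 9))
  r2 <- suppressWarnings(makeReferenceSets(b$labels, b$table, seed = 9))
  expect_identical(r1, r2)
  expect_error(simulateBinaryGwas(mafRange = c(0.4, 0.2)), "degenerate")
})

test_that("a null continuous trait yields standard-normal z-scores and a clean slope", {
  sim <- simulateContinuousGwas(nSnps = 1000, effectSd = 0, seed = 42)
  d <- ssData(sim$table)
  z <- d$beta / d$se
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  fit <- fitExpectedVsReported(buildEffectComparisons(sim$table))
  expect_false(fit$flagged)
})

test_that("expected continuous effects recover the generating effects", {
  sim <- simulateContinuousGwas(nSnps = 400, effectSd = 0.08, seed = 21)
  cmp <- buildEffectComparisons(sim$table)
  truth <- sim$labels$true_effects[cmp$rsid]
  sl <- coef(lm(cmp$expected ~ truth))[2]
  expect_gt(sl, 0.9)
  expect_lt(sl, 1.1)
})

test_that("a null binary trait keeps the slope within the accepted band", {
  ok <- vapply(1:8, function(s) {
    sim <- simulateBinaryGwas(nSnps = 120, logorSd = 0, seed = 300 + s)
    fit <- fitExpectedVsReported(buildEffectComparisons(sim$table))
    fit$slope >= 0.8 && fit$slope <= 1.20
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("emitted binary z-scores invert through the expected log OR", {
  sim <- simulateBinaryGwas(nSnps = 25, seed = 17)
  d <- ssData(sim$table)
  for (i in seq_len(10)) {
    r <- expectedLnOR(d$beta[i] / d$se[i], pmin(d$eaf[i], 1 - d$eaf[i]),
                      d$n_cases[i], d$n_controls[i])
    # the reconstruction reproduces the reported estimate up to the small
    # difference between reported EAF and generating MAF
    expect_equal(r$b, d$beta[i], tolerance = 0.05)
  }
})

test_that("injected frequency errors produce their designated patterns", {
  sim <- simulateBinaryGwas(seed = 31)
  refs <- makeReferenceSets(sim$labels, sim$table, seed = 32)

  flip <- injectError(sim$table, sim$labels, "eaf_is_noneffect", seed = 33)
  rec <- checkMafVsReference(flip$table, refs$mafRef)$data
  v <- classifyFrequencyPattern(rec$recoded, rec$ref_maf)
  expect_equal(v$classification, "systematic_flip")

  mafc <- injectError(sim$table, sim$labels, "eaf_is_maf", seed = 34)
  rec2 <- checkMafVsReference(mafc$table, refs$mafRef)$data
  v2 <- classifyFrequencyPattern(rec2$recoded, rec2$ref_maf)
  expect_equal(v2$classification, "maf_coded")

  expect_equal(flip$labels$injected_error, "eaf_is_noneffect")
  expect_setequal(flip$labels$affected_rsids, ssData(sim$table)$rsid)
})

test_that("a flipped effect allele column conflicts on every comparable SNP", {
  sim <- simulateBinaryGwas(seed = 35)
  refs <- makeReferenceSets(sim$labels, sim$table, seed = 36)
  flip <- injectError(sim$table, sim$labels, "flip_effect_allele",
                      seed = 37)
  res <- checkDirectionVsTopHits(flip$table, refs$tophits)
  expect_equal(res$verdict$conflict_fraction, 1.0)
  expect_equal(res$verdict$classification, "systematic_flip")
})

test_that("incompatible error/trait combinations are rejected", {
  sim <- simulateContinuousGwas(nSnps = 20, seed = 41)
  expect_error(injectError(sim$table, sim$labels, "linear_scale"),
               "binary")
  expect_error(injectError(sim$table, sim$labels, "not_an_error"))
  expect_error(injectError(sim$table, sim$labels, "wrong_n", fraction = 0))
})

test_that("reference sets respect their own invariants", {
  sim <- simulateBinaryGwas(seed = 51)
  refs <- makeReferenceSets(sim$labels, sim$table, seed = 52)
  # MAF reference restricted to the [0.1, 0.35] band, no palindromic tophits
  pops <- attr(refs$mafRef, "populations")
  m <- as.matrix(refs$mafRef[pops])
  expect_true(all(m >= 0.1 & m <= 0.35))
  true_maf <- pmin(sim$labels$true_eaf, 1 - sim$labels$true_eaf)
  low <- names(true_maf)[true_maf < 0.1]
  expect_false(any(low %in% refs$mafRef$rsid))
  expect_false(any(isPalindromic(refs$tophits$effect_allele,
                                 refs$tophits$other_allele)))
  # requesting more tophits than reference-significant SNPs warns
  expect_warning(makeReferenceSets(sim$labels, sim$table, nTopHits = 5000,
                                   seed = 53), "available")
  # an uncorrupted table agrees with its own references: no high flags
  rep <- runFullQc(sim$table, tophits = refs$tophits, mafRef = refs$mafRef,
                   ld = refs$ld, knownHits = refs$knownHits)
  expect_false(any(qcFlags(rep)$level == "high"))
  expect_equal(disposition(rep), "pass")
})

test_that("the fixture bundle round-trips through the readers", {
  sim <- simulateBinaryGwas(nSnps = 60, seed = 61)
  refs <- suppressWarnings(makeReferenceSets(sim$labels, sim$table,
                                             seed = 62))
  dir <- file.path(tempdir(), "bundle_a")
  files <- writeFixtureBundle(dir, sim$table, sim$labels, refs)
  expect_true(all(file.exists(files)))
  ss <- readSumStats(files[["sumstats"]], traitType = "binary")
  expect_equal(nRecords(ss), 60)
  th <- suppressMessages(readTopHits(files[["tophits"]]))
  expect_gt(nrow(th), 0)
  ref <- suppressMessages(readMafReference(files[["maf_reference"]]))
  expect_gt(nrow(ref), 0)
  ld <- readLdTable(files[["ld"]])
  expect_true(all(c("rsid_a", "rsid_b", "r2") %in% names(ld)))
  # byte-identical bundles from the same seed
  dir2 <- file.path(tempdir(), "bundle_b")
  sim2 <- simulateBinaryGwas(nSnps = 60, seed = 61)
  refs2 <- suppressWarnings(makeReferenceSets(sim2$labels, sim2$table,
                                              seed = 62))
  files2 <- writeFixtureBundle(dir2, sim2$table, sim2$labels, refs2)
  for (k in names(files)) {
    expect_identical(readLines(files[[k]]), readLines(files2[[k]]))
  }
})
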