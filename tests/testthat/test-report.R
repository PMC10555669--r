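cleanFixture <- function(seed = 7, nSnps = 200) {
  sim <- simulateBinaryGwas(nSnps = nSnps, seed = seed)
  refs <- makeReferenceSets(sim$labels, sim$table, seed = seed + 5000)
  list(sim = sim, refs = refs)
}

runOn <- function(sset, refs, ...) {
  runFullQc(sset, tophits = refs$tophits, mafRef = refs$mafRef,
            ld = refs$ld, knownHits = refs$knownHits, ...)
}

test_that("a clean fixture passes with an unflagged slope and exact P-Z", {
  fx <- cleanFixture(seed = 7)
  rep <- runOn(fx$sim$table, fx$refs)
  expect_equal(disposition(rep), "pass")
  expect_true(rep@slope$assessable)
  expect_gte(rep@slope$slope, 0.8)
  expect_lte(rep@slope$slope, 1.20)
  expect_gte(rep@pz$r, 0.999)
  expect_equal(dispositionStatus(disposition(rep)), 0L)
  v <- qcVerdicts(rep)
  expect_equal(v$classification[v$check == "direction_vs_tophits"],
               "consistent")
  expect_equal(v$classification[v$check == "maf_vs_reference"],
               "consistent")
})

test_that("a flipped effect allele column drives an exclusion recommendation", {
  fx <- cleanFixture(seed = 8)
  flip <- injectError(fx$sim$table, fx$sim$labels, "flip_effect_allele",
                      seed = 9)
  rep <- runOn(flip$table, fx$refs)
  expect_equal(disposition(rep), "exclude-recommended")
  expect_equal(dispositionStatus(disposition(rep)), 3L)
  expect_true(any(grepl("non-effect allele", recommendations(rep))))
})

test_that("a flip with few weak top hits yields investigate, not exclude", {
  # sparse, underpowered reference: direction evidence stays ambiguous
  fx <- cleanFixture(seed = 10, nSnps = 150)
  weak <- fx$refs$tophits[1:5, ]
  weak$beta <- weak$beta / 20      # z ~ 1: nothing near p < 1e-4
  weak$pval <- 2 * pnorm(-abs(weak$beta / weak$se))
  flip <- injectError(fx$sim$table, fx$sim$labels, "flip_effect_allele",
                      seed = 11)
  rep <- runFullQc(flip$table, tophits = weak, mafRef = fx$refs$mafRef)
  v <- qcVerdicts(rep)
  expect_equal(v$classification[v$check == "direction_vs_tophits"],
               "ambiguous")
  expect_false(disposition(rep) == "exclude-recommended")
})

test_that("a MAF-coded frequency column triggers the set-EAF-missing advice", {
  fx <- cleanFixture(seed = 12)
  mafc <- injectError(fx$sim$table, fx$sim$labels, "eaf_is_maf", seed = 13)
  rep <- runOn(mafc$table, fx$refs)
  expect_true(any(grepl("set the effect allele frequency to missing",
                        recommendations(rep))))
  expect_equal(disposition(rep), "investigate")
})

test_that("stages lacking references degrade to not assessable", {
  sim <- simulateBinaryGwas(nSnps = 30, seed = 14)
  rep <- runFullQc(sim$table)
  v <- qcVerdicts(rep)
  expect_true(all(v$classification == "ambiguous"))
  expect_true(rep@slope$assessable)  # needs no reference
  expect_s4_class(rep, "QcReport")
})

test_that("the exclude disposition requires systematic evidence", {
  expect_error(new("QcReport", metadata = list(),
                   disposition = "exclude-recommended"),
               "systematic")
  expect_error(new("QcReport", disposition = "maybe"), "disposition")
})

test_that("plots are rendered for every panel, with placeholders when empty", {
  fx <- cleanFixture(seed = 15, nSnps = 80)
  rep <- runOn(fx$sim$table, fx$refs)
  outdir <- file.path(tempdir(), "panels")
  files <- renderPlots(rep, outdir)
  expect_length(files, 4)
  expect_true(all(file.exists(files)))
  # no EAF anywhere: the frequency panels fall back to placeholders
  d <- ssData(fx$sim$table)
  d$eaf <- NA_real_
  noeaf <- sumstatQC:::setSS(fx$sim$table, d)
  rep2 <- runOn(noeaf, fx$refs)
  files2 <- renderPlots(rep2, file.path(tempdir(), "panels2"))
  expect_length(files2, 4)
  expect_true(all(file.exists(files2)))
})

test_that("the CLI runs check, simulate and clump end to end", {
  dir <- file.path(tempdir(), "clifix")
  status <- qcCli(c("simulate", "--out", dir, "--seed", "5",
                    "--n-snps", "80"))
  expect_equal(status, 0L)
  out1 <- file.path(tempdir(), "cliout1")
  status2 <- suppressMessages(qcCli(c(
    "check", "--sumstats", file.path(dir, "sumstats.tsv"),
    "--trait-type", "binary",
    "--tophits", file.path(dir, "tophits.tsv"),
    "--maf-ref", file.path(dir, "maf_reference.tsv"),
    "--ld", file.path(dir, "ld.tsv"),
    "--known-hits", file.path(dir, "known_hits.tsv"),
    "--n-cases", "5000", "--n-controls", "5000",
    "--out", out1, "--seed", "5")))
  expect_equal(status2, 0L)
  expect_true(file.exists(file.path(out1, "qc_report.json")))
  expect_true(file.exists(file.path(out1, "qc_log.txt")))
  expect_true(validateReportJSON(file.path(out1, "qc_report.json")))

  # a flipped fixture exits 3 through the same path
  dirf <- file.path(tempdir(), "clifix_flip")
  qcCli(c("simulate", "--out", dirf, "--seed", "5",
          "--error", "flip_effect_allele"))
  statusf <- suppressMessages(qcCli(c(
    "check", "--sumstats", file.path(dirf, "sumstats.tsv"),
    "--trait-type", "binary",
    "--tophits", file.path(dirf, "tophits.tsv"),
    "--maf-ref", file.path(dirf, "maf_reference.tsv"),
    "--n-cases", "5000", "--n-controls", "5000",
    "--out", file.path(tempdir(), "cliout_flip"), "--seed", "5")))
  expect_equal(statusf, 3L)

  statusc <- qcCli(c("clump", "--sumstats", file.path(dir, "sumstats.tsv"),
                     "--trait-type", "binary",
                     "--ld", file.path(dir, "ld.tsv"),
                     "--out", file.path(tempdir(), "cliclump")))
  expect_equal(statusc, 0L)
  expect_true(file.exists(file.path(tempdir(), "cliclump",
                                    "clump_index_snps.tsv")))

  # unknown flags report usage and exit 1
  expect_equal(suppressMessages(qcCli(c("check", "--bogus"))), 1L)
  expect_equal(suppressMessages(qcCli("frobnicate")), 1L)
})

test_that("every flag in the plot data appears in the flag table", {
  fx <- cleanFixture(seed = 16)
  flip <- injectError(fx$sim$table, fx$sim$labels, "eaf_is_noneffect",
                      seed = 17)
  rep <- runOn(flip$table, fx$refs)
  pd <- rep@plotData$maf
  flagged_rsids <- qcFlags(rep)$rsid[qcFlags(rep)$check == "maf_vs_reference"]
  expect_setequal(pd$rsid[pd$level != "none"], flagged_rsids)
})
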