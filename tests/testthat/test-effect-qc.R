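test_that("expected continuous effects match direct arithmetic", {
  # oracle: compute the closed form step by step
  direct <- function(z, p, n) z / sqrt(2 * p * (1 - p) * (n + z^2))
  expect_equal(expectedBetaContinuous(5, 0.5, 10000),
               5 / sqrt(0.5 * 10025), tolerance = 1e-12)
  expect_equal(round(expectedBetaContinuous(5, 0.5, 10000), 6), 0.070622)
  expect_equal(expectedBetaContinuous(2, 0.2, 1000),
               2 / sqrt(0.32 * 1004), tolerance = 1e-12)
  expect_equal(round(expectedBetaContinuous(2, 0.2, 1000), 5), 0.11158)
  expect_identical(expectedBetaContinuous(0, 0.3, 500), 0)
  set.seed(2)
  z <- rnorm(200, 0, 3); p <- runif(200, 0.01, 0.99)
  n <- runif(200, 100, 1e6)
  expect_equal(expectedBetaContinuous(z, p, n), direct(z, p, n),
               tolerance = 1e-14)
  # antisymmetry and monotonicity in n
  expect_identical(expectedBetaContinuous(z, p, n),
                   -expectedBetaContinuous(-z, p, n))
  expect_true(all(abs(expectedBetaContinuous(z, p, n * 2)) <
                    abs(expectedBetaContinuous(z, p, n))))
  expect_error(expectedBetaContinuous(1, 0, 100), "invalid input")
  expect_error(expectedBetaContinuous(1, 0.5, -1), "invalid input")
})

test_that("the expected log OR solver is self-consistent and sign-correct", {
  for (z in c(-8, -2, 0, 0.5, 3, 12)) {
    for (maf in c(0.1, 0.3, 0.45)) {
      r <- expectedLnOR(z, maf, 2000, 8000)
      if (z == 0) {
        expect_identical(r$b, 0)
        expect_gt(r$se, 0)
      } else {
        expect_equal(r$b / r$se, z, tolerance = 1e-6)
        expect_equal(sign(r$b), sign(z))
      }
    }
  }
  expect_error(expectedLnOR(1, 0.6, 100, 100), "invalid input")
  expect_error(expectedLnOR(1, 0.3, 0, 100), "invalid input")
  # a z-score no attainable log OR can produce
  expect_error(expectedLnOR(1e6, 0.3, 500, 500), "inconsistent")
})

test_that("the solver recovers a simulated true log OR", {
  # simulate case-control data at the true effect, fit logistic regression,
  # feed the resulting mean z back: the solver must return the true effect
  # within Monte-Carlo error
  mc <- oracleLnOR(b = 0.25, maf = 0.3, phi = 0.5, N = 10000,
                   nReps = 25, seed = 101)
  b_solver <- expectedLnOR(mean(mc$z_hat), 0.3, 5000, 5000)$b
  mc_se <- sd(mc$b_hat) / sqrt(length(mc$b_hat))
  expect_lt(abs(b_solver - mean(mc$b_hat)), 3 * mc_se)
  expect_lt(abs(b_solver - 0.25), 4 * mc_se + 0.01)
})

test_that("linear-scale effects rescale to log odds ratios and back", {
  expect_equal(transformLinearToLogOR(0.004, u = 0.02)$beta,
               0.004 / 0.0196, tolerance = 1e-12)
  expect_equal(round(transformLinearToLogOR(0.004, u = 0.02)$beta, 5),
               0.20408)
  expect_equal(transformLinearToLogOR(0.1, u = 0.5)$beta, 0.4)
  expect_identical(transformLinearToLogOR(0, u = 0.37)$beta, 0)
  tr <- transformLinearToLogOR(0.03, 0.01, u = 0.05)
  expect_equal(tr$se, 0.01 / (0.05 * 0.95))
  back <- transformLogORToLinear(tr$beta, tr$se, u = 0.05)
  expect_equal(back$beta, 0.03, tolerance = 1e-12)
  expect_equal(back$se, 0.01, tolerance = 1e-12)
  expect_error(transformLinearToLogOR(1, u = 0), "invalid input")
  expect_error(transformLinearToLogOR(1, u = 1.2), "invalid input")
})

test_that("the expected-vs-reported regression flags distorted scales", {
  set.seed(14)
  expected <- rnorm(50, 0, 0.1)
  # identity: slope 1, not flagged
  f1 <- fitExpectedVsReported(data.frame(reported = expected,
                                         expected = expected))
  expect_equal(f1$slope, 1.0, tolerance = 1e-12)
  expect_false(f1$flagged)
  # inflated reporting scale: reported = 1.5 * expected -> slope 2/3
  f2 <- fitExpectedVsReported(data.frame(reported = 1.5 * expected,
                                         expected = expected))
  expect_equal(f2$slope, 1 / 1.5, tolerance = 1e-10)
  expect_true(f2$flagged)
  # mean-zero noise at 5% of the spread keeps the slope near 1
  reported <- expected + rnorm(50, 0, 0.05 * sd(expected))
  f3 <- fitExpectedVsReported(data.frame(reported = reported,
                                         expected = expected))
  expect_gt(f3$slope, 0.9)
  expect_lt(f3$slope, 1.1)
  expect_false(f3$flagged)
  # fewer than 10 points: not assessable
  f4 <- fitExpectedVsReported(data.frame(reported = expected[1:5],
                                         expected = expected[1:5]))
  expect_false(f4$assessable)
})

test_that("deviations relate inversely to imputation quality", {
  # low-info SNPs with large deviations, high-info with small ones
  info <- rep(c(0.95, 0.5), each = 10)
  dev <- rep(c(1, 40), each = 10)
  ss <- toySet(20, info = info)
  cmp <- data.frame(rsid = ssData(ss)$rsid, reported = 0.1, expected = 0.1,
                    z = 1, pct_deviation = dev)
  res <- deviationVsQuality(cmp, ss)
  expect_lt(res$correlations[["info"]], 0)
  expect_equal(nrow(res$flags), 10)  # the info < 0.8 SNPs
  expect_true(all(grepl("info", res$flags$reason)))
  # constant metric: correlation undefined, reported missing
  ss2 <- toySet(20, info = 1.0)
  res2 <- deviationVsQuality(cmp, ss2)
  expect_true(is.na(res2$correlations[["info"]]))
})

test_that("P-Z consistency is exact for self-consistent data and catches corruption", {
  set.seed(23)
  beta <- rnorm(100, 0, 0.2)
  se <- runif(100, 0.02, 0.1)
  pval <- 2 * pnorm(-abs(beta / se))
  res <- pzConsistency(beta, se, pval)
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  expect_false(res$flagged)
  # permuting 10% of the P-values breaks the correlation
  corrupt <- pval
  idx <- sample(100, 10)
  corrupt[idx] <- corrupt[sample(idx)]
  res2 <- pzConsistency(beta, se, corrupt)
  expect_lt(res2$r, 0.99)
  expect_true(res2$flagged)
  # a huge z with p near 1 is listed as an outlier
  beta2 <- c(beta, 9.9); se2 <- c(se, 0.1); p2 <- c(pval, 0.95)
  res3 <- pzConsistency(beta2, se2, p2)
  expect_equal(nrow(res3$outliers), 1)
  expect_equal(res3$outliers$pval, 0.95)
  # p = 0 is capped, not fatal
  p3 <- pval; p3[1] <- 0
  res4 <- pzConsistency(beta, se, p3)
  expect_equal(res4$zero_p_capped, 1)
  expect_true(is.finite(res4$r))
})

test_that("extreme log odds ratios are flagged on the log-odds scale only", {
  ss <- toySet(3, beta = c(1.2, -0.99, -1.5), scale = "log_odds")
  fl <- flagExtremeEffects(ss)
  expect_setequal(fl$rsid, c("rs1", "rs3"))
  # not on the log-odds scale: nothing flagged
  ss2 <- toySet(3, beta = c(1.2, -0.99, -1.5), scale = "sd_units")
  expect_equal(nrow(flagExtremeEffects(ss2)), 0)
  expect_equal(nrow(flagExtremeEffects(toySet(0, scale = "log_odds"))), 0)
})
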