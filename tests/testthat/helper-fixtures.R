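# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data files.

# minimal record table with sensible defaults, overridable per column
toyRecords <- function(n = 5, ...) {
  if (n == 0) return(toyRecords(1, ...)[0, , drop = FALSE])
  d <- data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    chr = "1",
    pos = seq_len(n) * 1e5,
    effect_allele = rep(c("A", "C", "G", "A", "C"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "A"), length.out = n),
    eaf = seq(0.1, 0.45, length.out = n),
    beta = seq(-0.2, 0.2, length.out = n),
    se = rep(0.05, n),
    pval = rep(0.01, n),
    n = rep(10000, n),
    n_cases = NA_real_, n_controls = NA_real_,
    info = rep(0.99, n), hwe_p = rep(0.5, n), het_p = rep(0.5, n),
    n_studies = rep(3, n), scale = "sd_units",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

toySet <- function(n = 5, traitType = "continuous", ...) {
  SumStatSet(toyRecords(n, ...), traitName = "toy", traitType = traitType,
             ancestry = "EUR", publicationId = "TESTPUB")
}

writeTsv <- function(d, path = tempfile(fileext = ".tsv")) {
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "NA")
  path
}

# random clumping instance with sparse pairwise LD
randomInstance <- function(n_max = 50) {
  n <- sample(2:n_max, 1)
  d <- toyRecords(
    n,
    chr = as.character(sample(1:3, n, replace = TRUE)),
    pos = sample(1:5e7, n),
    pval = 10^runif(n, -12, 0))
  pairs <- t(combn(seq_len(n), 2))
  keep <- runif(nrow(pairs)) < 0.15
  ld <- data.frame(rsid_a = d$rsid[pairs[keep, 1]],
                   rsid_b = d$rsid[pairs[keep, 2]],
                   r2 = runif(sum(keep)), stringsAsFactors = FALSE)
  list(d = d, ld = ld)
}

# independent brute-force clumper: literal restatement of the greedy rule
# with naive O(n^2) scans, used as the oracle for ldClump
bruteClump <- function(d, ld, pThreshold, r2Threshold, kbWindow) {
  r2of <- function(a, b) {
    hit <- (ld$rsid_a == a & ld$rsid_b == b) |
      (ld$rsid_a == b & ld$rsid_b == a)
    if (any(hit)) max(ld$r2[hit]) else 0
  }
  d <- d[!is.na(d$pval) & d$pval < pThreshold, , drop = FALSE]
  d <- d[order(d$pval, d$chr, d$pos, d$rsid), , drop = FALSE]
  unassigned <- rep(TRUE, nrow(d))
  index <- character(0)
  members <- list()
  while (any(unassigned)) {
    i <- which(unassigned)[1]
    unassigned[i] <- FALSE
    index <- c(index, d$rsid[i])
    mem <- character(0)
    for (j in which(unassigned)) {
      if (identical(d$chr[j], d$chr[i]) &&
          abs(d$pos[j] - d$pos[i]) <= kbWindow * 1000 &&
          r2of(d$rsid[i], d$rsid[j]) >= r2Threshold) {
        mem <- c(mem, d$rsid[j])
        unassigned[j] <- FALSE
      }
    }
    members[[d$rsid[i]]] <- mem
  }
  list(index = index, members = members)
}

# independent Monte-Carlo oracle for the expected log OR: individual-level
# additive logistic model, intercept pinned to the case fraction by
# bisection, aggregated-genotype logistic fit per replicate
oracleLnOR <- function(b, maf, phi, N, nReps, seed) {
  set.seed(seed)
  g <- 0:2
  f <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  target <- function(a) sum(f * plogis(a + b * g)) - phi
  lo <- -50; hi <- 50
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (target(mid) > 0) hi <- mid else lo <- mid
  }
  a <- (lo + hi) / 2
  mu <- plogis(a + b * g)
  b_hat <- z_hat <- numeric(nReps)
  for (r in seq_len(nReps)) {
    ng <- as.vector(rmultinom(1, N, f))
    cases <- rbinom(3, ng, mu)
    fit <- glm(cbind(cases, ng - cases) ~ g, family = binomial())
    cf <- summary(fit)$coefficients
    b_hat[r] <- cf["g", "Estimate"]
    z_hat[r] <- cf["g", "Estimate"] / cf["g", "Std. Error"]
  }
  list(b_hat = b_hat, z_hat = z_hat)
}
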