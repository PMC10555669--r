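---
title: "Quality control of GWAS summary statistics for two-sample MR"
author: "sumstatQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of GWAS summary statistics for two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumstatQC)
```

## The problem

Two-sample Mendelian randomization consumes GWAS summary statistics collated
from many sources: consortium websites, supplementary tables, files shared by
correspondence. Two classes of defect recur in such data and can bias a
downstream MR analysis badly:

* **metadata errors** — the column labelled "effect allele" actually holds
  the non-effect allele (every effect sign flips), or the effect allele
  frequency column holds the frequency of the other allele or the minor
  allele frequency;
* **analytical issues** — effect sizes on an undeclared scale (e.g.
  absolute-risk effects from a linear mixed model of a binary trait),
  incorrect sample sizes, unfiltered low-quality imputed variants producing
  false-positive hits, or P-values inconsistent with the reported effect
  sizes.

None of these is visible from a single file in isolation. The pipeline in
this package detects them by comparing the test data set to (i) a
catalogue-style table of known top hits, (ii) a consensus
minor-allele-frequency reference, and (iii) theoretical expectations for the
effect sizes implied by the data set's own z-scores, allele frequencies and
sample sizes.

## The checks

### Effect allele orientation

For SNPs shared with the top-hits reference, test and reference records are
harmonized to the same effect allele (strand complementing is applied only
when direct allele matching fails; palindromic A/T and C/G variants are
excluded because their strand cannot be resolved). A conflict is an opposite
sign of effect after harmonization. Conflicts are graded *high* when the
association has P < 1e-4 in **both** data sets — a sign flip of a strong
association is very unlikely by chance — and *moderate* otherwise; if the two
data sets are the same publication every conflict is high. A data set in
which ≥ 80% of at least 10 comparable SNPs conflict, with at least half of
the conflicts high, is classified as a systematic flip: the effect allele
column refers to the non-effect allele. A small or weak comparison set stays
*ambiguous* — all-discordant-but-weak evidence is compatible with chance and
warrants investigation, not automatic exclusion.

### Effect allele frequency

Two comparisons. Against top hits: after harmonization the EAF should fall on
the same side of 0.5 in both data sets; conflicts are high when the minor
allele frequency is ≤ 0.4 in both (frequencies near 0.5 cross sides by
chance) or when the frequencies differ by more than ten percentage points.
Against the consensus-MAF reference: the reported frequency is recoded to the
reference minor allele, and a correctly coded data set must then show a minor
allele frequency, i.e. a value below 0.5, close to the reference MAF.
Per-SNP conflicts (recoded > 0.5) are high at ≥ 0.58 or when differing from
the reference by > 10 points.

The reference is restricted to SNPs with the same minor allele across all
superpopulations and MAF in [0.1, 0.35] in each; this makes the check
ancestry-agnostic, because no allele can drift across the 0.5 boundary
between populations. The data set level pattern of recoded frequencies is
classified numerically: conflict fraction ≥ 0.8 with correlation ≤ −0.5 is a
**systematic flip** (EAF column holds the non-effect allele frequency);
conflict fraction in [0.3, 0.7] with both the conforming subset and the
reflected conflicting subset correlating ≥ +0.5 with the reference is
**MAF-coded** (the EAF column is a minor allele frequency; recommended action
is to set it to missing); conflict fraction ≤ 0.05 with correlation ≥ +0.5 is
**consistent**; anything else is ambiguous. These cutoffs operationalize the
visual judgements "vast majority" and "approximately half"; they are recorded
in every report and overridable from the config. Correlations with each
superpopulation column are also reported descriptively — the best-correlated
population is information about the ancestry of the test sample — but never
used for exclusion.

### Expected vs reported effect sizes

For a continuous trait analysed on a standardized scale, the per-allele
effect implied by a z-score $z$, minor allele frequency $p$ and sample size
$n$ is

$$\hat\beta = \frac{z}{\sqrt{2p(1-p)\,(n + z^2)}},$$

the SD change in the trait per allele copy under an additive model. For a
binary trait the analogous expectation is the log odds ratio $b$ solving
$b/\mathrm{SE}(b) = z$, where $\mathrm{SE}(b)$ is derived from the expected
Fisher information of an additive logistic model: genotypes at HWE
proportions for the folded reported frequency, intercept pinned so the
model-implied case fraction matches the reported case/control counts, and
$\mathrm{SE}(b) = \sqrt{[I^{-1}]_{bb}/N}$. The solver brackets the monotone
fixed point to a tolerance of 1e-8 on $z$ (the bracket is grown adaptively
from $z\,\mathrm{SE}(0)$, because the information collapses for extreme log
odds ratios and $b/\mathrm{SE}(b)$ is monotone only over the plausible
range). A Monte-Carlo simulation of individual-level case-control data with
logistic fits — available as `simulateLnOR()` — is the independent oracle for
this solver in the test suite; the deterministic expected-information route
is used in the pipeline so regression tests are exact.

Expected effects are regressed (OLS, with intercept, as the published
protocol words it; the intercept is reported) on reported effects: a slope
above 1.20 or below 0.8 flags an unusual distribution — a scale conflict, a
sample-size error, or unfiltered low-quality variants. Because both axes
derive from the same z-score, the regression effectively compares the
reported standard errors with the frequency/sample-size expectation, which is
why inflated-variance SNPs and wrong sample sizes move the slope. The
absolute percentage deviation, $100\,(\text{reported} -
\text{expected})/\text{expected}$ (expected in the denominator; the report
metadata records this choice, and zero-expected SNPs are dropped), is also
correlated (Spearman) against imputation info scores, HWE and heterogeneity
P-values; SNPs with info < 0.8 are flagged.

P-Z consistency compares $z_b = \beta/\mathrm{SE}$ with the signed normal
quantile of the reported P-value; a Pearson correlation below 0.99 flags the
data set and below 0.90 is treated as irreconcilable. P-values of exactly 0
are capped at the smallest representable positive double, computed in log
space. SNPs with $|z_b| > 5$ but P > 0.9 are listed as outliers. Log odds
ratios beyond ±1 are flagged as implausibly large for common variants.

### Instruments

Greedy LD clumping (default P < 5e-8, r² ≥ 0.01, 10 000 kb window,
index-to-candidate inclusive — the window convention is recorded in the
result since conventions differ) selects index SNPs by ascending P; missing
LD pairs count as r² = 0 because local LD tables are sparse. Index SNPs are
compared to a known-hits table: an index absent from it, and with no known
hit within 200 kb on the same chromosome, is *novel* and flags the data set
— the signature of false positives from unfiltered variants, although a
larger-than-published study can produce genuine novel hits. Proxies are SNPs
at r² ≥ 0.8 with a query. A config-off post-GWAS filter (MAF ≥ 5%,
info ≥ 0.5, more than one contributing study) mirrors the corrective
filtering that resolves such false positives; it is off by default because
the required fields are often absent.

One caveat discovered while validating the clumper: the intuition that a
lower r² threshold can only merge clumps (never increase the index count) is
not strictly true for greedy clumping. A best hit weakly linked to the hub of
a strongly linked cluster can absorb the hub at a permissive threshold and
strand the rest of the cluster as separate indices. The property holds
exactly when each LD block has a single common r² (the regime the tests
exercise); with heterogeneous pairwise r² it holds typically but not
universally. This is inherent to the greedy algorithm, not an implementation
artifact — the implementation is verified against a brute-force restatement
of the rule on hundreds of random instances.

## Preflight filters

Before any check: standard errors are recovered from confidence intervals
(preferred; level defaults to 0.95) or from $|\beta|/z_p$; rsids are resolved
from a chromosome/position lookup and alias identifiers are rewritten to
canonical rsids. Then exclusions, each logged per record so that
input = retained + logged always holds: all copies of duplicated rsids
(keeping an arbitrary copy would risk exactly the silent errors the pipeline
exists to catch), rsids with more than two distinct alleles, records with
missing effect size or standard error, and — for binary traits — records
with a minor allele count $2N\,\mathrm{MAF} < 50$ in either cases or
controls, comparing the real-valued count without rounding. Records with
missing EAF skip the MAC rule with a note rather than an exclusion.
Ambiguous headers such as A1/A2 are never guessed at: the loader demands an
explicit column map and fails loudly otherwise.

## The synthetic-data generator

`simulateBinaryGwas()` / `simulateContinuousGwas()` draw, per SNP: MAF
uniform on [0.05, 0.5] with the effect allele equally likely to be the minor
or major allele; a true effect from N(0, sd²) with sd = 0.15 on the log-odds
scale (per-allele odds ratios mostly between 0.74 and 1.35, the range typical
of common-variant associations) and 0.05 SD for continuous traits; a
contributing-sample fraction uniform on [0.15, 1] of the nominal 5 000
cases / 5 000 controls — meta-analyses rarely have every cohort contributing
to every SNP, down to single-cohort SNPs; and an estimate drawn normally
around the true effect with the analytic (expected-information or
continuous-trait) standard error. Reported frequencies get binomial sampling
noise. Simulation is at summary level: the sampling distribution of a
per-SNP estimate is normal with the analytic SE, which is exactly what every
check consumes, and it keeps the full calibration experiments fast; the
individual-level mode backs the solver oracle only.

`makeReferenceSets()` derives the references from the *uncorrupted* truth:
top hits re-estimated in an independent reference study ten times the test
sample (catalogue hits come from the largest published meta-analyses; the
size ratio also keeps chance disagreements between test hits and the
known-hits table rare), the MAF reference from true frequencies restricted
to [0.1, 0.35], and a block LD structure (blocks of 5 adjacent SNPs,
within-block r² uniform on [0.5, 0.95], cross-block pairs absent).

`injectError()` reproduces each documented failure mode with truth labels.
Column-level errors (allele flip, EAF errors, scale error, the
constant-sample-size assumption `wrong_n`) default to affecting every
record, because in reality they are properties of a whole column; per-SNP
errors (scrambled P-values, appended unfiltered variants, single-SNP
sample-size typos) default to 10% of records.

What the generator does **not** emulate: realistic LD from population
panels, linkage between frequency and effect size, population stratification,
overlapping samples between test and reference, or pleiotropy — the MR
estimation itself is out of scope. Passing the detection tests therefore
shows that each error mode produces its designed signature under clean
additive sampling, not that the pipeline catches every failure of real
collated data.

## Calibration and problem sizes

The test suite and the acceptance script run the full pipeline on 40 seeded
clean fixtures of 200 SNPs (5 000 cases / 5 000 controls) and require the
pass disposition, a slope inside [0.8, 1.20] and P-Z correlation ≥ 0.999 in
at least 95% of them; the same 40 seeds are reused for the per-error
detection matrix. The expected-log-OR solver is checked against 50
Monte-Carlo logistic fits at N = 20 000 on a grid of MAF {0.1, 0.3, 0.45} ×
case fraction {0.1, 0.5} × log OR {0, 0.1, 0.5}, with agreement required
within 3 Monte-Carlo standard errors, and its fixed point must reproduce the
input z-score to 1e-6. The clumper is compared with a brute-force
restatement on hundreds of random instances of up to 50 SNPs. These sizes
were chosen so the whole battery runs in well under a minute per component
on a laptop while keeping Monte-Carlo standard errors small relative to the
tolerances.

Numerical details worth knowing: the logistic intercept is solved by Newton
with a bisection fallback; clump ties in P break by (chromosome, position,
rsid); frequencies exactly 0.5 have no side and yield a level-`none` note
rather than a conflict; indel alleles pass through but never participate in
strand logic; an EAF outside [0, 1] or a non-positive SE is set missing at
load time with a warning.

## Dispositions and limitations

`exclude-recommended` needs systematic evidence: a direction flip verdict or
an irreconcilable P-Z relationship. Everything else that deserves human
eyes — flagged slope, P-Z below 0.99, frequency-pattern verdicts, high
per-SNP conflicts, extreme effects, novel clump indices — yields
`investigate` with a targeted recommendation (a MAF-coded frequency column,
for example, recommends setting EAF to missing rather than dropping the data
set). The policy is deliberately conservative because a flagged data set is
not necessarily wrong: covariate adjustment in the original GWAS, genuine
HWE deviations or ancestry mismatch with the reference can all move the
diagnostics. The checks also lose power when few established hits exist for
the trait, and the frequency reference's narrow MAF band means it cannot
serve as an ancestry test.
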