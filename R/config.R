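#' Default QC thresholds and parameters
#'
#' All thresholds used anywhere in the pipeline live in this single block so
#' that a report can record exactly which values produced its flags, and so
#' that every one of them can be overridden from a flat YAML config file
#' (\code{\link{readQcConfig}}).
#'
#' The defaults are the operating points of the published QC protocol this
#' package implements:
#' \itemize{
#'   \item \code{p_both_threshold} (1e-4): a direction conflict is "high" only
#'     when the association is significant at this level in both data sets.
#'   \item \code{maf_high_bound} (0.4): an EAF conflict against top hits is
#'     "high" when the minor allele frequency is at or below this in both sets.
#'   \item \code{maf_ref_high} (0.58): a recoded frequency at or above this is
#'     a "high" conflict against the consensus-MAF reference.
#'   \item \code{freq_diff_points} (0.10): frequencies differing by more than
#'     ten percentage points upgrade a conflict to "high".
#'   \item \code{slope_range} (0.8, 1.20): expected-vs-reported slope outside
#'     this range is flagged.
#'   \item \code{pz_min} (0.99): minimum acceptable P-Z correlation;
#'     \code{pz_irreconcilable} (0.90): below this the relationship is treated
#'     as systematically broken.
#'   \item \code{extreme_logor} (1.0): |log OR| above this is an extreme
#'     effect-size flag.
#'   \item \code{info_min} (0.8): SNPs below this imputation-quality score are
#'     flagged.
#'   \item \code{mac_min} (50): minimum minor allele count per group.
#'   \item \code{clump_p} (5e-8), \code{clump_r2} (0.01), \code{clump_kb}
#'     (10000): LD clumping parameters; \code{known_bp_window} (200000):
#'     window for matching index SNPs to known hits; \code{proxy_r2} (0.8):
#'     minimum r-squared for a proxy SNP.
#'   \item pattern-classification cutoffs \code{pattern_flip_fraction} (0.8),
#'     \code{pattern_mafcoded_range} (0.3, 0.7),
#'     \code{pattern_consistent_fraction} (0.05), \code{pattern_cor_min}
#'     (0.5), \code{min_pattern_snps} (20), \code{min_direction_snps} (10):
#'     numeric operationalization of "vast majority" / "approximately half";
#'     recorded in the report so users can override them.
#'   \item \code{ci_level} (0.95): confidence level assumed when inferring
#'     standard errors from confidence intervals.
#'   \item \code{prevalence}: case prevalence used to rescale linear-model
#'     (absolute-risk) effect sizes to log odds ratios; NA unless declared.
#' }
#'
#' @return Named list of parameters.
#' @export
qcDefaults <- function() {
  list(
    p_both_threshold = 1e-4,
    maf_high_bound = 0.4,
    maf_ref_high = 0.58,
    freq_diff_points = 0.10,
    slope_range = c(0.8, 1.20),
    pz_min = 0.99,
    pz_irreconcilable = 0.90,
    pz_outlier_z = 5,
    pz_outlier_p = 0.9,
    extreme_logor = 1.0,
    info_min = 0.8,
    mac_min = 50,
    clump_p = 5e-8,
    clump_r2 = 0.01,
    clump_kb = 10000,
    known_bp_window = 200000,
    proxy_r2 = 0.8,
    pattern_flip_fraction = 0.8,
    pattern_mafcoded_range = c(0.3, 0.7),
    pattern_consistent_fraction = 0.05,
    pattern_cor_min = 0.5,
    min_pattern_snps = 20,
    min_direction_snps = 10,
    min_slope_snps = 10,
    min_pz_snps = 10,
    ci_level = 0.95,
    prevalence = NA_real_,
    postgwas_filter = FALSE,
    postgwas_maf_min = 0.05,
    postgwas_info_min = 0.5
  )
}

#' Read a flat YAML config file and merge it over the defaults
#'
#' Unknown keys raise an error (a misspelt threshold silently doing nothing
#' is exactly the class of mistake this package exists to catch).
#'
#' @param path YAML file of \code{key: value} pairs; vector-valued parameters
#'   such as \code{slope_range} may be given as two-element YAML sequences.
#' @return Named list as \code{\link{qcDefaults}}.
#' @export
readQcConfig <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- qcDefaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, lapply(user, unlist))
}

#' Read a column-map config file
#'
#' A flat YAML map from canonical field name to the raw column header in the
#' summary-statistics file, e.g. \code{beta: "Effect"}. See
#' \code{\link{readSumStats}} for the canonical field names.
#'
#' @param path YAML file.
#' @return Named character vector canonical field -> raw column name.
#' @export
readColumnMap <- function(path) {
  m <- yaml::read_yaml(path)
  vapply(m, as.character, character(1))
}
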