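#' Published endometrial-cancer protein associations
#'
#' The nine FDR-significant protein associations from a proteome-wide MR
#' screen of 1434 plasma proteins against endometrial cancer risk (12,906
#' cases / 108,979 controls), at the precision they were published: OR and
#' 95% CI per SD of genetically predicted protein, raw p-value, the
#' published FDR-adjusted p, and the p-value after conditioning on 19 known
#' risk variants (`NA` where the instrument SNP is itself a risk variant).
#' Shipped as inputs for the package's internal-consistency checks
#' ([consistency_report()], [bh_adjust()] with `m_total = 1434`).
#'
#' @return Tibble with one row per protein.
#' @export
ec_protein_associations <- function() {
  tibble::tribble(
    ~protein_id, ~instruments, ~n_snps, ~or, ~ci_low, ~ci_high, ~pval,
    ~fdr_p_published, ~pval_cond,
    "VCAM-1", "rs3184504", 1L, 0.60, 0.51, 0.70, 1.14e-10, 1.53e-7, NA,
    "RA51D", "rs6838228; rs45446698", 2L, 1.21, 1.13, 1.30, 2.46e-8,
    1.66e-5, 2.46e-8,
    "Desmoglein-2", "rs687621; rs2704050", 2L, 1.27, 1.14, 1.42, 2.18e-5,
    0.01, 2.18e-5,
    "MICB", "rs3134900", 1L, 1.14, 1.07, 1.22, 3.30e-5, 0.01, 2.41e-5,
    "BGAT", "rs505922", 1L, 1.05, 1.02, 1.08, 8.50e-5, 0.02, 8.51e-5,
    "Alkaline phosphatase intestine", "rs550057", 1L, 0.77, 0.68, 0.89,
    1.84e-4, 3.54e-2, 1.84e-4,
    "ST4S6", "rs550057", 1L, 0.82, 0.74, 0.91, 1.84e-4, 3.54e-2, 1.84e-4,
    "GLCE", "rs2519093; rs11854180", 2L, 1.07, 1.03, 1.11, 2.14e-4,
    3.61e-2, 2.14e-4,
    "DC-SIGN", "rs505922; rs145827860", 2L, 1.07, 1.03, 1.10, 3.04e-4,
    4.56e-2, 3.04e-4
  )
}

#' Published replication checks for earlier biomarker candidates
#'
#' OR (95% CI) and p-values reported for previously proposed circulating
#' biomarker candidates that did not replicate in the proteome-wide MR
#' screen; used to exercise [p_from_or_ci()] and [consistency_report()].
#'
#' @return Tibble with columns `protein_id`, `or`, `ci_low`, `ci_high`,
#'   `pval`.
#' @export
ec_replication_candidates <- function() {
  tibble::tribble(
    ~protein_id, ~or, ~ci_low, ~ci_high, ~pval,
    "DKK-1", 0.96, 0.87, 1.07, 0.44,
    "DJ-1", 0.94, 0.87, 1.03, 0.17,
    "GDF-15", 0.98, 0.93, 1.05, 0.59,
    "YKL-40", 1.00, 0.97, 1.03, 0.99,
    "IL-31", 0.95, 0.89, 1.02, 0.17
  )
}

#' Known endometrial-cancer GWAS risk variants used for conditioning
#'
#' The 19 GWAS-identified risk-variant rsIDs conditioned on in the published
#' robustness analysis.
#'
#' @return Character vector of rsIDs.
#' @export
ec_risk_variants <- function() {
  c("rs113998067", "rs148261157", "rs1679014", "rs10835920", "rs9668337",
    "rs3184504", "rs10850382", "rs1129506", "rs882380", "rs1740828",
    "rs2747716", "rs35286446", "rs4733613", "rs139584729", "rs7981863",
    "rs2498796", "rs937213", "rs17601876", "rs11263761")
}

#' The size of the published protein panel
#'
#' Number of proteins screened in the published proteome-wide analysis;
#' the `m_total` of its FDR and Bonferroni corrections.
#'
#' @return Integer, 1434.
#' @export
ec_panel_size <- function() 1434L
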