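#' Per-protein IVW estimates over an instrument table
#'
#' Runs [ivw_estimate()] on each protein's retained instruments
#' (`status == "ok"`) and assembles the results tibble.  Proteins present in
#' the table but with no retained instrument yield an `is_na` row rather
#' than disappearing (as when a single-SNP instrument is absent from one
#' stratum's GWAS).  Proteins whose every catalog row fell below the pQTL
#' threshold are not part of the tested panel and are skipped.
#'
#' @param instruments Output of [build_instruments()].
#' @param stratum Label recorded on every row.
#' @return Tibble with one row per tested protein: `protein_id`, `stratum`,
#'   `n_snps`, `beta`, `se`, `pval`, `or`, `ci_low`, `ci_high`, `is_na`,
#'   plus `snps` and `cis_trans` strings from [instrument_summary()].
#' @export
mr_ivw_all <- function(instruments, stratum = "overall") {
  tested <- instruments |>
    dplyr::filter(.data$status != "below_pqtl_threshold" &
                    .data$status != "duplicate_removed")
  summ <- instrument_summary(tested)
  res <- purrr::map(summ$protein_id, function(p) {
    d <- tested |>
      dplyr::filter(.data$protein_id == p, .data$status == "ok")
    glance(ivw_estimate(d[c("beta_gx", "beta_gy", "se_gy")],
                        protein_id = p, stratum = stratum))
  })
  dplyr::bind_rows(res) |>
    dplyr::left_join(summ[c("protein_id", "snps", "cis_trans")],
                     by = "protein_id")
}

#' Add panel-wide FDR-adjusted p-values to MR results
#'
#' Applies [bh_adjust()] across the analyzable rows, with `m_total`
#' defaulting to the number of proteins tested so that the correction spans
#' the full screened panel even when results are split across calls (set
#' `m_total` explicitly in that case, e.g. 1434 for a full proteome screen
#' of which only the top rows are in hand).
#'
#' @param results Tibble from [mr_ivw_all()].
#' @param m_total Total number of tests in the panel; default: number of
#'   non-`is_na` rows.
#' @param pad Padding p-value for unobserved tests (see [bh_adjust()]).
#' @return `results` with an `fdr_p` column (`NA` for `is_na` rows).
#' @export
add_fdr <- function(results, m_total = NULL, pad = 0.5) {
  ok <- !results$is_na
  m_total <- m_total %||% sum(ok)
  results$fdr_p <- NA_real_
  if (any(ok)) {
    results$fdr_p[ok] <- bh_adjust(results$pval[ok], m_total = m_total,
                                   pad = pad)
  }
  results
}
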