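#' Harmonize pQTL and outcome records onto a shared effect allele
#'
#' Aligns each exposure (pQTL) record with the outcome record of the same
#' `snp_id` so that both effects are expressed per copy of the exposure's
#' effect allele.  The policy is deliberately conservative and deterministic:
#'
#' * identical allele pairs: outcome effect taken as-is;
#' * swapped effect/other alleles: outcome beta sign-flipped, outcome EAF
#'   complemented, `flip_applied = TRUE`;
#' * palindromic SNPs (A/T or C/G) whose minor-allele frequency lies within
#'   `palindrome_eaf_window` of 0.5 in either source: dropped
#'   (`dropped_palindromic`) — strand orientation is not inferable there;
#' * any other allele configuration: `dropped_allele_mismatch` (no strand
#'   inference from flanking sequence is attempted);
#' * SNPs absent from the outcome table: `missing_in_outcome`.
#'
#' @param pqtl Tibble of pQTL records ([read_pqtl_catalog()] layout).
#' @param outcome Tibble of outcome records ([read_outcome_stats()] layout),
#'   `snp_id` unique.
#' @param palindrome_eaf_window Half-width of the ambiguity window around
#'   EAF 0.5 for palindromic SNPs (default 0.08).
#'
#' @return Tibble with one row per `pqtl` row: identifiers, `cis_trans`,
#'   `eaf`, `beta_gx`, `se_gx`, `pval_gx`, the harmonized `beta_gy`, `se_gy`,
#'   `eaf_gy`, plus `flip_applied` and `status` (one of `ok`,
#'   `dropped_palindromic`, `dropped_allele_mismatch`, `missing_in_outcome`).
#'   Effect sizes: `beta_gx` in protein SDs per allele, `beta_gy` in log odds
#'   per allele.
#' @export
harmonize <- function(pqtl, outcome, palindrome_eaf_window = 0.08) {
  if (anyDuplicated(outcome$snp_id) > 0) {
    stop_data("harmonize: outcome snp_id values must be unique")
  }
  idx <- match(pqtl$snp_id, outcome$snp_id)

  x_ea <- pqtl$effect_allele
  x_oa <- pqtl$other_allele
  y_ea <- outcome$effect_allele[idx]
  y_oa <- outcome$other_allele[idx]

  same <- !is.na(idx) & x_ea == y_ea & x_oa == y_oa
  swap <- !is.na(idx) & x_ea == y_oa & x_oa == y_ea
  pal  <- (same | swap) & is_palindromic_pair(x_ea, x_oa)
  y_eaf <- outcome$eaf[idx]
  near_half <- function(f) !is.na(f) & abs(pmin(f, 1 - f) - 0.5) <= palindrome_eaf_window
  ambiguous <- pal & (near_half(pqtl$eaf) | near_half(y_eaf))

  status <- dplyr::case_when(
    is.na(idx)  ~ "missing_in_outcome",
    ambiguous   ~ "dropped_palindromic",
    same | swap ~ "ok",
    TRUE        ~ "dropped_allele_mismatch"
  )
  ok <- status == "ok"

  beta_gy <- ifelse(ok, ifelse(swap, -1, 1) * outcome$beta_gy[idx], NA_real_)
  eaf_gy  <- ifelse(ok, ifelse(swap, 1 - y_eaf, y_eaf), NA_real_)

  tibble::tibble(
    snp_id        = pqtl$snp_id,
    protein_id    = pqtl$protein_id,
    chrom         = pqtl$chrom,
    pos           = pqtl$pos,
    effect_allele = x_ea,
    other_allele  = x_oa,
    cis_trans     = pqtl$cis_trans,
    eaf           = pqtl$eaf,
    beta_gx       = pqtl$beta_gx,
    se_gx         = pqtl$se_gx,
    pval_gx       = pqtl$pval,
    beta_gy       = beta_gy,
    se_gy         = ifelse(ok, outcome$se_gy[idx], NA_real_),
    eaf_gy        = eaf_gy,
    flip_applied  = ok & swap,
    status        = status
  )
}
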