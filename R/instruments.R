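#' Build per-protein instrument sets from a pQTL catalog
#'
#' Reproduces the instrument-construction recipe of a proteome-wide MR
#' screen: per protein, keep catalog associations at the pQTL significance
#' threshold, harmonize each against the outcome GWAS, then enforce
#' independence by greedy r-squared pruning *within* each chromosome
#' (variants on different chromosomes are independent by definition and are
#' never pruned against each other).  Nothing is dropped silently: every
#' catalog row comes back with a status.
#'
#' Policy details:
#' * a SNP listed twice for one protein keeps the row with the smaller
#'   p-value (`duplicate_removed` for the rest);
#' * a harmonized SNP absent from the LD panel is retained only when it is
#'   the sole candidate on its chromosome, otherwise it is excluded
#'   (`dropped_no_ld`) because independence against its neighbours cannot be
#'   established;
#' * the same SNP may instrument several proteins — no cross-protein
#'   deduplication.
#'
#' @param catalog pQTL records ([read_pqtl_catalog()] layout).
#' @param outcome Outcome records for one stratum
#'   ([read_outcome_stats()] layout).
#' @param panel A [genotype_panel()] LD reference.
#' @param pqtl_p_threshold Instrument significance threshold on the pQTL
#'   p-value (default 1.5e-11).
#' @param r2_threshold Same-chromosome independence threshold (default 0.1).
#' @param palindrome_eaf_window Passed to [harmonize()].
#'
#' @return Tibble with one row per catalog row: the [harmonize()] columns
#'   plus a final `status` in `ok`, `below_pqtl_threshold`,
#'   `duplicate_removed`, `missing_in_outcome`, `dropped_palindromic`,
#'   `dropped_allele_mismatch`, `dropped_no_ld`, `pruned_out`.  Rows with
#'   `status == "ok"` form the instrument sets; see [instrument_summary()].
#' @export
build_instruments <- function(catalog, outcome, panel,
                              pqtl_p_threshold = 1.5e-11,
                              r2_threshold = 0.1,
                              palindrome_eaf_window = 0.08) {
  if (nrow(catalog) == 0) stop_data("build_instruments: empty catalog")

  harm <- harmonize(catalog, outcome, palindrome_eaf_window)
  status <- harm$status

  status[catalog$pval > pqtl_p_threshold] <- "below_pqtl_threshold"

  # duplicate (snp, protein) rows: keep smallest catalog p among survivors
  key <- paste(harm$snp_id, harm$protein_id, sep = "\r")
  ord <- order(catalog$pval, seq_len(nrow(catalog)))
  dup <- logical(nrow(catalog))
  dup[ord] <- duplicated(key[ord])
  status[dup & status != "below_pqtl_threshold"] <- "duplicate_removed"

  in_panel <- harm$snp_id %in% panel$map$snp_id
  ok_idx <- which(status == "ok")
  if (length(ok_idx) > 0) {
    groups <- split(ok_idx,
                    paste(harm$protein_id[ok_idx], harm$chrom[ok_idx],
                          sep = "\r"))
    for (idx in groups) {
      if (length(idx) == 1) next  # sole candidate on its chromosome
      no_ld <- idx[!in_panel[idx]]
      status[no_ld] <- "dropped_no_ld"
      idx <- setdiff(idx, no_ld)
      if (length(idx) <= 1) next
      ld <- compute_ld(panel, harm$snp_id[idx])
      kept <- ld_prune(
        tibble::tibble(snp_id = harm$snp_id[idx], pval = harm$pval_gx[idx]),
        ld, r2_threshold
      )
      status[idx[!harm$snp_id[idx] %in% kept]] <- "pruned_out"
    }
  }

  harm$status <- status
  harm
}

#' Per-protein summary of an instrument table
#'
#' @param instruments Output of [build_instruments()].
#' @return Tibble with one row per protein: `n_candidates` (catalog rows at
#'   any status), `n_snps` (retained instruments), `n_cis`, `n_trans`,
#'   `snps` (retained ids, `"; "`-separated) and `analyzable`
#'   (`n_snps > 0`).  Proteins with zero surviving SNPs are present with
#'   `analyzable = FALSE`, never dropped.
#' @export
instrument_summary <- function(instruments) {
  instruments |>
    dplyr::arrange(.data$protein_id, .data$chrom, .data$pos,
                   .data$snp_id) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      n_snps = sum(.data$status == "ok"),
      n_cis = sum(.data$status == "ok" & .data$cis_trans == "cis"),
      n_trans = sum(.data$status == "ok" & .data$cis_trans == "trans"),
      snps = paste(.data$snp_id[.data$status == "ok"], collapse = "; "),
      cis_trans = paste(.data$cis_trans[.data$status == "ok"],
                        collapse = "; "),
      .groups = "drop"
    ) |>
    dplyr::mutate(analyzable = .data$n_snps > 0)
}

#' Write an instruments manifest
#'
#' One row per catalog SNP-protein pair with its harmonized effects and
#' final status; the audit trail of instrument construction.
#'
#' @param instruments Output of [build_instruments()].
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_instruments_manifest <- function(instruments, path) {
  out <- instruments |>
    dplyr::select("protein_id", "snp_id", "chrom", "pos", "cis_trans",
                  "beta_gx", "se_gx", "pval_gx", "beta_gy", "se_gy",
                  "flip_applied", "status")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
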