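# in-code fixture builders shared across test files

pqtl_row <- function(snp_id = "rs1", chrom = "1", pos = 1000L,
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta_gx = 0.3, se_gx = 0.05, pval = 1e-12,
                     protein_id = "P1", cis_trans = "cis") {
  tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta_gx = beta_gx, se_gx = se_gx, pval = pval,
    protein_id = protein_id, cis_trans = cis_trans
  )
}

outcome_row <- function(snp_id = "rs1", chrom = "1", pos = 1000L,
                        effect_allele = "A", other_allele = "G", eaf = 0.3,
                        beta_gy = 0.1, se_gy = 0.05, pval = NULL,
                        n_cases = 1000L, n_controls = 5000L,
                        stratum = "overall") {
  pval <- pval %||% 2 * stats::pnorm(-abs(beta_gy / se_gy))
  tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta_gy = beta_gy, se_gy = se_gy, pval = pval,
    n_cases = n_cases, n_controls = n_controls, stratum = stratum
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a tiny panel with explicitly controlled dosage columns
panel_from_columns <- function(..., chrom = NULL) {
  cols <- list(...)
  dos <- do.call(cbind, cols)
  ids <- names(cols)
  colnames(dos) <- ids
  map <- tibble::tibble(
    snp_id = ids,
    chrom = chrom %||% rep("1", length(ids)),
    pos = seq_along(ids) * 1000L,
    effect_allele = "A", other_allele = "G"
  )
  genotype_panel(dos, map)
}

write_tsv_text <- function(lines, path) {
  writeLines(lines, path)
  path
}

# the fixture bundle is expensive enough to share across tests
fixture_bundle_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "protmr-fixture-bundle")
      if (!file.exists(file.path(dir, "truth.json"))) {
        make_fixture_suite(dir)
      }
    }
    dir
  }
})

fixture_paths <- function(dir = fixture_bundle_dir()) {
  c(panel_dosages = file.path(dir, "panel_dosages.tsv"),
    panel_map = file.path(dir, "panel_map.tsv"),
    catalog = file.path(dir, "pqtl_catalog.tsv"),
    outcome_overall = file.path(dir, "outcome_overall.tsv"),
    outcome_endometrioid = file.path(dir, "outcome_endometrioid.tsv"),
    outcome_non_endometrioid = file.path(dir, "outcome_non_endometrioid.tsv"),
    conditioning = file.path(dir, "conditioning_snps.txt"),
    truth = file.path(dir, "truth.json"))
}

# direct min-over-suffix evaluation of the BH step-up definition
bh_oracle <- function(pvals, m_total = length(pvals), pad = 0.5) {
  full <- c(pvals, rep(pad, m_total - length(pvals)))
  o <- order(full)
  sorted <- full[o]
  adj_sorted <- vapply(seq_along(sorted), function(j) {
    min(1, min(m_total * sorted[j:m_total] / (j:m_total)))
  }, numeric(1))
  out <- numeric(m_total)
  out[o] <- adj_sorted
  out[seq_along(pvals)]
}
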