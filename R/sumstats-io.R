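#' Read a pQTL catalog
#'
#' Parses a tab-delimited catalog of SNP-protein associations (one row per
#' association, per-SD-of-protein effect scale).  Every row is either parsed
#' into a typed record or rejected with a line-numbered reason; rejected rows
#' are attached as the `"rejects"` attribute and reported with a warning.
#' Duplicate `(snp_id, protein_id)` pairs are rejected (first occurrence wins).
#'
#' @param path Path to a tab-delimited file with a header.  Missing values are
#'   encoded `NA`.
#' @param column_map Named character vector mapping the canonical column names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta_gx`, `se_gx`, `pval`, `protein_id`, `cis_trans`) to the column
#'   names used in the file.  Defaults to the canonical names themselves.
#'
#' @return A tibble with one row per valid record and the canonical columns;
#'   attribute `"rejects"` holds a tibble (`line`, `snp_id`, `reason`), where
#'   `line` is the physical file line (header is line 1).
#'
#' @seealso [read_outcome_stats()], [write_pqtl_catalog()]
#' @export
read_pqtl_catalog <- function(path, column_map = NULL) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta_gx", "se_gx", "pval", "protein_id", "cis_trans")
  raw <- read_mapped_table(path, column_map, req)

  rec <- tibble::tibble(
    snp_id        = raw$snp_id,
    chrom         = normalize_chrom(raw$chrom),
    pos           = suppressWarnings(as.integer(raw$pos)),
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    eaf           = suppressWarnings(as.numeric(raw$eaf)),
    beta_gx       = suppressWarnings(as.numeric(raw$beta_gx)),
    se_gx         = suppressWarnings(as.numeric(raw$se_gx)),
    pval          = suppressWarnings(as.numeric(raw$pval)),
    protein_id    = raw$protein_id,
    cis_trans     = tolower(raw$cis_trans)
  )

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) {
    ifelse(is.na(reason) & bad, why, reason)
  }
  reason <- flag(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  reason <- flag(is.na(rec$protein_id) | rec$protein_id == "", "missing protein_id")
  reason <- flag(is.na(rec$pos) | rec$pos < 1, "unparseable or non-positive pos")
  reason <- flag(!is_valid_allele(rec$effect_allele) |
                   !is_valid_allele(rec$other_allele), "invalid allele string")
  reason <- flag(!is.na(rec$effect_allele) &
                   rec$effect_allele == rec$other_allele, "identical alleles")
  reason <- flag(is.na(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1, "eaf outside (0,1)")
  reason <- flag(is.na(rec$beta_gx), "unparseable beta_gx")
  reason <- flag(is.na(rec$se_gx) | rec$se_gx <= 0, "se_gx not > 0")
  reason <- flag(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1, "pval outside (0,1]")
  reason <- flag(!rec$cis_trans %in% c("cis", "trans"), "cis_trans not cis/trans")
  dup <- duplicated(paste(rec$snp_id, rec$protein_id, sep = "\r"))
  reason <- flag(dup & is.na(reason), "duplicate (snp_id, protein_id)")

  finalize_read(rec, reason, key = rec$snp_id)
}

#' Read outcome GWAS summary statistics
#'
#' Parses tab-delimited case-control GWAS summary statistics (log-odds effect
#' scale) for one stratum.  Row-level validation and the rejects report work
#' as in [read_pqtl_catalog()]; `snp_id` must be unique within the file.
#' Rows whose p-value disagrees with the two-sided normal p implied by
#' `beta_gy / se_gy` by more than `pz_tol` (relative) are kept but reported
#' with a warning, since published p-values are rounded.
#'
#' @inheritParams read_pqtl_catalog
#' @param column_map Canonical names here: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_gy`, `se_gy`, `pval`,
#'   `n_cases`, `n_controls`.
#' @param stratum One of `"overall"`, `"endometrioid"`, `"non_endometrioid"`;
#'   recorded on every returned row.
#' @param pz_tol Relative tolerance of the p-value consistency check.
#'
#' @return Tibble of valid records with a `stratum` column; attribute
#'   `"rejects"` as in [read_pqtl_catalog()].
#' @export
read_outcome_stats <- function(path, column_map = NULL,
                               stratum = c("overall", "endometrioid",
                                           "non_endometrioid"),
                               pz_tol = 0.1) {
  stratum <- match.arg(stratum)
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta_gy", "se_gy", "pval", "n_cases", "n_controls")
  raw <- read_mapped_table(path, column_map, req)

  rec <- tibble::tibble(
    snp_id        = raw$snp_id,
    chrom         = normalize_chrom(raw$chrom),
    pos           = suppressWarnings(as.integer(raw$pos)),
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    eaf           = suppressWarnings(as.numeric(raw$eaf)),
    beta_gy       = suppressWarnings(as.numeric(raw$beta_gy)),
    se_gy         = suppressWarnings(as.numeric(raw$se_gy)),
    pval          = suppressWarnings(as.numeric(raw$pval)),
    n_cases       = suppressWarnings(as.integer(raw$n_cases)),
    n_controls    = suppressWarnings(as.integer(raw$n_controls)),
    stratum       = stratum
  )

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(is.na(rec$snp_id) | rec$snp_id == "", "missing snp_id")
  reason <- flag(is.na(rec$pos) | rec$pos < 1, "unparseable or non-positive pos")
  reason <- flag(!is_valid_allele(rec$effect_allele) |
                   !is_valid_allele(rec$other_allele), "invalid allele string")
  reason <- flag(!is.na(rec$effect_allele) &
                   rec$effect_allele == rec$other_allele, "identical alleles")
  reason <- flag(is.na(rec$eaf) | rec$eaf <= 0 | rec$eaf >= 1, "eaf outside (0,1)")
  reason <- flag(is.na(rec$beta_gy), "unparseable beta_gy")
  reason <- flag(is.na(rec$se_gy) | rec$se_gy <= 0, "se_gy not > 0")
  reason <- flag(is.na(rec$pval) | rec$pval <= 0 | rec$pval > 1, "pval outside (0,1]")
  reason <- flag(is.na(rec$n_cases) | rec$n_cases < 0, "n_cases not a count")
  reason <- flag(is.na(rec$n_controls) | rec$n_controls < 0, "n_controls not a count")
  reason <- flag(duplicated(rec$snp_id) & is.na(reason), "duplicate snp_id")

  out <- finalize_read(rec, reason, key = rec$snp_id)

  if (nrow(out) > 0) {
    p_z <- 2 * pnorm(-abs(out$beta_gy / out$se_gy))
    off <- abs(p_z - out$pval) / pmax(out$pval, .Machine$double.xmin) > pz_tol
    if (any(off)) {
      warn(paste0(
        sum(off), " row(s) have p-values inconsistent (> ", pz_tol * 100,
        "% relative) with beta/se under the two-sided normal: ",
        paste(head(out$snp_id[off], 5), collapse = ", ")
      ))
    }
  }
  out
}

# shared reader plumbing: all columns as character, canonical renaming
read_mapped_table <- function(path, column_map, required) {
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  column_map <- column_map %||% setNames(required, required)
  missing_canon <- setdiff(required, names(column_map))
  if (length(missing_canon) > 0) {
    stop_config(paste0("column_map does not cover: ",
                       paste(missing_canon, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  absent <- setdiff(unname(column_map[required]), names(raw))
  if (length(absent) > 0) {
    stop_config(paste0("required column(s) missing from ", path, ": ",
                       paste(absent, collapse = ", ")))
  }
  out <- raw[unname(column_map[required])]
  names(out) <- required
  out
}

finalize_read <- function(rec, reason, key) {
  bad <- !is.na(reason)
  rejects <- tibble::tibble(
    line   = which(bad) + 1L,  # header occupies line 1
    snp_id = key[bad],
    reason = reason[bad]
  )
  out <- rec[!bad, , drop = FALSE]
  attr(out, "rejects") <- rejects
  if (nrow(rejects) > 0) {
    warn(paste0(nrow(rejects), " row(s) rejected; first: line ",
                rejects$line[1], " (", rejects$reason[1], ")"))
  }
  out
}

#' Row-level rejects from a reader
#'
#' @param x A tibble returned by [read_pqtl_catalog()] or
#'   [read_outcome_stats()].
#' @return Tibble with columns `line`, `snp_id`, `reason`.
#' @export
reader_rejects <- function(x) {
  attr(x, "rejects") %||%
    tibble::tibble(line = integer(), snp_id = character(),
                   reason = character())
}

#' Write a pQTL catalog / outcome summary statistics
#'
#' Tab-delimited, header, `NA` for missing; numeric columns are written at
#' full precision so a write/read round trip reproduces the records exactly.
#'
#' @param records Tibble in the corresponding reader's canonical layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pqtl_catalog <- function(records, path) {
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_pqtl_catalog
#' @export
write_outcome_stats <- function(records, path) {
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-study estimates with weights \eqn{w_i = 1 / se_i^2}:
#' \eqn{\hat\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = (\sum w_i)^{-1/2}}.
#'
#' @param betas,ses Equal-length numeric vectors (`ses` all > 0).
#' @return One-row tibble with columns `beta` and `se`.
#'
#' @examples
#' fixed_effects_meta(c(0.2, 0.6), c(0.1, 0.3))
#' @export
fixed_effects_meta <- function(betas, ses) {
  if (length(betas) == 0) stop_data("fixed_effects_meta: empty input")
  if (length(betas) != length(ses)) {
    stop_data("fixed_effects_meta: betas and ses differ in length")
  }
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop_data("fixed_effects_meta: all ses must be finite and > 0")
  }
  w <- 1 / ses^2
  tibble::tibble(beta = sum(w * betas) / sum(w), se = 1 / sqrt(sum(w)))
}

#' Write / re-read an MR results table
#'
#' Emits one row per protein per stratum at publication-style precision:
#' odds ratios and confidence bounds with 2 decimals, p-values in scientific
#' notation with 3 significant digits, `NA` for non-analyzable rows.
#'
#' @param results MR results tibble (as from [mr_ivw_all()] /
#'   [run_overall()]), with columns `protein_id`, `stratum`, `snps`,
#'   `cis_trans`, `n_snps`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pval`,
#'   and optionally `fdr_p` and `pval_cond`.
#' @param path Output path (tab-delimited).
#' @param protein_info Optional tibble (`protein_id`, `gene`, `region`) used
#'   to fill the annotation columns; `NA` otherwise.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, protein_info = NULL) {
  fmt2 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  fmtp <- function(x) ifelse(is.na(x), NA_character_,
                             formatC(x, format = "e", digits = 2))
  n <- nrow(results)
  col_or <- function(nm, default) {
    if (nm %in% names(results)) results[[nm]] else rep(default, n)
  }
  out <- tibble::tibble(
    protein     = results$protein_id,
    gene        = NA_character_,
    region      = NA_character_,
    stratum     = results$stratum,
    instruments = col_or("snps", NA_character_),
    cis_trans   = col_or("cis_trans", NA_character_),
    n_snps      = results$n_snps,
    or          = fmt2(results$or),
    ci_low      = fmt2(results$ci_low),
    ci_high     = fmt2(results$ci_high),
    pval        = fmtp(results$pval),
    fdr_p       = fmtp(col_or("fdr_p", NA_real_)),
    pval_cond   = fmtp(col_or("pval_cond", NA_real_))
  )
  if (!is.null(protein_info)) {
    idx <- match(out$protein, protein_info$protein_id)
    out$gene <- protein_info$gene[idx]
    out$region <- protein_info$region[idx]
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, na = "NA", progress = FALSE,
                  col_types = readr::cols(
                    protein = "c", gene = "c", region = "c", stratum = "c",
                    instruments = "c", cis_trans = "c", n_snps = "i",
                    or = "d", ci_low = "d", ci_high = "d",
                    pval = "d", fdr_p = "d", pval_cond = "d"
                  ))
}
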