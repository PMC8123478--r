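#' Configure an end-to-end MR pipeline run
#'
#' Collects file paths and analysis thresholds, validates them, and returns
#' a `run_config` consumed by [run_overall()] and [run_subtypes()].
#'
#' @param catalog Path to the pQTL catalog.
#' @param outcome Named character vector of outcome summary-statistic paths;
#'   names are strata and must include `"overall"` (e.g. also
#'   `"endometrioid"`, `"non_endometrioid"`).
#' @param panel_dosages,panel_map LD reference panel files ([read_panel()]).
#' @param out_dir Output directory for result tables and logs.
#' @param conditioning Optional path to a known-risk-variant list (one id
#'   per line).
#' @param pqtl_p_threshold,r2_threshold,palindrome_eaf_window Instrument
#'   construction thresholds (see [build_instruments()]).
#' @param fdr_threshold FDR significance cutoff for the overall screen.
#' @param alpha Family-wise alpha for the Bonferroni reference threshold.
#' @param m_total Override for the total number of tests in the FDR
#'   correction (default: number of proteins analyzed).
#' @param conditional_scope Which proteins get conditional MR:
#'   `"significant"` (FDR < `fdr_threshold`, the default), `"all"`, or
#'   `"none"`.
#' @param catalog_map,outcome_map Optional reader column maps.
#' @return A `run_config` list.
#' @export
run_config <- function(catalog, outcome, panel_dosages, panel_map, out_dir,
                       conditioning = NULL,
                       pqtl_p_threshold = 1.5e-11, r2_threshold = 0.1,
                       palindrome_eaf_window = 0.08,
                       fdr_threshold = 0.05, alpha = 0.05, m_total = NULL,
                       conditional_scope = c("significant", "all", "none"),
                       catalog_map = NULL, outcome_map = NULL) {
  conditional_scope <- match.arg(conditional_scope)
  if (is.null(names(outcome)) || !"overall" %in% names(outcome)) {
    stop_config("run_config: outcome must be a named vector with an 'overall' entry")
  }
  for (f in c(catalog, unname(outcome), panel_dosages, panel_map,
              conditioning)) {
    if (!file.exists(f)) stop_config(paste0("file not found: ", f))
  }
  if (pqtl_p_threshold <= 0 || pqtl_p_threshold > 1 ||
      r2_threshold < 0 || r2_threshold > 1 ||
      fdr_threshold <= 0 || fdr_threshold > 1 ||
      alpha <= 0 || alpha > 1) {
    stop_config("run_config: thresholds out of range")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(
    catalog = catalog, outcome = outcome, panel_dosages = panel_dosages,
    panel_map = panel_map, out_dir = out_dir, conditioning = conditioning,
    pqtl_p_threshold = pqtl_p_threshold, r2_threshold = r2_threshold,
    palindrome_eaf_window = palindrome_eaf_window,
    fdr_threshold = fdr_threshold, alpha = alpha, m_total = m_total,
    conditional_scope = conditional_scope,
    catalog_map = catalog_map, outcome_map = outcome_map
  ), class = "run_config")
}

#' Read a conditioning-SNP list
#'
#' Plain text, one variant id per line; blanks ignored, duplicates removed.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_conditioning_list <- function(path) {
  ids <- trimws(readLines(path))
  unique(ids[ids != ""])
}

#' Run the overall proteome-wide MR analysis
#'
#' The full screen: read and validate inputs, build instruments, estimate
#' per-protein IVW effects, adjust over the protein panel with
#' Benjamini-Hochberg, and re-estimate FDR-significant proteins conditional
#' on the known risk variants.  A results table
#' (`results_overall.tsv`) and a reason-coded log (`run_overall.log`) are
#' written to the configured output directory; identical configuration and
#' inputs reproduce both byte for byte.
#'
#' @param config A [run_config()].
#' @return Results tibble (one row per tested protein) with `fdr_p`,
#'   `bonferroni_threshold` attribute, and — where conditional analysis ran
#'   — `pval_cond`.
#' @export
run_overall <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  catalog <- read_pqtl_catalog(config$catalog, config$catalog_map)
  if (nrow(catalog) == 0) {
    stop_data("run_overall: pQTL catalog has no valid rows")
  }
  outcome <- read_outcome_stats(config$outcome[["overall"]],
                                config$outcome_map, "overall")
  panel <- read_panel(config$panel_dosages, config$panel_map)
  note("[read] catalog rows=", nrow(catalog),
       " rejects=", nrow(reader_rejects(catalog)))
  note("[read] outcome rows=", nrow(outcome),
       " rejects=", nrow(reader_rejects(outcome)))

  instr <- build_instruments(
    catalog, outcome, panel,
    pqtl_p_threshold = config$pqtl_p_threshold,
    r2_threshold = config$r2_threshold,
    palindrome_eaf_window = config$palindrome_eaf_window
  )
  dropped <- instr[instr$status != "ok", ]
  for (i in seq_len(nrow(dropped))) {
    note("[instruments] protein=", dropped$protein_id[i],
         " snp=", dropped$snp_id[i], " status=", dropped$status[i])
  }
  note("[instruments] used=", sum(instr$status == "ok"),
       " dropped=", sum(instr$status != "ok"),
       " total=", nrow(instr))

  results <- mr_ivw_all(instr, "overall")
  results <- add_fdr(results, m_total = config$m_total)
  m_used <- config$m_total %||% sum(!results$is_na)
  attr(results, "bonferroni_threshold") <-
    bonferroni_threshold(config$alpha, max(m_used, 1))
  for (i in seq_len(nrow(results))) {
    note("[mr] protein=", results$protein_id[i],
         " n_snps=", results$n_snps[i],
         " p=", signif(results$pval[i], 4),
         " fdr_p=", signif(results$fdr_p[i], 4))
  }

  results$pval_cond <- NA_real_
  if (!is.null(config$conditioning) &&
      config$conditional_scope != "none") {
    cond_ids <- read_conditioning_list(config$conditioning)
    eligible <- if (config$conditional_scope == "all") {
      !results$is_na
    } else {
      !results$is_na & !is.na(results$fdr_p) &
        results$fdr_p < config$fdr_threshold
    }
    cond_records <- outcome[outcome$snp_id %in% cond_ids, ]
    absent <- setdiff(cond_ids, outcome$snp_id)
    if (length(absent) > 0) {
      note("[condition] risk variant(s) absent from outcome stats: ",
           paste(absent, collapse = ", "))
    }
    target_snps <- instr$snp_id[instr$status == "ok" &
                                  instr$protein_id %in%
                                    results$protein_id[eligible]]
    if (length(target_snps) > 0) {
      cond_est <- conditional_estimates(
        outcome[outcome$snp_id %in% setdiff(target_snps,
                                            cond_records$snp_id), ],
        cond_records, panel
      )
      for (p in results$protein_id[eligible]) {
        iv <- instr[instr$protein_id == p & instr$status == "ok", ]
        fit <- conditional_mr(iv, cond_est,
                              conditioning_ids = cond_records$snp_id,
                              protein_id = p)
        results$pval_cond[results$protein_id == p] <- fit$pval
        note("[condition] protein=", p,
             if (fit$is_na) " conditional=NA (instrument is a risk variant or collinear)"
             else paste0(" p_cond=", signif(fit$pval, 4)))
      }
    }
  }

  write_results_table(results,
                      file.path(config$out_dir, "results_overall.tsv"))
  writeLines(log_lines, file.path(config$out_dir, "run_overall.log"))
  results
}

#' Run subtype-stratified MR analyses
#'
#' Repeats the instrument-building and IVW machinery per non-overall
#' stratum.  An instrument SNP missing from a stratum's summary statistics
#' is dropped from that stratum's set; a protein whose entire instrument is
#' missing is reported as an `is_na` row (never silently dropped).  Subtype
#' results carry raw p-values only — the FDR correction belongs to the
#' overall screen.
#'
#' @param config A [run_config()] whose `outcome` names at least one
#'   stratum besides `"overall"`.
#' @return Combined results tibble across strata.
#' @export
run_subtypes <- function(config) {
  stopifnot(inherits(config, "run_config"))
  strata <- setdiff(names(config$outcome), "overall")
  if (length(strata) == 0) {
    stop_config("run_subtypes: no subtype strata configured")
  }
  catalog <- read_pqtl_catalog(config$catalog, config$catalog_map)
  if (nrow(catalog) == 0) {
    stop_data("run_subtypes: pQTL catalog has no valid rows")
  }
  panel <- read_panel(config$panel_dosages, config$panel_map)

  purrr::map(strata, function(s) {
    outcome <- read_outcome_stats(config$outcome[[s]], config$outcome_map,
                                  s)
    instr <- build_instruments(
      catalog, outcome, panel,
      pqtl_p_threshold = config$pqtl_p_threshold,
      r2_threshold = config$r2_threshold,
      palindrome_eaf_window = config$palindrome_eaf_window
    )
    res <- mr_ivw_all(instr, s)
    log_lines <- c(
      paste0("[read] stratum=", s, " outcome rows=", nrow(outcome)),
      paste0("[instruments] used=", sum(instr$status == "ok"),
             " dropped=", sum(instr$status != "ok"),
             " total=", nrow(instr)),
      vapply(seq_len(nrow(res)), function(i) {
        paste0("[mr] stratum=", s, " protein=", res$protein_id[i],
               if (res$is_na[i]) " result=NA (no instrument in stratum)"
               else paste0(" p=", signif(res$pval[i], 4)))
      }, character(1))
    )
    write_results_table(res, file.path(config$out_dir,
                                       paste0("results_", s, ".tsv")))
    writeLines(log_lines, file.path(config$out_dir,
                                    paste0("run_", s, ".log")))
    res
  }) |> dplyr::bind_rows()
}

#' Internal-consistency report for a published-style results table
#'
#' Recomputes each row's p-value from its printed-precision OR and 95% CI
#' via [p_from_or_ci()] and flags rows that disagree with the printed p by
#' more than a factor of `guard` (default 2, a rounding guard: printed ORs
#' carry 2 decimals, so small ratios are expected).
#'
#' @param results Tibble with columns `or`, `ci_low`, `ci_high`, `pval`
#'   (printed precision).
#' @param guard Maximum tolerated fold-change between printed and
#'   recomputed p.
#' @return `results` plus `p_recomputed`, `p_ratio`, `consistent`.
#' @export
consistency_report <- function(results, guard = 2) {
  ok <- !is.na(results$or) & !is.na(results$ci_low) &
    !is.na(results$ci_high) & !is.na(results$pval)
  p_rec <- rep(NA_real_, nrow(results))
  p_rec[ok] <- p_from_or_ci(results$or[ok], results$ci_low[ok],
                            results$ci_high[ok])
  ratio <- pmax(p_rec / results$pval, results$pval / p_rec)
  dplyr::mutate(
    tibble::as_tibble(results),
    p_recomputed = p_rec,
    p_ratio = ratio,
    consistent = ifelse(is.na(ratio), NA, ratio <= guard)
  )
}
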