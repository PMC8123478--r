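#' Approximate conditional association estimates from summary statistics
#'
#' Re-estimates each target SNP's outcome association conditional on a fixed
#' set of known risk variants, using only marginal summary statistics plus a
#' reference LD panel (the summary-data conditional analysis popularised by
#' COJO-style tools).  For each target the normal equations of the joint
#' regression of the phenotype on \{target + conditioning set\} are
#' reconstructed from reference correlations \eqn{r}, allele-frequency
#' variances \eqn{2p(1-p)} and per-SNP effective sample sizes, and solved;
#' the target's joint coefficient and its residual-variance-updated SE are
#' returned.  For case-control traits the effective sample size is
#' \eqn{4 / (1/n_{cases} + 1/n_{controls})} and the log-OR is treated as a
#' linear-scale effect; a quantitative-trait table may instead carry an
#' `n_eff` column.
#'
#' Safeguards: targets with squared correlation \eqn{\ge}
#' `collinearity_r2` against any conditioning SNP are flagged
#' `dropped_collinear` and not estimated; SNPs whose panel allele set does
#' not match the summary statistics, or whose panel allele frequency differs
#' from the summary EAF by more than `freq_mismatch`, are dropped with a
#' note; a numerically singular conditioning LD block is an error naming the
#' block.  Panel dosages coded on the opposite allele are flipped before
#' correlating, so reference LD signs line up with the summary betas.
#'
#' @param targets Outcome records for the SNPs to re-estimate
#'   ([read_outcome_stats()] layout, optionally with `n_eff`).
#' @param conditioning Outcome records for the conditioning SNPs (same
#'   layout, same trait).  Zero rows returns the marginal estimates
#'   unchanged.
#' @param panel A [genotype_panel()] containing all SNPs involved.
#' @param collinearity_r2 Target-vs-conditioning collinearity cutoff
#'   (default 0.9).
#' @param freq_mismatch Maximum tolerated |panel EAF - summary EAF|
#'   (default 0.2).
#' @return Tibble with one row per target: `snp_id`, `beta_cond`, `se_cond`,
#'   `pval_cond`, `dropped_collinear`, `note`.
#' @export
conditional_estimates <- function(targets, conditioning, panel,
                                  collinearity_r2 = 0.9,
                                  freq_mismatch = 0.2) {
  out <- tibble::tibble(
    snp_id = targets$snp_id,
    beta_cond = NA_real_, se_cond = NA_real_, pval_cond = NA_real_,
    dropped_collinear = FALSE, note = NA_character_
  )
  if (nrow(conditioning) == 0) {
    out$beta_cond <- targets$beta_gy
    out$se_cond <- targets$se_gy
    out$pval_cond <- targets$pval
    return(out)
  }

  cond <- align_to_panel(conditioning, panel, freq_mismatch)
  if (any(!is.na(cond$note))) {
    bad <- cond$snp_id[!is.na(cond$note)]
    stop_data(paste0("conditional_estimates: conditioning SNP(s) unusable (",
                     "allele/frequency mismatch with panel): ",
                     paste(bad, collapse = ", ")))
  }
  tar <- align_to_panel(targets, panel, freq_mismatch)

  w_ids <- cond$snp_id
  all_ids <- union(tar$snp_id[is.na(tar$note)], w_ids)
  ld <- compute_ld(panel, all_ids)
  # undo panel allele-coding flips so r matches the summary-stat orientation
  flip <- setNames(ifelse(c(tar$flip[match(all_ids, tar$snp_id)]), -1, 1),
                   all_ids)
  flip[w_ids] <- ifelse(cond$flip, -1, 1)
  flip[is.na(flip)] <- 1
  r_all <- sweep(sweep(ld$r, 1, flip, `*`), 2, flip, `*`)

  v <- function(df) 2 * df$eaf * (1 - df$eaf)
  n_eff_of <- function(df) {
    if ("n_eff" %in% names(df) && !all(is.na(df$n_eff))) {
      df$n_eff
    } else {
      4 / (1 / df$n_cases + 1 / df$n_controls)
    }
  }
  v_w <- v(cond); n_w <- n_eff_of(cond)
  v_t <- v(tar);  n_t <- n_eff_of(tar)

  # scaled cross-products of the conditioning block
  sqn <- sqrt(n_w)
  A_w <- (sqrt(v_w) %o% sqrt(v_w)) * r_all[w_ids, w_ids, drop = FALSE] *
    (sqn %o% sqn)
  diag(A_w) <- v_w * n_w
  if (rcond_safe(A_w) < 1e-10) {
    stop_data(paste0("conditional_estimates: singular conditioning LD block: ",
                     paste(w_ids, collapse = ", ")))
  }
  c_w <- v_w * n_w * cond$beta_gy

  # trait sum of squares reconstructed per SNP; median across all SNPs
  yty_each <- c(
    v_w * n_w * (cond$beta_gy^2 + (n_w - 2) * cond$se_gy^2),
    (v_t * n_t * (tar$beta_gy^2 + (n_t - 2) * tar$se_gy^2))[is.na(tar$note)]
  )
  yty <- median(yty_each)
  n_med <- median(c(n_w, n_t[is.na(tar$note)]))
  k <- length(w_ids)

  for (i in seq_len(nrow(tar))) {
    if (!is.na(tar$note[i])) {
      out$note[i] <- tar$note[i]
      next
    }
    t_id <- tar$snp_id[i]
    if (t_id %in% w_ids) {
      out$dropped_collinear[i] <- TRUE
      out$note[i] <- "target is a conditioning SNP"
      next
    }
    r_tw <- r_all[t_id, w_ids]
    if (max(r_tw^2) >= collinearity_r2) {
      out$dropped_collinear[i] <- TRUE
      out$note[i] <- "collinear with conditioning set"
      next
    }
    s_tw <- sqrt(v_t[i] * v_w) * r_tw * sqrt(n_t[i] * n_w)
    A <- rbind(
      cbind(v_t[i] * n_t[i], matrix(s_tw, nrow = 1)),
      cbind(matrix(s_tw, ncol = 1), A_w)
    )
    cc <- c(v_t[i] * n_t[i] * tar$beta_gy[i], c_w)
    beta_j <- solve(A, cc)
    sigma2 <- max((yty - sum(beta_j * cc)) / (n_med - k - 2), 1e-12)
    Ainv <- solve(A)
    out$beta_cond[i] <- beta_j[1]
    out$se_cond[i] <- sqrt(sigma2 * Ainv[1, 1])
    out$pval_cond[i] <- 2 * pnorm(-abs(out$beta_cond[i] / out$se_cond[i]))
  }
  out
}

# match summary records against the panel map: flip flag when the panel's
# effect allele is the summary other allele; note incompatibilities
align_to_panel <- function(records, panel, freq_mismatch) {
  idx <- match(records$snp_id, panel$map$snp_id)
  out <- tibble::tibble(
    snp_id = records$snp_id,
    eaf = records$eaf,
    beta_gy = records$beta_gy,
    se_gy = records$se_gy,
    flip = FALSE,
    note = NA_character_
  )
  if ("n_eff" %in% names(records)) out$n_eff <- records$n_eff
  if ("n_cases" %in% names(records)) {
    out$n_cases <- records$n_cases
    out$n_controls <- records$n_controls
  }
  out$note[is.na(idx)] <- "absent from panel"
  p_ea <- panel$map$effect_allele[idx]
  p_oa <- panel$map$other_allele[idx]
  same <- !is.na(idx) & records$effect_allele == p_ea &
    records$other_allele == p_oa
  swap <- !is.na(idx) & records$effect_allele == p_oa &
    records$other_allele == p_ea
  out$flip <- swap
  out$note[!is.na(idx) & !(same | swap)] <- "allele mismatch with panel"
  panel_eaf <- colMeans(panel$dosages, na.rm = TRUE)[records$snp_id] / 2
  panel_eaf_aligned <- ifelse(swap, 1 - panel_eaf, panel_eaf)
  far <- !is.na(idx) & (same | swap) &
    abs(panel_eaf_aligned - records$eaf) > freq_mismatch
  out$note[far] <- "allele frequency mismatch with panel"
  out
}

rcond_safe <- function(m) {
  tryCatch(1 / kappa(m, exact = TRUE), error = function(e) 0)
}

#' Conditional MR: IVW after conditioning the outcome associations
#'
#' Replaces each instrument's outcome effect and SE with its conditional
#' counterpart from [conditional_estimates()] and re-runs [ivw_estimate()].
#' A protein whose instrument contains a SNP that is itself a known risk
#' variant (in `conditioning_ids`) or was dropped as collinear cannot be
#' conditioned and yields an `is_na` fit.
#'
#' @param instruments Harmonized instrument rows for one protein
#'   (`status == "ok"`, columns `snp_id`, `beta_gx`, `beta_gy`, `se_gy`).
#' @param conditional Output of [conditional_estimates()] covering the
#'   instrument SNPs.
#' @param conditioning_ids Character vector of risk-variant ids conditioned
#'   on.
#' @param protein_id,stratum Labels for the result.
#' @return An `ivw_fit` (see [glance.ivw_fit()]).
#' @export
conditional_mr <- function(instruments, conditional,
                           conditioning_ids = character(),
                           protein_id = NA_character_,
                           stratum = "overall") {
  empty <- instruments[0, c("beta_gx", "beta_gy", "se_gy")]
  if (any(instruments$snp_id %in% conditioning_ids)) {
    return(ivw_estimate(empty, protein_id, stratum))
  }
  idx <- match(instruments$snp_id, conditional$snp_id)
  if (any(is.na(idx))) {
    stop_data(paste0("conditional_mr: no conditional record for: ",
                     paste(instruments$snp_id[is.na(idx)], collapse = ", ")))
  }
  if (any(conditional$dropped_collinear[idx]) ||
      any(is.na(conditional$beta_cond[idx]))) {
    return(ivw_estimate(empty, protein_id, stratum))
  }
  d <- tibble::tibble(
    beta_gx = instruments$beta_gx,
    beta_gy = conditional$beta_cond[idx],
    se_gy = conditional$se_cond[idx]
  )
  ivw_estimate(d, protein_id, stratum)
}
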