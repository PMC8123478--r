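#' Inverse-variance-weighted causal estimate for one instrument set
#'
#' Combines per-SNP exposure effects \eqn{\beta_{GX,i}} (protein SDs per
#' allele) and outcome effects \eqn{\beta_{GY,i}} (log odds per allele, with
#' SE \eqn{\sigma_{GY,i}}) into the IVW causal estimate
#' \deqn{\hat\beta = \frac{\sum_i \beta_{GX,i}\,\beta_{GY,i}\,
#'   \sigma_{GY,i}^{-2}}{\sum_i \beta_{GX,i}^2\,\sigma_{GY,i}^{-2}}, \qquad
#'   se(\hat\beta) = \Big(\sum_i \beta_{GX,i}^2\,\sigma_{GY,i}^{-2}
#'   \Big)^{-1/2},}
#' the weighted least-squares slope of \eqn{\beta_{GY}} on \eqn{\beta_{GX}}
#' through the origin with weights \eqn{\sigma_{GY}^{-2}}.  Exposure-side
#' uncertainty (`se_gx`) is deliberately not propagated (first-order IVW
#' under the no-measurement-error assumption); it is carried in the data for
#' diagnostics only.  A single SNP reduces exactly to the Wald ratio
#' \eqn{\beta_{GY}/\beta_{GX}} with \eqn{se = \sigma_{GY}/|\beta_{GX}|}.
#' The two-sided p-value is normal: \eqn{2(1 - \Phi(|\hat\beta/se|))}.
#'
#' @param data Tibble of harmonized instruments with columns `beta_gx`,
#'   `beta_gy`, `se_gy` (one row per SNP; rows with other [harmonize()]
#'   statuses should be filtered out first).  Zero rows yield a
#'   non-analyzable fit (`is_na = TRUE`), mirroring a protein whose whole
#'   instrument is unavailable in the outcome GWAS.
#' @param protein_id,stratum Optional labels carried into the result.
#'
#' @return An object of class `ivw_fit`; see [glance.ivw_fit()] for the
#'   one-row summary and [tidy.ivw_fit()] for per-SNP Wald ratios.
#'
#' @examples
#' fit <- ivw_estimate(tibble::tibble(
#'   beta_gx = c(0.5, 1.0), beta_gy = c(0.2, 0.3), se_gy = c(0.1, 0.1)
#' ))
#' glance(fit)
#' @export
ivw_estimate <- function(data, protein_id = NA_character_,
                         stratum = "overall") {
  n <- nrow(data)
  if (n == 0) {
    fit <- list(protein_id = protein_id, stratum = stratum, n_snps = 0L,
                beta = NA_real_, se = NA_real_, pval = NA_real_,
                is_na = TRUE, data = data)
    class(fit) <- "ivw_fit"
    return(fit)
  }
  if (any(!is.finite(data$se_gy)) || any(data$se_gy <= 0)) {
    stop_data("ivw_estimate: all se_gy must be finite and > 0")
  }
  if (any(data$beta_gx == 0)) {
    stop_data("ivw_estimate: beta_gx of 0 gives an undefined ratio")
  }
  if (n == 1) {
    # Wald ratio, the exact single-SNP reduction of the IVW sums
    beta <- data$beta_gy / data$beta_gx
    se <- data$se_gy / abs(data$beta_gx)
  } else {
    w <- data$se_gy^-2
    den <- sum(data$beta_gx^2 * w)
    beta <- sum(data$beta_gx * data$beta_gy * w) / den
    se <- 1 / sqrt(den)
  }
  fit <- list(
    protein_id = protein_id, stratum = stratum, n_snps = n,
    beta = beta, se = se, pval = 2 * pnorm(-abs(beta / se)),
    is_na = FALSE, data = data
  )
  class(fit) <- "ivw_fit"
  fit
}

#' @export
print.ivw_fit <- function(x, ...) {
  if (x$is_na) {
    cat("IVW fit <", x$protein_id, ">: not analyzable (no instruments)\n")
    return(invisible(x))
  }
  ci <- to_odds_ratio(x$beta, x$se)
  cat(sprintf(
    "IVW fit <%s> [%s]: %d SNP(s)\n  log-OR/SD %.4f (se %.4f)  OR %.2f (95%% CI %.2f-%.2f)  p = %.3g\n",
    x$protein_id, x$stratum, x$n_snps, x$beta, x$se,
    ci$or, ci$ci_low, ci$ci_high, x$pval
  ))
  invisible(x)
}

#' Per-SNP Wald ratios of an IVW fit
#'
#' @param x An `ivw_fit`.
#' @param ... Unused.
#' @return Tibble with one row per instrument SNP: the inputs plus the
#'   single-SNP Wald ratio `estimate` (`beta_gy / beta_gx`) and its
#'   `std.error` (`se_gy / |beta_gx|`).
#' @export
tidy.ivw_fit <- function(x, ...) {
  d <- tibble::as_tibble(x$data)
  d$estimate <- d$beta_gy / d$beta_gx
  d$std.error <- d$se_gy / abs(d$beta_gx)
  d
}

#' One-row summary of an IVW fit
#'
#' @param x An `ivw_fit`.
#' @param ... Unused.
#' @return One-row tibble: `protein_id`, `stratum`, `n_snps`, `beta`, `se`,
#'   `pval`, `or`, `ci_low`, `ci_high`, `is_na` (log-OR per SD of genetically
#'   predicted protein; OR obtained by exponentiation with a 1.96 normal
#'   multiplier).
#' @export
glance.ivw_fit <- function(x, ...) {
  ci <- if (x$is_na) {
    tibble::tibble(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  } else {
    to_odds_ratio(x$beta, x$se)
  }
  tibble::tibble(
    protein_id = x$protein_id, stratum = x$stratum, n_snps = x$n_snps,
    beta = x$beta, se = x$se, pval = x$pval,
    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high, is_na = x$is_na
  )
}

#' Log-odds effect to odds ratio with 95% CI
#'
#' @param beta,se Numeric vectors on the log-odds scale.
#' @return Tibble with `or = exp(beta)`, `ci_low = exp(beta - 1.96 se)`,
#'   `ci_high = exp(beta + 1.96 se)`.
#'
#' @examples
#' to_odds_ratio(0.1906, 0.0358)
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se < 0, na.rm = TRUE)) stop_data("to_odds_ratio: se must be >= 0")
  tibble::tibble(
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  )
}

#' Recover a two-sided p-value from a printed OR and 95% CI
#'
#' Inverts [to_odds_ratio()]: `beta = log(or)`,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`, p =
#' `2 * (1 - pnorm(|beta / se|))`.  Useful for checking the internal
#' consistency of published association tables.
#'
#' @param or,ci_low,ci_high Numeric vectors with
#'   `0 < ci_low < ci_high`.
#' @return Numeric vector of p-values.
#'
#' @examples
#' p_from_or_ci(0.96, 0.87, 1.07)  # ~0.44
#' @export
p_from_or_ci <- function(or, ci_low, ci_high) {
  if (any(ci_low <= 0 | ci_high <= ci_low, na.rm = TRUE)) {
    stop_data("p_from_or_ci: need 0 < ci_low < ci_high")
  }
  beta <- log(or)
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  2 * pnorm(-abs(beta / se))
}
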