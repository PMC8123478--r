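#' Benjamini-Hochberg step-up adjustment over a panel of m tests
#'
#' Standard BH adjusted p-values, generalised to the situation where only the
#' smallest `length(pvals)` p-values of a panel of `m_total` tests are
#' available (as when a publication reports only the significant rows of a
#' proteome-wide screen).  The unobserved tests are padded with `pad`
#' (default 0.5): any pad at least as large as the observed adjusted values
#' leaves the observed adjustments unchanged, so 0.5 is inert for top-of-table
#' p-values.  For rank `j` (ascending), the adjusted value is
#' \eqn{\min_{k \ge j} m\,p_{(k)} / k}, capped at 1, returned in input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param m_total Total number of tests in the panel (default
#'   `length(pvals)`).
#' @param pad P-value imputed for the `m_total - length(pvals)` unobserved
#'   tests.
#' @return Adjusted p-values, same length and order as `pvals`.
#'
#' @examples
#' bh_adjust(c(1e-6, 0.003, 0.04))
#' bh_adjust(c(1e-6, 0.003, 0.04), m_total = 1434)
#' @export
bh_adjust <- function(pvals, m_total = length(pvals), pad = 0.5) {
  n <- length(pvals)
  if (n == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop_data("bh_adjust: p-values must lie in (0, 1]")
  }
  if (m_total < n) stop_data("bh_adjust: m_total < length(pvals)")
  full <- c(pvals, rep(pad, m_total - n))
  o <- order(full)
  adj <- rev(cummin(rev(m_total * full[o] / seq_len(m_total))))
  adj <- pmin(adj, 1)
  out <- numeric(m_total)
  out[o] <- adj
  out[seq_len(n)]
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m_total Number of tests.
#' @return `alpha / m_total`.
#'
#' @examples
#' bonferroni_threshold(0.05, 1434)
#' @export
bonferroni_threshold <- function(alpha, m_total) {
  if (any(alpha <= 0 | alpha > 1)) stop_data("alpha must be in (0, 1]")
  if (any(m_total < 1)) stop_data("m_total must be >= 1")
  alpha / m_total
}
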