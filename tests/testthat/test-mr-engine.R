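test_that("IVW reduces to the Wald ratio for one SNP and pools multiple SNPs", {
  one <- ivw_estimate(tibble::tibble(beta_gx = 1.0, beta_gy = 0.5,
                                     se_gy = 0.1))
  expect_equal(one$beta, 0.5)
  expect_equal(one$se, 0.1)

  # hand computation: numerator 40, denominator 125
  two <- ivw_estimate(tibble::tibble(beta_gx = c(0.5, 1.0),
                                     beta_gy = c(0.2, 0.3),
                                     se_gy = c(0.1, 0.1)))
  expect_equal(two$beta, 0.32)
  expect_equal(two$se, 0.0894427, tolerance = 1e-6)

  # duplicated SNP: same point estimate, se shrinks by sqrt(2)
  dup <- ivw_estimate(tibble::tibble(beta_gx = c(1, 1), beta_gy = c(0.4, 0.4),
                                     se_gy = c(0.2, 0.2)))
  expect_equal(dup$beta, 0.4)
  expect_equal(dup$se, 0.2 / sqrt(2))

  empty <- ivw_estimate(tibble::tibble(beta_gx = numeric(0),
                                       beta_gy = numeric(0),
                                       se_gy = numeric(0)),
                        protein_id = "none")
  expect_true(empty$is_na)
  expect_true(glance(empty)$is_na)
  expect_error(ivw_estimate(tibble::tibble(beta_gx = 0, beta_gy = 1,
                                           se_gy = 0.1)),
               class = "protmr_data_error")
})

test_that("IVW equals weighted least squares through the origin and the Wald ratio exactly", {
  withr::local_seed(101)
  max_db <- 0
  max_ds <- 0
  for (i in 1:300) {
    k <- sample(1:10, 1)
    d <- tibble::tibble(
      beta_gx = runif(k, 0.05, 1.5) * sample(c(-1, 1), k, TRUE),
      beta_gy = rnorm(k, 0, 0.3),
      se_gy = runif(k, 0.01, 0.5)
    )
    fit <- ivw_estimate(d)
    w <- d$se_gy^-2
    ls <- lm(beta_gy ~ 0 + beta_gx, data = d, weights = w)
    beta_ls <- unname(coef(ls))
    # lm's se assumes estimated dispersion; rescale to the fixed-dispersion
    # (sigma = 1) summary-statistics convention for an independent se route
    se_ls <- unname(summary(ls)$coefficients[1, 2] / summary(ls)$sigma)
    max_db <- max(max_db, abs(fit$beta - beta_ls))
    if (k > 1) max_ds <- max(max_ds, abs(fit$se - se_ls))
    if (k == 1) {
      expect_identical(fit$beta, d$beta_gy / d$beta_gx)
      expect_identical(fit$se, d$se_gy / abs(d$beta_gx))
    }
  }
  expect_lt(max_db, 1e-10)
  expect_lt(max_ds, 1e-10)
})

test_that("IVW se ignores outcome betas and shrinks as instruments accrue", {
  withr::local_seed(17)
  d <- tibble::tibble(beta_gx = runif(5, 0.2, 1), beta_gy = rnorm(5),
                      se_gy = runif(5, 0.05, 0.3))
  d2 <- d
  d2$beta_gy <- rnorm(5)
  expect_equal(ivw_estimate(d)$se, ivw_estimate(d2)$se)
  for (k in 2:5) {
    expect_lt(ivw_estimate(d[1:k, ])$se, ivw_estimate(d[1:(k - 1), ])$se)
  }
})

test_that("odds-ratio conversion and its inverse behave as printed tables do", {
  null <- to_odds_ratio(0, 0.1)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low, exp(-0.196))
  expect_equal(null$ci_high, exp(0.196))
  expect_equal(null$ci_low, 0.822, tolerance = 1e-3)
  expect_equal(null$ci_high, 1.2165, tolerance = 1e-3)

  # matches a published-style row at 2-decimal rounding
  row <- to_odds_ratio(0.1906, 0.0358)
  expect_equal(round(unlist(row), 2), c(or = 1.21, ci_low = 1.13,
                                        ci_high = 1.30))

  # monotone in beta at fixed se
  betas <- seq(-0.5, 0.5, length.out = 11)
  ors <- to_odds_ratio(betas, 0.2)
  expect_true(all(diff(ors$or) > 0))
  expect_true(all(diff(ors$ci_low) > 0))
  expect_true(all(diff(ors$ci_high) > 0))
})

test_that("p_from_or_ci recovers p-values from printed OR/CI and round-trips", {
  expect_equal(round(p_from_or_ci(0.96, 0.87, 1.07), 2), 0.44)
  # symmetric CI around the null gives p = 1
  for (L in c(0.5, 0.8, 0.99)) {
    expect_equal(p_from_or_ci(1, L, 1 / L), 1)
  }
  # direct normal-CDF oracle
  z <- log(2) / (log(2.6667 / 1.5) / 3.92)
  expect_equal(p_from_or_ci(2.0, 1.5, 2.6667), 2 * (1 - pnorm(z)))
  expect_error(p_from_or_ci(1, 1.2, 1.1), class = "protmr_data_error")

  withr::local_seed(33)
  for (i in 1:50) {
    b <- rnorm(1)
    s <- runif(1, 0.01, 1)
    ci <- to_odds_ratio(b, s)
    expect_equal(p_from_or_ci(ci$or, ci$ci_low, ci$ci_high),
                 2 * pnorm(-abs(b / s)), tolerance = 1e-12)
  }
})

test_that("bh_adjust matches the exhaustive min-over-suffix oracle and p.adjust", {
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))
  withr::local_seed(55)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    p <- runif(n)^sample(1:3, 1)
    p <- pmin(pmax(p, 1e-12), 1)
    m <- n + sample(c(0, 0, 3, 50), 1)
    expect_equal(bh_adjust(p, m_total = m), bh_oracle(p, m_total = m))
    # the classic no-padding case agrees with stats::p.adjust
    expect_equal(bh_adjust(p), unname(stats::p.adjust(p, "BH")))
  }
  # adjusted values are monotone in rank and permutation-stable
  p <- c(1e-5, 2e-4, 0.01, 0.04, 0.2, 0.9)
  adj <- bh_adjust(p, m_total = 100)
  expect_true(all(diff(adj[order(p)]) >= 0))
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm], m_total = 100), adj[perm])
  expect_error(bh_adjust(c(0.1, 0)), class = "protmr_data_error")
  expect_error(bh_adjust(c(0.1, 0.2), m_total = 1),
               class = "protmr_data_error")
})

test_that("published FDR cells are reproduced by padding the panel to full size", {
  pub <- ec_protein_associations()
  adj <- bh_adjust(pub$pval, m_total = ec_panel_size())
  expect_equal(round(adj[pub$protein_id == "Desmoglein-2"], 2), 0.01)
  expect_equal(round(adj[pub$protein_id == "BGAT"], 2), 0.02)
  expect_true(all(adj < 0.05))
})

test_that("Bonferroni threshold is alpha over the panel size", {
  expect_equal(bonferroni_threshold(0.05, 1434), 0.05 / 1434)
  expect_equal(signif(bonferroni_threshold(0.05, 1434), 5), 3.4868e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  ms <- c(1, 10, 100, 1434, 5000)
  expect_true(all(diff(bonferroni_threshold(0.05, ms)) < 0))
})
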