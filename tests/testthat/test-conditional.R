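# linear-trait summary stats for a genotype matrix, in outcome layout
linear_summary <- function(y, panel) {
  st <- protmr:::marginal_linear_stats(y, panel$dosages)
  tibble::tibble(
    snp_id = panel$map$snp_id, chrom = panel$map$chrom,
    pos = panel$map$pos, effect_allele = panel$map$effect_allele,
    other_allele = panel$map$other_allele,
    eaf = colMeans(panel$dosages) / 2,
    beta_gy = st$beta, se_gy = st$se, pval = st$pval,
    n_cases = NA_integer_, n_controls = NA_integer_,
    n_eff = length(y)
  )
}

ten_snp_panel <- function(n = 5000, seed = 7) {
  scen <- sim_scenario(
    n_snps = 10, n_blocks = 2, within_block_rho = 0.5,
    maf_range = c(0.15, 0.45), n_reference = n, seed = seed,
    pqtl_effects = list(p = tibble::tibble(snp_index = 1L, beta = 0.4))
  )
  simulate_panel(scen)
}

test_that("an empty conditioning set returns the marginal estimates unchanged", {
  panel <- ten_snp_panel(800, seed = 12)
  withr::local_seed(12)
  y <- as.numeric(panel$dosages %*% c(0.2, rep(0, 9)) + rnorm(800))
  rec <- linear_summary(y, panel)
  ce <- conditional_estimates(rec, rec[0, ], panel)
  expect_equal(ce$beta_cond, rec$beta_gy)
  expect_equal(ce$se_cond, rec$se_gy)
  expect_false(any(ce$dropped_collinear))
})

test_that("orthogonal conditioning leaves estimates at their marginal values", {
  # cross-block SNPs are independent by construction; condition a block-2
  # target on block-1 SNPs of a near-orthogonal panel
  scen <- sim_scenario(n_snps = 6, n_blocks = 6, within_block_rho = 0,
                       maf_range = c(0.2, 0.4), n_reference = 4000, seed = 5,
                       pqtl_effects = list(p = tibble::tibble(snp_index = 1L,
                                                              beta = 0.4)))
  panel <- simulate_panel(scen)
  withr::local_seed(5)
  y <- as.numeric(panel$dosages %*% c(0.3, 0.1, rep(0, 4)) + rnorm(4000))
  rec <- linear_summary(y, panel)
  ce <- conditional_estimates(rec[3:6, ], rec[1:2, ], panel)
  expect_equal(ce$beta_cond, rec$beta_gy[3:6], tolerance = 0.02)
})

test_that("conditional estimates match the individual-level multiple-regression oracle", {
  panel <- ten_snp_panel(5000, seed = 7)
  X <- panel$dosages
  withr::local_seed(7)
  b_true <- c(0.3, 0, 0.2, 0, 0, 0.15, 0, 0, 0, 0)
  y <- as.numeric(X %*% b_true + rnorm(5000))
  rec <- linear_summary(y, panel)
  cond_ids <- c("rs00001", "rs00003")
  targets <- rec[!rec$snp_id %in% cond_ids, ]
  ce <- conditional_estimates(targets, rec[rec$snp_id %in% cond_ids, ],
                              panel)
  oracle <- vapply(targets$snp_id, function(t) {
    unname(coef(lm(y ~ X[, c(t, cond_ids)]))[2])
  }, numeric(1))
  expect_lt(max(abs(ce$beta_cond - oracle)), 0.05)
  # ...and the reconstructed SEs track the oracle's SEs
  se_oracle <- vapply(targets$snp_id, function(t) {
    summary(lm(y ~ X[, c(t, cond_ids)]))$coefficients[2, 2]
  }, numeric(1))
  expect_lt(max(abs(ce$se_cond - se_oracle)), 0.02)
})

test_that("collinear targets and panel mismatches are flagged, singular blocks error", {
  panel <- ten_snp_panel(1000, seed = 8)
  withr::local_seed(8)
  y <- as.numeric(panel$dosages[, 1] * 0.3 + rnorm(1000))
  rec <- linear_summary(y, panel)

  # a target that IS a conditioning SNP is collinear by definition
  ce <- conditional_estimates(rec[1:2, ], rec[1:2, ], panel)
  expect_true(all(ce$dropped_collinear))

  # near-duplicate column: r2 above the collinearity cutoff
  dup_map <- dplyr::bind_rows(panel$map,
                              tibble::tibble(snp_id = "dup", chrom = "1",
                                             pos = 99000L,
                                             effect_allele = "A",
                                             other_allele = "G"))
  dup_panel <- genotype_panel(cbind(panel$dosages,
                                    dup = panel$dosages[, 1]), dup_map)
  rec_dup <- rec[1, ]
  rec_dup$snp_id <- "dup"
  ce2 <- conditional_estimates(rec_dup, rec[1, ], dup_panel)
  expect_true(ce2$dropped_collinear)

  # duplicated conditioning columns make the block singular -> named error
  expect_error(
    conditional_estimates(rec[3, ],
                          dplyr::bind_rows(rec[1, ], rec_dup), dup_panel),
    "singular"
  )

  # allele-frequency disagreement with the panel is refused with a note
  rec_far <- rec[5, ]
  rec_far$eaf <- min(rec_far$eaf + 0.5, 0.95)
  ce3 <- conditional_estimates(rec_far, rec[1, ], panel)
  expect_match(ce3$note, "frequency mismatch")
  expect_true(is.na(ce3$beta_cond))
})

test_that("conditional se grows as target-conditioning LD grows", {
  ses <- vapply(c(0.1, 0.5, 0.8), function(rho) {
    scen <- sim_scenario(n_snps = 2, n_blocks = 1, within_block_rho = rho,
                         maf_range = c(0.3, 0.3), n_reference = 4000,
                         seed = 40,
                         pqtl_effects = list(p = tibble::tibble(
                           snp_index = 1L, beta = 0.4)))
    panel <- simulate_panel(scen)
    withr::local_seed(40)
    y <- as.numeric(panel$dosages[, 2] * 0.2 + rnorm(4000))
    rec <- linear_summary(y, panel)
    conditional_estimates(rec[1, ], rec[2, ], panel)$se_cond
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("pure LD leakage is removed: mean conditional effect of a null target is ~0", {
  # target SNP has no direct effect; its marginal effect is entirely LD
  # leakage from a conditioning causal neighbour
  withr::local_seed(99)
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    scen <- sim_scenario(n_snps = 2, n_blocks = 1, within_block_rho = 0.7,
                         maf_range = c(0.25, 0.35), n_reference = 1500,
                         seed = 5000 + i,
                         pqtl_effects = list(p = tibble::tibble(
                           snp_index = 1L, beta = 0.4)))
    panel <- simulate_panel(scen)
    y <- as.numeric(panel$dosages[, 2] * 0.3 + rnorm(1500))
    rec <- linear_summary(y, panel)
    conditional_estimates(rec[1, ], rec[2, ], panel)$beta_cond
  }, numeric(1))
  marg <- vapply(1:20, function(i) {
    scen <- sim_scenario(n_snps = 2, n_blocks = 1, within_block_rho = 0.7,
                         maf_range = c(0.25, 0.35), n_reference = 1500,
                         seed = 5000 + i,
                         pqtl_effects = list(p = tibble::tibble(
                           snp_index = 1L, beta = 0.4)))
    panel <- simulate_panel(scen)
    y <- as.numeric(panel$dosages[, 2] * 0.3 + rnorm(1500))
    linear_summary(y, panel)$beta_gy[1]
  }, numeric(1))
  expect_gt(mean(marg), 0.05)          # leakage is real before conditioning
  expect_lt(abs(mean(est)), 0.02)      # and gone after
})

test_that("conditional MR re-runs IVW on conditional effects with NA semantics", {
  instr <- tibble::tibble(
    snp_id = c("rs1", "rs2"), beta_gx = c(0.5, 1.0),
    beta_gy = c(0.2, 0.3), se_gy = c(0.1, 0.1)
  )
  unchanged <- tibble::tibble(
    snp_id = c("rs1", "rs2"), beta_cond = c(0.2, 0.3),
    se_cond = c(0.1, 0.1), pval_cond = c(0.1, 0.1),
    dropped_collinear = FALSE, note = NA_character_
  )
  base <- ivw_estimate(instr[, c("beta_gx", "beta_gy", "se_gy")])
  fit <- conditional_mr(instr, unchanged)
  expect_equal(fit$pval, base$pval)

  halved <- unchanged
  halved$beta_cond <- halved$beta_cond / 2
  expect_equal(conditional_mr(instr, halved)$beta, base$beta / 2)

  # an instrument that is itself a known risk variant cannot be conditioned
  fit_na <- conditional_mr(instr, unchanged, conditioning_ids = "rs2")
  expect_true(fit_na$is_na)
  collinear <- unchanged
  collinear$dropped_collinear[1] <- TRUE
  collinear$beta_cond[1] <- NA
  expect_true(conditional_mr(instr, collinear)$is_na)
  expect_error(conditional_mr(instr, unchanged[1, ]),
               class = "protmr_data_error")
})
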