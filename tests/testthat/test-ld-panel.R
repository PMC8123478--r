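test_that("compute_ld gives exact correlations for constructed columns", {
  withr::local_seed(2)
  x <- sample(0:2, 120, replace = TRUE)
  noisy <- pmin(pmax(x + sample(c(-1, 0, 1), 120, TRUE, c(.2, .6, .2)), 0), 2)
  panel <- panel_from_columns(a = x, b = 2 - x, c = noisy)
  ld <- compute_ld(panel)
  expect_equal(ld$r["a", "a"], 1)
  expect_equal(ld$r["a", "b"], -1)           # complemented allele coding
  expect_equal(ld$r["a", "b"]^2, 1)
  expect_equal(ld$r, t(ld$r), tolerance = 1e-12)
  expect_equal(unname(diag(ld$r)), rep(1, 3))
  # mean imputation keeps a column with missing dosages usable
  x_na <- as.numeric(x); x_na[c(5, 50)] <- NA
  panel_na <- panel_from_columns(a = x_na, b = 2 - x)
  expect_lt(abs(compute_ld(panel_na)$r["a", "b"] + 1), 0.05)
  # constant columns are an explicit error naming the SNP
  panel_const <- panel_from_columns(a = x, z = rep(1, 120))
  expect_error(compute_ld(panel_const), "z")
})

test_that("simulated correlated pair lands near its construction's population LD", {
  # shared-latent construction: two SNPs in one AR(1) block; the population
  # dosage correlation (below the latent rho, since thresholding attenuates)
  # comes from a direct large-sample correlation oracle
  mk_scen <- function(n, seed) {
    sim_scenario(n_snps = 2, n_blocks = 1, within_block_rho = 0.75,
                 maf_range = c(0.3, 0.3), n_reference = n, seed = seed,
                 pqtl_effects = list(p = tibble::tibble(snp_index = 1L,
                                                        beta = 0.4)))
  }
  big <- simulate_panel(mk_scen(100000, 31))
  r_pop <- cor(big$dosages[, 1], big$dosages[, 2])
  expect_gt(r_pop, 0.3)  # a genuinely linked pair

  panel <- simulate_panel(mk_scen(200, 3))
  r <- compute_ld(panel)$r[1, 2]
  expect_equal(cor(panel$dosages[, 1], panel$dosages[, 2]), r)
  expect_lt(abs(r - r_pop), 0.15)
})

test_that("greedy pruning keeps the best SNP and enforces pairwise independence", {
  withr::local_seed(5)
  n <- 400
  shared <- rnorm(n)
  mk <- function(w) {
    z <- w * shared + sqrt(1 - w^2) * rnorm(n)
    as.numeric(cut(z, c(-Inf, qnorm(0.3), qnorm(0.8), Inf))) - 1
  }
  panel <- panel_from_columns(A = mk(0.9), B = mk(0.9), C = mk(0.05))
  ld <- compute_ld(panel)
  r2 <- ld$r^2

  # two nearly independent SNPs: both retained under the strict < threshold
  two <- tibble::tibble(snp_id = c("A", "C"), pval = c(1e-12, 1e-8))
  expect_equal(sort(ld_prune(two, ld, r2_threshold = r2["A", "C"] + 1e-6)),
               c("A", "C"))
  # correlated pair: only the smaller p-value survives
  expect_gt(r2["A", "B"], 0.25)
  expect_equal(ld_prune(tibble::tibble(snp_id = c("A", "B"),
                                       pval = c(1e-12, 1e-8)), ld, 0.25),
               "A")
  # chain A-B, B-C dependent, A-C independent, p-ranked A<B<C -> {A, C}
  panel2 <- panel_from_columns(A = mk(0.8), B = mk(0.8), C = mk(0.8))
  # force r2(A,C) low by rebuilding C independently
  panel2$dosages[, "C"] <- mk(0.0)
  ld2 <- compute_ld(panel2)
  cand <- tibble::tibble(snp_id = c("A", "B", "C"),
                         pval = c(1e-12, 1e-10, 1e-8))
  th <- max(ld2$r["A", "C"]^2, ld2$r["B", "C"]^2) + 1e-6
  expect_equal(ld_prune(cand, ld2, r2_threshold = max(th, 0.1)),
               c("A", "C"))
  expect_error(ld_prune(tibble::tibble(snp_id = "nope", pval = 1e-3), ld),
               class = "protmr_data_error")
})

test_that("pruning output is order-invariant and respects threshold extremes", {
  withr::local_seed(6)
  for (i in 1:15) {
    m <- sample(3:7, 1)
    g <- matrix(sample(0:2, 250 * m, TRUE), 250, m)
    # inject correlation between random pairs
    for (j in seq_len(m - 1)) {
      if (runif(1) < 0.5) g[, j + 1] <- pmin(pmax(g[, j] +
        sample(c(-1, 0, 1), 250, TRUE, c(.3, .4, .3)), 0), 2)
    }
    ids <- paste0("s", seq_len(m))
    colnames(g) <- ids
    panel <- genotype_panel(g, tibble::tibble(
      snp_id = ids, chrom = "1", pos = seq_len(m) * 100L,
      effect_allele = "A", other_allele = "G"
    ))
    ld <- compute_ld(panel)
    cand <- tibble::tibble(snp_id = ids, pval = runif(m, 1e-14, 1e-6))
    kept <- ld_prune(cand, ld, 0.1)
    # pairwise independence always holds among the retained set
    if (length(kept) > 1) {
      r2k <- ld$r[kept, kept]^2
      expect_lt(max(r2k[upper.tri(r2k)]), 0.1)
    }
    # input order never matters
    perm <- cand[sample(m), ]
    expect_equal(ld_prune(perm, ld, 0.1), kept)
    # threshold above any r2 retains everything; 0 keeps only uncorrelated
    expect_equal(sort(ld_prune(cand, ld, 1 + 1e-9)), sort(ids))
    kept0 <- ld_prune(cand, ld, 1e-12)
    if (length(kept0) > 1) {
      rk0 <- ld$r[kept0, kept0]
      expect_lt(max(abs(rk0[upper.tri(rk0)])), 1e-6)
    }
  }
})

test_that("panel text round trip and VCF ingestion agree with the source dosages", {
  scen <- sim_scenario(n_snps = 4, n_blocks = 2, n_reference = 30, seed = 9,
                       pqtl_effects = list(p = tibble::tibble(snp_index = 1L,
                                                              beta = 0.4)))
  panel <- simulate_panel(scen)
  d <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, d, m)
  back <- read_panel(d, m)
  expect_equal(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$map, panel$map)

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt_of <- function(x) c("0/0", "0/1", "1/1")[x + 1]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("I", 1:30)), collapse = "\t"))
  body <- vapply(seq_len(4), function(j) {
    paste(c(panel$map$chrom[j], panel$map$pos[j], panel$map$snp_id[j],
            panel$map$other_allele[j], panel$map$effect_allele[j], ".",
            "PASS", ".", "GT", gt_of(panel$dosages[, j])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf)
  vp <- panel_from_vcf(vcf)
  expect_equal(unname(vp$dosages[, panel$map$snp_id]),
               unname(panel$dosages))
  expect_equal(vp$map$effect_allele, panel$map$effect_allele)
})
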