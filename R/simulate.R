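#' Define a simulation scenario for synthetic pQTL / GWAS summary data
#'
#' The generative model mirrors the design a proteome-wide two-sample MR
#' screen assumes: SNPs -> circulating protein -> disease.  Genotypes come
#' in LD blocks (one block per chromosome; AR(1) latent correlation
#' `within_block_rho` inside a block, independence across blocks) thresholded
#' to Hardy-Weinberg dosages at MAFs drawn from `maf_range`.  A protein is
#' the sum of its pQTL effects plus Gaussian noise, standardized to SD 1; a
#' measurement cohort of `n_exposure` individuals yields per-SNP linear
#' summary statistics.  Disease status in a disjoint population follows a
#' logistic model whose log odds add `theta` times the per-SD genetic
#' protein value and optional per-SNP direct (pleiotropic) effects
#' `N(0, pleiotropy_sd^2)`; `n_cases`/`n_controls` are sampled and per-SNP
#' logistic summary statistics computed.  All randomness flows from `seed`.
#'
#' @param n_snps,n_blocks Panel size; blocks are contiguous, near-equal, and
#'   each lives on its own chromosome.
#' @param within_block_rho Latent AR(1) correlation inside a block, in
#'   \[0, 1).
#' @param maf_range Range the per-SNP minor-allele frequencies are drawn
#'   from, inside (0, 0.5\].
#' @param pqtl_effects Named list: protein id -> tibble(`snp_index`,
#'   `beta`), raw protein units per effect-allele copy.  Default: one
#'   protein with three pQTLs of beta 0.4 on three different chromosomes.
#' @param theta Named numeric: true causal log-OR per SD of genetically
#'   predicted protein, one entry per protein.
#' @param pleiotropy_sd SD of per-SNP direct effects on disease log odds.
#' @param protein_noise_sd SD of the non-genetic protein component.
#' @param n_exposure Protein-measurement cohort size.
#' @param n_cases,n_controls Case-control sample drawn from the outcome
#'   population.
#' @param baseline_prevalence Disease probability at zero genetic value.
#' @param n_population Outcome source-population size the cases/controls are
#'   sampled from.
#' @param n_reference LD reference-panel size.
#' @param seed Integer master seed.
#' @return A `sim_scenario` list (with drawn `maf`, `blocks`, `chrom`,
#'   `snp_id`, allele assignments).
#' @export
sim_scenario <- function(n_snps = 30, n_blocks = 6, within_block_rho = 0.6,
                         maf_range = c(0.1, 0.4),
                         pqtl_effects = NULL, theta = NULL,
                         pleiotropy_sd = 0, protein_noise_sd = 1,
                         n_exposure = 3000, n_cases = 2000,
                         n_controls = 2000, baseline_prevalence = 0.15,
                         n_population = 20000, n_reference = 2000,
                         seed = 1) {
  stopifnot(n_snps >= 1, n_blocks >= 1, n_blocks <= n_snps,
            within_block_rho >= 0, within_block_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleiotropy_sd >= 0, protein_noise_sd > 0,
            baseline_prevalence > 0, baseline_prevalence < 1)
  if (is.null(pqtl_effects)) {
    block_len <- ceiling(n_snps / n_blocks)
    starts <- ((c(1, 3, 5) - 1) %% n_blocks) * block_len + 1
    pqtl_effects <- list(
      protein_1 = tibble::tibble(snp_index = as.integer(unique(starts)),
                                 beta = 0.4)
    )
  }
  theta <- theta %||% setNames(rep(0.2, length(pqtl_effects)),
                               names(pqtl_effects))
  if (!setequal(names(theta), names(pqtl_effects))) {
    stop_config("sim_scenario: theta must name exactly the pqtl_effects proteins")
  }
  bad <- unlist(lapply(pqtl_effects, function(x) x$snp_index))
  if (any(bad < 1 | bad > n_snps)) {
    stop_config("sim_scenario: pqtl snp_index out of range")
  }

  blocks <- rep(seq_len(n_blocks),
                each = ceiling(n_snps / n_blocks))[seq_len(n_snps)]
  block_start <- stats::ave(seq_len(n_snps), blocks, FUN = min)
  pairs <- c("A/G", "C/T", "G/T", "A/C")[(seq_len(n_snps) - 1) %% 4 + 1]
  maf <- withr::with_seed(
    derive_seed(seed, 0),
    runif(n_snps, maf_range[1], maf_range[2])
  )
  structure(list(
    n_snps = n_snps, n_blocks = n_blocks,
    within_block_rho = within_block_rho, maf_range = maf_range,
    pqtl_effects = pqtl_effects, theta = theta,
    pleiotropy_sd = pleiotropy_sd, protein_noise_sd = protein_noise_sd,
    n_exposure = n_exposure, n_cases = n_cases, n_controls = n_controls,
    baseline_prevalence = baseline_prevalence,
    n_population = n_population, n_reference = n_reference, seed = seed,
    maf = maf, blocks = blocks,
    snp_id = sprintf("rs%05d", seq_len(n_snps)),
    chrom = as.character(blocks),
    pos = as.integer(10000L * (seq_len(n_snps) - block_start + 1L)),
    effect_allele = sub("/.*", "", pairs),
    other_allele = sub(".*/", "", pairs)
  ), class = "sim_scenario")
}

# two haplotypes from block-wise AR(1) latent Gaussians, thresholded so the
# effect allele appears with probability maf; HWE dosage = their sum
sim_genotypes <- function(n, scenario) {
  m <- scenario$n_snps
  rho <- scenario$within_block_rho
  thr <- qnorm(scenario$maf)
  hap <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho > 0) {
      for (j in 2:m) {
        if (scenario$blocks[j] == scenario$blocks[j - 1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
    }
    sweep(z, 2, thr, `<`) * 1L
  }
  g <- hap() + hap()
  colnames(g) <- scenario$snp_id
  g
}

#' Simulate an LD reference panel
#'
#' @param scenario A [sim_scenario()].
#' @return A [genotype_panel()] of `scenario$n_reference` individuals;
#'   deterministic under `scenario$seed`.
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  g <- withr::with_seed(derive_seed(scenario$seed, 1),
                        sim_genotypes(scenario$n_reference, scenario))
  genotype_panel(g, scenario_map(scenario))
}

scenario_map <- function(scenario) {
  tibble::tibble(
    snp_id = scenario$snp_id, chrom = scenario$chrom, pos = scenario$pos,
    effect_allele = scenario$effect_allele,
    other_allele = scenario$other_allele
  )
}

# marginal simple-regression summary stats for columns of G against y
marginal_linear_stats <- function(y, G) {
  n <- length(y)
  yc <- y - mean(y)
  Gc <- sweep(G, 2, colMeans(G))
  sxx <- unname(colSums(Gc^2))
  b <- unname(colSums(Gc * yc)) / sxx
  sigma2 <- pmax(sum(yc^2) - b^2 * sxx, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tibble::tibble(beta = b, se = se,
                 pval = pmin(pmax(2 * pnorm(-abs(b / se)),
                                  .Machine$double.xmin), 1))
}

# per-SNP logistic regression (intercept + dosage), Wald beta/SE
marginal_logistic_stats <- function(y, G) {
  res <- apply(G, 2, function(g) {
    fit <- suppressWarnings(
      glm.fit(cbind(1, g), y, family = binomial())
    )
    se <- sqrt(diag(chol2inv(qr.R(fit$qr))))
    c(coef(fit)[2], se[2])
  })
  b <- unname(res[1, ])
  se <- unname(res[2, ])
  tibble::tibble(beta = b, se = se,
                 pval = pmin(pmax(2 * pnorm(-abs(b / se)),
                                  .Machine$double.xmin), 1))
}

#' Simulate disjoint exposure and outcome cohorts and their summary stats
#'
#' Draws a protein-measurement cohort and a case-control outcome population
#' (no shared individuals — the two-sample MR assumption holds by
#' construction), runs the per-SNP marginal regressions, and returns the
#' summary tables in exactly the layouts [read_pqtl_catalog()] and
#' [read_outcome_stats()] consume, together with the generative truth.
#'
#' The pQTL catalog contains one row per declared (protein, pQTL SNP) pair
#' with its *estimated* association — whether a pair clears an instrument
#' p-value threshold is left to [build_instruments()].  The outcome table
#' covers every SNP.  The per-SD scale is enforced by standardizing the
#' protein before regression, and the disease model uses the genetic protein
#' value divided by the population protein SD, so `theta` and the estimated
#' exposure betas share the per-SD scale.
#'
#' @param scenario A [sim_scenario()].
#' @param panel Optional [genotype_panel()]; only its variant map is reused
#'   (cohort genotypes are always drawn fresh).
#' @return List: `pqtl` (catalog tibble), `outcome` (overall stratum
#'   tibble), `truth` (theta, protein SDs, pleiotropic effects, MAFs, seed),
#'   `sample` (case-control genotype matrix and phenotype, for subtype
#'   partitions).
#' @export
simulate_cohorts <- function(scenario, panel = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  map <- if (is.null(panel)) scenario_map(scenario) else panel$map
  proteins <- names(scenario$pqtl_effects)

  withr::with_seed(derive_seed(scenario$seed, 2), {
    ## exposure cohort ----------------------------------------------------
    Ge <- sim_genotypes(scenario$n_exposure, scenario)
    pqtl <- purrr::map(proteins, function(p) {
      eff <- scenario$pqtl_effects[[p]]
      praw <- Ge[, eff$snp_index, drop = FALSE] %*% eff$beta +
        rnorm(scenario$n_exposure, sd = scenario$protein_noise_sd)
      pstd <- as.numeric(scale(praw))
      st <- marginal_linear_stats(pstd, Ge[, eff$snp_index, drop = FALSE])
      i <- eff$snp_index
      tibble::tibble(
        snp_id = map$snp_id[i], chrom = map$chrom[i], pos = map$pos[i],
        effect_allele = map$effect_allele[i],
        other_allele = map$other_allele[i],
        eaf = colMeans(Ge[, i, drop = FALSE]) / 2,
        beta_gx = st$beta, se_gx = st$se, pval = st$pval,
        protein_id = p,
        cis_trans = c("cis", rep("trans", nrow(eff) - 1))
      )
    }) |> dplyr::bind_rows()

    ## outcome population -------------------------------------------------
    Gp <- sim_genotypes(scenario$n_population, scenario)
    logit <- rep(qlogis(scenario$baseline_prevalence),
                 scenario$n_population)
    s_pop <- setNames(numeric(length(proteins)), proteins)
    for (p in proteins) {
      eff <- scenario$pqtl_effects[[p]]
      gv <- as.numeric(Gp[, eff$snp_index, drop = FALSE] %*% eff$beta)
      s_pop[p] <- sqrt(var(gv) + scenario$protein_noise_sd^2)
      logit <- logit + scenario$theta[p] * gv / s_pop[p]
    }
    delta <- if (scenario$pleiotropy_sd > 0) {
      rnorm(scenario$n_snps, sd = scenario$pleiotropy_sd)
    } else {
      numeric(scenario$n_snps)
    }
    if (scenario$pleiotropy_sd > 0) logit <- logit + Gp %*% delta
    y <- rbinom(scenario$n_population, 1, plogis(as.numeric(logit)))
    if (sum(y) < scenario$n_cases ||
        sum(1 - y) < scenario$n_controls) {
      stop_data(paste0(
        "simulate_cohorts: population of ", scenario$n_population,
        " at baseline prevalence ", scenario$baseline_prevalence,
        " yielded ", sum(y), " cases / ", sum(1 - y),
        " controls; cannot sample ", scenario$n_cases, "/",
        scenario$n_controls
      ))
    }
    keep <- c(sample(which(y == 1), scenario$n_cases),
              sample(which(y == 0), scenario$n_controls))
    Gs <- Gp[keep, , drop = FALSE]
    ys <- y[keep]
    st <- marginal_logistic_stats(ys, Gs)
    outcome <- tibble::tibble(
      snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
      effect_allele = map$effect_allele, other_allele = map$other_allele,
      eaf = colMeans(Gs) / 2,
      beta_gy = st$beta, se_gy = st$se, pval = st$pval,
      n_cases = scenario$n_cases, n_controls = scenario$n_controls,
      stratum = "overall"
    )

    list(
      pqtl = pqtl,
      outcome = outcome,
      truth = list(
        theta = as.list(scenario$theta),
        protein_sd = as.list(s_pop),
        pleiotropy = delta,
        maf = scenario$maf,
        pqtl_effects = lapply(scenario$pqtl_effects, as.data.frame),
        seed = scenario$seed
      ),
      sample = list(genotypes = Gs, y = ys)
    )
  })
}

#' Split the case-control sample into histotype strata
#'
#' Partitions cases at random into an "endometrioid" majority and a
#' "non_endometrioid" minority (controls shared), then recomputes per-SNP
#' logistic summary statistics per stratum — the desk-scale analogue of
#' subtype-stratified GWAS meta-analyses.
#'
#' @param cohorts Output of [simulate_cohorts()].
#' @param scenario The generating [sim_scenario()].
#' @param endometrioid_fraction Probability a case is endometrioid.
#' @return Named list of outcome tibbles (`endometrioid`,
#'   `non_endometrioid`).
#' @export
subtype_outcome_stats <- function(cohorts, scenario,
                                  endometrioid_fraction = 0.85) {
  G <- cohorts$sample$genotypes
  y <- cohorts$sample$y
  withr::with_seed(derive_seed(scenario$seed, 3), {
    case_idx <- which(y == 1)
    endo <- rbinom(length(case_idx), 1, endometrioid_fraction) == 1
    strata <- list(endometrioid = case_idx[endo],
                   non_endometrioid = case_idx[!endo])
    ctrl_idx <- which(y == 0)
    purrr::imap(strata, function(cases, nm) {
      keep <- c(cases, ctrl_idx)
      st <- marginal_logistic_stats(y[keep], G[keep, , drop = FALSE])
      out <- cohorts$outcome
      out$eaf <- colMeans(G[keep, , drop = FALSE]) / 2
      out$beta_gy <- st$beta
      out$se_gy <- st$se
      out$pval <- st$pval
      out$n_cases <- length(cases)
      out$n_controls <- length(ctrl_idx)
      out$stratum <- nm
      out
    })
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a small scenario end to end and writes every file the pipeline
#' consumes: reference panel (dosages + variant map), pQTL catalog, outcome
#' summary statistics for the overall stratum and two histotype strata,
#' a conditioning-SNP list, and a JSON truth manifest.  Re-running with the
#' same scenario reproduces the files byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param scenario A [sim_scenario()]; the default is a two-protein bundle
#'   (one protein with three independent pQTLs and true effect 0.2, one with
#'   a single pQTL and true effect 0) small enough to regenerate in seconds.
#' @param endometrioid_fraction Passed to [subtype_outcome_stats()].
#' @param conditioning_snps Ids written as the known-risk-variant list;
#'   default picks two non-instrument SNPs.
#' @return Named character vector of the file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, scenario = NULL,
                               endometrioid_fraction = 0.85,
                               conditioning_snps = NULL) {
  scenario <- scenario %||% fixture_scenario()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_panel(scenario)
  cohorts <- simulate_cohorts(scenario, panel)
  subtypes <- subtype_outcome_stats(cohorts, scenario,
                                    endometrioid_fraction)
  instrument_snps <- unique(unlist(
    lapply(scenario$pqtl_effects,
           function(x) scenario$snp_id[x$snp_index])
  ))
  conditioning_snps <- conditioning_snps %||%
    head(setdiff(scenario$snp_id, instrument_snps), 2)

  paths <- c(
    panel_dosages = file.path(out_dir, "panel_dosages.tsv"),
    panel_map = file.path(out_dir, "panel_map.tsv"),
    catalog = file.path(out_dir, "pqtl_catalog.tsv"),
    outcome_overall = file.path(out_dir, "outcome_overall.tsv"),
    outcome_endometrioid = file.path(out_dir, "outcome_endometrioid.tsv"),
    outcome_non_endometrioid = file.path(out_dir,
                                         "outcome_non_endometrioid.tsv"),
    conditioning = file.path(out_dir, "conditioning_snps.txt"),
    truth = file.path(out_dir, "truth.json")
  )
  write_panel(panel, paths[["panel_dosages"]], paths[["panel_map"]])
  write_pqtl_catalog(cohorts$pqtl, paths[["catalog"]])
  write_outcome_stats(cohorts$outcome, paths[["outcome_overall"]])
  write_outcome_stats(subtypes$endometrioid,
                      paths[["outcome_endometrioid"]])
  write_outcome_stats(subtypes$non_endometrioid,
                      paths[["outcome_non_endometrioid"]])
  writeLines(conditioning_snps, paths[["conditioning"]])
  truth <- cohorts$truth
  truth$conditioning_snps <- conditioning_snps
  truth$endometrioid_fraction <- endometrioid_fraction
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

# rebuild a scenario with an altered seed (re-draws the MAFs)
scenario_reseed <- function(scenario, seed) {
  args <- scenario[c("n_snps", "n_blocks", "within_block_rho", "maf_range",
                     "pqtl_effects", "theta", "pleiotropy_sd",
                     "protein_noise_sd", "n_exposure", "n_cases",
                     "n_controls", "baseline_prevalence", "n_population",
                     "n_reference")]
  do.call(sim_scenario, c(args, list(seed = seed)))
}

# desk-scale default bundle: regenerates in a few seconds
fixture_scenario <- function(seed = 20210426) {
  sim_scenario(
    n_snps = 12, n_blocks = 4, within_block_rho = 0.6,
    maf_range = c(0.15, 0.4),
    pqtl_effects = list(
      protein_1 = tibble::tibble(snp_index = c(1L, 4L, 7L), beta = 0.4),
      protein_2 = tibble::tibble(snp_index = 10L, beta = 0.5)
    ),
    theta = c(protein_1 = 0.2, protein_2 = 0),
    n_exposure = 1500, n_cases = 800, n_controls = 800,
    baseline_prevalence = 0.15, n_population = 8000, n_reference = 600,
    seed = seed
  )
}

#' Replicate-level calibration study of the full MR pipeline
#'
#' For each replicate: draw a fresh panel and cohorts under the scenario
#' (seed varied per replicate), build instruments, and record the IVW
#' estimate for every protein.  The workhorse behind bias / coverage /
#' type-I-error calibration of the estimator under known ground truth.
#'
#' @param scenario Scenario template (its `seed` field is replaced per
#'   replicate).
#' @param n_reps Number of replicates.
#' @param seed Master seed the per-replicate seeds derive from.
#' @return Tibble with one row per replicate x protein: `rep`,
#'   `protein_id`, `n_snps`, `beta`, `se`, `pval`, `theta_true`, `covered`
#'   (95% CI contains `theta_true`), `reject` (p < 0.05).
#' @export
mr_calibration_study <- function(scenario = sim_scenario(), n_reps = 200,
                                 seed = 1) {
  purrr::map(seq_len(n_reps), function(i) {
    scen <- scenario_reseed(scenario, derive_seed(seed, i))
    panel <- simulate_panel(scen)
    cohorts <- simulate_cohorts(scen, panel)
    instr <- build_instruments(cohorts$pqtl, cohorts$outcome, panel)
    res <- mr_ivw_all(instr)
    res$theta_true <- unname(scen$theta[res$protein_id])
    res$covered <- !res$is_na &
      res$beta - 1.96 * res$se <= res$theta_true &
      res$theta_true <= res$beta + 1.96 * res$se
    res$reject <- !res$is_na & res$pval < 0.05
    res$rep <- i
    res[c("rep", "protein_id", "n_snps", "beta", "se", "pval",
          "theta_true", "covered", "reject", "is_na")]
  }) |> dplyr::bind_rows()
}
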