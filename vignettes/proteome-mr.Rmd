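---
title: "Proteome-wide Mendelian randomization with protmr: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide Mendelian randomization with protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmr)
```

## The question and the design

protmr implements a summary-statistics pipeline for asking whether the
circulating concentration of a protein causally influences the risk of a
disease. The design is two-sample Mendelian randomization (MR): genetic
variants that shift a protein's blood concentration (protein quantitative
trait loci, pQTLs, measured in one cohort) are used as instruments, and
their effects on disease risk are read off an independent case-control GWAS.
Because genotypes are fixed at conception, such estimates are protected from
the reverse causation and much of the confounding that afflict observational
biomarker studies — at the price of the usual instrumental-variable
assumptions (relevance, no direct path from instrument to outcome other than
through the exposure).

The pipeline mirrors how proteome-wide screens of this kind are run in
practice: a stringent pQTL significance filter, allele harmonization against
the outcome GWAS, reference-panel LD pruning within chromosomes,
inverse-variance-weighted (IVW) estimation per protein, panel-wide FDR
control, and a robustness pass that conditions the outcome associations on
the disease's known GWAS risk variants.

## The estimator

For protein *P* with instruments *i = 1..k*, let `beta_GX_i` be the effect
of SNP *i* on *P* (in SDs of protein per effect-allele copy), and
`beta_GY_i` (SE `sigma_GY_i`) its effect on disease (log odds per copy).
The IVW estimate of the causal log-OR per SD of genetically predicted
protein is

    beta = sum_i beta_GX_i * beta_GY_i / sigma_GY_i^2
           ------------------------------------------
           sum_i beta_GX_i^2        / sigma_GY_i^2

    se   = ( sum_i beta_GX_i^2 / sigma_GY_i^2 )^(-1/2)

which is the weighted least-squares slope of `beta_GY` on `beta_GX` through
the origin with weights `1/sigma_GY^2` (`ivw_estimate()` is tested against
`lm()` on exactly that formulation). With a single SNP this reduces to the
Wald ratio `beta_GY / beta_GX` with `se = sigma_GY / |beta_GX|`, and the
implementation computes that reduction explicitly.

Three deliberate choices:

* **No exposure-side uncertainty.** `se_gx` does not enter the formula (the
  "NO measurement error" first-order IVW). It is kept in the data model for
  diagnostics. With the pQTL filter at p < 1.5e-11, instruments are strong
  and the resulting dilution is negligible; the calibration study below
  measures it directly.
* **Normal inference throughout.** Two-sided p-values come from the
  standard normal, and confidence intervals use a fixed 1.96 multiplier —
  the convention of fixed-effects summary-statistics work, and the one that
  reproduces published p-values from printed OR/CI pairs
  (`p_from_or_ci(0.96, 0.87, 1.07)` is 0.44).
* **ORs by exponentiation**: `or = exp(beta)`,
  `ci = exp(beta -/+ 1.96 se)`.

## Instrument construction

`build_instruments()` applies, per protein:

1. keep catalog associations with p <= 1.5e-11 (the threshold of the
   large pQTL study this kind of catalog comes from; configurable);
2. harmonize each SNP against the outcome GWAS (below);
3. within each chromosome, enforce independence by greedy r-squared
   pruning at r2 < 0.1 against a reference genotype panel. Variants on
   different chromosomes are treated as independent (r2 = 0) without
   computation.

**Harmonization policy.** Publications rarely spell this step out, so the
package fixes a conservative, deterministic policy: match on allele sets;
flip the outcome beta's sign (and complement the EAF) when effect and other
alleles are swapped; drop palindromic SNPs (A/T, C/G) whenever the
minor-allele frequency is within 0.08 of 0.5 in either source, since strand
orientation is not decidable there; never infer strand from flanking
sequence. Everything else with a non-matching allele set is dropped with a
reason code.

**Pruning algorithm.** Greedy p-value-ranked clumping: rank candidates by
ascending pQTL p-value (ties broken lexicographically by id), keep the best
remaining SNP, discard everything at r2 >= 0.1 with a kept SNP, repeat. The
retained set is always pairwise r2 < 0.1, always contains the top-ranked
candidate, and is maximal; tests verify all three against subset
enumeration. Whether the original screens ranked by p-value or effect size
is generally unstated; p-value ranking is the common clumping default and
is what this package does. Pruning runs *after* harmonization (so SNPs the
outcome GWAS lacks never crowd out usable ones); the order is documented
here because the reverse is also defensible.

**Failure is loud.** Every catalog row leaves the builder with a status
(`ok`, `below_pqtl_threshold`, `duplicate_removed`, `missing_in_outcome`,
`dropped_palindromic`, `dropped_allele_mismatch`, `dropped_no_ld`,
`pruned_out`); proteins with nothing left are reported as non-analyzable
`NA` rows, matching how published subtype tables report a missing
instrument rather than omitting the protein. A SNP absent from the LD panel
is kept only if it is alone on its chromosome — otherwise independence
cannot be verified and the builder fails closed.

## Multiple testing across the panel

FDR control uses the Benjamini-Hochberg step-up procedure across the full
protein panel, not per stratum; subtype analyses report raw p-values only.
`bh_adjust()` additionally supports the situation where only the top of the
p-value distribution is in hand (as when reproducing a publication's
significant rows): `m_total` sets the true panel size and unobserved tests
are padded at p = 0.5. Any pad at least as large as the observed adjusted
values is inert, so the padded adjustment of the reported rows is exact.
`bonferroni_threshold()` provides the companion family-wise threshold
(0.05 / panel size).

## Conditional analysis on known risk variants

A protein association that merely tags an established GWAS risk locus is
not news. `conditional_estimates()` therefore re-estimates each instrument
SNP's outcome association conditional on a fixed list of known risk
variants, from summary statistics alone: per target, the normal equations
of the joint regression on {target + conditioning set} are reconstructed
from reference-panel correlations, allele-frequency variances `2p(1-p)`,
and per-SNP effective sample sizes (`4/(1/cases + 1/controls)` for
case-control traits, with the log-OR treated as a linear-scale effect — the
standard move in summary-statistics conditional machinery). The trait sum
of squares is recovered per SNP from its marginal beta/SE and combined by
median. The target's joint coefficient and residual-variance-updated SE are
returned; this is exactly the quantity the individual-level multiple
regression would give, and the package's acceptance checks hold it to the
per-SNP coefficients of `lm()` on simulated individual-level data within
0.05.

Safeguards, all configurable: targets at r2 >= 0.9 with the conditioning
set are flagged collinear and not estimated; panel/summary allele-frequency
disagreements beyond 0.2 are refused with a note; a singular conditioning
block is an explicit error (no silent ridge). `conditional_mr()` then
re-runs the IVW on the conditional betas; a protein whose instrument *is* a
known risk variant is reported `NA` — the honest answer, since its signal
cannot be separated from the locus it sits on.

No distance window is applied: conditioning lists here are short and
explicit, so the full joint solve is cheap and windowing would only add a
parameter. Model *selection* (stepwise COJO) is out of scope — only
conditional estimation given a fixed list, which is all the robustness
check needs.

## The synthetic-data generator

Real pQTL catalogs and consortium GWAS cannot be shipped, so the package
carries a generator (`sim_scenario()`, `simulate_panel()`,
`simulate_cohorts()`, `make_fixture_suite()`) that emulates the study
design with known ground truth:

* **Genotypes**: latent Gaussians with AR(1) correlation `rho` inside LD
  blocks (one block per chromosome), independent across blocks, thresholded
  at the per-SNP MAF twice and summed — Hardy-Weinberg dosages with
  block-structured LD. Thresholding attenuates dosage correlation below the
  latent `rho`; tests therefore compare against large-sample dosage
  correlations, not against `rho` itself.
* **Exposure cohort**: protein = sum of pQTL effects + N(0, 1) noise,
  standardized to sample SD 1; per-SNP simple linear regressions give the
  catalog rows (only declared pQTL pairs are emitted — whether they clear
  the instrument threshold is the builder's decision, so a null protein
  yields no instruments, as it should).
* **Outcome population**: disjoint from the exposure cohort by
  construction (the two-sample assumption holds exactly). Disease follows a
  logistic model whose log odds add `theta` times the *genetic* protein
  value scaled to per-SD units (using the population protein SD, so `theta`
  and the estimated exposure betas share a scale) plus optional per-SNP
  direct effects N(0, `pleiotropy_sd`^2) — the knob that breaks the
  exclusion restriction on demand. Cases and controls are sampled from the
  population and per-SNP logistic regressions (MLE, Wald SEs) give the
  outcome rows. Case-control sampling leaves the slope of a logistic model
  consistent, which is why this works without weighting.
* **Subtypes**: cases are partitioned at random into an endometrioid-like
  majority (default fraction 0.85, echoing the published case mix) and a
  non-endometrioid-like minority, controls shared, and the per-SNP
  regressions are re-run per stratum — reduced-power strata with the same
  underlying effect, which is the aspect of subtype analyses the package
  needs to exercise (missing-instrument `NA` semantics, per-stratum
  subsetting). Distinct per-subtype causal effects are not simulated.

**Default scenario.** The defaults are the package's reference study
conditions, fixed once: 30 SNPs in 6 blocks at latent rho 0.6, MAFs drawn
from (0.1, 0.4), one protein with three pQTLs of raw effect 0.4 on three
different chromosomes, true causal effect theta = 0.2, no pleiotropy,
3000-person exposure cohort, and 2000 cases + 2000 controls sampled from a
population of 20,000 at baseline prevalence 0.15. The prevalence/population
pair is chosen as the smallest round configuration that comfortably yields
the case count; the cohort sizes are desk-scale stand-ins for the
real-world design (a few thousand protein-measured individuals; a
case-control GWAS an order of magnitude larger), small enough that a
200-replicate calibration runs in minutes on one CPU. Paper-scale sizes are
reachable by argument. An infeasible case count (population times
prevalence below the requested cases) is an explicit error.

All randomness flows from one integer seed through fixed offsets;
regenerating a fixture bundle with the same scenario is byte-identical,
and the truth manifest (JSON) records `theta`, the protein SDs, pleiotropic
draws, MAFs and the seed.

**What passing tests do and do not show.** The generator has exact HWE,
clean biallelic SNPs, no imputation noise, no population stratification,
MAF and LD spectra far simpler than real panels, and pleiotropy that is
(by default) off. Calibration on these data demonstrates that the
estimator and plumbing are correct under the model's own assumptions — not
that real-data applications are unbiased; instrument validity there is an
assumption, not a theorem.

## Calibration results the package itself computes

`mr_calibration_study()` re-runs the full pipeline (fresh panel, fresh
cohorts, instrument building, IVW) per replicate. The shipped acceptance
checks hold, at 200 replicates of the default scenario: mean estimate
within 0.02 of theta = 0.2; 95% CI coverage inside [0.92, 0.98]; and with
theta = 0, a rejection rate at alpha = 0.05 inside the exact binomial 99%
interval. The same script verifies the IVW/WLS equivalence (1000 random
instrument sets, 1e-10), the BH implementation against an exhaustive
min-over-suffix oracle (500 random vectors), the conditional solver against
individual-level regression (n = 5000, 10 SNPs, within 0.05), pruning
properties by subset enumeration, and the published-table self-consistency
checks (padded FDR cells 0.01/0.02; p = 0.44 from OR 0.96, CI 0.87–1.07).
Run it with:

    Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json

## Numerical and degenerate-input choices

* Readers never coerce silently: a row violating a type invariant is
  rejected with its file line and reason; duplicate keys keep the first
  (catalog duplicates for the same protein keep the smaller p); a p-value
  inconsistent with beta/SE by more than 10% relative is a warning, not an
  error, because published p-values are rounded.
* Positions are 1-based; chromosome labels are normalized by stripping a
  leading `chr`; files are tab-delimited UTF-8 with `NA` for missing and a
  mandatory header, with user-supplied column maps for foreign layouts.
* LD is computed on dosages (allelic correlation), with per-column mean
  imputation of missing dosages; a constant column is an error naming the
  SNP.
* `ivw_estimate()` refuses `beta_gx = 0` (undefined ratio) and returns an
  `is_na` fit for an empty instrument set rather than erroring — the
  pipeline's `NA`-row semantics depend on that.
* The conditional solver floors its residual variance at a tiny positive
  value and declares singularity via reciprocal condition number < 1e-10.
* Results tables print ORs and CI bounds at 2 decimals and p-values in
  scientific notation with 3 significant digits, and re-parse to exactly
  those printed values.

## Known limitations

* IVW only: no MR-Egger, weighted-median, or heterogeneity statistics —
  deliberate scope, since the screen this package reproduces used IVW
  alone. With one or two SNPs per protein those diagnostics are mostly
  undefined anyway.
* No proxy-SNP search when an instrument is missing from a stratum's GWAS;
  the estimate uses the surviving subset, or reports `NA` when nothing
  survives.
* No liftover, no dbSNP resolution, no multi-allelic splitting; inputs are
  assumed build-consistent and biallelic.
* The conditional solver assumes the reference panel's LD matches the GWAS
  population; the allele-frequency check catches gross mismatch only.
* Exposure-side uncertainty is ignored by design; with weak instruments
  (which the 1.5e-11 filter is there to prevent) the estimate would
  attenuate.
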