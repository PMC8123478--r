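#' Construct a reference genotype panel
#'
#' A genotype panel holds an individuals-by-variants dosage matrix (entries
#' in \[0, 2\], `NA` allowed) and a variant map.  It stands in for a
#' population-matched LD reference (e.g. a 1000-Genomes-style European
#' panel) when computing pairwise r-squared for pruning and conditional
#' analysis.
#'
#' @param dosages Numeric matrix, individuals x variants; column names must
#'   equal `map$snp_id`.
#' @param map Tibble with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele` (one row per dosage column, same order).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(map)) {
    stop_data("genotype_panel: dosage columns and map rows differ")
  }
  if (anyDuplicated(map$snp_id) > 0) {
    stop_data("genotype_panel: variant ids must be unique")
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- map$snp_id
  } else if (!identical(colnames(dosages), as.character(map$snp_id))) {
    stop_data("genotype_panel: dosage column names disagree with map$snp_id")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop_data("genotype_panel: dosages must lie in [0, 2]")
  }
  structure(
    list(dosages = dosages, map = tibble::as_tibble(map),
         n_individuals = nrow(dosages)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", x$n_individuals, "individuals x",
      ncol(x$dosages), "variants on chromosome(s)",
      paste(unique(x$map$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise LD (allelic correlation) from a reference panel
#'
#' Pearson correlation of dosage columns; missing dosages are mean-imputed
#' per column before correlating.  The squared entries are the r-squared
#' used by [ld_prune()].
#'
#' @param panel A [genotype_panel()].
#' @param snp_ids Variants to correlate (default: all in the panel).
#' @return An `ld_matrix`: list with `snp_ids` and the symmetric correlation
#'   matrix `r` (unit diagonal).
#' @export
compute_ld <- function(panel, snp_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  snp_ids <- snp_ids %||% panel$map$snp_id
  missing <- setdiff(snp_ids, colnames(panel$dosages))
  if (length(missing) > 0) {
    stop_data(paste0("compute_ld: SNP(s) absent from panel: ",
                     paste(missing, collapse = ", ")))
  }
  g <- panel$dosages[, snp_ids, drop = FALSE]
  g <- apply(g, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  sds <- apply(g, 2, sd)
  if (any(sds == 0)) {
    stop_data(paste0("compute_ld: constant dosage column for SNP(s): ",
                     paste(snp_ids[sds == 0], collapse = ", ")))
  }
  r <- cor(g)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(snp_ids = snp_ids, r = r), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix over", length(x$snp_ids), "variants; max off-diagonal r^2 =",
      signif(max((x$r^2)[upper.tri(x$r)], 0), 3), "\n")
  invisible(x)
}

#' Greedy r-squared pruning of same-chromosome candidates
#'
#' Retains an independent subset of candidate SNPs: candidates are ranked by
#' ascending p-value (ties broken lexicographically by `snp_id`); the best
#' remaining SNP is kept and every remaining SNP with squared correlation at
#' or above `r2_threshold` against any kept SNP is discarded.  The retained
#' set is therefore pairwise r-squared strictly below the threshold and
#' always contains the top-ranked candidate.
#'
#' @param candidates Tibble with columns `snp_id` and `pval`, all on one
#'   chromosome and all present in `ld`.
#' @param ld An [compute_ld()] result covering the candidates.
#' @param r2_threshold Squared-correlation threshold (default 0.1):
#'   pairs with r-squared >= the threshold are dependent.
#' @return Character vector of retained `snp_id`s, in ranking order.
#' @export
ld_prune <- function(candidates, ld, r2_threshold = 0.1) {
  if (nrow(candidates) == 0) return(character(0))
  missing <- setdiff(candidates$snp_id, ld$snp_ids)
  if (length(missing) > 0) {
    stop_data(paste0("ld_prune: candidate(s) missing from LD matrix: ",
                     paste(missing, collapse = ", ")))
  }
  ord <- order(candidates$pval, candidates$snp_id)
  queue <- candidates$snp_id[ord]
  r2 <- ld$r[queue, queue, drop = FALSE]^2
  kept <- character(0)
  while (length(queue) > 0) {
    best <- queue[1]
    kept <- c(kept, best)
    queue <- queue[-1]
    queue <- queue[r2[best, queue] < r2_threshold]
  }
  kept
}

#' Read / write a genotype panel as delimited text
#'
#' The dosage file is tab-delimited with variant ids as header and one row
#' per individual; the map file is tab-delimited with the
#' [genotype_panel()] map columns.
#'
#' @param dosage_path,map_path File paths.
#' @return [read_panel()]: a `genotype_panel`.  [write_panel()]: the dosage
#'   path, invisibly.
#' @export
read_panel <- function(dosage_path, map_path) {
  map <- readr::read_tsv(map_path, na = "NA", progress = FALSE,
                         col_types = readr::cols(
                           snp_id = "c", chrom = "c", pos = "i",
                           effect_allele = "c", other_allele = "c"
                         ))
  map$chrom <- normalize_chrom(map$chrom)
  dos <- readr::read_tsv(dosage_path, na = "NA", progress = FALSE,
                         col_types = readr::cols(.default = "d"))
  genotype_panel(as.matrix(dos), map)
}

#' @param panel A `genotype_panel`.
#' @rdname read_panel
#' @export
write_panel <- function(panel, dosage_path, map_path) {
  readr::write_tsv(tibble::as_tibble(panel$dosages), dosage_path,
                   na = "NA", progress = FALSE)
  readr::write_tsv(panel$map, map_path, na = "NA", progress = FALSE)
  invisible(dosage_path)
}

#' Extract a genotype panel from a VCF
#'
#' Builds a [genotype_panel()] from biallelic VCF records, preferring the
#' `DS` (dosage) FORMAT field and falling back to ALT-allele counts from
#' `GT`.  The ALT allele is taken as the effect allele.  Requires the vcfR
#' package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param snp_ids Optional subset of variant ids to keep.
#' @return A `genotype_panel`.
#' @export
panel_from_vcf <- function(path, snp_ids = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_config("panel_from_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT)  # biallelic records only
  if (!is.null(snp_ids)) keep <- keep & fix$ID %in% snp_ids
  if (!any(keep)) stop_data("panel_from_vcf: no matching biallelic variants")

  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (length(a) == 0 || any(a == ".")) NA_real_
        else sum(a != "0")
      }, numeric(1))
    })
  }
  dosages <- t(fmt[keep, , drop = FALSE])
  map <- tibble::tibble(
    snp_id = fix$ID[keep],
    chrom = normalize_chrom(fix$CHROM[keep]),
    pos = as.integer(fix$POS[keep]),
    effect_allele = fix$ALT[keep],
    other_allele = fix$REF[keep]
  )
  colnames(dosages) <- map$snp_id
  genotype_panel(dosages, map)
}
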