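#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# strip a leading "chr" prefix; positions and ids untouched
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

# valid allele strings: non-empty runs of ACGT (covers SNVs and indels)
is_valid_allele <- function(x) {
  !is.na(x) & grepl("^[ACGT]+$", x)
}

# A/T and C/G single-base pairs are their own reverse complement
is_palindromic_pair <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  p %in% c("A/T", "C/G")
}

stop_config <- function(msg) {
  abort(msg, class = "protmr_config_error")
}

stop_data <- function(msg) {
  abort(msg, class = "protmr_data_error")
}

# deterministic child seeds below 2^31, derived from one scenario seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
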