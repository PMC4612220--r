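# Internal helpers. All genomic coordinates in this package are 1-based
# inclusive (the IRanges/GFF3 convention); interval length is end - start + 1.

`%||%` <- function(a, b) if (is.null(a)) b else a

interval_len <- function(start, end) end - start + 1

# Deterministic 32-bit sub-seed from a base seed and one or two indices.
# Plain integer arithmetic in double space (exact below 2^53), reduced mod a
# prime below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, i, j = 0L) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(i) * 16807 +
                as.numeric(j) * 69621 + 1) %% 2147483587)
}

# First element of a list-ish Parent attribute column from rtracklayer.
first_or_na <- function(x) {
  vapply(x, function(p) if (length(p) >= 1) as.character(p[[1]]) else NA_character_,
         character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

scaffold_pair_key <- function(scaffold_beta, scaffold_gamma) {
  paste(scaffold_beta, scaffold_gamma, sep = "|")
}
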