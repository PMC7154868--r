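RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' @noRd
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @noRd
toupper_seq <- function(x) toupper(x)

# Validate that sequences use only the RNA alphabet (after U/T normalization).
#' @noRd
check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", dna_to_rna(toupper(x)))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the ACGU alphabet (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
normalize_rna <- function(x) dna_to_rna(toupper(x))

# Reverse complement in DNA space; input/output character vectors.
#' @noRd
revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# All k-mers over the RNA alphabet in lexicographic (A<C<G<U) order.
#' @noRd
all_kmers <- function(k) {
  stopifnot(is_count(k))
  dna_to_rna(Biostrings::mkAllStrings(DNA_BASES, k))
}

# Derive a stream-specific 32-bit seed from a base seed.  Keeps derived seeds
# below 2^31 so they remain valid R integers.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483563) + 1L
}
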