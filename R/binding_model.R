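#' Construct a protein-RNA binding model
#'
#' A `binding_model` assigns a relative, dimensionless affinity to every read
#' of a random pool: reads carrying one of the motif k-mers get that k-mer's
#' affinity (combined across multiple occurrences by `combine_rule`), all
#' other reads get `background_affinity`.  Together with a protein
#' concentration it defines the probability that a read is pulled down (see
#' [read_binding_probability()]), i.e. the selection step of a simulated
#' Bind-n-Seq experiment.
#'
#' @param motif_affinities named numeric vector; names are RNA k-mers (ACGU,
#'   all of one length), values are relative affinities (> 0).
#' @param background_affinity affinity (> 0) of reads containing none of the
#'   motif k-mers; must not exceed the smallest motif affinity (motifs are
#'   enriched, never depleted).
#' @param combine_rule how affinities combine when a read contains several
#'   motif occurrences: `"max"` (default; one protein binds the best site) or
#'   `"sum"` (occurrences contribute additively).
#' @return an object of class `binding_model`.
#' @seealso [default_binding_model()] for the packaged demo model.
#' @examples
#' binding_model(c(UGGAAGUA = 2), background_affinity = 0.01)
#' @export
binding_model <- function(motif_affinities, background_affinity = 1,
                          combine_rule = c("max", "sum")) {
  combine_rule <- match.arg(combine_rule)
  if (length(motif_affinities) == 0 || is.null(names(motif_affinities)) ||
      any(!nzchar(names(motif_affinities)))) {
    stop("motif_affinities must be a non-empty named numeric vector", call. = FALSE)
  }
  kmers <- normalize_rna(names(motif_affinities))
  check_rna_alphabet(kmers, "motif k-mer")
  if (length(unique(nchar(kmers))) != 1L) {
    stop("all motif k-mers must have identical length", call. = FALSE)
  }
  if (anyDuplicated(kmers)) stop("duplicated motif k-mers", call. = FALSE)
  aff <- as.numeric(motif_affinities)
  if (any(!is.finite(aff)) || any(aff <= 0)) {
    stop("all motif affinities must be finite and strictly positive", call. = FALSE)
  }
  if (!is.numeric(background_affinity) || length(background_affinity) != 1L ||
      !is.finite(background_affinity) || background_affinity <= 0) {
    stop("background_affinity must be a single positive number", call. = FALSE)
  }
  if (background_affinity > min(aff)) {
    stop("background_affinity must not exceed the smallest motif affinity", call. = FALSE)
  }
  structure(list(motif_affinities = setNames(aff, kmers),
                 background_affinity = background_affinity,
                 combine_rule = combine_rule),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  k <- nchar(names(x$motif_affinities)[1])
  cat(sprintf("binding_model: %d motif %d-mer(s), affinities [%.4g, %.4g], background %.4g, combine '%s'\n",
              length(x$motif_affinities), k, min(x$motif_affinities),
              max(x$motif_affinities), x$background_affinity, x$combine_rule))
  invisible(x)
}

#' Selection experiment configuration
#'
#' Holds the experimental frame of a simulated Bind-n-Seq run: the protein
#' concentration series, the RNA concentration, read length and library
#' depths.  Defaults mirror the published CP33B experiment (zero-protein
#' control plus 100 and 1000 nM protein, 0.5 uM random 40-mer RNA); library
#' depths default to 1e6 reads, the upper end of desk scale, so that the
#' per-cell depth at k = 8 (~500 counts) supports stable z-score selection
#' (see the methods vignette for the power analysis).
#'
#' @param protein_concentrations numeric vector of concentrations in nM; must
#'   contain 0 (the control).
#' @param rna_concentration RNA concentration in uM (metadata only).
#' @param read_length read length in nucleotides.
#' @param n_input_reads,n_pulldown_reads library depths.
#' @param seed integer seed driving all randomness of the run.
#' @return an object of class `selection_config`.
#' @examples
#' selection_config(n_input_reads = 1000, n_pulldown_reads = 1000, seed = 1)
#' @export
selection_config <- function(protein_concentrations = c(0, 100, 1000),
                             rna_concentration = 0.5,
                             read_length = 40,
                             n_input_reads = 1e6,
                             n_pulldown_reads = 1e6,
                             seed = 1L) {
  if (!is.numeric(protein_concentrations) || length(protein_concentrations) < 1 ||
      any(protein_concentrations < 0)) {
    stop("protein_concentrations must be non-negative", call. = FALSE)
  }
  if (!any(protein_concentrations == 0)) {
    stop("protein_concentrations must contain 0 (the zero-protein control)", call. = FALSE)
  }
  if (!is_count(read_length)) stop("read_length must be a positive integer", call. = FALSE)
  if (!is_count(n_input_reads) || !is_count(n_pulldown_reads)) {
    stop("library depths must be positive integers", call. = FALSE)
  }
  structure(list(protein_concentrations = as.numeric(protein_concentrations),
                 rna_concentration = as.numeric(rna_concentration),
                 read_length = as.integer(read_length),
                 n_input_reads = as.integer(n_input_reads),
                 n_pulldown_reads = as.integer(n_pulldown_reads),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' @export
print.selection_config <- function(x, ...) {
  cat(sprintf("selection_config: [%s] nM protein, %.3g uM RNA, %d-mers, %d input / %d pulldown reads, seed %d\n",
              paste(x$protein_concentrations, collapse = ", "),
              x$rna_concentration, x$read_length,
              x$n_input_reads, x$n_pulldown_reads, x$seed))
  invisible(x)
}

# Combined affinity of each read under the model: motif occurrences counted
# with Biostrings::vcountPDict (Aho-Corasick), combined by max or sum;
# motif-free reads fall back to the background affinity.
#' @noRd
read_affinity <- function(reads, model) {
  stopifnot(inherits(model, "binding_model"))
  check_rna_alphabet(reads, "read")
  dna <- Biostrings::DNAStringSet(rna_to_dna(normalize_rna(reads)))
  pd <- Biostrings::PDict(rna_to_dna(names(model$motif_affinities)))
  aff <- unname(model$motif_affinities)
  if (model$combine_rule == "sum") {
    # occurrence multiplicity matters: count in chunks to bound memory
    a <- numeric(length(dna))
    chunk <- 100000L
    for (lo in seq(1L, length(dna), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(dna))
      counts <- Biostrings::vcountPDict(pd, dna[lo:hi])
      a[lo:hi] <- as.numeric(crossprod(counts, aff))
    }
  } else {
    wh <- Biostrings::vwhichPDict(pd, dna)
    a <- vapply(wh, function(i) if (length(i)) max(aff[i]) else 0, numeric(1))
  }
  ifelse(a > 0, a, model$background_affinity)
}

#' Probability that a read is pulled down
#'
#' Langmuir-type saturating capture probability
#' \deqn{p = \frac{c A}{1 + c A}}
#' with \eqn{A} the read's combined affinity under `model` and
#' \eqn{c = \mathrm{conc} / 100\,\mathrm{nM}} the protein concentration on a
#' fixed reference scale, so that 100 nM gives \eqn{cA = A}.  At zero protein
#' the probability is exactly 0; it increases strictly with both concentration
#' and affinity and saturates at 1.
#'
#' @param reads character vector of RNA reads (ACGU; T accepted and mapped to
#'   U).
#' @param model a [binding_model()].
#' @param conc protein concentration in nM (scalar, >= 0).
#' @return numeric vector of probabilities in \[0, 1\], one per read.
#' @examples
#' m <- binding_model(c(ACGU = 10), background_affinity = 1)
#' read_binding_probability(c("ACGUACGU", "AAAAAAAA"), m, conc = 100)
#' @export
read_binding_probability <- function(reads, model, conc) {
  if (!is.numeric(conc) || length(conc) != 1L || is.na(conc) || conc < 0) {
    stop("conc must be a single non-negative number (nM)", call. = FALSE)
  }
  if (conc == 0) return(rep(0, length(reads)))
  ca <- (conc / 100) * read_affinity(reads, model)
  ca / (1 + ca)
}
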