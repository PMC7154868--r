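#' Construct a read pool
#'
#' Light container for one sequencing library of a Bind-n-Seq experiment: an
#' ordered collection of fixed-length RNA reads plus a label ("input", "0nM",
#' "100nM", ...) and the [selection_config()] that produced it.
#'
#' @param reads character vector of RNA reads over ACGU, all the same length.
#' @param label library label.
#' @param config the provenance [selection_config()], or `NULL`.
#' @return an object of class `read_pool`.
#' @export
read_pool <- function(reads, label = "pool", config = NULL) {
  if (length(reads) == 0) stop("a read_pool must contain at least one read", call. = FALSE)
  reads <- unname(normalize_rna(reads))
  check_rna_alphabet(reads, "read")
  if (length(unique(nchar(reads))) != 1L) {
    stop("all reads in a pool must have identical length", call. = FALSE)
  }
  structure(list(reads = reads, label = label, config = config),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("read_pool '%s': %d reads of %d nt\n",
              x$label, length(x$reads), nchar(x$reads[1])))
  invisible(x)
}

#' @export
length.read_pool <- function(x) length(x$reads)

#' Generate a random input pool
#'
#' Simulates the random-oligonucleotide input library of a Bind-n-Seq
#' experiment: `n_input_reads` reads of `read_length` bases drawn i.i.d.
#' uniformly from ACGU.  Fully reproducible for a fixed `config$seed`.
#'
#' @param config a [selection_config()].
#' @return a [read_pool()] labelled `"input"`.
#' @examples
#' pool <- generate_input_pool(selection_config(n_input_reads = 5,
#'                                              n_pulldown_reads = 5, seed = 7))
#' pool$reads
#' @export
generate_input_pool <- function(config) {
  stopifnot(inherits(config, "selection_config"))
  n <- config$n_input_reads
  L <- config$read_length
  set.seed(derive_seed(config$seed, 1L))
  draws <- sample.int(4L, n * L, replace = TRUE)
  cols <- lapply(seq_len(L), function(j) RNA_BASES[draws[seq.int(j, by = L, length.out = n)]])
  reads <- do.call(paste0, cols)
  read_pool(reads, label = "input", config = config)
}

#' Simulate the pulldown selection of a read pool
#'
#' Draws `n_out` reads with replacement from `input`, weighted by each read's
#' capture probability [read_binding_probability()] at protein concentration
#' `conc`.  At `conc = 0` (zero-protein control) all capture probabilities are
#' zero and sampling is uniform, modelling nonspecific background carryover.
#' Sampling with replacement reflects that PCR amplification makes read
#' multiplicity uninformative.
#'
#' @param input a [read_pool()] (normally the output of
#'   [generate_input_pool()]).
#' @param model a [binding_model()].
#' @param conc protein concentration in nM.
#' @param n_out number of reads in the selected library; defaults to the
#'   config's `n_pulldown_reads` when available, else `length(input)`.
#' @param seed integer seed for the sampling step.
#' @return a [read_pool()] labelled `"<conc>nM"`.
#' @examples
#' cfg <- selection_config(n_input_reads = 200, n_pulldown_reads = 100, seed = 3)
#' pool <- generate_input_pool(cfg)
#' m <- binding_model(c(ACGUACGU = 100), background_affinity = 1)
#' sel <- simulate_selection(pool, m, conc = 100, seed = 3)
#' @export
simulate_selection <- function(input, model, conc, n_out = NULL, seed = 1L) {
  stopifnot(inherits(input, "read_pool"))
  if (is.null(n_out)) {
    n_out <- if (!is.null(input$config)) input$config$n_pulldown_reads else length(input$reads)
  }
  if (!is_count(n_out)) stop("n_out must be a positive integer", call. = FALSE)
  if (conc == 0) {
    w <- rep(1, length(input$reads))
  } else {
    w <- read_binding_probability(input$reads, model, conc)
    if (all(w == 0)) stop("all selection weights are zero; nothing can be pulled down", call. = FALSE)
  }
  set.seed(derive_seed(seed, 2L + as.integer(round(conc))))
  idx <- sample.int(length(input$reads), n_out, replace = TRUE, prob = w)
  read_pool(input$reads[idx], label = sprintf("%gnM", conc), config = input$config)
}

#' Write a read pool to FASTQ or FASTA
#'
#' Standard 4-line FASTQ with constant quality `"I"` (quality carries no
#' information in a simulated pool), or FASTA.  Reads are written in the RNA
#' dialect (U) by default; `dna = TRUE` maps U to T on write, and the paired
#' readers map T back to U.  Read ids are `read_0`, `read_1`, ...
#'
#' @param pool a [read_pool()].
#' @param path output file path.
#' @param dna write in the DNA dialect (U mapped to T)?
#' @return `path`, invisibly.
#' @export
write_fastq <- function(pool, path, dna = FALSE) {
  stopifnot(inherits(pool, "read_pool"))
  seqs <- if (dna) rna_to_dna(pool$reads) else pool$reads
  ids <- paste0("read_", seq_along(seqs) - 1L)
  qual <- strrep("I", nchar(seqs[1]))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(pool, path, dna = FALSE) {
  stopifnot(inherits(pool, "read_pool"))
  seqs <- if (dna) rna_to_dna(pool$reads) else pool$reads
  ids <- paste0("read_", seq_along(seqs) - 1L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Read a pool back from FASTQ/FASTA
#'
#' Sequences are normalized to the RNA alphabet (T mapped to U).  Format is
#' chosen from the file's first character unless given explicitly.
#'
#' @param path input file.
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @param label label for the returned pool; defaults to the file name.
#' @return a [read_pool()].
#' @export
read_pool_file <- function(path, format = c("auto", "fastq", "fasta"), label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readChar(path, 1L)
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  # BStringSet: accepts both the RNA (U) and DNA (T) dialects
  set <- Biostrings::readBStringSet(path, format = format)
  read_pool(dna_to_rna(as.character(set)),
            label = label %||% basename(path))
}
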