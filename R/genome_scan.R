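#' Load a genome sequence from FASTA
#'
#' First record of the FASTA is used unless `which` selects another; sequence
#' is uppercased and U mapped to T (DNA space internally).
#'
#' @param path FASTA file.
#' @param circular is the molecule circular (plastome)?
#' @param which record index.
#' @return list of class `genome_seq`: `id`, `sequence` (DNA string),
#'   `circular`.
#' @export
read_genome <- function(path, circular = FALSE, which = 1L) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) < which) stop("FASTA record not found", call. = FALSE)
  seq <- rna_to_dna(toupper(as.character(set[[which]])))
  if (grepl("[^ACGT]", seq)) stop("genome contains non-ACGT characters", call. = FALSE)
  structure(list(id = sub("\\s.*$", "", names(set)[which]),
                 sequence = seq, circular = circular),
            class = "genome_seq")
}

#' @noRd
as_genome <- function(genome, circular = FALSE, id = "genome") {
  if (inherits(genome, "genome_seq")) return(genome)
  seq <- rna_to_dna(toupper(genome))
  if (grepl("[^ACGT]", seq)) stop("genome contains non-ACGT characters", call. = FALSE)
  structure(list(id = id, sequence = seq, circular = circular),
            class = "genome_seq")
}

#' Exact k-mer scan of a genome, both strands
#'
#' Reports every exact occurrence of each query k-mer: plus-strand matches of
#' the query itself, and minus-strand matches where the reverse complement of
#' the query occurs in the genome.  Overlapping hits are all reported.  For
#' circular genomes (`circular = TRUE`, or the genome's own flag) a
#' junction-spanning pad of k-1 bases is scanned and wrap hits are reported
#' with `start` modulo the genome length (so `end = start + k` may exceed the
#' length; such hits carry `wrap = TRUE`).
#'
#' Coordinates are 0-based half-open.  `matched` is the hit sequence read in
#' the hit's own strand (i.e. always equal to the query), `source_kmer` the
#' query as supplied.
#'
#' @param genome a `genome_seq`, or a plain character string.
#' @param queries character vector of equal-length k-mers (RNA or DNA).
#' @param circular override the genome's circular flag.
#' @return data.frame (class `motif_hits`): seq_id, start, end, strand,
#'   matched, source_kmer, score, wrap; sorted by (seq_id, start, strand).
#' @examples
#' scan_kmers("ACGTACGT", "CGTA")
#' @export
scan_kmers <- function(genome, queries, circular = NULL) {
  genome <- as_genome(genome)
  if (!is.null(circular)) genome$circular <- circular
  if (length(queries) == 0) stop("queries must be non-empty", call. = FALSE)
  q_rna <- normalize_rna(queries)
  check_rna_alphabet(q_rna, "query")
  k <- unique(nchar(q_rna))
  if (length(k) != 1) stop("queries must all have the same length", call. = FALSE)
  L <- nchar(genome$sequence)
  subject_seq <- genome$sequence
  if (genome$circular && k > 1 && L >= k) {
    subject_seq <- paste0(subject_seq, substr(genome$sequence, 1L, k - 1L))
  }
  if (k > nchar(subject_seq)) {
    return(empty_hits())
  }
  subject <- Biostrings::DNAString(subject_seq)
  q_dna <- rna_to_dna(q_rna)
  rows <- list()
  for (i in seq_along(q_dna)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") q_dna[i] else revcomp_dna(q_dna[i])
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject)
      if (length(m) == 0) next
      start0 <- Biostrings::start(m) - 1L
      keep <- start0 < L  # drop pad-only duplicates of linear-start hits
      if (!any(keep)) next
      start0 <- start0[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = genome$id, start = start0, end = start0 + k,
        strand = str, matched = queries[i], source_kmer = queries[i],
        score = 0, wrap = start0 + k > L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$seq_id, hits$start, hits$strand, hits$source_kmer), ]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' @noRd
empty_hits <- function() {
  structure(data.frame(seq_id = character(), start = integer(), end = integer(),
                       strand = character(), matched = character(),
                       source_kmer = character(), score = numeric(),
                       wrap = logical(), stringsAsFactors = FALSE),
            class = c("motif_hits", "data.frame"))
}

#' Count hits fully contained in an annotated feature
#'
#' A hit counts if it lies entirely within the feature interval
#' (`start >= feature start` and `end <= feature end`, 0-based half-open) on
#' the same sequence; with `sense_only = TRUE` the hit strand must equal the
#' feature strand ("sense direction").  Wrap hits never count as contained in
#' a linear feature interval.
#'
#' @param hits a `motif_hits` data.frame.
#' @param feature one row of a feature table ([read_features()]) or a list
#'   with `feature_id`, `seq_id`, `start`, `end`, `strand`.
#' @param sense_only restrict to sense hits?
#' @return list with `count` and `hits` (the subset).
#' @export
hits_in_feature <- function(hits, feature, sense_only = FALSE) {
  if (is.data.frame(feature)) feature <- as.list(feature[1, ])
  inside <- hits$seq_id == feature$seq_id &
    hits$start >= feature$start & hits$end <= feature$end
  if (sense_only) inside <- inside & hits$strand == feature$strand
  sub <- hits[inside, , drop = FALSE]
  rownames(sub) <- NULL
  list(count = nrow(sub), hits = sub)
}

#' Scan a genome with a position frequency matrix
#'
#' Sliding log-likelihood ratio score against a uniform background,
#' `score(w) = sum_j log2(p[base_j, j] / 0.25)` in bits, both strands
#' (minus-strand windows scored on the reverse complement).  Positions with
#' score >= `score_min` are reported.  Zero frequencies require a
#' `pseudocount` (entries become `(p + pc) / (1 + 4 pc)`), otherwise scoring
#' errors out.
#'
#' @param genome a `genome_seq` or character string.
#' @param pfm a `pfm` or 4 x w column-stochastic matrix (rows A/C/G/U).
#' @param score_min minimum score in bits.
#' @param pseudocount pseudo-frequency added to matrix cells.
#' @param circular override the genome's circular flag.
#' @param name reported in `source_kmer` (prefixed "pfm:").
#' @return a `motif_hits` data.frame; `matched` is the window sequence in the
#'   hit's strand (RNA alphabet), `score` the bit score.
#' @export
scan_pfm <- function(genome, pfm, score_min, pseudocount = 0,
                     circular = NULL, name = "motif") {
  genome <- as_genome(genome)
  if (!is.null(circular)) genome$circular <- circular
  mat <- if (inherits(pfm, "pfm")) pfm$matrix else pfm
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (!is.finite(score_min)) {
    if (!identical(score_min, -Inf)) stop("score_min must be finite or -Inf", call. = FALSE)
  }
  if (any(mat == 0) && pseudocount <= 0) {
    stop("pfm has zero frequencies; supply a positive pseudocount", call. = FALSE)
  }
  if (pseudocount > 0) mat <- (mat + pseudocount) / (1 + 4 * pseudocount)
  w <- ncol(mat)
  W <- log2(mat / 0.25)
  L <- nchar(genome$sequence)
  subject <- genome$sequence
  if (genome$circular && w > 1 && L >= w) {
    subject <- paste0(subject, substr(genome$sequence, 1L, w - 1L))
  }
  n_pos <- nchar(subject) - w + 1L
  if (n_pos < 1) return(empty_hits())
  idx <- match(strsplit(subject, "")[[1]], DNA_BASES)
  score_strand <- function(Wm) {
    s <- numeric(n_pos)
    for (j in seq_len(w)) s <- s + Wm[idx[seq_len(n_pos) + j - 1L], j]
    s
  }
  # minus strand: revcomp the matrix (reverse columns, complement rows)
  Wrc <- W[rev(seq_len(4)), rev(seq_len(w)), drop = FALSE]
  rows <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") score_strand(W) else score_strand(Wrc)
    pos <- which(s >= score_min)
    pos <- pos[pos - 1L < L]  # drop pad-only duplicates
    if (length(pos) == 0) next
    start0 <- pos - 1L
    winseq <- substring(subject, pos, pos + w - 1L)
    if (str == "-") winseq <- revcomp_dna(winseq)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = genome$id, start = start0, end = start0 + w,
      strand = str, matched = dna_to_rna(winseq),
      source_kmer = paste0("pfm:", name), score = s[pos],
      wrap = start0 + w > L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$seq_id, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Read feature annotation from GFF3
#'
#' Parsed with `rtracklayer::import`; 1-based inclusive GFF intervals are
#' converted to the package's 0-based half-open convention.  The feature id
#' is taken from the `ID`, `Name` or `gene` attribute, first available.
#'
#' @param path GFF3 file.
#' @return data.frame: feature_id, seq_id, start, end (0-based half-open),
#'   strand, type.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  pick <- function(col) if (col %in% names(md)) as.character(md[[col]]) else rep(NA_character_, nrow(df))
  id <- pick("ID")
  id <- ifelse(is.na(id), pick("Name"), id)
  id <- ifelse(is.na(id), pick("gene"), id)
  id <- ifelse(is.na(id), sprintf("feature_%d", seq_len(nrow(df))), id)
  out <- data.frame(feature_id = id,
                    seq_id = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    strand = as.character(df$strand),
                    type = if ("type" %in% names(md)) as.character(md$type) else as.character(df$type),
                    stringsAsFactors = FALSE)
  bad <- out$start >= out$end | !(out$strand %in% c("+", "-"))
  out[!bad, , drop = FALSE]
}

#' Write feature annotation as GFF3
#'
#' Inverse of [read_features()] for the package's own feature tables
#' (0-based half-open converted back to 1-based inclusive).
#'
#' @param features data.frame as returned by [read_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\trbnsrip\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     features$seq_id, features$type %||% "CDS",
                     features$start + 1L, features$end,
                     features$strand, features$feature_id), con)
  invisible(path)
}

#' Write / read hits as BED6
#'
#' BED6: chrom, start, end, name (= source_kmer), score, strand; 0-based
#' half-open, matching the package's internal convention, so the round-trip
#' is exact.
#'
#' @param hits a `motif_hits` data.frame.
#' @param path file path.
#' @return `path` (writer) or a `motif_hits` (reader; `matched` is restored
#'   as `NA` for pfm hits and as the query for k-mer hits).
#' @export
write_bed <- function(hits, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(hits) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       hits$seq_id, hits$start, hits$end, hits$source_kmer,
                       format(hits$score, digits = 10, trim = TRUE),
                       hits$strand), con)
  }
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(empty_hits())
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("seq_id", "start", "end", "name", "score", "strand")
  is_pfm <- startsWith(df$name, "pfm:")
  out <- data.frame(seq_id = df$seq_id, start = as.integer(df$start),
                    end = as.integer(df$end), strand = df$strand,
                    matched = ifelse(is_pfm, NA_character_, df$name),
                    source_kmer = df$name, score = as.numeric(df$score),
                    wrap = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Simulate a genome with planted motif occurrences
#'
#' Generates a uniform-random (circular) genome, scrubs it of accidental
#' occurrences of the query k-mers (on either strand), then plants
#' occurrences at requested positions/strands so that the planted set is the
#' exact ground truth.  Features (CDS-like intervals with strands) are laid
#' out and the per-feature sense/antisense counts of the planted hits are
#' recorded.
#'
#' @param length genome length.
#' @param queries k-mers to control (RNA or DNA).
#' @param plant data.frame with columns `start` (0-based), `strand`, `query`
#'   (index or k-mer); wrap-around planting is allowed on circular genomes.
#' @param features optional data.frame `feature_id`, `start`, `end`,
#'   `strand`, `type` (0-based half-open).
#' @param circular circular genome?
#' @param seed integer seed.
#' @param id sequence id.
#' @param max_iter scrub iterations before giving up.
#' @return list of class `synthetic_genome`: `genome` (a `genome_seq`),
#'   `features`, `truth` (planted hits as a `motif_hits` data.frame).
#' @export
simulate_genome <- function(length = 10000L, queries, plant,
                            features = NULL, circular = TRUE, seed = 1L,
                            id = "synthetic_plastome", max_iter = 50L) {
  stopifnot(is_count(length), is.data.frame(plant))
  q_rna <- normalize_rna(queries)
  check_rna_alphabet(q_rna, "query")
  k <- unique(nchar(q_rna))
  if (base::length(k) != 1) stop("queries must share one length", call. = FALSE)
  q_dna <- rna_to_dna(q_rna)
  set.seed(derive_seed(seed, 31L))
  seq <- paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")

  # scrub accidental occurrences (both strands, incl. junction) by mutating
  # one base inside each occurrence until clean
  for (iter in seq_len(max_iter)) {
    acc <- scan_kmers(as_genome(seq, circular = circular, id = id), q_rna)
    if (nrow(acc) == 0) break
    chars <- strsplit(seq, "")[[1]]
    for (r in seq_len(nrow(acc))) {
      pos <- (acc$start[r] + sample.int(k, 1L) - 1L) %% length + 1L
      chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    }
    seq <- paste(chars, collapse = "")
  }
  if (iter == max_iter) stop("could not scrub accidental motif occurrences", call. = FALSE)

  # plant requested occurrences
  chars <- strsplit(seq, "")[[1]]
  truth <- list()
  for (r in seq_len(nrow(plant))) {
    qi <- plant$query[r]
    q <- if (is.numeric(qi)) q_dna[qi] else rna_to_dna(normalize_rna(qi))
    ins <- if (plant$strand[r] == "+") q else revcomp_dna(q)
    pos <- (plant$start[r] + seq_len(k) - 1L) %% length + 1L
    chars[pos] <- strsplit(ins, "")[[1]]
    truth[[r]] <- data.frame(
      seq_id = id, start = as.integer(plant$start[r]),
      end = as.integer(plant$start[r] + k), strand = plant$strand[r],
      matched = dna_to_rna(q), source_kmer = dna_to_rna(q), score = 0,
      wrap = plant$start[r] + k > length, stringsAsFactors = FALSE)
  }
  seq <- paste(chars, collapse = "")
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$seq_id, truth$start, truth$strand, truth$source_kmer), ]
  rownames(truth) <- NULL
  class(truth) <- c("motif_hits", "data.frame")

  genome <- as_genome(seq, circular = circular, id = id)
  # planting may, in principle, create new overlapping occurrences; verify
  verify <- scan_kmers(genome, q_rna)
  if (nrow(verify) != nrow(truth)) {
    stop("planting created unintended motif occurrences; choose other positions", call. = FALSE)
  }
  if (!is.null(features)) {
    features$seq_id <- id
    if (is.null(features$type)) features$type <- "CDS"
  }
  structure(list(genome = genome, features = features, truth = truth),
            class = "synthetic_genome")
}

#' Write a genome to FASTA
#'
#' @param genome a `genome_seq`.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", genome$id), con)
  n <- nchar(genome$sequence)
  starts <- seq(1L, n, by = width)
  writeLines(substring(genome$sequence, starts, pmin(starts + width - 1L, n)), con)
  invisible(path)
}
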