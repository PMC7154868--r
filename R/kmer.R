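#' Count all k-mers in a read library
#'
#' Counts every overlapping k-mer occurrence within each read (reads are not
#' concatenated, so no phantom junction k-mers arise).  The count table covers
#' all 4^k RNA k-mers, zeros included, in lexicographic order.  Reads shorter
#' than k are skipped with a warning.
#'
#' @param pool a [read_pool()] or a character vector of RNA/DNA reads.
#' @param k k-mer length (>= 1).
#' @return an object of class `kmer_counts`: list with `k`, `counts` (named
#'   integer vector over all 4^k k-mers), `total_positions`
#'   (= sum over reads of len - k + 1) and `library_label`.
#' @examples
#' count_kmers(read_pool("AAAAA", label = "demo"), k = 4)$counts[["AAAA"]]
#' @export
count_kmers <- function(pool, k) {
  if (!inherits(pool, "read_pool")) {
    # bare character input may mix lengths; only the alphabet is enforced
    reads <- unname(normalize_rna(pool))
    check_rna_alphabet(reads, "read")
    pool <- list(reads = reads, label = "reads")
  }
  if (!is_count(k)) stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  reads <- pool$reads
  short <- nchar(reads) < k
  if (any(short)) {
    warning(sprintf("%d read(s) shorter than k = %d skipped", sum(short), k))
    reads <- reads[!short]
  }
  if (length(reads) == 0) stop("no read of length >= k", call. = FALSE)
  dna <- Biostrings::DNAStringSet(rna_to_dna(reads))
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k,
                                                 simplify.as = "collapsed")
  names(counts) <- dna_to_rna(names(counts))
  structure(list(k = as.integer(k),
                 counts = counts,
                 total_positions = sum(nchar(reads) - k + 1L),
                 library_label = pool$label),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts '%s': k = %d, %d positions, top k-mer %s (%d)\n",
              x$library_label, x$k, x$total_positions,
              names(x$counts)[which.max(x$counts)], max(x$counts)))
  invisible(x)
}

#' Per-k-mer enrichment (R values) of a sample library against the input
#'
#' For every k-mer the pseudocount-adjusted frequencies
#' `f = (count + pseudocount) / (total + 4^k * pseudocount)` are computed in
#' both libraries and the enrichment is their ratio `R = f_sample / f_input`.
#' With `pseudocount > 0` every R is finite; with `pseudocount = 0`, k-mers
#' with zero input count get non-finite R and are excluded from the z-score
#' computation.
#'
#' @param sample,input `kmer_counts` of the same k.
#' @param pseudocount added to every k-mer cell (default 1).
#' @return a data.frame of class `kmer_enrichment` with one row per k-mer:
#'   `kmer`, `count_sample`, `count_input`, `f_sample`, `f_input`, `R`, `z`
#'   (`NA` until [compute_zscores()] is applied), ordered by R descending
#'   (ties lexicographic).  Attributes: `k`, `sample_label`, `input_label`,
#'   `pseudocount`.
#' @examples
#' a <- count_kmers(read_pool(c("ACGUACGU", "ACGUACGA")), k = 4)
#' compute_enrichment(a, a)$R[1]  # identical libraries: R = 1 everywhere
#' @export
compute_enrichment <- function(sample, input, pseudocount = 1) {
  stopifnot(inherits(sample, "kmer_counts"), inherits(input, "kmer_counts"))
  if (sample$k != input$k) stop("sample and input were counted at different k", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (sample$total_positions <= 0 || input$total_positions <= 0) {
    stop("both libraries must contain counted positions", call. = FALSE)
  }
  ncell <- 4^sample$k
  f_s <- (sample$counts + pseudocount) / (sample$total_positions + ncell * pseudocount)
  f_i <- (input$counts + pseudocount) / (input$total_positions + ncell * pseudocount)
  R <- ifelse(f_i > 0, f_s / f_i, NA_real_)
  out <- data.frame(kmer = names(sample$counts),
                    count_sample = as.integer(sample$counts),
                    count_input = as.integer(input$counts),
                    f_sample = as.numeric(f_s), f_input = as.numeric(f_i),
                    R = as.numeric(R), z = NA_real_,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$R, out$kmer), ]
  rownames(out) <- NULL
  structure(out, k = sample$k, sample_label = sample$library_label,
            input_label = input$library_label, pseudocount = pseudocount,
            class = c("kmer_enrichment", "data.frame"))
}

#' Standardize R values to z-scores
#'
#' z-scores of the raw R values over all 4^k k-mers (population sd), as used
#' for significance selection of enriched k-mers; `log_space = TRUE`
#' standardizes log(R) instead.  Non-finite R values are excluded.
#'
#' @param table a `kmer_enrichment`.
#' @param log_space standardize log(R) instead of R?
#' @return the table with its `z` column filled in.
#' @examples
#' # R = {1,1,1,5}: the 5 gets z = (5 - 2)/sqrt(3)
#' @export
compute_zscores <- function(table, log_space = FALSE) {
  stopifnot(inherits(table, "kmer_enrichment"))
  v <- if (log_space) log(table$R) else table$R
  ok <- is.finite(v)
  if (sum(ok) < 2) stop("need at least 2 finite R values", call. = FALSE)
  mu <- mean(v[ok])
  sd_pop <- sqrt(mean((v[ok] - mu)^2))
  if (sd_pop == 0) stop("degenerate R distribution: all R values are equal", call. = FALSE)
  table$z <- ifelse(ok, (v - mu) / sd_pop, NA_real_)
  attr(table, "z_log_space") <- log_space
  table
}

#' Select significant k-mers
#'
#' K-mers with `z >= z_min` (default 3, the published significance
#' threshold), sorted by R descending with lexicographic tie-break.
#'
#' @param table a `kmer_enrichment` with z computed.
#' @param z_min z-score threshold.
#' @return data.frame with columns `kmer`, `R`, `z` (possibly 0 rows).
#' @export
select_significant <- function(table, z_min = 3) {
  stopifnot(inherits(table, "kmer_enrichment"))
  if (all(is.na(table$z))) stop("z-scores not computed; call compute_zscores() first", call. = FALSE)
  keep <- !is.na(table$z) & table$z >= z_min
  out <- table[keep, c("kmer", "R", "z")]
  out <- out[order(-out$R, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Compare enrichment across protein concentrations
#'
#' Summarizes a concentration series: the maximum R per concentration, the
#' concentration with the overall highest R, and for every concentration pair
#' the Spearman rank correlation of the top-`top_n` k-mers.  The top set of a
#' pair is taken from the member with the larger maximum R (the more enriched
#' library) and those k-mers' R values are correlated across the pair.
#'
#' @param tables named list of `kmer_enrichment` tables (names = the
#'   concentration labels), all at the same k.
#' @param top_n size of the top k-mer set used for rank correlation.
#' @return list with `per_concentration` (data.frame: label, max_R,
#'   top_kmer), `best` (label with the highest max R) and `pairwise`
#'   (data.frame: label_a, label_b, spearman).
#' @export
concentration_report <- function(tables, top_n = 50) {
  if (!is.list(tables) || length(tables) < 2) {
    stop("need enrichment tables for at least 2 concentrations", call. = FALSE)
  }
  ks <- vapply(tables, attr, integer(1), "k")
  if (length(unique(ks)) != 1) stop("all tables must share the same k", call. = FALSE)
  labels <- names(tables) %||% paste0("table_", seq_along(tables))
  per <- data.frame(label = labels,
                    max_R = vapply(tables, function(t) max(t$R, na.rm = TRUE), numeric(1)),
                    top_kmer = vapply(tables, function(t) t$kmer[which.max(t$R)], character(1)),
                    stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(tables), 2)
  pairwise <- do.call(rbind, apply(pairs, 2, function(ij) {
    a <- tables[[ij[1]]]; b <- tables[[ij[2]]]
    ref <- if (per$max_R[ij[1]] >= per$max_R[ij[2]]) a else b
    top <- head(ref$kmer[order(-ref$R, ref$kmer)], top_n)
    ra <- a$R[match(top, a$kmer)]
    rb <- b$R[match(top, b$kmer)]
    data.frame(label_a = labels[ij[1]], label_b = labels[ij[2]],
               spearman = suppressWarnings(cor(ra, rb, method = "spearman")),
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  rownames(pairwise) <- NULL
  list(per_concentration = per,
       best = per$label[which.max(per$max_R)],
       pairwise = pairwise)
}

#' Write / read an enrichment table as TSV
#'
#' Columns kmer, count_sample, count_input, f_sample, f_input, R, z, sorted
#' by R descending; attributes (k, labels, pseudocount) are stored in `#`
#' header comment lines and restored on read.
#'
#' @param table a `kmer_enrichment`.
#' @param path file path.
#' @return `path` (writer) or a `kmer_enrichment` (reader).
#' @export
write_enrichment <- function(table, path) {
  stopifnot(inherits(table, "kmer_enrichment"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("# k=%d sample=%s input=%s pseudocount=%.15g",
                 attr(table, "k"), attr(table, "sample_label"),
                 attr(table, "input_label"), attr(table, "pseudocount"))
  writeLines(hdr, con)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec("# k=(\\d+) sample=(\\S+) input=(\\S+) pseudocount=(\\S+)", hdr))[[1]]
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  structure(df,
            k = as.integer(meta[2]), sample_label = meta[3],
            input_label = meta[4], pseudocount = as.numeric(meta[5]),
            class = c("kmer_enrichment", "data.frame"))
}
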