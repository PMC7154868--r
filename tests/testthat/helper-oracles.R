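# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# O(reads x positions) k-mer counting by substring extraction.
oracle_count_kmers <- function(reads, k) {
  reads <- chartr("Tt", "Uu", toupper(reads))
  reads <- reads[nchar(reads) >= k]
  kmers <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - k + 1), k:n)
  }))
  alphabet <- c("A", "C", "G", "U")
  all_k <- alphabet
  if (k > 1) for (i in 2:k) all_k <- as.vector(outer(all_k, alphabet, paste0))
  all_k <- sort(all_k)
  tab <- table(factor(kmers, levels = all_k))
  list(counts = setNames(as.integer(tab), names(tab)), total = length(kmers))
}

# Per-position exact scan of a genome (character comparison), both strands,
# optional circular wrap via an explicit pad.
oracle_scan <- function(genome_seq, query_dna, circular = FALSE) {
  L <- nchar(genome_seq)
  k <- nchar(query_dna)
  comp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  padded <- if (circular && k > 1) paste0(genome_seq, substr(genome_seq, 1, k - 1)) else genome_seq
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") query_dna else comp(query_dna)
    for (s in seq_len(nchar(padded) - k + 1)) {
      if (s - 1 >= L) next
      if (substr(padded, s, s + k - 1) == pat) {
        hits[[length(hits) + 1]] <- data.frame(start = s - 1L, strand = strand,
                                               stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Per-position PFM log2-likelihood-ratio scores on the plus strand.
oracle_pfm_scores <- function(genome_seq, mat) {
  w <- ncol(mat)
  L <- nchar(genome_seq)
  base_row <- c(A = 1, C = 2, G = 3, T = 4)
  vapply(seq_len(L - w + 1), function(s) {
    win <- strsplit(substr(genome_seq, s, s + w - 1), "")[[1]]
    sum(log2(mat[cbind(base_row[win], seq_len(w))] / 0.25))
  }, numeric(1))
}

# Frequencies of a named count vector without pseudocounts.
oracle_freq <- function(counts) counts / sum(counts)

# Small uniform random RNA pool.
random_pool <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}
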