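#' Assemble a consensus motif from significant k-mers
#'
#' Greedy seed alignment: the top-R k-mer seeds the motif at offset 0; every
#' further significant k-mer is slid across the seed over offsets in
#' `[-max_offset, max_offset]`, placed at the offset maximizing matching
#' positions (ties: fewer mismatches, then smaller |offset|, then the more
#' negative offset), and accepted if its overlap with the seed is at least
#' `min_overlap` and it has at most `mismatch_max` mismatches.  Accepted
#' k-mers add their weight to the base counts at their aligned positions;
#' columns are then trimmed from both ends while their total support is below
#' `trim` times the maximum column support, and each remaining column is
#' normalized to frequencies.
#'
#' Input order does not matter: k-mers are re-sorted by R descending with
#' lexicographic tie-break before assembly, so equal-R permutations yield the
#' identical matrix.
#'
#' @param significant data.frame with columns `kmer` and `R` (e.g. from
#'   [select_significant()]); all R must be > 1.
#' @param max_offset maximum shift against the seed (default 2).
#' @param mismatch_max maximum mismatches within the overlap (default 1).
#' @param min_overlap minimum seed overlap; default k - 2.
#' @param weighting contribution weight per k-mer: excess enrichment
#'   `"Rminus1"` (default), raw `"R"`, or `"equal"`.
#' @param trim column-support trim threshold as a fraction of the maximum
#'   column support (default 0.25).
#' @return an object of class `pfm`: list with `matrix` (4 x width, rows
#'   A/C/G/U, columns summing to 1), `support` (total weight per column),
#'   `seed`, and `aligned` (per-k-mer data.frame: kmer, offset, weight,
#'   mismatches, accepted).
#' @examples
#' sig <- data.frame(kmer = c("UGGUUG", "GGUUGA"), R = c(5, 3))
#' consensus_string(assemble_motif(sig))
#' @export
assemble_motif <- function(significant, max_offset = 2L, mismatch_max = 1L,
                           min_overlap = NULL,
                           weighting = c("Rminus1", "R", "equal"),
                           trim = 0.25) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(significant), all(c("kmer", "R") %in% names(significant)))
  if (nrow(significant) == 0) stop("no significant k-mers to assemble", call. = FALSE)
  kmers <- normalize_rna(significant$kmer)
  check_rna_alphabet(kmers, "k-mer")
  if (length(unique(nchar(kmers))) != 1L) stop("k-mers must share one length", call. = FALSE)
  if (any(significant$R <= 1)) stop("assembly requires R > 1 for every k-mer", call. = FALSE)
  k <- nchar(kmers[1])
  if (is.null(min_overlap)) min_overlap <- k - 2L
  ord <- order(-significant$R, kmers)
  kmers <- kmers[ord]
  Rv <- significant$R[ord]
  w <- switch(weighting, Rminus1 = Rv - 1, R = Rv, equal = rep(1, length(Rv)))

  seed <- strsplit(kmers[1], "")[[1]]
  # column grid spans all admissible offsets
  offs <- seq.int(-max_offset, max_offset)
  ncol_grid <- k + 2L * max_offset
  counts <- matrix(0, nrow = 4, ncol = ncol_grid,
                   dimnames = list(RNA_BASES, NULL))
  col0 <- max_offset  # grid column of seed position 1 is col0 + 1

  align_one <- function(km) {
    b <- strsplit(km, "")[[1]]
    best <- NULL
    for (o in offs) {
      # k-mer position j sits at seed position j + o
      js <- seq_len(k)
      seed_pos <- js + o
      in_seed <- seed_pos >= 1 & seed_pos <= k
      overlap <- sum(in_seed)
      matches <- sum(b[in_seed] == seed[seed_pos[in_seed]])
      mism <- overlap - matches
      cand <- c(matches = matches, mism = mism, abso = abs(o), o = o, overlap = overlap)
      if (is.null(best) ||
          cand["matches"] > best["matches"] ||
          (cand["matches"] == best["matches"] && cand["mism"] < best["mism"]) ||
          (cand["matches"] == best["matches"] && cand["mism"] == best["mism"] &&
           cand["abso"] < best["abso"]) ||
          (cand["matches"] == best["matches"] && cand["mism"] == best["mism"] &&
           cand["abso"] == best["abso"] && cand["o"] < best["o"])) {
        best <- cand
      }
    }
    best
  }

  aligned <- data.frame(kmer = kmers, offset = NA_integer_, weight = w,
                        mismatches = NA_integer_, accepted = FALSE,
                        stringsAsFactors = FALSE)
  for (i in seq_along(kmers)) {
    if (i == 1L) {
      best <- c(matches = k, mism = 0, abso = 0, o = 0, overlap = k)
    } else {
      best <- align_one(kmers[i])
    }
    aligned$offset[i] <- best[["o"]]
    aligned$mismatches[i] <- best[["mism"]]
    ok <- best[["overlap"]] >= min_overlap && best[["mism"]] <= mismatch_max
    aligned$accepted[i] <- ok
    if (ok) {
      b <- strsplit(kmers[i], "")[[1]]
      cols <- col0 + best[["o"]] + seq_len(k)
      for (j in seq_len(k)) counts[b[j], cols[j]] <- counts[b[j], cols[j]] + w[i]
    }
  }
  if (length(kmers) > 1L && sum(aligned$accepted) == 1L) {
    warning("all non-seed k-mers were discarded; motif equals the seed profile")
  }

  support <- colSums(counts)
  thr <- trim * max(support)
  keep <- which(support >= thr)
  keep <- seq.int(min(keep), max(keep))  # trim ends only, never interior columns
  counts <- counts[, keep, drop = FALSE]
  support <- support[keep]
  mat <- sweep(counts, 2, ifelse(support > 0, support, 1), "/")
  colnames(mat) <- NULL
  structure(list(matrix = mat, support = unname(support),
                 seed = kmers[1], aligned = aligned),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("pfm: %d columns, seed %s, consensus %s\n",
              ncol(x$matrix), x$seed, consensus_string(x)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Consensus string of a position frequency matrix
#'
#' Per column the most frequent base; ties are broken alphabetically
#' (A < C < G < U).
#'
#' @param pfm a `pfm` (or a bare 4 x w column-stochastic matrix with rows
#'   A/C/G/U).
#' @return RNA string of length `ncol`.
#' @export
consensus_string <- function(pfm) {
  mat <- if (inherits(pfm, "pfm")) pfm$matrix else pfm
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  paste(RNA_BASES[apply(mat, 2, which.max)], collapse = "")
}

#' Write a motif in MEME minimal format
#'
#' One motif per file, RNA alphabet (ACGU), uniform background, letter
#' probability rows = columns of the matrix.  [read_meme()] restores it.
#'
#' @param pfm a `pfm`.
#' @param path output path.
#' @param name motif name written to the file.
#' @param nsites nominal site count recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfm, path, name = "motif_1", nsites = 20) {
  mat <- if (inherits(pfm, "pfm")) pfm$matrix else pfm
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGU", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
                       ncol(mat), nsites)), con)
  writeLines(apply(mat, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_meme
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix:", lines)
  if (length(hdr) != 1) stop("not a single-motif MEME minimal file", call. = FALSE)
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x), numeric(4)))
  mat <- t(mat)  # back to 4 x w
  rownames(mat) <- RNA_BASES
  name <- sub("^MOTIF +", "", grep("^MOTIF ", lines, value = TRUE)[1])
  structure(list(matrix = mat, support = rep(NA_real_, w),
                 seed = NA_character_,
                 aligned = data.frame()),
            class = "pfm")
}
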