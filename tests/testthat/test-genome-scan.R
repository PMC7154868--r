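test_that("scan_kmers reproduces the hand-enumerated example", {
  hits <- scan_kmers("ACGTACGT", "CGTA")
  expect_equal(nrow(hits), 2)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_equal(plus$start, 1)          # ACGTACGT: CGTA at 1 (+)
  expect_equal(minus$start, 3)         # TACG (revcomp of CGTA) at 3 (-)
  expect_equal(hits$end - hits$start, c(4, 4))

  # query equal to the whole genome
  whole <- scan_kmers("ACGTT", "ACGTT")
  expect_equal(whole$start[whole$strand == "+"], 0)

  # query longer than the genome: empty result, not an error
  expect_equal(nrow(scan_kmers("ACG", "ACGTT")), 0)
  expect_error(scan_kmers("ACGT", "AXGT"), "ACGU")
})

test_that("RNA and DNA query dialects are equivalent", {
  expect_equal(scan_kmers("ACGTACGT", "CGUA")$start,
               scan_kmers("ACGTACGT", "CGTA")$start)
})

test_that("strand symmetry: reverse-complementing the genome swaps strand counts", {
  set.seed(5)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  q <- c("ACGTAA", "GGGCGC")
  h1 <- scan_kmers(g, q)
  h2 <- scan_kmers(rc, q)
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  expect_equal(sum(h1$strand == "-"), sum(h2$strand == "+"))
  # revcomp involution restores the original hit table
  rcrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc)))
  expect_equal(as.data.frame(scan_kmers(rcrc, q)), as.data.frame(h1))
})

test_that("scan_kmers agrees with the per-position oracle, including wrap hits", {
  set.seed(9)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  # force a junction-spanning occurrence
  q <- "ACGTTGCA"
  g <- paste0(substr(q, 4, 8), substr(g, 6, 2000 - 3), substr(q, 1, 3))
  for (circ in c(FALSE, TRUE)) {
    hits <- scan_kmers(g, q, circular = circ)
    or <- oracle_scan(g, q, circular = circ)
    expect_equal(hits$start, or$start)
    expect_equal(hits$strand, or$strand)
  }
  # the wrap hit only exists on the circular molecule
  expect_gt(nrow(scan_kmers(g, q, circular = TRUE)),
            nrow(scan_kmers(g, q, circular = FALSE)))
  wrap <- scan_kmers(g, q, circular = TRUE)
  expect_true(any(wrap$wrap & wrap$start + 8 > nchar(g)))
})

test_that("hits_in_feature applies containment and sense filtering", {
  hits <- structure(data.frame(seq_id = "chr", start = c(10L, 50L, 95L),
                               end = c(18L, 58L, 103L),
                               strand = c("+", "-", "+"),
                               matched = "X", source_kmer = "X", score = 0,
                               wrap = FALSE, stringsAsFactors = FALSE),
                    class = c("motif_hits", "data.frame"))
  feat <- list(feature_id = "psbA", seq_id = "chr", start = 0L, end = 100L, strand = "+")
  expect_equal(hits_in_feature(hits, feat)$count, 2)             # 95-103 not contained
  expect_equal(hits_in_feature(hits, feat, sense_only = TRUE)$count, 1)
  featm <- modifyList(feat, list(strand = "-"))
  expect_equal(hits_in_feature(hits, featm, sense_only = TRUE)$count, 1)
  expect_equal(hits_in_feature(hits, featm)$count, 2)
  # containment monotonicity: enlarging the feature never loses hits
  featbig <- modifyList(feat, list(end = 150L))
  expect_gte(hits_in_feature(hits, featbig)$count, hits_in_feature(hits, feat)$count)
})

test_that("scan_pfm equals scan_kmers on a one-hot matrix and the brute-force oracle", {
  set.seed(13)
  g <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  onehot <- assemble_motif(data.frame(kmer = "ACGUAC", R = 2))
  full_score <- 6 * log2(1 / 0.25) * (1 - 1e-5)  # just below the perfect score
  hp <- scan_pfm(g, onehot, score_min = full_score, pseudocount = 1e-9)
  hk <- scan_kmers(g, "ACGUAC")
  expect_equal(hp$start, hk$start)
  expect_equal(hp$strand, hk$strand)

  # threshold -Inf reports every position on both strands
  hall <- scan_pfm(g, onehot, score_min = -Inf, pseudocount = 1e-9)
  expect_equal(nrow(hall), 2 * (1000 - 6 + 1))

  # zero frequencies without pseudocount must error
  expect_error(scan_pfm(g, onehot, score_min = 0), "pseudocount")

  # plus-strand scores match an independent per-position scorer
  mat <- (onehot$matrix + 0.01) / (1 + 0.04)
  sc <- oracle_pfm_scores(g, mat)
  hexact <- scan_pfm(g, onehot$matrix, score_min = -Inf, pseudocount = 0.01)
  plus <- hexact[hexact$strand == "+", ]
  expect_equal(plus$score, unname(sc), tolerance = 1e-12)
})

test_that("simulate_genome plants exact ground truth recovered by the scanner", {
  plant <- data.frame(start = c(1000L, 4000L, 9996L),
                      strand = c("+", "-", "+"), query = 1L)
  feats <- data.frame(feature_id = c("psbA", "psbB"),
                      start = c(900L, 3000L), end = c(2000L, 3500L),
                      strand = c("+", "-"), type = "CDS")
  sg <- simulate_genome(length = 10000L, queries = "UGGAAGUA", plant = plant,
                        features = feats, circular = TRUE, seed = 77)
  hits <- scan_kmers(sg$genome, "UGGAAGUA")
  expect_equal(as.data.frame(hits), as.data.frame(sg$truth))
  # per-feature sense counts match the planted layout exactly
  expect_equal(hits_in_feature(hits, sg$features[1, ], sense_only = TRUE)$count, 1)
  expect_equal(hits_in_feature(hits, sg$features[2, ], sense_only = TRUE)$count, 0)
  expect_true(any(hits$wrap))
})

test_that("BED and GFF round-trips preserve coordinates", {
  hits <- scan_kmers("ACGTACGTACGT", c("CGTA", "ACGT"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits, bed)
  back <- read_bed(bed)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$source_kmer, hits$source_kmer)

  feats <- data.frame(feature_id = c("psbA", "rbcL"), seq_id = "plastome",
                      start = c(99L, 1199L), end = c(600L, 2000L),
                      strand = c("+", "-"), type = "CDS",
                      stringsAsFactors = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, gff)
  back2 <- read_features(gff)
  expect_equal(back2$feature_id, feats$feature_id)
  expect_equal(back2$start, feats$start)
  expect_equal(back2$end, feats$end)
  expect_equal(back2$strand, feats$strand)
})
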