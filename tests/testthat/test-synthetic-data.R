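test_that("generate_input_pool honours the length/alphabet contract and is deterministic", {
  cfg <- selection_config(read_length = 4, n_input_reads = 1,
                          n_pulldown_reads = 1, seed = 42)
  p <- generate_input_pool(cfg)
  expect_length(p$reads, 1)
  expect_equal(nchar(p$reads), 4)
  expect_true(grepl("^[ACGU]+$", p$reads))

  cfg2 <- selection_config(n_input_reads = 500, n_pulldown_reads = 500, seed = 7)
  expect_identical(generate_input_pool(cfg2)$reads, generate_input_pool(cfg2)$reads)
  cfg3 <- selection_config(n_input_reads = 500, n_pulldown_reads = 500, seed = 8)
  expect_false(identical(generate_input_pool(cfg2)$reads, generate_input_pool(cfg3)$reads))
})

test_that("input pool base composition is uniform at depth", {
  cfg <- selection_config(n_input_reads = 100000, n_pulldown_reads = 100,
                          seed = 11)
  p <- generate_input_pool(cfg)
  comp <- table(strsplit(paste(p$reads[1:10000], collapse = ""), "")[[1]])
  freqs <- comp / sum(comp)
  # binomial CI at 4e5 draws is far tighter than [0.24, 0.26]
  expect_true(all(freqs > 0.24 & freqs < 0.26))
})

test_that("configuration errors are caught", {
  expect_error(selection_config(n_input_reads = 0), "positive integer")
  expect_error(selection_config(read_length = -1), "positive integer")
  expect_error(selection_config(protein_concentrations = c(100, 1000)), "contain 0")
})

test_that("binding_model validates its invariants", {
  expect_error(binding_model(c(ACGU = 1, ACG = 2)), "identical length")
  expect_error(binding_model(c(ACGU = -1)), "strictly positive")
  expect_error(binding_model(c(ACGU = 1), background_affinity = 2), "not exceed")
  expect_error(binding_model(c(ACGX = 1)), "ACGU")
  m <- binding_model(c(acgt = 5), background_affinity = 1)
  expect_identical(names(m$motif_affinities), "ACGU")  # normalized to RNA
  expect_error(binding_model(c(ACGU = 5, acgu = 3)), "duplicated")
})

test_that("read_binding_probability closed forms hold", {
  m <- binding_model(c(UUUUUUUU = 100), background_affinity = 1)
  reads <- c("ACGAGCUAGCAUCGAUCGAU", "GCAUCGAUGCAUGCAUGCAA")
  # zero protein: p = 0 for every read
  expect_identical(read_binding_probability(reads, m, 0), c(0, 0))
  # background read at c*A = 1 (100 nM, A = 1): p = 0.5
  expect_equal(read_binding_probability(reads, m, 100), c(0.5, 0.5))
  # motif read at 100 nM: cA = 100 -> p = 100/101
  expect_equal(read_binding_probability("UUUUUUUUACGU", m, 100), 100 / 101)
  expect_error(read_binding_probability("ACGN", m, 100), "ACGU")
})

test_that("selection ratio motif/background decreases monotonically with concentration", {
  m <- binding_model(c(GGGGGGGG = 100), background_affinity = 1)
  concs <- c(1, 10, 100, 1000, 10000)
  ratio <- vapply(concs, function(cc) {
    read_binding_probability("GGGGGGGGAAAA", m, cc) /
      read_binding_probability("ACAUCGAUACGA", m, cc)
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
  # probability increases with concentration and with affinity
  p <- vapply(concs, function(cc) read_binding_probability("GGGGGGGGAAAA", m, cc), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("combine_rule max vs sum differ only for multi-occurrence reads", {
  mmax <- binding_model(c(ACGUA = 2, GGGGG = 3), background_affinity = 1,
                        combine_rule = "max")
  msum <- binding_model(c(ACGUA = 2, GGGGG = 3), background_affinity = 1,
                        combine_rule = "sum")
  one <- "AAACGUAAAAAAAAA"    # single ACGUA occurrence
  two <- "ACGUAACGUAAAAAA"    # two ACGUA occurrences
  both <- "ACGUAGGGGGAAAAA"   # one of each
  c100 <- function(m, r) read_binding_probability(r, m, 100)
  expect_equal(c100(mmax, one), c100(msum, one))      # A = 2 either way
  expect_equal(c100(msum, two), 4 / 5)                # A = 4
  expect_equal(c100(mmax, two), 2 / 3)                # A = 2
  expect_equal(c100(mmax, both), 3 / 4)               # A = max(2,3)
  expect_equal(c100(msum, both), 5 / 6)               # A = 2+3
})

test_that("simulate_selection enriches the planted k-mer and is neutral without selection", {
  cfg <- selection_config(n_input_reads = 20000, n_pulldown_reads = 20000, seed = 3)
  pool <- generate_input_pool(cfg)
  m <- binding_model(c(UGGAAGUA = 100), background_affinity = 1)
  sel <- simulate_selection(pool, m, 100, seed = 3)
  f <- function(p) mean(grepl("UGGAAGUA", p$reads, fixed = TRUE))
  expect_gt(f(sel), f(pool))
  expect_identical(sel$label, "100nM")

  # zero protein: frequencies match input within sampling noise
  sel0 <- simulate_selection(pool, m, 0, seed = 3)
  expect_lt(abs(f(sel0) - f(pool)), 5 * sqrt(f(pool) / length(pool$reads)))

  # flat model: no selection
  flat <- binding_model(c(UGGAAGUA = 1), background_affinity = 1)
  self <- simulate_selection(pool, flat, 100, seed = 4)
  expect_lt(abs(f(self) - f(pool)), 5 * sqrt(f(pool) / length(pool$reads)))

  # determinism
  expect_identical(simulate_selection(pool, m, 100, seed = 9)$reads,
                   simulate_selection(pool, m, 100, seed = 9)$reads)
})

test_that("FASTQ/FASTA round-trips preserve sequence, order and dialect", {
  p <- read_pool(c("ACGU", "UUUU", "GCGC"), label = "rt")
  fq <- withr::local_tempfile(fileext = ".fastq")
  fa <- withr::local_tempfile(fileext = ".fasta")

  write_fastq(p, fq)
  lines <- readLines(fq)
  expect_length(lines, 12)
  expect_identical(lines[1], "@read_0")
  expect_identical(lines[2], "ACGU")
  expect_identical(lines[3], "+")
  expect_identical(lines[4], "IIII")
  expect_identical(read_pool_file(fq)$reads, p$reads)

  write_fasta(p, fa)
  expect_identical(read_pool_file(fa)$reads, p$reads)

  # DNA dialect maps U->T on write and back on read
  write_fastq(p, fq, dna = TRUE)
  expect_identical(readLines(fq)[2], "ACGT")
  expect_identical(read_pool_file(fq)$reads, p$reads)
})

test_that("simulate_array_table: exact factors without noise, planted recovery with noise", {
  d <- default_array_design(n_probes = 20)
  tabs <- simulate_array_table(d$design, d$factors, noise_sd = 0, seed = 2)
  r <- replicate_ratios(tabs$wt)
  expect_equal(r$ratio, unname(d$factors[r$probe_id]))
  # factor 1 and noise 0 means identical channels
  rr <- tabs$wt[tabs$wt$is_rrna, ]
  expect_equal(rr$F635, rr$F532)
  # control carries no planted enrichment
  rc <- replicate_ratios(tabs$control)
  expect_true(all(rc$ratio == 1))

  # ranking recovery at lognormal noise 0.2, 3 replicates
  noisy <- simulate_array_table(d$design, d$factors, noise_sd = 0.2,
                                n_replicates = 3, seed = 2)
  est <- median_of_ratios(replicate_ratios(noisy$wt))
  rho <- cor(est$median_ratio, unname(d$factors[est$probe_id]), method = "spearman")
  expect_gt(rho, 0.9)

  expect_error(simulate_array_table(d$design, d$factors, genome_length = 100),
               "genome_length")
  expect_error(simulate_array_table(d$design, rep(0.5, 20)), ">= 1")
})

test_that("simulate_blot_table matches its closed-form cases", {
  t1 <- simulate_blot_table(data.frame(target = "x", fraction = 0.5),
                            total_signal = 100, background = 0, seed = 1)
  wt <- t1[t1$genotype == "wt", ]
  expect_equal(wt$signal[wt$fraction_label == "P"],
               wt$signal[wt$fraction_label == "S"])
  t0 <- simulate_blot_table(data.frame(target = "x", fraction = 0),
                            total_signal = 100, background = 2, seed = 1)
  p0 <- t0$signal[t0$genotype == "wt" & t0$fraction_label == "P"]
  expect_lt(p0, 10)  # background only
  expect_error(simulate_blot_table(data.frame(target = "x", fraction = 1.5)),
               "\\[0, 1\\]")
})

test_that("config JSON round-trips the model and configuration", {
  cfg <- selection_config(n_input_reads = 123, n_pulldown_reads = 456, seed = 9)
  m <- default_binding_model(max_mismatches = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, m, path)
  back <- read_config(path)
  expect_equal(back$config, cfg)
  expect_equal(back$model$motif_affinities, m$motif_affinities)
  expect_equal(back$model$background_affinity, m$background_affinity)
  expect_identical(back$model$combine_rule, m$combine_rule)
})
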