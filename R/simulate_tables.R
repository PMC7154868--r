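#' Simulate two-channel array signal tables
#'
#' Emulates a two-colour RIP-chip hybridization over a tiled genome.  Per
#' probe and replicate the unbound channel is drawn as a lognormal baseline,
#' `F532 ~ lognormal(baseline_log_mean, baseline_log_sd)`, and the
#' co-precipitated channel is `F635 = F532 * factor * exp(noise)` with
#' `noise ~ N(0, noise_sd)`.  A paired control (mutant / pre-immune) table is
#' generated with all planted factors equal to 1.  With `noise_sd = 0` the
#' per-replicate ratio F635/F532 equals the planted factor exactly.
#'
#' @param design data.frame with columns `probe_id`, `start`, `end`,
#'   `feature`, `is_rrna`; probes must lie within `[0, genome_length)`.
#' @param enrichment_factors numeric vector of planted factors (>= 1), one
#'   per probe (recycled names checked against `probe_id` when named).
#' @param genome_length genome length used to validate probe coordinates.
#' @param n_replicates replicates per genotype.
#' @param noise_sd lognormal noise sd on the F635 channel.
#' @param baseline_log_mean,baseline_log_sd lognormal baseline of F532.
#' @param seed integer seed.
#' @return list of two data.frames, `wt` and `control`, each with columns
#'   probe_id, start, end, feature, is_rrna, replicate, F635, F532, genotype.
#' @examples
#' d <- default_array_design(n_probes = 10)
#' tabs <- simulate_array_table(d$design, d$factors, noise_sd = 0, seed = 1)
#' head(tabs$wt)
#' @export
simulate_array_table <- function(design, enrichment_factors,
                                 genome_length = max(design$end),
                                 n_replicates = 3L, noise_sd = 0.2,
                                 baseline_log_mean = log(1000),
                                 baseline_log_sd = 0.5, seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("probe_id", "start", "end", "feature", "is_rrna") %in% names(design)))
  n <- nrow(design)
  if (any(design$start < 0) || any(design$end > genome_length) ||
      any(design$end <= design$start)) {
    stop("probe coordinates must satisfy 0 <= start < end <= genome_length", call. = FALSE)
  }
  if (length(enrichment_factors) != n) {
    stop("need one enrichment factor per probe", call. = FALSE)
  }
  if (!is.null(names(enrichment_factors)) &&
      !identical(names(enrichment_factors), design$probe_id)) {
    enrichment_factors <- enrichment_factors[design$probe_id]
  }
  if (any(enrichment_factors < 1)) stop("enrichment factors must be >= 1", call. = FALSE)
  if (!is_count(n_replicates)) stop("n_replicates must be a positive integer", call. = FALSE)

  one_genotype <- function(factors, genotype, sub_seed) {
    set.seed(sub_seed)
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      f532 <- rlnorm(n, baseline_log_mean, baseline_log_sd)
      noise <- if (noise_sd > 0) exp(rnorm(n, 0, noise_sd)) else rep(1, n)
      data.frame(probe_id = design$probe_id, start = design$start,
                 end = design$end, feature = design$feature,
                 is_rrna = design$is_rrna, replicate = r,
                 F635 = f532 * factors * noise, F532 = f532,
                 genotype = genotype, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  list(wt = one_genotype(unname(enrichment_factors), "wt", derive_seed(seed, 11L)),
       control = one_genotype(rep(1, n), "control", derive_seed(seed, 12L)))
}

#' Simulate a paired pellet/supernatant blot table
#'
#' Per target the pellet signal is `total * fraction` and the supernatant
#' signal `total * (1 - fraction)`, each plus additive Gaussian background
#' noise of sd `background`, floored at 0.  Mutant-control rows are generated
#' with bound fraction 0 for every target.  Equal volume fractions (1) are
#' recorded, matching the equal-volume blotting protocol.
#'
#' @param targets data.frame with columns `target` and `fraction` (true bound
#'   fraction in \[0, 1\]); defaults to [default_blot_targets()].
#' @param total_signal total signal per target (scalar or per-target vector).
#' @param background sd of additive background noise, in signal units.
#' @param seed integer seed.
#' @return data.frame with columns target, genotype, fraction_label (`"P"` /
#'   `"S"`), signal, volume_fraction.
#' @examples
#' simulate_blot_table(data.frame(target = "psbA", fraction = 0.9),
#'                     background = 0, seed = 1)
#' @export
simulate_blot_table <- function(targets = default_blot_targets(),
                                total_signal = 100, background = 1,
                                seed = 1L) {
  stopifnot(is.data.frame(targets), all(c("target", "fraction") %in% names(targets)))
  if (any(targets$fraction < 0 | targets$fraction > 1)) {
    stop("bound fractions must lie in [0, 1]", call. = FALSE)
  }
  total <- rep_len(total_signal, nrow(targets))
  set.seed(derive_seed(seed, 21L))
  rows <- function(fraction, genotype) {
    p <- pmax(0, total * fraction + rnorm(nrow(targets), 0, background))
    s <- pmax(0, total * (1 - fraction) + rnorm(nrow(targets), 0, background))
    data.frame(target = rep(targets$target, 2L),
               genotype = genotype,
               fraction_label = rep(c("P", "S"), each = nrow(targets)),
               signal = c(p, s),
               volume_fraction = 1,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rows(targets$fraction, "wt"), rows(0, "control"))
  rownames(out) <- NULL
  out
}

#' Write / read the tab-separated tables used across the package
#'
#' Plain TSV with header, no quoting, no row names; numbers written with
#' 15 significant digits so write/read round-trips are lossless at double
#' precision and byte-deterministic for fixed inputs.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_tsv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) {
    w <- format(v, digits = 15, trim = TRUE, scientific = FALSE)
    # integers stay integers so round-trips compare cleanly
    ifelse(is.finite(v) & v == round(v) & abs(v) < 1e15,
           format(round(v), trim = TRUE, scientific = FALSE), w)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
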