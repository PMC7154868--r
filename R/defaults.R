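# Packaged demo world: a CP33B-like single-motif binder.  All values are
# frozen design choices, documented in the methods vignette; none is derived
# from data at run time.

DEMO_CONSENSUS <- "UGGAAGUA"

# Position-specific mismatch tolerance: mismatches at the motif ends are
# penalized least, central positions most (RRM cores contact central bases
# most tightly).  Length must equal nchar(DEMO_CONSENSUS).
DEMO_POS_WEIGHT <- c(0.50, 0.40, 0.30, 0.22, 0.22, 0.30, 0.40, 0.50)

# Base-dependent multiplier for the substituted base: transitions (A<->G,
# C<->U) are tolerated better than transversions; substituting to U slightly
# better than to other transversions (U pairs weakly with everything).
#' @noRd
demo_base_mult <- function(ref, alt) {
  transitions <- c(A = "G", G = "A", C = "U", U = "C")
  if (transitions[[ref]] == alt) 1.4 else if (alt == "U") 1.0 else 0.8
}

#' Packaged demo binding model
#'
#' A single-motif binding model emulating a sequence-specific two-RRM
#' chloroplast RNA-binding protein.  The consensus 8-mer
#' (`UGGAAGUA`) has affinity 0.5 on the package's Langmuir scale, i.e. a
#' bound fraction of 1/3 at 100 nM protein and 5/6 at 1000 nM -- partially
#' saturated at the lower and strongly saturated at the higher concentration.
#' Every single- and double-mismatch derivative carries a graded affinity
#' (position- and base-dependent multiplicative penalties), giving a family
#' of 277 k-mers whose enrichment ranking is resolvable at desk-scale
#' sequencing depth.  Background carryover affinity is 0.005 (~0.5% capture
#' probability at 100 nM), typical of a washed streptavidin pulldown.
#'
#' @param consensus consensus 8-mer (RNA alphabet).
#' @param consensus_affinity affinity of the consensus.
#' @param background_affinity affinity of motif-free reads.
#' @param max_mismatches how many mismatch shells to include (0, 1 or 2).
#' @return a [binding_model()].
#' @examples
#' m <- default_binding_model()
#' m
#' @export
default_binding_model <- function(consensus = DEMO_CONSENSUS,
                                  consensus_affinity = 0.5,
                                  background_affinity = 0.005,
                                  max_mismatches = 2L) {
  consensus <- normalize_rna(consensus)
  check_rna_alphabet(consensus, "consensus")
  k <- nchar(consensus)
  if (k != length(DEMO_POS_WEIGHT)) {
    pos_weight <- rep(DEMO_POS_WEIGHT, length.out = k)
  } else {
    pos_weight <- DEMO_POS_WEIGHT
  }
  cb <- strsplit(consensus, "")[[1]]
  aff <- setNames(consensus_affinity, consensus)
  if (max_mismatches >= 1L) {
    for (i in seq_len(k)) {
      for (b in setdiff(RNA_BASES, cb[i])) {
        km <- cb; km[i] <- b
        aff[paste(km, collapse = "")] <-
          consensus_affinity * pos_weight[i] * demo_base_mult(cb[i], b)
      }
    }
  }
  if (max_mismatches >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        for (bi in setdiff(RNA_BASES, cb[i])) {
          for (bj in setdiff(RNA_BASES, cb[j])) {
            km <- cb; km[i] <- bi; km[j] <- bj
            aff[paste(km, collapse = "")] <- consensus_affinity *
              pos_weight[i] * demo_base_mult(cb[i], bi) *
              pos_weight[j] * demo_base_mult(cb[j], bj)
          }
        }
      }
    }
  }
  binding_model(aff, background_affinity = background_affinity, combine_rule = "max")
}

#' Packaged demo tiling-array design
#'
#' A plastome-like tiling design: `n_probes` 1-kb probes covering a circular
#' genome of `genome_length` bases, with four rRNA probes (flagged
#' `is_rrna`, planted enrichment exactly 1) and a graded enrichment spectrum
#' over the mRNA probes -- one dominant psbA-like probe at `top_factor`
#' (default 10) followed by a smooth exponential decay from 6 towards 1,
#' emulating the continuum of transcript association seen in RIP-chip data.
#'
#' @param n_probes number of probes.
#' @param genome_length genome length in bases.
#' @param top_factor planted enrichment of the dominant probe.
#' @return list with `design` (data.frame: probe_id, start, end, feature,
#'   is_rrna) and `factors` (named numeric planted enrichment per probe).
#' @export
default_array_design <- function(n_probes = 150L, genome_length = 150000L,
                                 top_factor = 10) {
  width <- genome_length %/% n_probes
  start <- (seq_len(n_probes) - 1L) * width
  probe_id <- sprintf("probe_%03d", seq_len(n_probes))
  feature <- sprintf("locus_%03d", seq_len(n_probes))
  # four rRNA probes spread over the genome, away from the top probe
  rrna_idx <- unique(pmax(1L, round(seq(0.3, 0.9, length.out = 4) * n_probes)))
  is_rrna <- seq_len(n_probes) %in% rrna_idx
  feature[rrna_idx] <- c("rrn16", "rrn23", "rrn23b", "rrn5")[seq_along(rrna_idx)]
  mrna_idx <- setdiff(seq_len(n_probes), rrna_idx)
  top_idx <- mrna_idx[min(length(mrna_idx), max(1L, round(0.07 * n_probes)))]
  feature[top_idx] <- "psbA"
  design <- data.frame(probe_id = probe_id, start = start, end = start + width,
                       feature = feature, is_rrna = is_rrna,
                       stringsAsFactors = FALSE)
  factors <- rep(1, n_probes)
  mrna <- setdiff(seq_len(n_probes), c(rrna_idx, top_idx))
  factors[mrna] <- exp(seq(log(6), log(1.02), length.out = length(mrna)))
  factors[top_idx] <- top_factor
  names(factors) <- probe_id
  list(design = design, factors = factors)
}

#' Packaged demo dot-blot targets
#'
#' Default target set for the paired pellet/supernatant blot simulator:
#' a dominant psbA-like target (bound fraction 0.987, i.e. ~74-fold
#' pellet/supernatant ratio), secondary targets with intermediate fractions,
#' and two non-target controls with fraction 0.
#'
#' @return data.frame with columns `target` and `fraction`.
#' @export
default_blot_targets <- function() {
  data.frame(
    target = c("psbA", "psbD", "psaC", "ndhK", "rbcL", "psbF", "rrn23"),
    fraction = c(0.987, 0.92, 0.5, 0.5, 0.1, 0, 0),
    stringsAsFactors = FALSE
  )
}
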