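#' Paired-signal binding metrics
#'
#' Quantitative metrics from paired compartment signals (pellet/supernatant
#' of an immunoprecipitation, or stroma/membrane of a fractionation), blotted
#' at known volume fractions.  All functions are vectorized over pairs.
#'
#' `fold_enrichment` is the volume-corrected signal ratio
#' `(a / va) / (b / vb)`; with equal volumes it is the direct
#' pellet/supernatant ratio ("74-fold" scale).  A zero `b` signal yields
#' `Inf` (flagged, not an error).
#'
#' `fraction_bound` is the volume-corrected bound fraction
#' `(a/va) / (a/va + b/vb)` in \[0, 1\] ("90% in precipitates" scale); it
#' relates to the fold enrichment by `fraction = fold / (1 + fold)`.
#'
#' `partition_fraction` is the same statistic applied to a
#' stroma/membrane western pair (the "75% in the stroma" scale); the
#' membrane share is its complement.
#'
#' @param signal_a pellet (or stroma) signal, >= 0.
#' @param signal_b supernatant (or membrane) signal, >= 0.
#' @param volume_fraction_a,volume_fraction_b blotted volume fractions in
#'   (0, 1]; equal by default, as in equal-volume blotting.
#' @return numeric vector.
#' @examples
#' fold_enrichment(74, 1)        # 74-fold
#' fraction_bound(9, 1)          # 0.9
#' partition_fraction(3, 1)      # 0.75 stroma
#' @name quant_metrics
NULL

#' @noRd
check_pair <- function(signal_a, signal_b, volume_fraction_a, volume_fraction_b) {
  if (any(signal_a < 0) || any(signal_b < 0)) {
    stop("signals must be non-negative", call. = FALSE)
  }
  if (any(volume_fraction_a <= 0) || any(volume_fraction_a > 1) ||
      any(volume_fraction_b <= 0) || any(volume_fraction_b > 1)) {
    stop("volume fractions must lie in (0, 1]", call. = FALSE)
  }
}

#' @rdname quant_metrics
#' @export
fold_enrichment <- function(signal_a, signal_b,
                            volume_fraction_a = 1, volume_fraction_b = 1) {
  check_pair(signal_a, signal_b, volume_fraction_a, volume_fraction_b)
  a <- signal_a / volume_fraction_a
  b <- signal_b / volume_fraction_b
  ifelse(b > 0, a / b, ifelse(a > 0, Inf, NaN))
}

#' @rdname quant_metrics
#' @export
fraction_bound <- function(signal_a, signal_b,
                           volume_fraction_a = 1, volume_fraction_b = 1) {
  check_pair(signal_a, signal_b, volume_fraction_a, volume_fraction_b)
  a <- signal_a / volume_fraction_a
  b <- signal_b / volume_fraction_b
  ifelse(a + b > 0, a / (a + b), NaN)
}

#' @rdname quant_metrics
#' @export
partition_fraction <- function(signal_a, signal_b,
                               volume_fraction_a = 1, volume_fraction_b = 1) {
  fraction_bound(signal_a, signal_b, volume_fraction_a, volume_fraction_b)
}

#' Specificity call against a control precipitation
#'
#' A target is called specifically bound when its wild-type fold enrichment
#' reaches `min_ratio` and exceeds the control (pre-immune / null-mutant)
#' fold enrichment by at least the same factor:
#' `is_specific = fold_wt >= min_ratio & fold_wt / fold_control >= min_ratio`.
#' A zero control fold makes the second ratio infinite (passes); a missing
#' control makes the call abstain (`NA`).
#'
#' @param fold_wt,fold_control fold enrichments of matched targets (`NA`
#'   control = abstain).
#' @param target optional target labels for the report.
#' @param min_ratio call threshold (default 2).
#' @return data.frame: target, fold_wt, fold_control, is_specific.
#' @examples
#' control_adjusted_call(74, 0.5, target = "psbA")
#' @export
control_adjusted_call <- function(fold_wt, fold_control, target = NULL,
                                  min_ratio = 2) {
  n <- length(fold_wt)
  if (length(fold_control) != n) stop("fold_wt and fold_control must be matched", call. = FALSE)
  ratio <- ifelse(fold_control > 0, fold_wt / fold_control,
                  ifelse(fold_wt > 0, Inf, NaN))
  call <- fold_wt >= min_ratio & ratio >= min_ratio
  call[is.na(fold_control)] <- NA
  data.frame(target = target %||% sprintf("target_%d", seq_len(n)),
             fold_wt = fold_wt, fold_control = fold_control,
             is_specific = call, stringsAsFactors = FALSE)
}

#' Quantify a paired blot table
#'
#' Computes per-target fold enrichment, bound fraction and the
#' control-adjusted specificity call from a long blot table (as produced by
#' [simulate_blot_table()] or read with [read_tsv()]): columns `target`,
#' `genotype` (`wt` / `control`), `fraction_label` (two levels, e.g. `P` /
#' `S`), `signal`, `volume_fraction`.  An optional `background` column is
#' subtracted from the signals with a floor at 0 before any ratio is formed.
#'
#' @param blot long-format blot table.
#' @param labels the two fraction labels, `c(a, b)` = (pellet, supernatant).
#' @param min_ratio specificity threshold passed to
#'   [control_adjusted_call()].
#' @return data.frame with one row per target: fold_wt, fold_control,
#'   fraction_bound_wt, is_specific.
#' @export
quantify_blot <- function(blot, labels = c("P", "S"), min_ratio = 2) {
  stopifnot(is.data.frame(blot),
            all(c("target", "genotype", "fraction_label", "signal") %in% names(blot)))
  if (!"volume_fraction" %in% names(blot)) blot$volume_fraction <- 1
  if ("background" %in% names(blot)) {
    blot$signal <- pmax(0, blot$signal - blot$background)
  }
  targets <- unique(blot$target)
  grab <- function(tg, gt, lab) {
    d <- blot[blot$target == tg & blot$genotype == gt & blot$fraction_label == lab, ]
    if (nrow(d) == 0) return(c(NA_real_, NA_real_))
    c(d$signal[1], d$volume_fraction[1])
  }
  rows <- lapply(targets, function(tg) {
    pw <- grab(tg, "wt", labels[1]);  sw <- grab(tg, "wt", labels[2])
    pc <- grab(tg, "control", labels[1]); sc <- grab(tg, "control", labels[2])
    fw <- if (is.na(pw[1])) NA_real_ else fold_enrichment(pw[1], sw[1], pw[2], sw[2])
    fc <- if (is.na(pc[1])) NA_real_ else fold_enrichment(pc[1], sc[1], pc[2], sc[2])
    fb <- if (is.na(pw[1])) NA_real_ else fraction_bound(pw[1], sw[1], pw[2], sw[2])
    data.frame(target = tg, fold_wt = fw, fold_control = fc,
               fraction_bound_wt = fb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_specific <- control_adjusted_call(out$fold_wt, out$fold_control,
                                           target = out$target,
                                           min_ratio = min_ratio)$is_specific
  rownames(out) <- NULL
  out
}
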