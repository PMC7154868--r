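#' Per-probe, per-replicate fluorescence ratios
#'
#' Ratio of the co-precipitated channel to the unbound channel,
#' `ratio = F635 / F532`, exactly.  Probe-replicates with `F532 <= 0` cannot
#' be ratioed; they are excluded with a warning.
#'
#' @param measurements data.frame with at least `probe_id`, `replicate`,
#'   `F635`, `F532` (as produced by [simulate_array_table()] or read with
#'   [read_tsv()]).
#' @return the surviving rows with a `ratio` column appended.
#' @export
replicate_ratios <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("probe_id", "replicate", "F635", "F532") %in% names(measurements)))
  bad <- !(measurements$F532 > 0)
  if (any(bad)) {
    warning(sprintf("%d probe-replicate(s) with F532 <= 0 excluded from ratio computation", sum(bad)))
    measurements <- measurements[!bad, , drop = FALSE]
  }
  measurements$ratio <- measurements$F635 / measurements$F532
  rownames(measurements) <- NULL
  measurements
}

#' Median of replicate ratios per probe
#'
#' Standard median (even replicate counts average the central pair).  Probes
#' with no surviving replicate are dropped with a warning by
#' [replicate_ratios()] upstream.
#'
#' @param ratios output of [replicate_ratios()].
#' @return data.frame with one row per probe: probe metadata, `n_replicates`
#'   and `median_ratio`, ordered by genome position when coordinates are
#'   present.
#' @export
median_of_ratios <- function(ratios) {
  stopifnot(is.data.frame(ratios), "ratio" %in% names(ratios))
  sp <- split(ratios, ratios$probe_id)
  meta_cols <- intersect(c("probe_id", "start", "end", "feature", "is_rrna", "genotype"),
                         names(ratios))
  out <- do.call(rbind, lapply(sp, function(d) {
    cbind(d[1, meta_cols, drop = FALSE],
          data.frame(n_replicates = nrow(d), median_ratio = median(d$ratio)))
  }))
  if ("start" %in% names(out)) out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

#' Ribosomal-RNA normalization factor of one array
#'
#' Sum over the rRNA-flagged probes of the median (over replicates) F532
#' signal -- the unbound-channel rRNA signal used to normalize probe ratios
#' across arrays.  The factor is linear in the F532 scale of the array.
#'
#' @param measurements one array's measurement table (one genotype).
#' @return positive scalar.
#' @export
rrna_normalization_factor <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("probe_id", "is_rrna", "F532") %in% names(measurements)))
  rr <- measurements[as.logical(measurements$is_rrna), , drop = FALSE]
  if (nrow(rr) == 0) stop("no rRNA-flagged probes; cannot normalize", call. = FALSE)
  med <- vapply(split(rr$F532, rr$probe_id), median, numeric(1))
  factor <- sum(med)
  if (!(factor > 0)) stop("rRNA normalization factor must be positive", call. = FALSE)
  factor
}

#' Per-probe enrichment of one array
#'
#' Replicate ratios, their per-probe median, and the rRNA-normalized value
#' `normalized = median_ratio / rrna_normalization_factor`.
#'
#' @param measurements one genotype's measurement table.
#' @return data.frame with probe metadata, `median_ratio` and `normalized`.
#' @export
probe_enrichment <- function(measurements) {
  med <- median_of_ratios(replicate_ratios(measurements))
  med$normalized <- med$median_ratio / rrna_normalization_factor(measurements)
  med
}

#' Compare wild-type and control arrays
#'
#' Joins the per-probe enrichments of a wild-type IP and a control IP
#' (pre-immune serum or null-mutant) on probe id and reports the
#' differential enrichment `normalized_wt / normalized_control`.  Probes
#' missing from the control get `NA` differential.  The top probe (maximal
#' differential among non-rRNA probes) is attached as attribute
#' `"top_probe"`.
#'
#' @param wt,control measurement tables of the two genotypes.
#' @return data.frame sorted by genome position: probe metadata,
#'   `median_ratio`, `normalized`, `control_normalized`, `differential`.
#' @examples
#' d <- default_array_design(n_probes = 12)
#' tabs <- simulate_array_table(d$design, d$factors, noise_sd = 0, seed = 1)
#' enr <- normalize_and_compare(tabs$wt, tabs$control)
#' attr(enr, "top_probe")
#' @export
normalize_and_compare <- function(wt, control) {
  ew <- probe_enrichment(wt)
  ec <- probe_enrichment(control)
  m <- match(ew$probe_id, ec$probe_id)
  if (any(is.na(m))) warning(sprintf("%d probe(s) missing in control; differential set NA", sum(is.na(m))))
  ew$control_normalized <- ec$normalized[m]
  ew$differential <- ifelse(!is.na(ew$control_normalized) & ew$control_normalized > 0,
                            ew$normalized / ew$control_normalized, NA_real_)
  if ("start" %in% names(ew)) ew <- ew[order(ew$start), ]
  rownames(ew) <- NULL
  cand <- ew[!as.logical(ew$is_rrna) & !is.na(ew$differential), ]
  attr(ew, "top_probe") <- if (nrow(cand)) cand$probe_id[which.max(cand$differential)] else NA_character_
  ew
}

#' Export probe enrichments as a bedGraph track
#'
#' Four-column bedGraph (chrom, start, end, value) of the chosen value
#' column, sorted by position.  Overlapping probe intervals are refused
#' unless `allow_overlap = TRUE`.
#'
#' @param enrichments per-probe table with `start`, `end` and the value
#'   column.
#' @param path output path.
#' @param value which column to export.
#' @param seq_id chromosome name written to the track.
#' @param allow_overlap permit overlapping intervals?
#' @return `path` (writer); the reader returns a data.frame (seq_id, start,
#'   end, value).
#' @export
export_track <- function(enrichments, path,
                         value = c("normalized", "differential", "median_ratio"),
                         seq_id = "plastome", allow_overlap = FALSE) {
  value <- match.arg(value)
  stopifnot(is.data.frame(enrichments),
            all(c("start", "end", value) %in% names(enrichments)))
  d <- enrichments[order(enrichments$start), ]
  if (!allow_overlap && nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
    stop("overlapping probe intervals; pass allow_overlap = TRUE to export anyway", call. = FALSE)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", value), con)
  writeLines(sprintf("%s\t%d\t%d\t%s", seq_id, as.integer(d$start),
                     as.integer(d$end),
                     format(d[[value]], digits = 10, trim = TRUE)), con)
  invisible(path)
}

#' @rdname export_track
#' @export
read_track <- function(path) {
  df <- read.delim(path, header = FALSE, skip = 1, stringsAsFactors = FALSE)
  names(df) <- c("seq_id", "start", "end", "value")
  df
}
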