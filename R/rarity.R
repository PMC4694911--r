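# Dataset-internal CNV frequency and the rare (<0.5%) definition.
# Carrier status between variable-boundary CNVs uses reciprocal overlap,
# the convention of array-CNV burden tools.

#' Carrier counts by reciprocal overlap
#'
#' For each call, counts the distinct samples (including the call's own
#' carrier) that harbour a call of the same type (when `match_type`)
#' whose overlap with it is at least `overlap_frac` of *both* calls'
#' lengths. A call with no overlapping call in any other sample has
#' carrier count 1.
#'
#' @param cs a [callset()].
#' @param overlap_frac required reciprocal overlap fraction (default 0.5).
#' @param match_type if TRUE (default), only calls of the same
#'   deletion/duplication type can witness each other.
#' @return integer vector of carrier counts, one per row of `cs$calls`.
#' @export
carrier_counts <- function(cs, overlap_frac = 0.5, match_type = TRUE) {
  stopifnot(inherits(cs, "cnv_callset"))
  d <- cs$calls
  n <- nrow(d)
  if (n == 0L) return(integer())
  counts <- integer(n)
  key <- if (match_type) paste(d$chrom, d$cnv_type, sep = "\r") else d$chrom
  for (grp in split(seq_len(n), key)) {
    ir <- IRanges::IRanges(start = d$start_bp[grp], end = d$end_bp[grp])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(d$end_bp[grp][q], d$end_bp[grp][s]) -
      pmax(d$start_bp[grp][q], d$start_bp[grp][s]) + 1L
    recip <- ov >= overlap_frac * d$length_bp[grp][q] &
      ov >= overlap_frac * d$length_bp[grp][s]
    q <- q[recip]; s <- s[recip]
    # distinct carrier samples per query call (self-hits supply the carrier)
    pair <- paste(q, d$sample_id[grp][s], sep = "\r")
    first <- !duplicated(pair)
    counts[grp] <- tabulate(q[first], nbins = length(grp))
  }
  counts
}

#' Filter a call set to rare CNVs
#'
#' A call is rare when its carrier frequency — carrier count divided by
#' the size of the post-QC sample universe (cases and controls pooled) —
#' is strictly below `freq_threshold` (default 0.5%).
#'
#' @param cs a [callset()]; its `samples` slot defines the frequency
#'   denominator.
#' @param freq_threshold strict upper bound on carrier frequency.
#' @param overlap_frac,match_type carrier definition, see
#'   [carrier_counts()].
#' @return a [callset()] of the rare calls; the call table gains
#'   `carrier_count`, `frequency` and `is_rare` columns (the returned
#'   set keeps only rows with `is_rare` TRUE).
#' @export
filter_rare <- function(cs, freq_threshold = 0.005, overlap_frac = 0.5,
                        match_type = TRUE) {
  stopifnot(inherits(cs, "cnv_callset"))
  n_universe <- length(cs$samples)
  if (n_universe == 0L) stop("filter_rare: empty sample universe")
  d <- cs$calls
  cc <- carrier_counts(cs, overlap_frac = overlap_frac,
                       match_type = match_type)
  d$carrier_count <- cc
  d$frequency <- cc / n_universe
  d$is_rare <- d$frequency < freq_threshold
  out <- d[d$is_rare, , drop = FALSE]
  rownames(out) <- NULL
  res <- callset(out, samples = cs$samples, provenance = cs$provenance)
  add_provenance(res, sprintf(
    "filter_rare[freq<%g,recip>=%g,N=%d]: kept %d/%d",
    freq_threshold, overlap_frac, n_universe, nrow(out), nrow(d)))
}
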