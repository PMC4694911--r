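# Post-processing of raw caller output: adjacent-segment merging,
# two-caller consensus, and per-call quality control.

#' Merge adjacent same-state CNV segments
#'
#' Within each sample and chromosome, two consecutive calls with the same
#' copy-number state are merged into a single call when the gap between
#' them is shorter than half the total length of the two segments:
#' `gap_bp < 0.5 * (len1 + len2)`, with `gap_bp = start2 - end1 - 1`
#' (the number of intervening bases under inclusive coordinates; the
#' comparison is strict). Merging is applied left-to-right and repeated
#' until a fixpoint, re-evaluating the rule against the already-merged
#' segment's length, so the result is idempotent. A merged call spans
#' the union of the pair, its probe count is the sum, and its Bayes
#' factor the maximum of the pair. Overlapping same-state calls merge
#' unconditionally (their gap is <= 0); overlapping calls with
#' *different* states are inconsistent input and raise an error.
#'
#' @param cs a [callset()].
#' @return a [callset()] with merged calls.
#' @export
merge_adjacent <- function(cs) {
  stopifnot(inherits(cs, "cnv_callset"))
  d <- cs$calls
  if (nrow(d) < 2L) return(add_provenance(cs, "merge_adjacent"))
  key <- paste(d$sample_id, d$chrom, sep = "\r")
  pieces <- lapply(split(d, key), .merge_group)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  res <- callset(out, samples = cs$samples, provenance = cs$provenance)
  add_provenance(res, "merge_adjacent")
}

# One sample x chromosome, already sorted by start.
.merge_group <- function(g) {
  repeat {
    changed <- FALSE
    keep <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      last <- keep[nrow(keep), ]
      cur <- g[i, ]
      if (cur$start_bp <= last$end_bp && cur$state != last$state)
        stop("merge_adjacent: overlapping calls with different states in ",
             "sample ", cur$sample_id, " chr", cur$chrom)
      gap <- cur$start_bp - last$end_bp - 1L
      if (cur$state == last$state &&
          gap < 0.5 * (last$length_bp + cur$length_bp)) {
        last$end_bp <- max(last$end_bp, cur$end_bp)
        last$length_bp <- last$end_bp - last$start_bp + 1L
        last$n_probes <- last$n_probes + cur$n_probes
        last$bayes_factor <-
          if (all(is.na(c(last$bayes_factor, cur$bayes_factor))))
            NA_real_
          else max(last$bayes_factor, cur$bayes_factor, na.rm = TRUE)
        keep[nrow(keep), ] <- last
        changed <- TRUE
      } else {
        keep <- rbind(keep, cur)
      }
    }
    g <- keep
    if (!changed) return(g)
  }
}

#' Two-caller consensus of CNV calls
#'
#' Retains calls detected in both input sets for the same sample with
#' matching breakpoints (within `tolerance_bp` on each end) and an
#' identical copy-number state. The default tolerance of 0 demands
#' identical breakpoints. Output coordinates and probe counts are taken
#' from caller `a`; the Bayes factor from the matching call in `b`
#' (conventionally the QuantiSNP side, which carries it). Each `b` call
#' can witness at most one `a` call; at tolerance > 0 matching is
#' greedy in sorted order.
#'
#' @param a,b post-merge [callset()]s over the same sample universe.
#' @param tolerance_bp maximum per-breakpoint discrepancy in bp.
#' @return a consensus [callset()].
#' @export
intersect_callers <- function(a, b, tolerance_bp = 0) {
  stopifnot(inherits(a, "cnv_callset"), inherits(b, "cnv_callset"))
  only_a <- setdiff(a$samples, b$samples)
  only_b <- setdiff(b$samples, a$samples)
  if (length(only_a) || length(only_b))
    stop("intersect_callers: sample universes differ; only in a: [",
         paste(only_a, collapse = ", "), "]; only in b: [",
         paste(only_b, collapse = ", "), "]")
  da <- a$calls; db <- b$calls
  if (nrow(da) == 0L || nrow(db) == 0L)
    return(callset(empty_calls(), samples = a$samples,
                   provenance = "intersect_callers"))
  kept <- logical(nrow(da))
  bf <- rep(NA_real_, nrow(da))
  used_b <- logical(nrow(db))
  ka <- paste(da$sample_id, da$chrom, da$state, sep = "\r")
  kb <- paste(db$sample_id, db$chrom, db$state, sep = "\r")
  idx_b <- split(seq_len(nrow(db)), kb)
  for (i in seq_len(nrow(da))) {
    cand <- idx_b[[ka[i]]]
    if (is.null(cand)) next
    cand <- cand[!used_b[cand] &
                 abs(db$start_bp[cand] - da$start_bp[i]) <= tolerance_bp &
                 abs(db$end_bp[cand] - da$end_bp[i]) <= tolerance_bp]
    if (length(cand)) {
      j <- cand[1]
      kept[i] <- TRUE
      bf[i] <- db$bayes_factor[j]
      used_b[j] <- TRUE
    }
  }
  out <- da[kept, , drop = FALSE]
  out$bayes_factor <- bf[kept]
  out$caller <- rep("consensus", nrow(out))
  rownames(out) <- NULL
  callset(out, samples = a$samples,
          provenance = c(a$provenance,
                         paste0("intersect_callers[a=",
                                paste(unique(da$caller), collapse = "+"),
                                ",b=",
                                paste(unique(db$caller), collapse = "+"),
                                ",tol=", tolerance_bp, "]")))
}

#' CNV-level quality control
#'
#' Retains high-confidence calls: length strictly greater than
#' `min_length_bp` (default 10 kb), probe span of at least `min_probes`
#' (default 10; "ten or more" passes at exactly 10), and Bayes factor
#' strictly greater than `min_bayes_factor` (default 10). Calls with no
#' Bayes factor fail the Bayes-factor criterion.
#'
#' @param cs a [callset()].
#' @param min_length_bp strict lower bound on call length in bp.
#' @param min_probes inclusive lower bound on probe count.
#' @param min_bayes_factor strict lower bound on the Bayes factor.
#' @return the filtered [callset()].
#' @export
filter_calls <- function(cs, min_length_bp = 10000, min_probes = 10,
                         min_bayes_factor = 10) {
  stopifnot(inherits(cs, "cnv_callset"))
  d <- cs$calls
  keep <- d$length_bp > min_length_bp &
    d$n_probes >= min_probes &
    !is.na(d$bayes_factor) & d$bayes_factor > min_bayes_factor
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  res <- callset(out, samples = cs$samples, provenance = cs$provenance)
  add_provenance(res, sprintf(
    "filter_calls[len>%g,probes>=%g,bf>%g]: kept %d/%d",
    min_length_bp, min_probes, min_bayes_factor, nrow(out), nrow(d)))
}
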