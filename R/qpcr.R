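# Relative copy-number quantification from qPCR Ct values by the
# delta-delta-Ct method, as used to validate array CNV calls.

#' Copy number from qPCR Ct values (delta-delta-Ct)
#'
#' For each sample and primer pair, the target Ct is referenced against
#' an endogenous single-copy assay (e.g. RNase P):
#' `dCt = mean(Ct_target) - mean(Ct_reference)`. The delta-delta-Ct
#' against a calibrator sample assumed diploid at the locus,
#' `ddCt = dCt_sample - dCt_calibrator`, gives the relative quantity
#' `RQ = 2^-ddCt`, and the copy-number estimate is `2 * mean(RQ)`
#' across primer pairs (two per CNV region by design). Estimates are
#' classified as deletion (`CN < 1.5`), normal (`1.5 <= CN < 2.5`) or
#' duplication (`CN >= 2.5`); the cut-offs are conventions of this
#' implementation. Replicate Ct spreads above `max_ct_spread` cycles
#' flag the estimate rather than dropping it.
#'
#' @param ct data.frame with one row per Ct replicate and columns
#'   `sample_id`, `primer_pair`, `assay` (`"target"` or `"reference"`),
#'   `ct` (numeric cycles).
#' @param calibrator sample_id of the diploid calibrator.
#' @param max_ct_spread replicate max-minus-min spread (cycles) above
#'   which the estimate is flagged.
#' @return data.frame per sample: `sample_id`, `n_primer_pairs`,
#'   `copy_number`, `cn_class`, `flag_ct_spread`.
#' @export
ddct_copy_number <- function(ct, calibrator, max_ct_spread = 0.5) {
  req <- c("sample_id", "primer_pair", "assay", "ct")
  stopifnot(is.data.frame(ct), all(req %in% names(ct)))
  if (!all(ct$assay %in% c("target", "reference")))
    stop("ddct_copy_number: assay must be 'target' or 'reference'")
  if (anyNA(ct$ct)) stop("ddct_copy_number: missing Ct value")
  if (!calibrator %in% ct$sample_id)
    stop("ddct_copy_number: calibrator sample '", calibrator,
         "' not present in the Ct table")
  key <- interaction(ct$sample_id, ct$primer_pair, ct$assay, drop = TRUE)
  agg <- data.frame(
    sample_id = tapply(ct$sample_id, key, `[`, 1),
    primer_pair = tapply(ct$primer_pair, key, `[`, 1),
    assay = tapply(ct$assay, key, `[`, 1),
    mean_ct = as.numeric(tapply(ct$ct, key, mean)),
    spread = as.numeric(tapply(ct$ct, key, function(v)
      max(v) - min(v))),
    stringsAsFactors = FALSE
  )
  wide_key <- paste(agg$sample_id, agg$primer_pair, sep = "\r")
  dct <- lapply(split(agg, wide_key), function(g) {
    tt <- g[g$assay == "target", ]; rr <- g[g$assay == "reference", ]
    if (nrow(tt) != 1L || nrow(rr) != 1L)
      stop("ddct_copy_number: sample ", g$sample_id[1], " primer pair ",
           g$primer_pair[1], " needs one target and one reference assay")
    data.frame(sample_id = g$sample_id[1], primer_pair = g$primer_pair[1],
               dct = tt$mean_ct - rr$mean_ct,
               spread = max(tt$spread, rr$spread),
               stringsAsFactors = FALSE)
  })
  dct <- do.call(rbind, dct)
  cal <- dct[dct$sample_id == calibrator, ]
  rows <- lapply(split(dct, dct$sample_id), function(g) {
    cal_m <- cal$dct[match(g$primer_pair, cal$primer_pair)]
    if (anyNA(cal_m))
      stop("ddct_copy_number: calibrator lacks primer pair(s): ",
           paste(g$primer_pair[is.na(cal_m)], collapse = ", "))
    rq <- 2^(-(g$dct - cal_m))
    cn <- 2 * mean(rq)
    data.frame(sample_id = g$sample_id[1], n_primer_pairs = nrow(g),
               copy_number = cn,
               cn_class = if (cn < 1.5) "deletion"
                          else if (cn < 2.5) "normal" else "duplication",
               flag_ct_spread = any(g$spread > max_ct_spread),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
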