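# Per-sample quality control: the five exclusion criteria applied to
# array-derived per-sample metrics, with per-sample reasons.

#' Default sample-exclusion thresholds
#'
#' Genotype call rate below 95%; more than 200 raw CNV calls (each
#' caller's own pre-consensus count); absolute GC wave factor above
#' 0.05; PennCNV LRR standard deviation above 0.3; QuantiSNP
#' genome-wide LRR standard deviation above 3.5. All comparisons are
#' strict, following the usual "more than / larger than / less than"
#' phrasing of these criteria.
#'
#' @return named list of thresholds.
#' @export
sample_qc_thresholds <- function() {
  list(min_call_rate = 0.95, max_cnv_count = 200, max_abs_gcwf = 0.05,
       max_lrr_sd = 0.3, max_quantisnp_lrr_sd = 3.5)
}

#' Apply sample-level quality control
#'
#' Excludes a sample when any criterion fires: `call_rate <
#' min_call_rate`, `cnv_count_raw > max_cnv_count`, `|gcwf| >
#' max_abs_gcwf`, `lrr_sd > max_lrr_sd`, or `quantisnp_lrr_sd >
#' max_quantisnp_lrr_sd`. All triggered reasons are reported. A missing
#' metric excludes the sample with reason `missing_metric:<name>`.
#' When a call set is supplied, calls belonging to excluded samples are
#' removed and the sample universe shrunk accordingly.
#'
#' @param samples data.frame of sample records (see [read_samples()]).
#' @param calls optional [callset()] to subset to the kept samples.
#' @param thresholds list as returned by [sample_qc_thresholds()].
#' @return list with `kept` (sample data.frame), `excluded` (data.frame
#'   of sample_id and comma-separated reasons), and `calls` (filtered
#'   call set, or NULL if none was given).
#' @export
apply_sample_qc <- function(samples, calls = NULL,
                            thresholds = sample_qc_thresholds()) {
  stopifnot(is.data.frame(samples))
  th <- utils::modifyList(sample_qc_thresholds(), thresholds)
  metrics <- c("call_rate", "cnv_count_raw", "gcwf", "lrr_sd",
               "quantisnp_lrr_sd")
  reasons <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    r <- character()
    for (m in metrics)
      if (is.na(samples[[m]][i])) r <- c(r, paste0("missing_metric:", m))
    if (!is.na(samples$call_rate[i]) &&
        samples$call_rate[i] < th$min_call_rate) r <- c(r, "call_rate")
    if (!is.na(samples$cnv_count_raw[i]) &&
        samples$cnv_count_raw[i] > th$max_cnv_count) r <- c(r, "cnv_count")
    if (!is.na(samples$gcwf[i]) &&
        abs(samples$gcwf[i]) > th$max_abs_gcwf) r <- c(r, "gcwf")
    if (!is.na(samples$lrr_sd[i]) &&
        samples$lrr_sd[i] > th$max_lrr_sd) r <- c(r, "lrr_sd")
    if (!is.na(samples$quantisnp_lrr_sd[i]) &&
        samples$quantisnp_lrr_sd[i] > th$max_quantisnp_lrr_sd)
      r <- c(r, "quantisnp_lrr_sd")
    reasons[[i]] <- r
  }
  failed <- lengths(reasons) > 0L
  excluded <- data.frame(
    sample_id = samples$sample_id[failed],
    reasons = vapply(reasons[failed], paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  kept <- samples[!failed, , drop = FALSE]
  rownames(kept) <- NULL
  out_calls <- NULL
  if (!is.null(calls)) {
    stopifnot(inherits(calls, "cnv_callset"))
    d <- calls$calls[calls$calls$sample_id %in% kept$sample_id, ,
                     drop = FALSE]
    rownames(d) <- NULL
    out_calls <- callset(d,
                         samples = intersect(calls$samples, kept$sample_id),
                         provenance = calls$provenance)
    out_calls <- add_provenance(out_calls, sprintf(
      "sample_qc: excluded %d/%d samples", sum(failed), nrow(samples)))
  }
  list(kept = kept, excluded = excluded, calls = out_calls)
}
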