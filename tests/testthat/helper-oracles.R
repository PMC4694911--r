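# Independent brute-force oracles and small fixture builders used across
# the suite. These re-derive expected values by direct enumeration and
# stay independent of the package's implementation paths.

# Repeated O(n^2) scan merger: keep merging any adjacent same-state pair
# (sorted order) whose gap is < half the summed lengths, until stable.
brute_merge <- function(df) {
  repeat {
    df <- df[order(df$start_bp, df$end_bp), , drop = FALSE]
    merged <- FALSE
    for (i in seq_len(nrow(df) - 1)) {
      a <- df[i, ]; b <- df[i + 1, ]
      if (a$state != b$state) next
      gap <- b$start_bp - a$end_bp - 1
      if (gap < 0.5 * ((a$end_bp - a$start_bp + 1) +
                       (b$end_bp - b$start_bp + 1))) {
        a$end_bp <- max(a$end_bp, b$end_bp)
        a$n_probes <- a$n_probes + b$n_probes
        a$bayes_factor <- if (all(is.na(c(a$bayes_factor,
                                          b$bayes_factor)))) NA_real_
          else max(a$bayes_factor, b$bayes_factor, na.rm = TRUE)
        df <- rbind(df[seq_len(i - 1), , drop = FALSE], a,
                    df[setdiff(seq_len(nrow(df)), seq_len(i + 1)), ,
                       drop = FALSE])
        merged <- TRUE
        break
      }
    }
    if (!merged) return(df)
  }
}

# All-pairs reciprocal-overlap carrier counter.
brute_carriers <- function(calls, overlap_frac = 0.5,
                           match_type = TRUE) {
  n <- nrow(calls)
  out <- integer(n)
  for (i in seq_len(n)) {
    carriers <- character()
    for (j in seq_len(n)) {
      if (calls$chrom[i] != calls$chrom[j]) next
      if (match_type && calls$cnv_type[i] != calls$cnv_type[j]) next
      ov <- min(calls$end_bp[i], calls$end_bp[j]) -
        max(calls$start_bp[i], calls$start_bp[j]) + 1
      li <- calls$end_bp[i] - calls$start_bp[i] + 1
      lj <- calls$end_bp[j] - calls$start_bp[j] + 1
      if (ov >= overlap_frac * li && ov >= overlap_frac * lj)
        carriers <- union(carriers, calls$sample_id[j])
    }
    out[i] <- length(carriers)
  }
  out
}

# All-pairs call-vs-gene overlap (inclusive coordinates, flanked).
brute_genic <- function(calls, genes, flank = 10000) {
  vapply(seq_len(nrow(calls)), function(i) {
    any(genes$chrom == calls$chrom[i] &
          calls$end_bp[i] >= genes$tx_start_bp - flank &
          calls$start_bp[i] <= genes$tx_end_bp + flank)
  }, logical(1))
}

# Exact hypergeometric upper tail by enumerating all query draws.
brute_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(q) sum(q <= K) >= k))
}

# quick call-table builder on one sample/chromosome
mk_calls <- function(starts, ends, state = 1L, sample_id = "s1",
                     chrom = "1", n_probes = 10L, bf = 20,
                     caller = "quantisnp") {
  cnv_calls(rep_len(sample_id, length(starts)),
            rep_len(chrom, length(starts)), starts, ends,
            rep_len(state, length(starts)),
            rep_len(n_probes, length(starts)),
            caller = caller, bayes_factor = rep_len(bf, length(starts)))
}

mk_samples <- function(n_cases, n_controls, age = NULL) {
  n <- n_cases + n_controls
  data.frame(
    sample_id = sprintf("P%04d", seq_len(n)),
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    site = rep(c("colon", "none"), c(n_cases, n_controls)),
    sex = rep_len(c("M", "F"), n),
    age = if (is.null(age)) rep_len(c(45, 60, 75), n) else age,
    ms_status = rep(c("unknown", "non_ms"), c(n_cases, n_controls)),
    call_rate = 0.99, lrr_sd = 0.2, gcwf = 0.01,
    quantisnp_lrr_sd = 2.5, cnv_count_raw = 5L,
    stringsAsFactors = FALSE)
}
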