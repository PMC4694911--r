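# Reconstruct a cohort-scale call table from published group totals:
# 694 cases (336 colon / 340 rectal / 18 both) vs 1641 controls, with
# per-stratum deletion/duplication and genic/non-genic call counts.
# Calls are distributed round-robin within each stratum; burden rates
# and fold changes depend only on the totals and group sizes.
published_cohort <- function() {
  n_colon <- 336; n_rectal <- 340; n_both <- 18; n_controls <- 1641
  samples <- mk_samples(n_colon + n_rectal + n_both, n_controls)
  samples$site[samples$phenotype == "case"] <-
    rep(c("colon", "rectal", "both"), c(n_colon, n_rectal, n_both))
  # counts per stratum: deletion/duplication split into genic + rest
  cells <- rbind(
    data.frame(stratum = "colon",   type = "deletion",    total = 431,
               genic = 231),
    data.frame(stratum = "colon",   type = "duplication", total = 320,
               genic = 220),
    data.frame(stratum = "rectal",  type = "deletion",    total = 389,
               genic = 207),
    data.frame(stratum = "rectal",  type = "duplication", total = 293,
               genic = 208),
    data.frame(stratum = "both",    type = "deletion",    total = 25,
               genic = 11),
    data.frame(stratum = "both",    type = "duplication", total = 13,
               genic = 10),
    data.frame(stratum = "control", type = "deletion",    total = 1184,
               genic = 576),
    data.frame(stratum = "control", type = "duplication", total = 1091,
               genic = 695))
  out <- list(); off <- 0L
  for (i in seq_len(nrow(cells))) {
    ids <- if (cells$stratum[i] == "control")
      samples$sample_id[samples$phenotype == "control"]
    else samples$sample_id[samples$site == cells$stratum[i]]
    for (gen in c(TRUE, FALSE)) {
      k <- if (gen) cells$genic[i] else cells$total[i] - cells$genic[i]
      if (k == 0) next
      who <- rep_len(ids, k)
      start <- 1000L + 60000L * (seq_len(k) %/% length(ids)) + off
      d <- cnv_calls(who, "1", start, start + 20000L,
                     if (cells$type[i] == "deletion") 1L else 3L,
                     12L, "consensus", 15)
      d$is_genic <- rep(gen, k)
      d$is_cds <- logical(k)
      out[[length(out) + 1]] <- d
      off <- off + 4L
    }
  }
  list(samples = samples, calls = do.call(rbind, out))
}
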