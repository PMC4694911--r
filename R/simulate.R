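# Synthetic case-control CNV cohorts with known truth: per-sample call
# counts with a case/control rate ratio, log-scale lengths, genic
# placement tilt, two caller outputs with breakpoint jitter / dropout /
# segment splitting, and per-sample QC metrics with injected failures.
# Every downstream stage can be validated against the generating truth.

#' Simulation configuration
#'
#' Defaults are calibrated to the scale of a genome-wide rare-CNV
#' case-control scan on a SNP array: 694 cases vs 1641 controls, a mean
#' of 1.39 rare CNVs per control with a 1.53-fold excess in cases,
#' 55% deletions, log-normal lengths in the 10 kb-1 Mb range, and a
#' synthetic genome of 22 autosomes of 10 Mb with a 1 kb probe grid
#' (dense enough that every >10 kb call spans >= 10 probes, the regime
#' the CNV quality-control filters assume).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param control_rate mean rare CNVs per control sample.
#' @param case_fold case/control rate ratio.
#' @param p_deletion fraction of calls that are deletions.
#' @param length_log_mean,length_log_sd log-normal length parameters
#'   (bp scale); lengths are truncated to > 10 kb.
#' @param genic_enrichment relative odds that a *case* call is placed
#'   in a gene +/- 10 kb region (1 = no tilt; controls are uniform).
#' @param n_genes number of synthetic genes.
#' @param n_chrom,chrom_length_bp,probe_spacing_bp synthetic genome:
#'   number of autosomes, length of each, and probe grid spacing.
#' @param caller_jitter_sd_bp sd of independent per-caller breakpoint
#'   jitter (rounded to the probe grid); 0 = callers agree to the bp.
#' @param caller_dropout probability each caller independently misses a
#'   true call.
#' @param caller_split_prob probability a caller reports a call as two
#'   adjacent segments separated by a one-probe gap (exercising the
#'   adjacent-merge rule).
#' @param qc_fail_fraction fraction of samples given a failing QC
#'   metric.
#' @param age_effect rate multiplier for cases in the lowest two age
#'   tertiles (1 = no age effect).
#' @param overdispersion negative-binomial size parameter; `Inf`
#'   (default) gives Poisson counts.
#' @param seed mandatory integer seed.
#' @return validated config list of class `sim_config`.
#' @export
simulation_config <- function(n_cases = 694, n_controls = 1641,
                              control_rate = 1.39, case_fold = 1.53,
                              p_deletion = 0.55,
                              length_log_mean = log(4e4),
                              length_log_sd = 0.8,
                              genic_enrichment = 1.2, n_genes = 300,
                              n_chrom = 22, chrom_length_bp = 1e7,
                              probe_spacing_bp = 1000,
                              caller_jitter_sd_bp = 0,
                              caller_dropout = 0.03,
                              caller_split_prob = 0.05,
                              qc_fail_fraction = 0.02,
                              age_effect = 1, overdispersion = Inf,
                              seed = NULL) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              control_rate = control_rate, case_fold = case_fold,
              p_deletion = p_deletion,
              length_log_mean = length_log_mean,
              length_log_sd = length_log_sd,
              genic_enrichment = genic_enrichment, n_genes = n_genes,
              n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
              probe_spacing_bp = probe_spacing_bp,
              caller_jitter_sd_bp = caller_jitter_sd_bp,
              caller_dropout = caller_dropout,
              caller_split_prob = caller_split_prob,
              qc_fail_fraction = qc_fail_fraction,
              age_effect = age_effect, overdispersion = overdispersion,
              seed = seed)
  if (is.null(cfg$seed)) stop("simulation_config: seed is mandatory")
  stopifnot(cfg$n_cases >= 1, cfg$n_controls >= 1,
            cfg$control_rate > 0, cfg$case_fold > 0,
            cfg$p_deletion >= 0, cfg$p_deletion <= 1,
            cfg$length_log_sd > 0, cfg$genic_enrichment > 0,
            cfg$n_genes >= 1, cfg$n_chrom >= 1, cfg$n_chrom <= 22,
            cfg$chrom_length_bp >= 1e6, cfg$probe_spacing_bp >= 1,
            cfg$caller_jitter_sd_bp >= 0,
            cfg$caller_dropout >= 0, cfg$caller_dropout < 1,
            cfg$caller_split_prob >= 0, cfg$caller_split_prob <= 1,
            cfg$qc_fail_fraction >= 0, cfg$qc_fail_fraction < 1,
            cfg$age_effect > 0, cfg$overdispersion > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Synthetic gene models: three-exon transcripts, CDS covering the inner
# two thirds, placed uniformly on the probe grid.
.simulate_genes <- function(cfg) {
  sp <- cfg$probe_spacing_bp
  chrom <- as.character(sample.int(cfg$n_chrom, cfg$n_genes,
                                   replace = TRUE))
  glen <- pmax(10L, round(stats::rlnorm(cfg$n_genes, log(30), 0.5)))  # in probes
  max_j <- cfg$chrom_length_bp %/% sp - glen - 1L
  j <- 1L + floor(stats::runif(cfg$n_genes) * pmax(1L, max_j))
  tx_start <- j * sp
  tx_end <- tx_start + glen * sp
  cds <- lapply(seq_len(cfg$n_genes), function(i) {
    span <- tx_end[i] - tx_start[i]
    a <- tx_start[i] + round(span / 6); b <- tx_end[i] - round(span / 6)
    mid <- (a + b) %/% 2
    data.frame(start_bp = c(a, min(mid + 50L, b)),
               end_bp = c(max(mid - 50L, a), b))
  })
  out <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                    symbol = sprintf("G%04d", seq_len(cfg$n_genes)),
                    chrom = chrom, tx_start_bp = tx_start,
                    tx_end_bp = tx_end, strand = "+",
                    stringsAsFactors = FALSE)
  out$cds_exons <- cds
  out
}

.write_refflat <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- g$cds_exons[[1]]
    # single exon spanning the transcript; CDS bounds from the exon set
    paste(g$symbol, g$gene_id, paste0("chr", g$chrom), g$strand,
          g$tx_start_bp - 1L, g$tx_end_bp,
          if (nrow(ex)) min(ex$start_bp) - 1L else g$tx_start_bp - 1L,
          if (nrow(ex)) max(ex$end_bp) else g$tx_start_bp - 1L,
          1L, paste0(g$tx_start_bp - 1L, ","),
          paste0(g$tx_end_bp, ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
}

# Genic target windows (gene +/- flank) per chromosome, reduced.
.genic_windows <- function(genes, flank, chrom_len) {
  lapply(split(genes, genes$chrom), function(g) {
    r <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, g$tx_start_bp - flank),
      pmin(chrom_len, g$tx_end_bp + flank)))
    data.frame(start = IRanges::start(r), end = IRanges::end(r))
  })
}

#' Simulate a case-control CNV cohort with known truth
#'
#' Draws per-sample true CNV calls (Poisson or negative-binomial counts
#' at `control_rate` for controls, `control_rate * case_fold` for
#' cases), places them on a synthetic genome with an optional genic
#' tilt for cases, and emits two caller files (PennCNV and QuantiSNP
#' dialects) with independent breakpoint jitter, dropout, and segment
#' splitting, a sample metadata table with QC metrics (a
#' `qc_fail_fraction` of samples get a failing metric), and a refFlat
#' gene-model file. With the same seed the output files are
#' byte-identical across runs.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return object of class `cnv_sim`: `config`, `samples`
#'   (data.frame), `truth` (a [callset()] of true calls), `genes`, and
#'   `paths` (penncnv/quantisnp/samples/genes files).
#' @export
simulate_cohort <- function(config, dir = tempfile("simcohort")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, {
    sp <- cfg$probe_spacing_bp
    n <- cfg$n_cases + cfg$n_controls
    sample_id <- sprintf("S%05d", seq_len(n))
    phenotype <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
    site <- ifelse(phenotype == "control", "none",
                   sample(c("colon", "rectal", "both"), n, replace = TRUE,
                          prob = c(336, 340, 18) / 694))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    age <- ifelse(phenotype == "case",
                  round(pmin(90, pmax(30, stats::rnorm(n, 63, 9)))),
                  round(pmin(90, pmax(30, stats::rnorm(n, 58, 10)))))
    ms_status <- ifelse(phenotype == "control",
                        sample(c("ms", "non_ms"), n, replace = TRUE,
                               prob = c(815, 826) / 1641),
                        "unknown")

    genes <- .simulate_genes(cfg)
    windows <- .genic_windows(genes, 10000L, cfg$chrom_length_bp)
    genic_bp <- sum(vapply(windows, function(w)
      sum(w$end - w$start + 1), numeric(1)))
    p_genic <- genic_bp / (cfg$n_chrom * cfg$chrom_length_bp)
    w_case <- (cfg$genic_enrichment * p_genic) /
      (cfg$genic_enrichment * p_genic + (1 - p_genic))

    # per-sample target rates
    rate <- ifelse(phenotype == "case",
                   cfg$control_rate * cfg$case_fold, cfg$control_rate)
    if (cfg$age_effect != 1) {
      ci <- phenotype == "case"
      tert <- assign_age_tertiles(age[ci])
      rate[ci][tert <= 2L] <- rate[ci][tert <= 2L] * cfg$age_effect
    }
    counts <- if (is.finite(cfg$overdispersion))
      stats::rnbinom(n, mu = rate, size = cfg$overdispersion)
    else stats::rpois(n, rate)

    max_j <- cfg$chrom_length_bp %/% sp
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      ni <- counts[i]
      if (ni == 0L) next
      placed <- data.frame(chrom = character(), start_bp = integer(),
                           end_bp = integer(), state = integer(),
                           stringsAsFactors = FALSE)
      for (j in seq_len(ni)) {
        for (try in 1:50) {
          L <- stats::rlnorm(1, cfg$length_log_mean, cfg$length_log_sd)
          k <- max(10L, as.integer(round(L / sp)))   # length = k*sp + 1
          targeted <- phenotype[i] == "case" &&
            stats::runif(1) < w_case
          if (targeted) {
            g <- genes[sample.int(nrow(genes), 1), ]
            lo <- max(1L, (g$tx_start_bp - 10000L - k * sp) %/% sp)
            hi <- min(max_j - k, (g$tx_end_bp + 10000L) %/% sp)
            if (hi < lo) next
            jj <- lo + floor(stats::runif(1) * (hi - lo + 1))
            chr <- g$chrom
          } else {
            chr <- as.character(sample.int(cfg$n_chrom, 1))
            jj <- 1L + floor(stats::runif(1) * (max_j - k - 1L))
          }
          s <- jj * sp; e <- s + k * sp
          # keep same-sample calls far enough apart that the
          # adjacent-merge rule can never join them (gap >= half the
          # summed lengths)
          clash <- FALSE
          if (nrow(placed)) {
            same <- placed$chrom == chr
            if (any(same)) {
              ps <- placed$start_bp[same]; pe <- placed$end_bp[same]
              pl <- pe - ps + 1L; ln <- e - s + 1L
              gap <- ifelse(s > pe, s - pe - 1L,
                            ifelse(e < ps, ps - e - 1L, -1L))
              clash <- any(gap < 0.5 * (pl + ln))
            }
          }
          if (!clash) {
            is_del <- stats::runif(1) < cfg$p_deletion
            st <- if (is_del) {
              if (stats::runif(1) < 0.1) 0L else 1L
            } else {
              if (stats::runif(1) < 0.1) 4L else 3L
            }
            placed <- rbind(placed, data.frame(
              chrom = chr, start_bp = s, end_bp = e, state = st,
              stringsAsFactors = FALSE))
            break
          }
        }
      }
      if (nrow(placed)) {
        placed$sample_id <- sample_id[i]
        truth_rows[[i]] <- placed
      }
    }
    tr <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                            logical(1))])
    truth_calls <- if (!is.null(tr) && nrow(tr)) {
      cnv_calls(tr$sample_id, tr$chrom, tr$start_bp, tr$end_bp,
                tr$state,
                n_probes = (tr$end_bp - tr$start_bp) %/% sp + 1L,
                caller = "truth")
    } else empty_calls()
    truth <- callset(truth_calls, samples = sample_id,
                     provenance = "simulate_cohort:truth")

    # caller channels: jitter, dropout, split
    emit_caller <- function(d) {
      keep <- stats::runif(nrow(d)) >= cfg$caller_dropout
      d <- d[keep, , drop = FALSE]
      if (nrow(d) == 0L) return(d)
      if (cfg$caller_jitter_sd_bp > 0) {
        js <- round(stats::rnorm(nrow(d), 0, cfg$caller_jitter_sd_bp) /
                      sp) * sp
        je <- round(stats::rnorm(nrow(d), 0, cfg$caller_jitter_sd_bp) /
                      sp) * sp
        d$start_bp <- pmax(sp, d$start_bp + as.integer(js))
        d$end_bp <- pmax(d$start_bp + sp, d$end_bp + as.integer(je))
      }
      split_it <- stats::runif(nrow(d)) < cfg$caller_split_prob
      out <- vector("list", nrow(d))
      for (i in seq_len(nrow(d))) {
        r <- d[i, ]
        k <- (r$end_bp - r$start_bp) %/% sp
        if (split_it[i] && k >= 4L) {
          m <- r$start_bp + (k %/% 2L) * sp
          r1 <- r; r1$end_bp <- m
          r2 <- r; r2$start_bp <- m + 2L * sp
          out[[i]] <- rbind(r1, r2)
        } else out[[i]] <- r
      }
      d <- do.call(rbind, out)
      d$n_probes <- (d$end_bp - d$start_bp) %/% sp + 1L
      d$bayes_factor <- round(10 + stats::rexp(nrow(d), 1 / 15), 2)
      d[order(d$sample_id, as.integer(d$chrom), d$start_bp), ,
        drop = FALSE]
    }
    tc <- truth$calls
    penn <- emit_caller(tc)
    quanti <- emit_caller(tc)

    # per-sample raw call counts (per caller, pre-consensus; QC uses max)
    raw_counts <- pmax(
      tabulate(factor(penn$sample_id, levels = sample_id), nbins = n),
      tabulate(factor(quanti$sample_id, levels = sample_id), nbins = n))

    samples <- data.frame(
      sample_id = sample_id, phenotype = phenotype, site = site,
      sex = sex, age = age, ms_status = ms_status,
      call_rate = round(stats::runif(n, 0.96, 0.995), 4),
      lrr_sd = round(stats::runif(n, 0.12, 0.28), 3),
      gcwf = round(stats::runif(n, -0.04, 0.04), 4),
      quantisnp_lrr_sd = round(stats::runif(n, 1.5, 3.2), 3),
      cnv_count_raw = raw_counts, stringsAsFactors = FALSE)
    n_fail <- round(cfg$qc_fail_fraction * n)
    if (n_fail > 0) {
      fi <- sample.int(n, n_fail)
      mode <- sample(5, n_fail, replace = TRUE)
      samples$call_rate[fi[mode == 1]] <- 0.90
      samples$cnv_count_raw[fi[mode == 2]] <- 250L
      samples$gcwf[fi[mode == 3]] <- 0.08 * sample(c(-1, 1),
                                                   sum(mode == 3),
                                                   replace = TRUE)
      samples$lrr_sd[fi[mode == 4]] <- 0.35
      samples$quantisnp_lrr_sd[fi[mode == 5]] <- 4.0
    }

    paths <- list(penncnv = file.path(dir, "penncnv.rawcnv"),
                  quantisnp = file.path(dir, "quantisnp.cnv.tsv"),
                  samples = file.path(dir, "samples.tsv"),
                  genes = file.path(dir, "genes.refflat"))
    state_label <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
    writeLines(if (nrow(penn)) sprintf(
      "chr%s:%d-%d\tnumsnp=%d\tlength=%d\tstate%d,cn=%d\t%s\tconf=%.2f",
      penn$chrom, penn$start_bp, penn$end_bp, penn$n_probes,
      penn$end_bp - penn$start_bp + 1L,
      state_label[as.character(penn$state)], penn$state,
      penn$sample_id, penn$bayes_factor) else character(),
      paths$penncnv)
    qd <- data.frame(`Sample Name` = quanti$sample_id,
                     Chromosome = quanti$chrom,
                     `Start Position (bp)` = quanti$start_bp,
                     `End Position (bp)` = quanti$end_bp,
                     `Length (bp)` = quanti$end_bp - quanti$start_bp + 1L,
                     `No. Probes` = quanti$n_probes,
                     `Copy Number` = quanti$state,
                     `Max. Log BF` = quanti$bayes_factor,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(qd, paths$quantisnp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(samples, paths$samples, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_refflat(genes, paths$genes)

    structure(list(config = cfg, samples = samples, truth = truth,
                   genes = genes, paths = paths), class = "cnv_sim")
  })
}

#' @export
print.cnv_sim <- function(x, ...) {
  cat("Synthetic CNV cohort: ", x$config$n_cases, " cases / ",
      x$config$n_controls, " controls, ", nrow(x$truth$calls),
      " true calls (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

# match calls between two tables by sample/chrom/state + reciprocal
# overlap; returns logical vector over `a` rows
.has_match <- function(a, b, overlap_frac = 0.5) {
  if (nrow(a) == 0L) return(logical())
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  hit <- rep(FALSE, nrow(a))
  ka <- paste(a$sample_id, a$chrom, a$cnv_type, sep = "\r")
  kb <- paste(b$sample_id, b$chrom, b$cnv_type, sep = "\r")
  idx <- split(seq_len(nrow(b)), kb)
  for (i in seq_len(nrow(a))) {
    cand <- idx[[ka[i]]]
    if (is.null(cand)) next
    ov <- pmin(b$end_bp[cand], a$end_bp[i]) -
      pmax(b$start_bp[cand], a$start_bp[i]) + 1L
    la <- a$end_bp[i] - a$start_bp[i] + 1L
    lb <- b$end_bp[cand] - b$start_bp[cand] + 1L
    hit[i] <- any(ov >= overlap_frac * la & ov >= overlap_frac * lb)
  }
  hit
}

#' Recovery metrics of a pipeline run against simulation truth
#'
#' Compares the estimated case/control rate fold change with the
#' configured one, and scores the consensus and rarity stages against
#' the generating truth (restricted to samples that survived QC):
#' sensitivity (true calls recovered, by same-sample same-type
#' reciprocal-overlap matching) and precision, plus the rare/not-rare
#' confusion counts.
#'
#' @param sim a `cnv_sim` object from [simulate_cohort()].
#' @param pipeline result of [run_pipeline()] on the simulated files.
#' @return list of recovery metrics.
#' @export
recovery_report <- function(sim, pipeline) {
  stopifnot(inherits(sim, "cnv_sim"))
  kept <- pipeline$samples$sample_id
  tcalls <- sim$truth$calls[sim$truth$calls$sample_id %in% kept, ,
                            drop = FALSE]
  ccalls <- pipeline$consensus$calls
  sens <- if (nrow(tcalls)) mean(.has_match(tcalls, ccalls)) else NA_real_
  prec <- if (nrow(ccalls)) mean(.has_match(ccalls, tcalls)) else NA_real_
  # rarity confusion: truth rare status vs pipeline rare set
  truth_kept <- callset(tcalls, samples = kept,
                        provenance = "truth_postqc")
  truth_rare <- filter_rare(truth_kept)$calls
  pipe_rare <- pipeline$rare$calls
  conf <- c(
    true_rare_recovered = sum(.has_match(truth_rare, pipe_rare)),
    true_rare_total = nrow(truth_rare),
    called_rare_total = nrow(pipe_rare),
    called_rare_matching_truth = sum(.has_match(pipe_rare, truth_rare)))
  est_fold <- pipeline$burden$fold_change[
    pipeline$burden$cnv_type == "all" &
      pipeline$burden$genic_class == "all"][1]
  list(estimated_fold = est_fold,
       config_fold = sim$config$case_fold,
       fold_error = est_fold - sim$config$case_fold,
       empirical_p = pipeline$burden$empirical_p[
         pipeline$burden$cnv_type == "all" &
           pipeline$burden$genic_class == "all"][1],
       consensus_sensitivity = sens,
       consensus_precision = prec,
       rarity_confusion = conf)
}
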