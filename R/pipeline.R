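# End-to-end driver: caller files -> merge -> consensus -> sample QC ->
# CNV QC -> rarity -> annotation -> burden table.

#' Run the rare-CNV burden pipeline
#'
#' Reads the two caller files, merges adjacent same-state segments per
#' caller, intersects the callers into a consensus set, applies sample
#' QC (dropping excluded samples' calls), applies CNV QC (length, probe
#' count, Bayes factor), computes dataset-internal frequencies and
#' filters to rare calls, optionally annotates against gene models, and
#' computes the case-vs-control burden table (total / deletion /
#' duplication, crossed with genic class when annotation is available)
#' with permutation empirical p-values.
#'
#' @param penncnv_path,quantisnp_path caller output files.
#' @param samples_path sample metadata TSV (see [read_samples()]).
#' @param genes_path optional gene-model file for genic annotation.
#' @param genes_format `"refflat"` or `"bed12"`.
#' @param tolerance_bp consensus breakpoint tolerance.
#' @param min_length_bp,min_probes,min_bayes_factor CNV QC thresholds.
#' @param qc_thresholds sample-QC thresholds
#'   ([sample_qc_thresholds()]).
#' @param freq_threshold,overlap_frac rarity definition
#'   ([filter_rare()]).
#' @param flank_bp genic flank ([classify_genic()]).
#' @param n_perm,seed,alternative permutation settings
#'   ([permutation_test()]).
#' @return list with `samples` (kept), `excluded`, `consensus`, `rare`
#'   ([callset()]s), `annotated` (call table or NULL), `gene_sets`,
#'   `exclusive_case_genes`, and `burden` (data.frame of burden rows).
#' @export
run_pipeline <- function(penncnv_path, quantisnp_path, samples_path,
                         genes_path = NULL, genes_format = "refflat",
                         tolerance_bp = 0, min_length_bp = 10000,
                         min_probes = 10, min_bayes_factor = 10,
                         qc_thresholds = sample_qc_thresholds(),
                         freq_threshold = 0.005, overlap_frac = 0.5,
                         flank_bp = 10000, n_perm = 10000, seed = NULL,
                         alternative = "greater") {
  penn <- merge_adjacent(read_penncnv(penncnv_path))
  quanti <- merge_adjacent(read_quantisnp(quantisnp_path))
  samples <- read_samples(samples_path)
  # align the caller sample universes to the metadata table
  penn$samples <- quanti$samples <- samples$sample_id
  consensus <- intersect_callers(penn, quanti,
                                 tolerance_bp = tolerance_bp)
  qc <- apply_sample_qc(samples, consensus, thresholds = qc_thresholds)
  consensus <- filter_calls(qc$calls, min_length_bp = min_length_bp,
                            min_probes = min_probes,
                            min_bayes_factor = min_bayes_factor)
  rare <- filter_rare(consensus, freq_threshold = freq_threshold,
                      overlap_frac = overlap_frac)
  annotated <- NULL; gene_sets <- NULL; exclusive <- NULL
  if (!is.null(genes_path)) {
    genes <- read_gene_models(genes_path, format = genes_format)
    annotated <- classify_genic(rare, genes, flank_bp = flank_bp)
    gene_sets <- disrupted_gene_sets(annotated, qc$kept)
    if (all(c("case", "control") %in% names(gene_sets)))
      exclusive <- exclusive_genes(gene_sets$case, gene_sets$control)
  }
  cases <- qc$kept[qc$kept$phenotype == "case", , drop = FALSE]
  controls <- qc$kept[qc$kept$phenotype == "control", , drop = FALSE]
  tab <- if (!is.null(annotated)) annotated else rare$calls
  combos <- expand.grid(cnv_type = c("all", "deletion", "duplication"),
                        genic_class = if (!is.null(annotated))
                          c("all", "genic") else "all",
                        stringsAsFactors = FALSE)
  burden <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    burden_test(tab, cases, controls,
                statistic = "rate_per_sample",
                cnv_type = combos$cnv_type[i],
                genic_class = combos$genic_class[i],
                n_perm = n_perm,
                seed = if (is.null(seed)) NULL else seed + i,
                alternative = alternative)))
  list(samples = qc$kept, excluded = qc$excluded,
       consensus = consensus, rare = rare, annotated = annotated,
       gene_sets = gene_sets, exclusive_case_genes = exclusive,
       burden = burden)
}
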