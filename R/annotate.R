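# Genic / CDS classification of rare CNVs against gene models, and
# per-group disrupted-gene sets.

#' Collapse transcript models per gene symbol
#'
#' Isoforms of the same symbol (on the same chromosome) are collapsed to
#' one gene: the union of their transcript bounds and the union (merged)
#' of their CDS exons. Gene-level overlap counts genes, not transcripts.
#'
#' @param genes data.frame as returned by [read_gene_models()].
#' @return data.frame with one row per gene symbol per chromosome.
#' @export
collapse_gene_models <- function(genes) {
  stopifnot(is.data.frame(genes))
  if (nrow(genes) == 0L) return(genes)
  key <- paste(genes$symbol, genes$chrom, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(genes)), key), function(idx) {
    g <- genes[idx, , drop = FALSE]
    ex <- do.call(rbind, g$cds_exons)
    merged <- if (!is.null(ex) && nrow(ex)) {
      red <- IRanges::reduce(IRanges::IRanges(ex$start_bp, ex$end_bp))
      data.frame(start_bp = IRanges::start(red), end_bp = IRanges::end(red))
    } else data.frame(start_bp = integer(), end_bp = integer())
    out <- data.frame(gene_id = g$symbol[1], symbol = g$symbol[1],
                      chrom = g$chrom[1],
                      tx_start_bp = min(g$tx_start_bp),
                      tx_end_bp = max(g$tx_end_bp),
                      strand = g$strand[1], stringsAsFactors = FALSE)
    out$cds_exons <- list(merged)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(as.integer(out$chrom), out$tx_start_bp), , drop = FALSE]
}

#' Classify calls as genic / CDS-overlapping
#'
#' A call is *genic* when it overlaps, by at least 1 bp, the transcript
#' interval of any gene extended by `flank_bp` on either side (default
#' 10 kb); flank boundaries are inclusive, so a call ending exactly at
#' the flanked start touches the gene. A call is *CDS-overlapping* when
#' it overlaps any CDS exon (no flank), a stricter class: every CDS
#' call is genic. Isoforms are collapsed per symbol before flanking.
#'
#' @param cs a [callset()] (typically the rare set).
#' @param genes data.frame from [read_gene_models()].
#' @param flank_bp flank added to each transcript side for the genic
#'   test.
#' @return the call table with added columns `is_genic`, `is_cds`, and
#'   the list-column `genes_hit` (character vectors of gene ids).
#' @export
classify_genic <- function(cs, genes, flank_bp = 10000) {
  stopifnot(inherits(cs, "cnv_callset"))
  d <- cs$calls
  g <- collapse_gene_models(genes)
  d$is_genic <- logical(nrow(d))
  d$is_cds <- logical(nrow(d))
  d$genes_hit <- replicate(nrow(d), character(), simplify = FALSE)
  if (nrow(d) == 0L || nrow(g) == 0L) return(d)
  for (chr in intersect(unique(d$chrom), unique(g$chrom))) {
    ci <- which(d$chrom == chr)
    gi <- which(g$chrom == chr)
    ir_call <- IRanges::IRanges(d$start_bp[ci], d$end_bp[ci])
    ir_gene <- IRanges::IRanges(pmax(1L, g$tx_start_bp[gi] - flank_bp),
                                g$tx_end_bp[gi] + flank_bp)
    hits <- IRanges::findOverlaps(ir_call, ir_gene)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(q)) {
      for (k in unique(q)) {
        idx <- ci[k]
        d$genes_hit[[idx]] <- sort(g$gene_id[gi][s[q == k]])
      }
      d$is_genic[ci[unique(q)]] <- TRUE
    }
    # CDS exons, unflanked
    ex <- do.call(rbind, lapply(gi, function(j) g$cds_exons[[j]]))
    if (!is.null(ex) && nrow(ex)) {
      ir_cds <- IRanges::IRanges(ex$start_bp, ex$end_bp)
      ch <- IRanges::findOverlaps(ir_call, ir_cds)
      d$is_cds[ci[unique(S4Vectors::queryHits(ch))]] <- TRUE
    }
  }
  d
}

#' Disrupted-gene sets per group
#'
#' For each level of a grouping column in the sample table, returns the
#' union of `genes_hit` over that group's calls.
#'
#' @param annotated annotated call table from [classify_genic()].
#' @param samples sample data.frame; must contain `sample_id` and the
#'   grouping column.
#' @param group_by name of the grouping column (default `"phenotype"`;
#'   use `"site"` for colon/rectal strata).
#' @return named list of character gene-id vectors, one per group level.
#' @export
disrupted_gene_sets <- function(annotated, samples,
                                group_by = "phenotype") {
  stopifnot(group_by %in% names(samples))
  grp <- samples[[group_by]][match(annotated$sample_id,
                                   samples$sample_id)]
  levels <- sort(unique(stats::na.omit(samples[[group_by]])))
  out <- lapply(levels, function(lv) {
    hits <- annotated$genes_hit[!is.na(grp) & grp == lv]
    sort(unique(unlist(hits)))
  })
  names(out) <- levels
  out
}

#' Genes disrupted exclusively in one group
#'
#' Set difference: genes hit by the case group's rare CNVs but by none
#' of the control group's.
#'
#' @param case_set,control_set character vectors of gene ids.
#' @return character vector `case_set \ control_set`.
#' @export
exclusive_genes <- function(case_set, control_set) {
  sort(setdiff(case_set, control_set))
}
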