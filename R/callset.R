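#' cnvburden: rare CNV case-control burden analysis
#'
#' Tools for genome-wide rare copy-number variant (CNV) burden analysis in
#' case-control cohorts: two-caller consensus calling, sample and CNV quality
#' control, dataset-internal rarity filtering, genic annotation, permutation
#' burden tests with stratification, gene-set enrichment of case-exclusive
#' genes, delta-delta-Ct copy-number quantification, and a synthetic-cohort
#' simulator for validation.
#'
#' @keywords internal
"_PACKAGE"

# Internal data model -------------------------------------------------------
#
# A CNV call table is a data.frame with one call per row and the columns
# below. Coordinates are 1-based inclusive (the convention of the callers'
# region strings); BED input is converted on ingest.

CALL_COLUMNS <- c("sample_id", "chrom", "start_bp", "end_bp", "state",
                  "cnv_type", "n_probes", "length_bp", "caller",
                  "bayes_factor")

AUTOSOMES <- as.character(1:22)

#' Build a CNV call table
#'
#' Constructs and validates the canonical per-call data.frame used
#' throughout the pipeline. Copy-number state 2 (diploid) is rejected:
#' a CNV is a departure from the diploid state, so only states 0, 1
#' (deletions) and 3, 4 (duplications) are admissible. Only autosomes
#' ("1".."22") are allowed; burden analyses here are autosomal.
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome labels; a leading "chr" prefix is stripped.
#' @param start_bp,end_bp 1-based inclusive coordinates, `start_bp <= end_bp`.
#' @param state integer copy number in `{0, 1, 3, 4}`.
#' @param n_probes positive integer probe counts.
#' @param caller one of `"penncnv"`, `"quantisnp"`, `"consensus"`, `"truth"`.
#' @param bayes_factor per-call QuantiSNP log Bayes factor, `NA` if absent.
#' @return data.frame with columns sample_id, chrom, start_bp, end_bp,
#'   state, cnv_type, n_probes, length_bp, caller, bayes_factor.
#' @export
cnv_calls <- function(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      state = integer(), n_probes = integer(),
                      caller = character(), bayes_factor = NA_real_) {
  n <- length(sample_id)
  chrom <- sub("^chr", "", as.character(chrom))
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = chrom,
    start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp),
    state = as.integer(state),
    cnv_type = ifelse(as.integer(state) < 2L, "deletion", "duplication"),
    n_probes = as.integer(n_probes),
    length_bp = as.integer(end_bp) - as.integer(start_bp) + 1L,
    caller = rep_len(as.character(caller), n),
    bayes_factor = rep_len(as.numeric(bayes_factor), n),
    stringsAsFactors = FALSE
  )
  validate_calls(df)
  df
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls), all(CALL_COLUMNS %in% names(calls)))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad <- which(!(calls$chrom %in% AUTOSOMES))
  if (length(bad))
    stop("non-autosomal chromosome in call table (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  if (any(calls$state == 2L))
    stop("state 2 (diploid) is not a CNV call")
  if (!all(calls$state %in% c(0L, 1L, 3L, 4L)))
    stop("copy-number state must be in {0, 1, 3, 4}")
  if (any(calls$start_bp > calls$end_bp))
    stop("start_bp > end_bp in call table")
  if (any(calls$length_bp != calls$end_bp - calls$start_bp + 1L))
    stop("length_bp inconsistent with coordinates")
  if (any(calls$n_probes < 1L))
    stop("n_probes must be positive")
  invisible(calls)
}

#' Bundle CNV calls with their sample universe
#'
#' A call set carries the calls *and* the full set of samples the calling
#' was performed on (carriers and non-carriers alike): per-sample rates and
#' carrier frequencies need zero-call samples in their denominators.
#'
#' @param calls a call data.frame (see [cnv_calls()]).
#' @param samples character vector of all sample ids in the universe;
#'   defaults to the samples observed in `calls`.
#' @param provenance character vector describing the processing lineage.
#' @return an object of class `cnv_callset` with elements `calls`,
#'   `samples`, `provenance`.
#' @export
callset <- function(calls, samples = NULL, provenance = character()) {
  validate_calls(calls)
  if (is.null(samples)) samples <- unique(calls$sample_id)
  samples <- as.character(samples)
  if (!all(calls$sample_id %in% samples))
    stop("call table contains samples outside the declared sample universe: ",
         paste(utils::head(setdiff(calls$sample_id, samples), 5),
               collapse = ", "))
  structure(
    list(calls = sort_calls(calls), samples = samples,
         provenance = as.character(provenance)),
    class = "cnv_callset"
  )
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat("CNV call set: ", nrow(x$calls), " calls across ",
      length(x$samples), " samples\n", sep = "")
  if (nrow(x$calls)) {
    tab <- table(x$calls$cnv_type)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$provenance))
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n",
        sep = "")
  invisible(x)
}

# Deterministic order: sample, chromosome (numeric), start, end, state.
sort_calls <- function(calls) {
  ord <- order(calls$sample_id, as.integer(calls$chrom), calls$start_bp,
               calls$end_bp, calls$state)
  calls[ord, , drop = FALSE]
}

add_provenance <- function(cs, note) {
  cs$provenance <- c(cs$provenance, note)
  cs
}

empty_calls <- function() {
  cnv_calls()
}
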