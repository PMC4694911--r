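# Readers and writers for the external table dialects the pipeline touches.
# All coordinates are normalized to 1-based inclusive internally; BED and
# refFlat (0-based starts) are converted on ingest. Sex-chromosome rows are
# dropped with a logged count: all burden analyses here are autosomal.

#' Read a PennCNV-style call file
#'
#' Parses the whitespace-separated per-call output dialect of PennCNV:
#' one call per line, a `chrN:start-end` region string, `numsnp=` probe
#' count, `stateS,cn=C` copy-number field, and the sample identifier.
#' Trailing `key=value` fields (startsnp, endsnp, conf, length) are ignored.
#'
#' @param path path to the call file.
#' @return a [callset()]; the number of skipped non-autosomal rows is
#'   recorded in the provenance.
#' @export
read_penncnv <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(callset(empty_calls(), samples = character(),
                   provenance = paste0("read_penncnv:", path)))
  recs <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    region <- tok[1]
    m <- regmatches(region,
                    regexec("^(chr)?([0-9XYMxym]+):([0-9,]+)-([0-9,]+)$",
                            region))[[1]]
    if (length(m) == 0L)
      stop("read_penncnv: malformed region string on line ", i, ": ", region)
    chrom <- toupper(m[3])
    numsnp <- grep("^numsnp=", tok, value = TRUE)
    cnfield <- grep("^state[0-9]+,cn=[0-9]+$", tok, value = TRUE)
    if (!length(numsnp) || !length(cnfield))
      stop("read_penncnv: missing numsnp or state/cn field on line ", i)
    kv <- grepl("^(numsnp|length|startsnp|endsnp|conf)=|^state[0-9]+,cn=",
                tok[-1])
    sample <- tok[-1][!kv][1]
    if (is.na(sample))
      stop("read_penncnv: no sample identifier on line ", i)
    state <- as.integer(sub("^state[0-9]+,cn=", "", cnfield[1]))
    if (state == 2L)
      stop("read_penncnv: diploid state (cn=2) on line ", i,
           " is not a CNV call")
    if (!chrom %in% AUTOSOMES) {
      skipped <- skipped + 1L
      next
    }
    recs[[i]] <- data.frame(
      sample_id = sample, chrom = chrom,
      start_bp = as.integer(gsub(",", "", m[4])),
      end_bp = as.integer(gsub(",", "", m[5])),
      state = state,
      n_probes = as.integer(sub("^numsnp=", "", numsnp[1])),
      stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (skipped) message("read_penncnv: skipped ", skipped,
                       " non-autosomal call(s)")
  calls <- if (length(recs)) {
    d <- do.call(rbind, recs)
    cnv_calls(d$sample_id, d$chrom, d$start_bp, d$end_bp, d$state,
              d$n_probes, caller = "penncnv")
  } else empty_calls()
  callset(calls,
          provenance = c(paste0("read_penncnv:", path),
                         if (skipped) paste0("skipped_nonautosomal:", skipped)))
}

# Normalize a header name: lower-case, strip everything but letters/digits.
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.match_column <- function(headers, synonyms, what, required = TRUE) {
  idx <- which(headers %in% synonyms)
  if (!length(idx)) {
    if (required) stop("missing required column: ", what)
    return(NA_integer_)
  }
  idx[1]
}

#' Read a QuantiSNP-style call file
#'
#' Parses the tab-separated QuantiSNP output dialect (header row with
#' sample, chromosome, start/end position, probe count, copy number and
#' the per-call maximum log Bayes factor). Header names are matched
#' case- and punctuation-insensitively; unknown columns are ignored.
#' The Bayes-factor column is required because downstream CNV quality
#' control filters on it.
#'
#' @param path path to the call file.
#' @return a [callset()] with `bayes_factor` populated.
#' @export
read_quantisnp <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    return(callset(empty_calls(), samples = character(),
                   provenance = paste0("read_quantisnp:", path)))
  h <- .norm_header(names(d))
  col <- function(syn, what, required = TRUE)
    .match_column(h, syn, what, required)
  i_samp <- col(c("samplename", "sampleid", "sample"), "sample")
  i_chr  <- col(c("chromosome", "chrom", "chr"), "chromosome")
  i_sta  <- col(c("startpositionbp", "startposition", "start", "bp1"),
                "start position")
  i_end  <- col(c("endpositionbp", "endposition", "end", "bp2"),
                "end position")
  i_np   <- col(c("noprobes", "numprobes", "nprobes", "probes", "numsnp"),
                "probe count")
  i_cn   <- col(c("copynumber", "cn", "state"), "copy number")
  i_bf   <- col(c("maxlogbf", "maxbf", "logbf", "bayesfactor"),
                "Max. Log BF (required for CNV quality control)")
  chrom <- toupper(sub("^chr", "", as.character(d[[i_chr]])))
  keep <- chrom %in% AUTOSOMES
  skipped <- sum(!keep)
  if (skipped) message("read_quantisnp: skipped ", skipped,
                       " non-autosomal call(s)")
  d <- d[keep, , drop = FALSE]
  chrom <- chrom[keep]
  if (any(as.integer(d[[i_cn]]) == 2L))
    stop("read_quantisnp: diploid state (copy number 2) is not a CNV call")
  calls <- if (nrow(d)) {
    cnv_calls(d[[i_samp]], chrom, d[[i_sta]], d[[i_end]],
              as.integer(d[[i_cn]]), as.integer(d[[i_np]]),
              caller = "quantisnp", bayes_factor = as.numeric(d[[i_bf]]))
  } else empty_calls()
  dup <- sum(duplicated(calls[, c("sample_id", "chrom", "start_bp",
                                  "end_bp", "state")]))
  callset(calls,
          provenance = c(paste0("read_quantisnp:", path),
                         if (skipped) paste0("skipped_nonautosomal:", skipped),
                         if (dup) paste0("duplicate_rows:", dup)))
}

SITE_LEVELS <- c("colon", "rectal", "both", "none")

#' Read the sample metadata table
#'
#' Tab-separated table with one row per genotyped sample. Required
#' columns: `sample_id`, `phenotype` (case/control), `site`
#' (colon/rectal/both for cases, none for controls), `sex` (M/F), `age`,
#' `ms_status` (ms/non_ms/unknown; metabolic syndrome), and the
#' per-sample QC metrics `call_rate`, `lrr_sd`, `gcwf`,
#' `quantisnp_lrr_sd`, `cnv_count_raw`. Unknown extra columns are
#' ignored. A control annotated with a tumor site, or a case without
#' one, is an error, as is a missing age.
#'
#' @param path path to the TSV file.
#' @return data.frame of sample records.
#' @export
read_samples <- function(path) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "phenotype", "site", "sex", "age", "ms_status",
           "call_rate", "lrr_sd", "gcwf", "quantisnp_lrr_sd",
           "cnv_count_raw")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_samples: missing required column(s): ",
         paste(miss, collapse = ", "))
  d <- d[, req]
  d$sample_id <- as.character(d$sample_id)
  if (anyDuplicated(d$sample_id))
    stop("read_samples: duplicated sample_id")
  if (!all(d$phenotype %in% c("case", "control")))
    stop("read_samples: phenotype must be 'case' or 'control'")
  if (!all(d$site %in% SITE_LEVELS))
    stop("read_samples: site must be one of ",
         paste(SITE_LEVELS, collapse = "/"))
  bad_site <- (d$phenotype == "control") != (d$site == "none")
  if (any(bad_site))
    stop("read_samples: site must be 'none' for controls and a tumor site ",
         "for cases; offending sample(s): ",
         paste(utils::head(d$sample_id[bad_site], 5), collapse = ", "))
  if (!all(d$sex %in% c("M", "F")))
    stop("read_samples: sex must be 'M' or 'F'")
  age <- suppressWarnings(as.numeric(d$age))
  bad_age <- is.na(age) | age < 0
  if (any(bad_age))
    stop("read_samples: missing or negative age; record(s) rejected: ",
         paste(utils::head(d$sample_id[bad_age], 5), collapse = ", "))
  d$age <- age
  if (!all(d$ms_status %in% c("ms", "non_ms", "unknown")))
    stop("read_samples: ms_status must be ms/non_ms/unknown")
  for (m in c("call_rate", "lrr_sd", "gcwf", "quantisnp_lrr_sd"))
    d[[m]] <- suppressWarnings(as.numeric(d[[m]]))
  d$cnv_count_raw <- suppressWarnings(as.integer(d$cnv_count_raw))
  d
}

# Intersect a set of 1-based inclusive intervals with a single window.
.clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- s <= e
  data.frame(start_bp = s[keep], end_bp = e[keep])
}

#' Read gene models from BED12 or refFlat
#'
#' Converts the file's native coordinate convention (half-open 0-based
#' starts in both dialects) into 1-based inclusive transcript bounds,
#' and derives CDS exon intervals by intersecting the exon blocks with
#' the thick/CDS region. Non-coding transcripts (empty CDS region) get
#' zero CDS exons. Non-autosomal transcripts are skipped with a logged
#' count.
#'
#' @param path path to the annotation file.
#' @param format `"bed12"` or `"refflat"`.
#' @return data.frame with columns gene_id, symbol, chrom, tx_start_bp,
#'   tx_end_bp, strand, and a list-column `cds_exons` of per-transcript
#'   CDS-exon interval data.frames (1-based inclusive).
#' @export
read_gene_models <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (format == "bed12") {
    if (ncol(d) < 12) stop("read_gene_models: BED12 requires 12 columns")
    names(d)[1:12] <- c("chrom", "chromStart", "chromEnd", "name", "score",
                        "strand", "thickStart", "thickEnd", "itemRgb",
                        "blockCount", "blockSizes", "blockStarts")
    chrom <- sub("^chr", "", d$chrom)
    keep <- chrom %in% AUTOSOMES
    if (any(!keep)) message("read_gene_models: skipped ", sum(!keep),
                            " non-autosomal transcript(s)")
    d <- d[keep, , drop = FALSE]; chrom <- chrom[keep]
    cds <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      sizes <- as.integer(strsplit(d$blockSizes[i], ",")[[1]])
      offs <- as.integer(strsplit(d$blockStarts[i], ",")[[1]])
      bs <- d$chromStart[i] + offs + 1L       # 1-based inclusive
      be <- bs + sizes - 1L
      if (any(bs < d$chromStart[i] + 1L) || any(be > d$chromEnd[i]))
        stop("read_gene_models: block outside transcript bounds, line ", i)
      cds[[i]] <- .clip_intervals(bs, be, d$thickStart[i] + 1L,
                                  d$thickEnd[i])
    }
    out <- data.frame(gene_id = d$name, symbol = d$name, chrom = chrom,
                      tx_start_bp = d$chromStart + 1L,
                      tx_end_bp = d$chromEnd, strand = d$strand,
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(d) < 11) stop("read_gene_models: refFlat requires 11 columns")
    names(d)[1:11] <- c("geneName", "name", "chrom", "strand", "txStart",
                        "txEnd", "cdsStart", "cdsEnd", "exonCount",
                        "exonStarts", "exonEnds")
    chrom <- sub("^chr", "", d$chrom)
    keep <- chrom %in% AUTOSOMES
    if (any(!keep)) message("read_gene_models: skipped ", sum(!keep),
                            " non-autosomal transcript(s)")
    d <- d[keep, , drop = FALSE]; chrom <- chrom[keep]
    cds <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      es <- as.integer(strsplit(d$exonStarts[i], ",")[[1]]) + 1L
      ee <- as.integer(strsplit(d$exonEnds[i], ",")[[1]])
      if (any(es < d$txStart[i] + 1L) || any(ee > d$txEnd[i]))
        stop("read_gene_models: exon outside transcript bounds, line ", i)
      cds[[i]] <- .clip_intervals(es, ee, d$cdsStart[i] + 1L, d$cdsEnd[i])
    }
    out <- data.frame(gene_id = d$name, symbol = d$geneName, chrom = chrom,
                      tx_start_bp = d$txStart + 1L,
                      tx_end_bp = d$txEnd, strand = d$strand,
                      stringsAsFactors = FALSE)
  }
  out$cds_exons <- cds
  out
}

#' Write a call set as a PLINK-style .cnv table
#'
#' Tab-separated with columns FID, IID, CHR, BP1, BP2, TYPE (copy-number
#' state), SCORE (Bayes factor), SITES (probe count), plus CALLER so
#' that a round trip through [read_cnv_table()] reproduces the calls
#' field-exactly.
#'
#' @param cs a [callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cs, path) {
  stopifnot(inherits(cs, "cnv_callset"))
  d <- cs$calls
  out <- data.frame(FID = d$sample_id, IID = d$sample_id, CHR = d$chrom,
                    BP1 = d$start_bp, BP2 = d$end_bp, TYPE = d$state,
                    SCORE = d$bayes_factor, SITES = d$n_probes,
                    CALLER = d$caller, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PLINK-style .cnv table written by [write_cnv_table()]
#'
#' @param path path to the table.
#' @param samples optional character vector giving the full sample
#'   universe (PLINK keeps it in a separate .fam file); defaults to the
#'   samples present in the table.
#' @return a [callset()].
#' @export
read_cnv_table <- function(path, samples = NULL) {
  stopifnot(file.exists(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("IID", "CHR", "BP1", "BP2", "TYPE", "SCORE", "SITES")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_cnv_table: missing column(s): ", paste(miss, collapse = ", "))
  caller <- if ("CALLER" %in% names(d)) d$CALLER else "consensus"
  calls <- if (nrow(d)) {
    cnv_calls(d$IID, d$CHR, d$BP1, d$BP2, as.integer(d$TYPE),
              as.integer(d$SITES), caller = caller,
              bayes_factor = as.numeric(d$SCORE))
  } else empty_calls()
  callset(calls, samples = samples,
          provenance = paste0("read_cnv_table:", path))
}

#' Read gene-set definitions from a GMT file
#'
#' One set per line: term id, description, then member gene ids,
#' tab-separated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids; term
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (ln in lines) {
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 2) stop("read_gmt: malformed line (need id + description)")
    genes <- unique(tok[-(1:2)])
    sets[[tok[1]]] <- genes[nzchar(genes)]
    descs[tok[1]] <- tok[2]
  }
  attr(sets, "description") <- descs
  sets
}
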