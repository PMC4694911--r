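# Over-representation testing of disrupted-gene sets against GMT
# collections: hypergeometric upper tail, with DAVID's conservative
# EASE variant, and Bonferroni correction.

#' Gene-set over-representation test
#'
#' For each term, computes the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when `query_size` genes are
#' sampled without replacement from the background with `term_size`
#' genes marked. `mode = "ease"` is the conservative EASE variant:
#' one member is removed from the overlap (`max(overlap - 1, 0)`)
#' before the tail is computed, penalising terms supported by a single
#' gene. Terms are intersected with the background before testing;
#' terms with no background member are dropped. Bonferroni correction
#' multiplies by the number of terms actually tested with non-zero
#' overlap.
#'
#' @param query character vector of gene ids (must lie in `background`).
#' @param terms named list of gene-id vectors (see [read_gmt()]).
#' @param background character vector: the gene universe (e.g. all
#'   genes in the annotation).
#' @param mode `"fisher"` (plain hypergeometric tail) or `"ease"`.
#' @return data.frame sorted by p-value with columns `term_id`,
#'   `term_name`, `overlap_count`, `term_size`, `query_size`,
#'   `background_size`, `percent` (overlap as % of term size),
#'   `p_value`, `bonferroni_p`.
#' @export
enrichment_test <- function(query, terms, background,
                            mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  off <- setdiff(query, background)
  if (length(off))
    stop("enrichment_test: query genes absent from background: ",
         paste(utils::head(off, 10), collapse = ", "))
  N <- length(background)
  n_query <- length(query)
  descs <- attr(terms, "description")
  rows <- lapply(names(terms), function(id) {
    term <- intersect(unique(terms[[id]]), background)
    K <- length(term)
    if (K == 0L) return(NULL)
    k <- length(intersect(term, query))
    k_eff <- if (mode == "ease") max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1L, K, N - K, n_query,
                       lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = if (!is.null(descs) && id %in% names(descs))
                 descs[[id]] else id,
               overlap_count = k, term_size = K, query_size = n_query,
               background_size = N, percent = 100 * k / K,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), term_name = character(),
                      overlap_count = integer(), term_size = integer(),
                      query_size = integer(),
                      background_size = integer(), percent = numeric(),
                      p_value = numeric(), bonferroni_p = numeric(),
                      stringsAsFactors = FALSE))
  m <- sum(out$overlap_count >= 1L)
  out$bonferroni_p <- pmin(1, out$p_value * max(m, 1L))
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
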