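# Burden statistics, fold changes, permutation empirical p-values, and
# stratified comparisons.

BURDEN_STATISTICS <- c("rate_per_sample", "proportion_ge1",
                       "total_kb_per_sample", "avg_kb_per_sample")

# Run code with a temporary RNG state seeded at `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Subset a (possibly annotated) call table by deletion/duplication type
# and genic class.
.filter_class <- function(d, cnv_type = "all", genic_class = "all") {
  cnv_type <- match.arg(cnv_type, c("all", "deletion", "duplication"))
  genic_class <- match.arg(genic_class, c("all", "genic", "nongenic", "cds"))
  if (cnv_type != "all") d <- d[d$cnv_type == cnv_type, , drop = FALSE]
  if (genic_class != "all") {
    if (!all(c("is_genic", "is_cds") %in% names(d)))
      stop("genic class filter requires an annotated call table ",
           "(run classify_genic first)")
    d <- switch(genic_class,
                genic = d[d$is_genic, , drop = FALSE],
                nongenic = d[!d$is_genic, , drop = FALSE],
                cds = d[d$is_cds, , drop = FALSE])
  }
  d
}

# Per-sample scalar underlying a burden statistic, over a fixed sample
# universe (zero-call samples get 0).
per_sample_scalar <- function(d, sample_ids, statistic) {
  statistic <- match.arg(statistic, BURDEN_STATISTICS)
  idx <- factor(d$sample_id, levels = sample_ids)
  switch(statistic,
         rate_per_sample = as.numeric(table(idx)),
         proportion_ge1 = as.numeric(table(idx) >= 1L),
         total_kb_per_sample = ,
         avg_kb_per_sample = as.numeric(tapply(d$length_bp / 1000, idx,
                                               sum, default = 0)))
}

# Group summary of a per-sample scalar. avg_kb averages over carriers
# (samples with >=1 matching call) only.
.group_value <- function(x, statistic) {
  if (statistic == "avg_kb_per_sample") {
    if (!any(x > 0)) return(NA_real_)
    mean(x[x > 0])
  } else mean(x)
}

#' Per-group burden statistics
#'
#' Computes, for each level of a grouping column, the per-sample rate of
#' matching calls (zero-call samples count in the denominator), the
#' proportion of samples with at least one matching call, the mean
#' total span in kb per sample, and the mean span among carriers.
#'
#' @param calls a [callset()] or a (possibly annotated) call table.
#' @param samples sample data.frame with `sample_id` and the grouping
#'   column; every group must be non-empty.
#' @param group_by grouping column name (default `"phenotype"`).
#' @param cnv_type `"all"`, `"deletion"` or `"duplication"`.
#' @param genic_class `"all"`, `"genic"`, `"nongenic"` or `"cds"`
#'   (needs [classify_genic()] columns).
#' @return data.frame, one row per group, with columns `group`,
#'   `n_samples`, `n_calls`, and the four statistics.
#' @export
burden_statistics <- function(calls, samples, group_by = "phenotype",
                              cnv_type = "all", genic_class = "all") {
  d <- if (inherits(calls, "cnv_callset")) calls$calls else calls
  stopifnot(group_by %in% names(samples))
  d <- .filter_class(d, cnv_type, genic_class)
  d <- d[d$sample_id %in% samples$sample_id, , drop = FALSE]
  if (nrow(samples) == 0L) stop("burden_statistics: empty group")
  levels <- sort(unique(samples[[group_by]]))
  rows <- lapply(levels, function(lv) {
    ids <- samples$sample_id[samples[[group_by]] == lv]
    if (!length(ids)) stop("burden_statistics: empty group ", lv)
    cnt <- per_sample_scalar(d[d$sample_id %in% ids, , drop = FALSE],
                             ids, "rate_per_sample")
    kb <- per_sample_scalar(d[d$sample_id %in% ids, , drop = FALSE],
                            ids, "total_kb_per_sample")
    data.frame(group = lv, n_samples = length(ids), n_calls = sum(cnt),
               rate_per_sample = mean(cnt),
               proportion_ge1 = mean(cnt >= 1),
               total_kb_per_sample = mean(kb),
               avg_kb_per_sample = if (any(kb > 0)) mean(kb[kb > 0])
                                   else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fold change between two group values
#'
#' Ratio `a / b` computed on unrounded values; `NA` when the
#' denominator is zero (undefined).
#'
#' @param a,b non-negative group statistics (e.g. per-sample rates).
#' @return `a / b`, or `NA_real_` if `b == 0`.
#' @export
fold_change <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  if (b == 0) return(NA_real_)
  a / b
}

#' Label-permutation empirical p-value
#'
#' Compares the between-group difference of a per-sample statistic with
#' its permutation distribution under random reassignment of group
#' labels (group sizes held fixed). The Monte-Carlo estimate is
#' `p = (r + 1) / (n_perm + 1)` with `r` the number of permutations
#' whose difference is at least the observed one (one-sided,
#' `alternative = "greater"`: group A exceeds group B). When the number
#' of distinct label assignments `choose(n, n_A)` is at most
#' `exhaustive_limit`, all assignments are enumerated instead and the
#' exact proportion returned. Reproducible given `seed`.
#'
#' @param x numeric per-sample statistic (e.g. rare-CNV count).
#' @param is_case logical; TRUE marks group A (cases).
#' @param n_perm number of Monte-Carlo permutations (>= 1).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param group_stat function reducing a group's per-sample values to a
#'   scalar (default `mean`); the test statistic is
#'   `group_stat(x[A]) - group_stat(x[B])`.
#' @param exhaustive_limit enumerate exactly when the assignment count
#'   does not exceed this (default 20000); set to 0 to force Monte
#'   Carlo.
#' @return list with `p_value`, `observed` difference, `method`
#'   (`"exhaustive"` or `"monte_carlo"`), `n_perm`, `seed`,
#'   `alternative`.
#' @export
permutation_test <- function(x, is_case, n_perm = 10000, seed = NULL,
                             alternative = c("greater", "less",
                                             "two.sided"),
                             group_stat = NULL,
                             exhaustive_limit = 20000) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), length(x) == length(is_case))
  is_case <- as.logical(is_case)
  if (anyNA(x) || anyNA(is_case)) stop("permutation_test: NA input")
  n <- length(x); n1 <- sum(is_case); n2 <- n - n1
  if (n1 == 0L || n2 == 0L) stop("permutation_test: empty group")
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1")
  simple <- is.null(group_stat)
  gstat <- if (simple) mean else group_stat
  obs <- gstat(x[is_case]) - gstat(x[!is_case])
  tol <- 1e-9 * max(1, abs(obs))
  exceeds <- switch(alternative,
                    greater = function(d) d >= obs - tol,
                    less = function(d) d <= obs + tol,
                    two.sided = function(d) abs(d) >= abs(obs) - tol)
  n_comb <- suppressWarnings(choose(n, n1))
  if (is.finite(n_comb) && n_comb <= exhaustive_limit) {
    splits <- utils::combn(n, n1)
    diffs <- apply(splits, 2, function(idx)
      gstat(x[idx]) - gstat(x[-idx]))
    return(list(p_value = mean(exceeds(diffs)), observed = obs,
                method = "exhaustive", n_perm = ncol(splits),
                seed = seed, alternative = alternative))
  }
  diffs <- with_seed(seed, {
    if (simple) {
      S <- sum(x)
      vapply(seq_len(n_perm), function(i) {
        s1 <- sum(x[sample.int(n, n1)])
        s1 / n1 - (S - s1) / n2
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, n1)
        gstat(x[idx]) - gstat(x[-idx])
      }, numeric(1))
    }
  })
  r <- sum(exceeds(diffs))
  list(p_value = (r + 1) / (n_perm + 1), observed = obs,
       method = "monte_carlo", n_perm = n_perm, seed = seed,
       alternative = alternative)
}

#' One burden comparison between two groups
#'
#' Computes a burden statistic in two groups of samples, their fold
#' change (group A over group B, on unrounded values), and a
#' permutation empirical p-value.
#'
#' @param calls a [callset()] or (annotated) call table.
#' @param samples_a,samples_b sample data.frames for the two groups.
#' @param statistic one of `"rate_per_sample"`, `"proportion_ge1"`,
#'   `"total_kb_per_sample"`, `"avg_kb_per_sample"`.
#' @param cnv_type,genic_class class filters, see [burden_statistics()].
#' @param n_perm,seed,alternative passed to [permutation_test()].
#' @param label_a,label_b group labels for the report.
#' @return one-row data.frame (a burden result): labels, group sizes,
#'   group values, `fold_change`, `empirical_p`, `n_perm`, `method`,
#'   `seed`.
#' @export
burden_test <- function(calls, samples_a, samples_b,
                        statistic = "rate_per_sample",
                        cnv_type = "all", genic_class = "all",
                        n_perm = 10000, seed = NULL,
                        alternative = "greater",
                        label_a = "case", label_b = "control") {
  statistic <- match.arg(statistic, BURDEN_STATISTICS)
  d <- if (inherits(calls, "cnv_callset")) calls$calls else calls
  d <- .filter_class(d, cnv_type, genic_class)
  ids_a <- samples_a$sample_id; ids_b <- samples_b$sample_id
  if (!length(ids_a) || !length(ids_b))
    stop("burden_test: empty group")
  base_stat <- if (statistic == "avg_kb_per_sample")
    "total_kb_per_sample" else statistic
  x <- per_sample_scalar(d[d$sample_id %in% c(ids_a, ids_b), ,
                           drop = FALSE],
                         c(ids_a, ids_b), base_stat)
  is_case <- c(rep(TRUE, length(ids_a)), rep(FALSE, length(ids_b)))
  gstat <- if (statistic == "avg_kb_per_sample")
    function(v) if (any(v > 0)) mean(v[v > 0]) else 0
  else NULL
  va <- .group_value(x[is_case], statistic)
  vb <- .group_value(x[!is_case], statistic)
  pt <- permutation_test(x, is_case, n_perm = n_perm, seed = seed,
                         alternative = alternative, group_stat = gstat)
  data.frame(group_a = label_a, group_b = label_b,
             statistic = statistic, cnv_type = cnv_type,
             genic_class = genic_class,
             n_a = length(ids_a), n_b = length(ids_b),
             group_a_value = va, group_b_value = vb,
             fold_change = fold_change(va, vb),
             empirical_p = pt$p_value, n_perm = pt$n_perm,
             method = pt$method,
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}

#' Age tertile assignment
#'
#' Splits ages into three groups at the tertile boundaries of the
#' supplied distribution (the values at ranks `ceiling(n/3)` and
#' `ceiling(2n/3)` of the sorted ages). Ties at a boundary go to the
#' lower tertile.
#'
#' @param ages numeric vector.
#' @return integer vector of tertiles (1 = youngest); boundaries in
#'   `attr(, "boundaries")`.
#' @export
assign_age_tertiles <- function(ages) {
  stopifnot(is.numeric(ages), !anyNA(ages), length(ages) >= 3)
  s <- sort(ages)
  n <- length(s)
  b <- c(s[ceiling(n / 3)], s[ceiling(2 * n / 3)])
  tert <- 1L + (ages > b[1]) + (ages > b[2])
  attr(tert, "boundaries") <- b
  tert
}

#' Stratified burden comparisons
#'
#' Runs the burden comparison across the strata reported in
#' case-control CNV studies:
#' * `site`: each tumor-site stratum of the cases vs all controls;
#' * `sex`: males vs females within cases and within controls;
#' * `age_tertile`: case age tertiles (cut points from the case age
#'   distribution) vs all controls, plus the within-case contrasts
#'   T1 vs T3, T2 vs T3 and T1 vs T2;
#' * `age_decade`: cases vs controls within decade-of-age bins
#'   (boundaries at 50, 60, 70, 80 years);
#' * `ms_excluded`: all cases vs controls without metabolic syndrome.
#'
#' @param calls a [callset()] or (annotated) call table of rare CNVs.
#' @param samples post-QC sample data.frame.
#' @param strata character vector of strata to run (default all five).
#' @param statistic,cnv_type,genic_class,n_perm,seed,alternative passed
#'   to [burden_test()]; stratum seeds are derived deterministically
#'   from `seed`.
#' @return data.frame of burden-result rows with a `stratum` column.
#' @export
stratified_burden <- function(calls, samples,
                              strata = c("site", "sex", "age_tertile",
                                         "age_decade", "ms_excluded"),
                              statistic = "rate_per_sample",
                              cnv_type = "all", genic_class = "all",
                              n_perm = 10000, seed = NULL,
                              alternative = "greater") {
  strata <- match.arg(strata, several.ok = TRUE)
  cases <- samples[samples$phenotype == "case", , drop = FALSE]
  controls <- samples[samples$phenotype == "control", , drop = FALSE]
  out <- list()
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    if (is.null(seed)) NULL else (seed + 1000L * k) %% .Machine$integer.max
  }
  run <- function(a, b, la, lb, stratum) {
    res <- burden_test(calls, a, b, statistic = statistic,
                       cnv_type = cnv_type, genic_class = genic_class,
                       n_perm = n_perm, seed = next_seed(),
                       alternative = alternative,
                       label_a = la, label_b = lb)
    cbind(stratum = stratum, res, stringsAsFactors = FALSE)
  }
  if ("site" %in% strata) {
    for (st in intersect(c("colon", "rectal", "both"),
                         unique(cases$site))) {
      a <- cases[cases$site == st, , drop = FALSE]
      out <- c(out, list(run(a, controls, st, "control", "site")))
    }
  }
  if ("sex" %in% strata) {
    for (ph in c("case", "control")) {
      g <- samples[samples$phenotype == ph, , drop = FALSE]
      if (length(unique(g$sex)) == 2L)
        out <- c(out, list(run(g[g$sex == "M", , drop = FALSE],
                               g[g$sex == "F", , drop = FALSE],
                               paste0(ph, ":M"), paste0(ph, ":F"),
                               "sex")))
    }
  }
  if ("age_tertile" %in% strata && nrow(cases) >= 3) {
    tert <- assign_age_tertiles(cases$age)
    tg <- lapply(1:3, function(t) cases[tert == t, , drop = FALSE])
    for (t in 1:3)
      if (nrow(tg[[t]]))
        out <- c(out, list(run(tg[[t]], controls, paste0("T", t),
                               "control", "age_tertile")))
    for (pair in list(c(1, 3), c(2, 3), c(1, 2)))
      if (nrow(tg[[pair[1]]]) && nrow(tg[[pair[2]]]))
        out <- c(out, list(run(tg[[pair[1]]], tg[[pair[2]]],
                               paste0("T", pair[1]),
                               paste0("T", pair[2]), "age_tertile")))
  }
  if ("age_decade" %in% strata) {
    breaks <- c(-Inf, 50, 60, 70, 80, Inf)
    labs <- c("<=50", "51-60", "61-70", "71-80", ">80")
    dc <- cut(cases$age, breaks, labels = labs)
    dk <- cut(controls$age, breaks, labels = labs)
    for (b in labs) {
      a <- cases[!is.na(dc) & dc == b, , drop = FALSE]
      g <- controls[!is.na(dk) & dk == b, , drop = FALSE]
      if (nrow(a) && nrow(g))
        out <- c(out, list(run(a, g, paste0("case:", b),
                               paste0("control:", b), "age_decade")))
    }
  }
  if ("ms_excluded" %in% strata) {
    nonms <- controls[controls$ms_status != "ms", , drop = FALSE]
    if (nrow(nonms))
      out <- c(out, list(run(cases, nonms, "case", "non_ms_control",
                             "ms_excluded")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
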