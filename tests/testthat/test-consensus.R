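test_that("adjacent same-state calls merge by the half-length gap rule", {
  # gap 999 < 0.5*(4001+3001) = 3501 -> merged
  cs <- callset(mk_calls(c(1000L, 6000L), c(5000L, 9000L),
                         n_probes = c(5L, 7L), bf = c(12, 30)))
  m <- merge_adjacent(cs)
  expect_equal(nrow(m$calls), 1L)
  expect_equal(m$calls$start_bp, 1000L)
  expect_equal(m$calls$end_bp, 9000L)
  expect_equal(m$calls$n_probes, 12L)
  expect_equal(m$calls$bayes_factor, 30)

  # gap 7999 >= 0.5*(1001+1001) = 1001 -> not merged
  cs2 <- callset(mk_calls(c(1000L, 10000L), c(2000L, 11000L)))
  expect_equal(nrow(merge_adjacent(cs2)$calls), 2L)

  # single call unchanged
  cs3 <- callset(mk_calls(1000L, 9000L))
  expect_equal(merge_adjacent(cs3)$calls, cs3$calls)
})

test_that("merging uses the grown segment and same-state overlaps merge", {
  # chain: after [1000,5000]+[6000,9000] -> [1000,9000], the 8001 bp
  # segment reaches [12000,13000] (gap 2999 < 0.5*(8001+1001))
  cs <- callset(mk_calls(c(1000L, 6000L, 12000L),
                         c(5000L, 9000L, 13000L)))
  m <- merge_adjacent(cs)
  expect_equal(nrow(m$calls), 1L)
  expect_equal(m$calls$end_bp, 13000L)

  # overlapping same-state calls merge unconditionally
  ov <- callset(mk_calls(c(1000L, 2000L), c(5000L, 8000L)))
  expect_equal(nrow(merge_adjacent(ov)$calls), 1L)

  # overlapping different states are inconsistent input
  bad <- callset(mk_calls(c(1000L, 2000L), c(5000L, 8000L),
                          state = c(1L, 3L)))
  expect_error(merge_adjacent(bad), "different states")
})

test_that("merge is idempotent and matches the brute-force oracle", {
  withr::local_seed(23)
  for (rep in 1:200) {
    n <- sample.int(20, 1)
    starts <- sort(sample.int(2e5, n))
    df <- mk_calls(starts, starts + sample.int(3e4, n),
                   n_probes = sample.int(30, n, replace = TRUE),
                   bf = round(stats::runif(n, 5, 40), 2))
    cs <- callset(df)
    m1 <- merge_adjacent(cs)
    m2 <- merge_adjacent(m1)
    expect_equal(m2$calls, m1$calls, ignore_attr = TRUE)
    oracle <- brute_merge(df)
    expect_equal(m1$calls$start_bp, oracle$start_bp)
    expect_equal(m1$calls$end_bp, oracle$end_bp)
    expect_equal(m1$calls$n_probes, oracle$n_probes)
    expect_equal(m1$calls$bayes_factor, oracle$bayes_factor)
  }
})

test_that("consensus requires matching sample, state and breakpoints", {
  a <- callset(mk_calls(c(1000L, 20000L), c(9000L, 30000L),
                        state = c(1L, 3L), caller = "penncnv", bf = NA),
               samples = c("s1", "s2"))
  b <- callset(mk_calls(c(1000L, 20001L), c(9000L, 30000L),
                        state = c(1L, 3L), caller = "quantisnp",
                        bf = c(15, 18)),
               samples = c("s1", "s2"))
  cons <- intersect_callers(a, b)
  # identical first call retained, 1 bp start offset dropped at tol 0
  expect_equal(nrow(cons$calls), 1L)
  expect_equal(cons$calls$start_bp, 1000L)
  expect_equal(cons$calls$caller, "consensus")
  expect_equal(cons$calls$bayes_factor, 15)  # from the b member

  # with 1 bp tolerance the second call comes back
  expect_equal(nrow(intersect_callers(a, b, tolerance_bp = 1)$calls), 2L)

  # same coordinates but different state never match
  b2 <- callset(mk_calls(1000L, 9000L, state = 3L, bf = 15),
                samples = c("s1", "s2"))
  a2 <- callset(mk_calls(1000L, 9000L, state = 1L, bf = NA,
                         caller = "penncnv"),
                samples = c("s1", "s2"))
  expect_equal(nrow(intersect_callers(a2, b2)$calls), 0L)
})

test_that("consensus output is a subset of a with witnesses in b", {
  withr::local_seed(31)
  for (rep in 1:25) {
    n <- sample.int(15, 1)
    starts <- sort(sample.int(5e5, n)) * 10L
    base <- mk_calls(starts, starts + 20000L,
                     state = sample(c(1L, 3L), n, replace = TRUE),
                     bf = round(stats::runif(n, 11, 40), 2))
    keep_b <- stats::runif(n) < 0.7
    b <- callset(base[keep_b, , drop = FALSE], samples = "s1")
    a <- callset(base, samples = "s1")
    a$calls$bayes_factor <- NA_real_
    cons <- intersect_callers(a, b)
    expect_lte(nrow(cons$calls), min(nrow(a$calls), nrow(b$calls)))
    key <- function(d) paste(d$sample_id, d$chrom, d$start_bp,
                             d$end_bp, d$state)
    expect_true(all(key(cons$calls) %in% key(a$calls)))
    expect_true(all(key(cons$calls) %in% key(b$calls)))
  }
})

test_that("consensus rejects asymmetric sample universes", {
  a <- callset(mk_calls(1000L, 9000L), samples = c("s1", "s2"))
  b <- callset(mk_calls(1000L, 9000L), samples = c("s1", "s3"))
  expect_error(intersect_callers(a, b), "s2.*s3|s3.*s2")
})

test_that("CNV QC applies strict length, probe, and Bayes-factor rules", {
  cs <- callset(cnv_calls(
    sample_id = c("s1", "s2", "s3", "s4", "s5"),
    chrom = "1",
    start_bp = c(1000L, 1000L, 1000L, 1000L, 1000L),
    end_bp = c(10499L, 13000L, 13000L, 13000L, 13000L),
    state = 1L,
    n_probes = c(15L, 9L, 10L, 10L, 10L),
    caller = "consensus",
    bayes_factor = c(20, 20, 10.0, 10.01, NA)))
  kept <- filter_calls(cs)
  # 9.5 kb fails length; 9 probes fails span; BF 10.0 fails strict >10;
  # missing BF fails; only BF 10.01 passes
  expect_equal(kept$calls$sample_id, "s4")

  # exactly 10 kb + 1 bp passes the strict > 10 kb rule
  edge <- callset(cnv_calls("s1", "1", 1000L, 11000L, 1L, 12L,
                            "consensus", 11))
  expect_equal(nrow(filter_calls(edge)$calls), 1L)
  expect_equal(nrow(filter_calls(callset(cnv_calls(
    "s1", "1", 1000L, 10999L, 1L, 12L, "consensus", 11)))$calls), 0L)
})

test_that("relaxing any QC threshold never drops a previously kept call", {
  withr::local_seed(7)
  n <- 200
  starts <- sample.int(1e6, n)
  cs <- callset(cnv_calls(
    sample_id = sprintf("m%02d", sample.int(30, n, replace = TRUE)),
    chrom = as.character(sample.int(22, n, replace = TRUE)),
    start_bp = starts, end_bp = starts + sample.int(3e4, n),
    state = sample(c(1L, 3L), n, replace = TRUE),
    n_probes = sample.int(25, n, replace = TRUE),
    caller = "consensus",
    bayes_factor = stats::runif(n, 0, 30)))
  strict <- filter_calls(cs)$calls
  for (relaxed in list(
    filter_calls(cs, min_length_bp = 5000)$calls,
    filter_calls(cs, min_probes = 5)$calls,
    filter_calls(cs, min_bayes_factor = 5)$calls)) {
    key <- function(d) paste(d$sample_id, d$chrom, d$start_bp, d$end_bp)
    expect_true(all(key(strict) %in% key(relaxed)))
  }
})
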