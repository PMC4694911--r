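# Distribute k calls round-robin over the given sample ids, with fixed
# type/genic attributes, for burden arithmetic checks.
spread_calls <- function(ids, k, cnv_type = "deletion",
                         is_genic = FALSE, offset = 0L) {
  if (k == 0L) return(NULL)
  who <- rep_len(ids, k)
  start <- 1000L + 50000L * (seq_len(k) %/% length(ids)) + offset
  d <- cnv_calls(who, "1", start, start + 20000L,
                 if (cnv_type == "deletion") 1L else 3L,
                 12L, "consensus", 15)
  d$is_genic <- is_genic
  d$is_cds <- FALSE
  d
}

test_that("per-sample rate and carrier proportion count zero-call samples", {
  s <- mk_samples(3, 3)
  cases <- s$sample_id[1:3]
  # 0/1/2 calls across the three cases
  d <- rbind(spread_calls(cases[2], 1),
             spread_calls(cases[3], 2, offset = 4L))
  b <- burden_statistics(callset(d, samples = s$sample_id), s)
  ca <- b[b$group == "case", ]
  expect_equal(ca$rate_per_sample, 1.0)
  expect_equal(ca$proportion_ge1, 2 / 3)
  expect_equal(ca$n_calls, 3)
  co <- b[b$group == "control", ]
  expect_equal(co$rate_per_sample, 0)
  expect_equal(co$proportion_ge1, 0)
  # empty group errors
  expect_error(burden_statistics(callset(d, samples = s$sample_id),
                                 s[0, ]), "group|empty")
})

test_that("kb statistics average over all samples vs carriers", {
  s <- mk_samples(2, 2)
  d <- spread_calls(s$sample_id[1], 2, offset = 8L)  # two 20,001 bp calls
  b <- burden_statistics(callset(d, samples = s$sample_id), s)
  ca <- b[b$group == "case", ]
  expect_equal(ca$total_kb_per_sample, 2 * 20.001 / 2)  # over both cases
  expect_equal(ca$avg_kb_per_sample, 2 * 20.001)        # carrier only
  expect_true(is.na(b$avg_kb_per_sample[b$group == "control"]))
})

test_that("fold change is a ratio of unrounded values with inverse symmetry", {
  expect_equal(round(fold_change(1471 / 694, 2275 / 1641), 2), 1.53)
  expect_equal(round(fold_change(887 / 694, 1271 / 1641), 2), 1.65)
  expect_equal(fold_change(2, 2), 1)
  expect_true(is.na(fold_change(1, 0)))
  withr::local_seed(3)
  for (i in 1:20) {
    a <- stats::runif(1, 0.1, 5); b <- stats::runif(1, 0.1, 5)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1)
  }
})

test_that("exhaustive permutation enumerates label splits exactly", {
  # 2 cases {2,2} vs 2 controls {0,0}: of the C(4,2)=6 splits only the
  # identity attains a difference >= 2 -> p = 1/6
  pt <- permutation_test(c(2, 2, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pt$method, "exhaustive")
  expect_equal(pt$p_value, 1 / 6)
  # reversed labels: every split is >= the observed -2 difference
  expect_equal(permutation_test(c(0, 0, 2, 2),
                                c(TRUE, TRUE, FALSE, FALSE))$p_value, 1)
  # constant statistic -> p = 1
  expect_equal(permutation_test(rep(3, 10),
                                rep(c(TRUE, FALSE), 5))$p_value, 1)
})

test_that("Monte-Carlo permutation is deterministic given a seed", {
  withr::local_seed(99)
  x <- rpois(60, 1.5)
  lab <- rep(c(TRUE, FALSE), 30)
  p1 <- permutation_test(x, lab, n_perm = 499, seed = 7,
                         exhaustive_limit = 0)
  p2 <- permutation_test(x, lab, n_perm = 499, seed = 7,
                         exhaustive_limit = 0)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$method, "monte_carlo")
  expect_gte(p1$p_value, 1 / 500)
  expect_error(permutation_test(x, lab, n_perm = 0), "n_perm")
})

test_that("burden rates are additive across type and genic partitions", {
  withr::local_seed(55)
  s <- mk_samples(40, 60)
  d <- rbind(spread_calls(s$sample_id[1:40], 55, "deletion", TRUE),
             spread_calls(s$sample_id[1:40], 35, "duplication", FALSE,
                          offset = 4L),
             spread_calls(s$sample_id[41:100], 50, "deletion", FALSE,
                          offset = 8L),
             spread_calls(s$sample_id[41:100], 45, "duplication", TRUE,
                          offset = 12L))
  cs <- callset(d, samples = s$sample_id)
  r <- function(ct, gc) burden_statistics(cs, s, cnv_type = ct,
                                          genic_class = gc)$rate_per_sample
  expect_equal(r("all", "all"), r("deletion", "all") +
                 r("duplication", "all"))
  expect_equal(r("all", "all"), r("all", "genic") + r("all", "nongenic"))
})

test_that("burden_test reports group values, fold and empirical p", {
  s <- mk_samples(30, 50)
  cases <- s[s$phenotype == "case", ]
  controls <- s[s$phenotype == "control", ]
  d <- rbind(spread_calls(cases$sample_id, 60),
             spread_calls(controls$sample_id, 50, offset = 4L))
  res <- burden_test(d, cases, controls, n_perm = 199, seed = 5)
  expect_equal(res$group_a_value, 2)
  expect_equal(res$group_b_value, 1)
  expect_equal(res$fold_change, 2)
  expect_lte(res$empirical_p, 1)
  expect_gte(res$empirical_p, 1 / 200)
})

test_that("age tertiles split exactly with ties to the lower tertile", {
  t1 <- assign_age_tertiles(c(50, 55, 60, 65, 70, 75))
  expect_equal(t1, c(1L, 1L, 2L, 2L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(attr(t1, "boundaries"), c(55, 65))
  # a tie at the boundary value goes to the lower tertile
  t2 <- assign_age_tertiles(c(50, 55, 55, 65, 70, 75))
  expect_equal(t2[2:3], c(1L, 1L))
  # order-independence
  shuffled <- c(70, 50, 75, 60, 55, 65)
  expect_equal(assign_age_tertiles(shuffled)[order(shuffled)],
               sort(t1), ignore_attr = TRUE)
})

test_that("stratified burden covers site, sex, age and MS strata", {
  withr::local_seed(77)
  n_cases <- 30; n_controls <- 40
  s <- mk_samples(n_cases, n_controls,
                  age = round(stats::runif(70, 40, 85)))
  s$site[1:15] <- "colon"; s$site[16:30] <- "rectal"
  d <- rbind(spread_calls(s$sample_id[1:30], 60),
             spread_calls(s$sample_id[31:70], 40, offset = 4L))
  res <- stratified_burden(d, s, n_perm = 99, seed = 11)
  expect_setequal(unique(res$stratum),
                  c("site", "sex", "age_tertile", "age_decade",
                    "ms_excluded"))
  expect_setequal(res$group_a[res$stratum == "site"],
                  c("colon", "rectal"))
  # tertile contrasts: three vs controls plus the within-case pairs
  at <- res[res$stratum == "age_tertile", ]
  expect_setequal(paste(at$group_a, at$group_b),
                  c("T1 control", "T2 control", "T3 control",
                    "T1 T3", "T2 T3", "T1 T2"))
  ms <- res[res$stratum == "ms_excluded", ]
  expect_equal(ms$n_b, sum(s$phenotype == "control" &
                             s$ms_status != "ms"))
  expect_true(all(res$empirical_p > 0 & res$empirical_p <= 1))
})
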