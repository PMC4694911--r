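mk_gene <- function(gene_id, chrom, tx_start, tx_end,
                    cds = data.frame(start_bp = integer(),
                                     end_bp = integer()),
                    symbol = gene_id) {
  g <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                  tx_start_bp = tx_start, tx_end_bp = tx_end,
                  strand = "+", stringsAsFactors = FALSE)
  g$cds_exons <- list(cds)
  g
}

test_that("genic classification honours the 10 kb flank inclusively", {
  genes <- mk_gene("G1", "1", 125000L, 130000L)
  # call ends 5 kb short of the transcript: inside the flank -> genic
  cs <- callset(mk_calls(100000L, 120000L))
  ann <- classify_genic(cs, genes)
  expect_true(ann$is_genic)
  expect_equal(ann$genes_hit[[1]], "G1")

  # touching exactly at tx_start - 10 kb is genic (inclusive boundary)
  touch <- classify_genic(callset(mk_calls(100000L, 115000L)), genes)
  expect_true(touch$is_genic)
  # one bp short of the flank is not
  miss <- classify_genic(callset(mk_calls(100000L, 114999L)), genes)
  expect_false(miss$is_genic)
  expect_length(miss$genes_hit[[1]], 0L)
})

test_that("intronic calls are genic but not CDS-overlapping", {
  genes <- mk_gene("G2", "1", 50000L, 90000L,
                   cds = data.frame(start_bp = c(50000L, 85000L),
                                    end_bp = c(55000L, 90000L)))
  intron <- classify_genic(callset(mk_calls(60000L, 80000L)), genes)
  expect_true(intron$is_genic)
  expect_false(intron$is_cds)
  exonic <- classify_genic(callset(mk_calls(54000L, 80000L)), genes)
  expect_true(exonic$is_cds)
  # CDS overlap gets no flank: a call in the flank region is genic only
  flank_only <- classify_genic(callset(mk_calls(40001L, 49999L)), genes)
  expect_true(flank_only$is_genic)
  expect_false(flank_only$is_cds)
  # is_cds implies is_genic; is_genic iff genes_hit non-empty
  for (a in list(intron, exonic, flank_only)) {
    expect_true(!a$is_cds || a$is_genic)
    expect_equal(a$is_genic, lengths(a$genes_hit) > 0)
  }
})

test_that("isoforms collapse to one gene per symbol", {
  g <- rbind(mk_gene("NM_1", "2", 1000L, 5000L,
                     data.frame(start_bp = 2000L, end_bp = 3000L),
                     symbol = "SYM"),
             mk_gene("NM_2", "2", 4000L, 9000L,
                     data.frame(start_bp = c(2500L, 6000L),
                                end_bp = c(3500L, 7000L)),
                     symbol = "SYM"))
  cg <- collapse_gene_models(g)
  expect_equal(nrow(cg), 1L)
  expect_equal(cg$tx_start_bp, 1000L)
  expect_equal(cg$tx_end_bp, 9000L)
  expect_equal(cg$cds_exons[[1]],
               data.frame(start_bp = c(2000L, 6000L),
                          end_bp = c(3500L, 7000L)))
})

test_that("zero flank marks no more calls genic than the 10 kb flank", {
  withr::local_seed(17)
  n <- 100
  starts <- sample.int(5e5, n)
  cs <- callset(cnv_calls(sprintf("s%02d", sample.int(30, n, TRUE)),
                          as.character(sample.int(3, n, TRUE)),
                          starts, starts + 15000L, 1L, 12L,
                          "consensus", 15))
  genes <- do.call(rbind, lapply(1:60, function(i)
    mk_gene(sprintf("G%02d", i), as.character(sample.int(3, 1)),
            s <- sample.int(5e5, 1), s + 20000L)))
  a0 <- classify_genic(cs, genes, flank_bp = 0)
  a10 <- classify_genic(cs, genes, flank_bp = 10000)
  expect_true(all(a10$is_genic[a0$is_genic]))
  # interval machinery agrees with the brute-force all-pairs oracle
  expect_equal(a10$is_genic, brute_genic(cs$calls, genes, 10000))
  expect_equal(a0$is_genic, brute_genic(cs$calls, genes, 0))
})

test_that("disrupted gene sets union per group; exclusivity is set difference", {
  s <- mk_samples(2, 1)
  genes <- rbind(mk_gene("A", "1", 10000L, 20000L),
                 mk_gene("B", "1", 40000L, 50000L),
                 mk_gene("C", "1", 70000L, 80000L))
  cs <- callset(cnv_calls(
    sample_id = c(s$sample_id[1], s$sample_id[2], s$sample_id[2],
                  s$sample_id[3]),
    chrom = "1", start_bp = c(9000L, 41000L, 69000L, 41000L),
    end_bp = c(42000L, 45000L, 81000L, 45000L),
    state = 1L, n_probes = 12L, caller = "consensus",
    bayes_factor = 15), samples = s$sample_id)
  ann <- classify_genic(cs, genes)
  sets <- disrupted_gene_sets(ann, s)
  expect_equal(sets$case, c("A", "B", "C"))
  expect_equal(sets$control, "B")
  expect_equal(exclusive_genes(sets$case, sets$control), c("A", "C"))
  expect_equal(exclusive_genes(c("A", "B"), c("X")), c("A", "B"))
  expect_equal(exclusive_genes(c("A", "B"), c("A", "B")), character())

  # site-restricted grouping uses only that stratum's calls
  by_site <- disrupted_gene_sets(ann, s, group_by = "site")
  expect_equal(by_site$colon, c("A", "B", "C"))
  expect_equal(by_site$none, "B")

  # empty annotated table -> empty sets
  empty <- classify_genic(callset(cnv_calls(), samples = s$sample_id),
                          genes)
  expect_length(disrupted_gene_sets(empty, s)$case, 0L)
})
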