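test_that("window tiling covers contigs with flagged terminal partials", {
  w <- make_windows(c("1" = 150000))
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(1, 50001, 100001))
  expect_equal(w$end, c(50000, 100000, 150000))
  expect_false(any(w$partial))

  w2 <- make_windows(c("1" = 120000))
  expect_equal(nrow(w2), 3L)
  expect_equal(w2$end[3] - w2$start[3] + 1, 20000)
  expect_true(w2$partial[3])

  # 5-Mb contig -> 100 windows; SNP counts conserved
  sim <- simulate_neutral(sweep_sim_config(n_sites = 5000, seq_length = 5e6,
                                           seed = 3))
  w3 <- make_windows(c("1" = 5e6))
  expect_equal(nrow(w3), 100L)
  xp <- tibble::tibble(chrom = "1", pos = sim$haplotypes$positions,
                       std = rnorm(5000))
  wm <- window_max(xp, w3)
  expect_equal(sum(wm$snp_count), 5000L)
})

test_that("window summary takes the signed maximum per window", {
  w <- make_windows(c("1" = 100000))
  sc <- tibble::tibble(chrom = "1",
                       pos = c(10, 20, 30, 50010, 50020),
                       std = c(-2, 0.5, 1.7, -3, -1))
  wm <- window_max(sc, w)
  expect_equal(wm$stat, c(1.7, -1))   # signed max, even when all negative
  # abs-max variant keeps the extreme magnitude with its sign
  wm2 <- window_max(sc, w, abs_max = TRUE)
  expect_equal(wm2$stat, c(-2, -3))
  # windows without scored SNPs are omitted
  sc2 <- sc[sc$pos < 50000, ]
  expect_equal(nrow(window_max(sc2, w)), 1L)
  # brute force agreement on simulated data
  sim_sc <- tibble::tibble(chrom = "1", pos = sample.int(1e5, 300),
                           std = rnorm(300))
  wm3 <- window_max(sim_sc, w)
  for (k in seq_len(nrow(wm3)))
    expect_equal(wm3$stat[k],
                 max(sim_sc$std[sim_sc$pos >= wm3$start[k] &
                                  sim_sc$pos <= wm3$end[k]]))
})

test_that("SNP-density binning pools at 1000 with exact boundaries", {
  ws <- tibble::tibble(snp_count = c(10L, 499L, 500L, 501L, 999L, 1000L,
                                     1500L, 0L),
                       stat = rnorm(8))
  b <- bin_windows(ws)
  expect_equal(b$bin, c(0L, 0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(attr(b, "n_zero_snp"), 1L)
  expect_equal(nrow(b), 7L)   # zero-SNP window excluded
})

test_that("empirical P is the strict-exceedance fraction within bins", {
  # 200 distinct values in one bin: the 10th largest has p = 9/200
  set.seed(71)
  stat <- sample(seq(0.001, 0.2, 0.001), 200)
  ws <- tibble::tibble(snp_count = 100L, stat = stat)
  ep <- empirical_p(bin_windows(ws))
  tenth <- sort(stat, decreasing = TRUE)[10]
  expect_equal(ep$empirical_p[ep$stat == tenth], 9 / 200)
  expect_false(ep$outlier[ep$stat == tenth])
  # the bin maximum has p = 0 and is an outlier
  expect_equal(ep$empirical_p[which.max(ep$stat)], 0)
  expect_true(ep$outlier[which.max(ep$stat)])
  # distinct stats: p values are exactly {0, 1/n, ..., (n-1)/n}
  expect_equal(sort(ep$empirical_p), (0:199) / 200)
  # outlier fraction is exactly the threshold-compatible count
  expect_equal(sum(ep$outlier), sum((0:199) / 200 < 0.005))

  # all tied -> p = 0 for all, with a tie message
  ws_tied <- tibble::tibble(snp_count = 100L, stat = rep(1, 300))
  expect_message(ep2 <- empirical_p(bin_windows(ws_tied)), "tied")
  expect_true(all(ep2$empirical_p == 0))

  # small bins warn
  ws_small <- tibble::tibble(snp_count = 10L, stat = rnorm(50))
  expect_warning(empirical_p(bin_windows(ws_small)), "fewer than 200")
})

test_that("top-fraction rule keeps ceiling(fraction n) windows plus ties", {
  set.seed(73)
  ws <- tibble::tibble(stat = sample(seq_len(2000), 1000))  # distinct
  tf <- top_fraction(ws)
  expect_equal(sum(tf$outlier), 5L)
  expect_equal(sort(tf$stat[tf$outlier]), sort(tf$stat, decreasing = TRUE)[5:1])

  # ties at the threshold are all included
  ws2 <- tibble::tibble(stat = c(rep(100, 10), runif(990)))
  expect_message(tf2 <- top_fraction(ws2), "ties")
  expect_equal(sum(tf2$outlier), 10L)

  # sort-and-slice oracle on arbitrary values
  ws3 <- tibble::tibble(stat = rnorm(400))
  tf3 <- top_fraction(ws3, fraction = 0.01)
  k <- ceiling(0.01 * 400)
  expect_setequal(which(tf3$outlier), order(-ws3$stat)[seq_len(k)])
})

test_that("candidate genes require >= 1 bp overlap with outlier windows", {
  wins <- tibble::tibble(chrom = "1",
                         start = c(50001, 150001), end = c(100000, 200000),
                         outlier = TRUE)
  genes <- tibble::tibble(
    gene_id = c("inside", "before", "spans", "adjacent_left", "one_bp"),
    chrom = "1",
    start = c(60000, 10000, 40000, 30000, 100000),
    end = c(70000, 50000, 210000, 50000, 120000))
  cg <- candidate_genes(wins, genes)
  expect_setequal(unique(cg$gene_id), c("inside", "spans", "one_bp"))
  # gene ending 1 bp before the window start is excluded
  expect_false("adjacent_left" %in% cg$gene_id)
  # "before" ends exactly at 50000 < 50001 -> excluded
  expect_false("before" %in% cg$gene_id)

  # brute-force overlap oracle on a random fixture
  set.seed(79)
  wins2 <- tibble::tibble(chrom = "1",
                          start = sample.int(1e6, 20) %/% 1000 * 1000 + 1)
  wins2$end <- wins2$start + 49999
  wins2$outlier <- TRUE
  genes2 <- tibble::tibble(gene_id = sprintf("g%02d", 1:50), chrom = "1",
                           start = sample.int(1e6, 50))
  genes2$end <- genes2$start + sample.int(20000, 50)
  cg2 <- candidate_genes(wins2, genes2)
  manual <- c()
  for (i in seq_len(50)) for (j in seq_len(20))
    if (genes2$start[i] <= wins2$end[j] && genes2$end[i] >= wins2$start[j])
      manual <- c(manual, genes2$gene_id[i])
  expect_setequal(unique(cg2$gene_id), unique(manual))
})

test_that("candidate-set intersection keeps shared ids with their windows", {
  mk <- function(ids, scan)
    tibble::tibble(scan = scan, chrom = "1", window_start = 1,
                   window_end = 50000, gene_id = ids,
                   gene_start = 1, gene_end = 10)
  a <- mk(sprintf("a%03d", 1:96), "xpehh")
  b <- mk(sprintf("b%03d", 1:78), "xpclr")
  shared <- sprintf("s%03d", 1:28)
  set_a <- dplyr::bind_rows(a, mk(shared, "xpehh"))     # 124 genes
  set_b <- dplyr::bind_rows(b, mk(shared, "xpclr"))     # 106 genes
  both <- intersect_candidates(set_a, set_b)
  expect_equal(length(unique(both$gene_id)), 28L)
  expect_setequal(unique(both$gene_id), shared)
  expect_setequal(unique(both$scan), c("xpehh", "xpclr"))
  # identical sets -> everything; disjoint sets -> empty
  expect_equal(length(unique(intersect_candidates(set_a, set_a)$gene_id)),
               124L)
  expect_equal(nrow(intersect_candidates(a, b)), 0L)
})

test_that("the full pipeline flags the sweep and reproduces byte-identically", {
  cfg <- sweep_sim_config(seq_length = 1e6, n_sites = 1000, seed = 17,
                          qual_fail_fraction = 0.05,
                          sweep = sweep_spec("pop1", 475000,
                                             final_frequency = 0.95))
  g <- simulate_genome(cfg, n_contigs = 4, sweep_contig = 1)
  genes <- tibble::tibble(gene_id = sprintf("gene%03d", 1:40),
                          chrom = rep(as.character(1:4), each = 10),
                          start = rep(seq(1, 1e6, length.out = 10), 4),
                          strand = "+")
  genes$end <- genes$start + 30000
  run_once <- function() {
    suppressWarnings(run_scan(
      g$haplotypes, g$quality, pop_test = "pop1", pop_ref = "pop2",
      contig_lengths = g$contig_lengths, genes = genes))
  }
  rep1 <- run_once()
  # sweep window is an outlier in at least one scan
  sw <- g$truth[!is.na(g$truth$sweep_start), ][1, ]
  hit_xpehh <- with(rep1$xpehh_windows,
                    any(outlier & chrom == sw$chrom & start == sw$sweep_start))
  hit_xpclr <- with(rep1$xpclr_windows,
                    any(outlier & chrom == sw$chrom & start == sw$sweep_start))
  expect_true(hit_xpehh || hit_xpclr)
  # determinism: identical report files from a rerun
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scan_report(rep1, d1)
  write_scan_report(run_once(), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # tidy/glance views are consistent with the report
  td <- tidy(rep1)
  expect_setequal(unique(td$scan), c("xpehh", "xpclr"))
  gl <- glance(rep1)
  expect_equal(gl$n_xpehh_outliers, sum(rep1$xpehh_windows$outlier))
  expect_equal(gl$n_candidates_shared,
               length(unique(rep1$candidates_shared$gene_id)))
  expect_s3_class(autoplot(rep1), "ggplot")
})

test_that("pipeline stage failures name the stage", {
  sim <- small_sim(seed = 10, n_sites = 100, seq_length = 1e5)
  expect_error(suppressWarnings(
    run_scan(sim$haplotypes, NULL, pop_test = "nope", pop_ref = "pop2")),
    "stage 'xpehh'")
})
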