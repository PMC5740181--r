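test_that("adjacent intervals are per-chromosome successive differences", {
  degs <- data.frame(gene_id = paste0("g", 1:5),
                     chrom = c("1", "1", "1", "2", "2"),
                     pos = c(10, 30, 100, 5, 50))
  out <- adjacent_intervals(degs)
  expect_equal(out$interval[out$chrom == "1"], c(20, 70))
  expect_equal(out$interval[out$chrom == "2"], 45)   # never -15 across chroms
  # one gene per chromosome: no intervals
  solo <- data.frame(chrom = c("1", "2"), pos = c(5, 9))
  expect_equal(nrow(adjacent_intervals(solo)), 0)
  expect_message(
    adjacent_intervals(data.frame(chrom = "1", pos = c(7, 7))),
    "zero interval")
})

test_that("expected interval is genome size over gene count", {
  expect_equal(expected_interval(1e8, 1000), 1e5)
  expect_equal(expected_interval(432e6, 432), 1e6)
  expect_equal(expected_interval(5e6, 1), 5e6)
  expect_error(expected_interval(1e6, 0), ">= 1")
})

test_that("ratio summary applies strict fractions and bins", {
  # all intervals equal to expected: strictly-below fractions are 0
  out <- ratio_summary(rep(1000, 10), expected = 1000)
  expect_equal(out$fraction_below_1, 0)
  expect_equal(out$fraction_below_0.1, 0)
  mix <- ratio_summary(c(50, 500, 1500, 3000), expected = 1000)
  expect_equal(mix$fraction_below_1, 0.5)
  expect_equal(mix$fraction_below_0.1, 0.25)
  expect_equal(sum(mix$histogram), 4)
  expect_error(ratio_summary(1, 0), "> 0")
})

test_that("call_clusters finds maximal runs with strict thresholds", {
  degs <- data.frame(chrom = "1", pos = c(0, 10000, 20000, 200000, 210000))
  out <- call_clusters(degs, "absolute", 30000)
  expect_equal(nrow(out), 1)        # the pair at 200k/210k is too short
  expect_equal(out$n_genes, 3)
  expect_equal(out$start, 0)
  expect_equal(out$end, 20000)
  # interval exactly at the threshold breaks the run
  tied <- data.frame(chrom = "1", pos = c(0, 30000, 60000))
  expect_equal(nrow(call_clusters(tied, "absolute", 30000)), 0)
  expect_equal(nrow(call_clusters(tied, "absolute", 30001)), 1)
  # everything far apart: no clusters
  sparse <- data.frame(chrom = "1", pos = c(0, 1e6, 2e6, 3e6))
  expect_equal(nrow(call_clusters(sparse, "absolute", 30000)), 0)
})

test_that("fraction mode thresholds against the expected interval", {
  degs <- data.frame(chrom = "1", pos = c(0, 5000, 10000, 5e6))
  attr(degs, "genome_size") <- 4e6   # expected = 1e6; 10% = 100 kb
  frac <- call_clusters(degs, "fraction", 0.1)
  expect_equal(attr(frac, "threshold_bp"), 1e5)
  expect_equal(frac$n_genes, 3)
  expect_error(call_clusters(degs[, c("chrom", "pos")], "fraction", 0.1),
               "genome_size")
})

test_that("cluster calling matches the brute-force run scanner", {
  for (s in 1:3) {
    degs <- simulate_deg_positions(1e4, 3e8, mode = "clustered",
                                   cluster_fraction = 0.4,
                                   cluster_size = 4, cluster_gap = 5000,
                                   chrom_lengths = rep(1e7, 30), seed = s)
    got <- call_clusters(degs, "absolute", 30000)
    want <- brute_clusters(degs, 30000)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_genes, want$n_genes)
  }
})

test_that("cluster calls are invariant to input row order", {
  degs <- simulate_deg_positions(500, 5e7, mode = "clustered", seed = 4)
  shuf <- degs[sample(nrow(degs)), ]
  attr(shuf, "genome_size") <- attr(degs, "genome_size")
  expect_equal(call_clusters(degs, "absolute", 30000),
               call_clusters(shuf, "absolute", 30000),
               ignore_attr = TRUE)
})

test_that("cluster member runs all pass the threshold internally", {
  degs <- simulate_deg_positions(2000, 1e8, mode = "clustered",
                                 cluster_gap = 2000, seed = 5)
  calls <- call_clusters(degs, "absolute", 30000)
  expect_gt(nrow(calls), 0)
  for (i in seq_len(nrow(calls))) {
    ids <- strsplit(calls$gene_ids[i], ",")[[1]]
    pos <- sort(degs$pos[match(ids, degs$gene_id)])
    expect_true(all(diff(pos) < 30000))
    expect_gte(length(ids), 3)
  }
})

test_that("the permutation null separates clustered from uniform placement", {
  lens <- rep(5e7, 4)
  clustered <- simulate_deg_positions(400, 2e8, mode = "clustered",
                                      cluster_fraction = 0.8,
                                      cluster_gap = 1000,
                                      chrom_lengths = lens, seed = 6)
  out <- cluster_null_test(clustered, n_permutations = 100, seed = 7)
  expect_equal(out$p_cluster_count, 1 / 101)   # strong clustering: minimal p
  uni <- simulate_deg_positions(400, 2e8, mode = "uniform",
                                chrom_lengths = lens, seed = 8)
  out0 <- cluster_null_test(uni, n_permutations = 100, seed = 9)
  expect_gt(out0$p_cluster_count, 0.05)
  expect_error(cluster_null_test(uni, n_permutations = 10), ">= 100")
})

test_that("cluster_report runs both threshold conventions side by side", {
  degs <- simulate_deg_positions(1000, 1e8, mode = "clustered", seed = 10)
  rep <- cluster_report(degs)
  expect_named(rep, c("ratio", "absolute", "fraction", "size_histogram",
                      "per_chrom", "agree", "expected"))
  expect_equal(rep$expected, 1e5)
  expect_true(is.logical(rep$agree))
  expect_true(all(rep$absolute$n_genes >= 3))
})
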