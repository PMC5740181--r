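test_that("cross_design validates its fields", {
  expect_s3_class(cross_design(), "cross_design")
  expect_error(cross_design(pool_fraction = 0), "pool_fraction")
  expect_error(cross_design(pool_fraction = 0.6), "pool_fraction")
  expect_error(cross_design(mean_depth = 0), "mean_depth")
  expect_error(
    cross_design(qtl = data.frame(chrom = 99, pos_cm = 10, effect = 1)),
    "outside the simulated map")
  expect_error(
    cross_design(qtl = data.frame(chrom = 1, pos_cm = 500, effect = 1)),
    "outside the simulated map")
})

test_that("BC1 genotypes segregate ~1:1 and totals respect the family range", {
  des <- cross_design(seed = 5)   # study defaults: 7 families of 127-174
  pop <- simulate_bc1(des)
  n <- length(pop$phenotypes)
  expect_gte(n, 7 * 127)
  expect_lte(n, 7 * 174)
  expect_equal(length(unique(pop$family)), 7)
  # aa proportion centred on 0.5: within 3 binomial SD at almost every
  # marker (a 3-SD bound leaves ~0.3% expected strays over 300+ markers)
  frac_aa <- 1 - colMeans(pop$genotypes)
  tol <- 3 * sqrt(0.25 / n)
  expect_lte(mean(abs(frac_aa - 0.5) > tol), 0.02)
  expect_lt(abs(mean(frac_aa) - 0.5), 0.01)
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_bc1(small_design(seed = 3))
  b <- simulate_bc1(small_design(seed = 3))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_bc1(small_design(seed = 4))
  expect_false(identical(a$phenotypes, c$phenotypes))
})

test_that("adjacent-marker recombination matches the Haldane map function", {
  des <- cross_design(n_families = 7, family_size_range = c(170, 174),
                      n_chromosomes = 2, marker_spacing_cm = 10, seed = 8)
  pop <- simulate_bc1(des)
  m <- pop$map
  on1 <- which(m$chrom == 1)
  g <- pop$genotypes
  obs <- mean(g[, on1[1]] != g[, on1[2]])
  r <- 0.5 * (1 - exp(-2 * 10 / 100))    # 0.0906
  expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / nrow(g)))
  # markers on different chromosomes are unlinked
  on2 <- which(m$chrom == 2)
  obs_free <- mean(g[, on1[1]] != g[, on2[1]])
  expect_lt(abs(obs_free - 0.5), 3 * sqrt(0.25 / nrow(g)))
})

test_that("phenotypes respond to QTL genotype as designed", {
  # null design: phenotype uncorrelated with every marker
  pop0 <- simulate_bc1(cross_design(n_families = 7,
                                    family_size_range = c(140, 150),
                                    n_chromosomes = 2, seed = 31))
  r <- abs(cor(pop0$genotypes, pop0$phenotypes))
  expect_lt(max(r), 5 / sqrt(length(pop0$phenotypes)))
  # dominant-effect limit: effect = 10 noise SD separates the groups
  des <- small_design(seed = 32,
                      qtl = data.frame(chrom = 1, pos_cm = 20, effect = 0.5))
  pop <- simulate_bc1(des)
  g <- pop$genotypes[, "M01_020"]
  expect_gt(min(pop$phenotypes[g == 1]), max(pop$phenotypes[g == 0]))
})

test_that("pool selection takes exact floor(f*n) per tail per family", {
  pop <- simulate_bc1(small_design(seed = 6))
  pools <- build_pools(pop, 0.10)
  sizes <- table(pop$family)
  expect_equal(unname(pools$per_family), unname(pmax(1, floor(0.10 * sizes))))
  expect_length(pools$low_ids, sum(pools$per_family))
  expect_length(intersect(pools$low_ids, pools$high_ids), 0)
  # selected tails really are the extremes within each family
  for (f in unique(pop$family)) {
    idx <- which(pop$family == f)
    lo <- intersect(pools$low_ids, idx)
    hi <- intersect(pools$high_ids, idx)
    rest <- setdiff(idx, c(lo, hi))
    expect_lte(max(pop$phenotypes[lo]), min(pop$phenotypes[rest]))
    expect_gte(min(pop$phenotypes[hi]), max(pop$phenotypes[rest]))
  }
})

test_that("fraction 0.5 partitions families; equal phenotypes fall back to index order", {
  des <- cross_design(n_families = 2, family_size_range = c(40, 40),
                      n_chromosomes = 2, seed = 7)
  pop <- simulate_bc1(des)
  pools <- build_pools(pop, 0.5)
  expect_length(c(pools$low_ids, pools$high_ids), length(pop$phenotypes))
  expect_length(intersect(pools$low_ids, pools$high_ids), 0)
  pop$phenotypes[] <- 1   # degenerate: all equal
  pools <- build_pools(pop, 0.25)
  idx1 <- which(pop$family == 1)
  expect_equal(intersect(pools$low_ids, idx1), head(idx1, 10))
  expect_equal(intersect(pools$high_ids, idx1), tail(idx1, 10))
})

test_that("pooled depths reflect pool composition under both conventions", {
  pop <- simulate_bc1(small_design(seed = 9))
  pools <- build_pools(pop)
  # force a marker to be all-aa in the low pool: zero ab-channel reads
  pop$genotypes[pools$low_ids, 1] <- 0L
  for (conv in c("allele", "dosage")) {
    d <- pooled_depths(pop, pools$low_ids, pools$high_ids,
                       error_rate = 0, convention = conv, seed = 11)
    expect_equal(d$Mab[1], 0)
    expect_true(all(d[, c("Maa", "Mab", "Paa", "Pab")] >= 0))
  }
  expect_error(pooled_depths(pop, pools$low_ids,
                             c(pools$high_ids, pools$low_ids[1])),
               "disjoint")
})

test_that("unlinked markers give symmetric indices in expectation", {
  # equal pool sizes and depths: E[Maa/(Maa+Paa)] = 0.5 at null markers
  des <- cross_design(n_families = 4, family_size_range = c(100, 100),
                      n_chromosomes = 6, marker_spacing_cm = 5, seed = 10)
  pop <- simulate_bc1(des)
  pools <- build_pools(pop)
  d <- snp_index(pooled_depths(pop, pools$low_ids, pools$high_ids))
  # markers within a chromosome are correlated, so the effective number of
  # independent draws is closer to the chromosome count than the marker count
  expect_lt(abs(mean(d$snp_index_aa) - 0.5), 0.02)
  expect_lt(abs(mean(d$delta)), 0.05)
})

test_that("perfect linkage under the allele convention drives delta to 2/3", {
  # pools made perfectly informative by construction at marker 1
  pop <- simulate_bc1(small_design(seed = 12, mean_depth = 5000))
  pools <- build_pools(pop)
  pop$genotypes[pools$low_ids, 1] <- 0L
  pop$genotypes[pools$high_ids, 1] <- 1L
  d <- snp_index(pooled_depths(pop, pools$low_ids, pools$high_ids,
                               error_rate = 0, convention = "allele"))
  expect_equal(d$delta[1], 2 / 3, tolerance = 0.02)
  expect_equal(d$snp_index_ab[1], 0)
})

test_that("uniform DEG placement matches Poisson-process spacing", {
  degs <- simulate_deg_positions(1e5, 1e9, mode = "uniform", seed = 13)
  ints <- adjacent_intervals(degs)$interval
  frac <- mean(ints / expected_interval(1e9, 1e5) < 0.1)
  expected <- 1 - exp(-0.1)   # 0.0952
  se <- sqrt(expected * (1 - expected) / length(ints))
  expect_lt(abs(frac - expected), 3 * se + 0.002)
})

test_that("clustered DEG placement and edge cases behave as constructed", {
  degs <- simulate_deg_positions(100, 1e8, mode = "clustered",
                                 cluster_fraction = 1, cluster_gap = 1,
                                 seed = 14)
  ints <- adjacent_intervals(degs)$interval
  expect_gte(mean(ints <= 1), 0.75)   # within-run gaps dominate
  two <- simulate_deg_positions(2, 1e6, seed = 15)
  expect_equal(nrow(adjacent_intervals(two)), 1)
  expect_error(simulate_deg_positions(100, 50, min_gap = 1), "too small")
  expect_error(simulate_deg_positions(1, 1e6), ">= 2")
})

test_that("expression tables carry the designed association", {
  pos <- simulate_expression_tables(association = "positive", noise_sd = 0,
                                    seed = 16)
  m <- merge(pos$expression_strain, pos$csw, by = "strain")
  expect_equal(cor(m$expr, m$csw, method = "spearman"), 1)
  inc <- growth_increments(pos$gland_volume)
  md <- merge(pos$expression_day, inc, by = "day")
  expect_gt(cor(md$expr, md$increment), 0.99)
  # null association: correlation centred at zero over seeds
  r0 <- vapply(1:20, function(s) {
    t0 <- simulate_expression_tables(association = "none", seed = s)
    m0 <- merge(t0$expression_strain, t0$csw, by = "strain")
    cor(m0$expr, m0$csw)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.2)
  # constant volumes give zero increments
  expect_true(all(growth_increments(c(5, 5, 5))$increment == 0))
  expect_error(simulate_expression_tables(n_strains = 3), "n_strains")
})
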