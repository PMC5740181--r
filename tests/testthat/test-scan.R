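test_that("snp_index computes both channel indices and their contrast", {
  d <- tiny_depths()
  out <- snp_index(d)
  # m1: symmetric depths -> 0.5, 0.5, 0
  expect_equal(out$snp_index_aa[1], 0.5)
  expect_equal(out$snp_index_ab[1], 0.5)
  expect_equal(out$delta[1], 0)
  # m2: 100/(50+100), 0/(75+0) -> 2/3, 0, 2/3 (the perfect-linkage limit)
  expect_equal(out$snp_index_aa[2], 2 / 3)
  expect_equal(out$snp_index_ab[2], 0)
  expect_equal(out$delta[2], 2 / 3)
  expect_true(all(out$defined))
})

test_that("zero-depth channels leave the index undefined, never imputed", {
  d <- data.frame(Maa = c(0, 5), Mab = c(10, 0), Paa = c(0, 5), Pab = c(10, 0))
  out <- snp_index(d)
  expect_false(out$defined[1])   # aa channel empty
  expect_false(out$defined[2])   # ab channel empty
  expect_true(is.na(out$snp_index_aa[1]))
  expect_error(snp_index(data.frame(Maa = -1, Mab = 1, Paa = 1, Pab = 1)),
               ">= 0")
})

test_that("z_scores reproduces hand arithmetic in verbatim mode", {
  # deltas 0.1, 0.2, 0.3: mu0 = 0.2, S = 0.1, n = 3 -> z = (-sqrt 3, 0, sqrt 3)
  zs <- z_scores(c(0.1, 0.2, 0.3), mode = "verbatim")
  expect_equal(zs$z, c(-sqrt(3), 0, sqrt(3)))
  expect_equal(zs$mu0, 0.2)
  expect_equal(zs$S, 0.1)
  expect_equal(zs$n, 3)
  # classic mode drops the sqrt(n)
  expect_equal(z_scores(c(0.1, 0.2, 0.3), mode = "classic")$z, c(-1, 0, 1))
})

test_that("z_scores are centred and location-invariant", {
  set.seed(4)
  d <- rnorm(50)
  for (mode in c("verbatim", "classic")) {
    zs <- z_scores(d, mode = mode)
    expect_equal(mean(zs$z), 0)
    expect_equal(z_scores(d + 0.7, mode = mode)$z, zs$z)
  }
  expect_error(z_scores(rep(0.3, 5)), "S = 0")
  expect_error(z_scores(0.1), "at least 2")
})

test_that("p_from_z follows the spreadsheet tail conventions", {
  expect_equal(p_from_z(0, "one"), 0.5)
  expect_equal(p_from_z(0, "two"), 1)
  # uncapped two-sided: published confirmation values, to printed digits
  expect_equal(p_from_z(2.203548955, "two"), 0.02755608, tolerance = 1e-7)
  expect_equal(p_from_z(-1.337554725, "two"), 1.818958368, tolerance = 1e-9)
  expect_error(p_from_z(Inf), "finite")
})

test_that("two-sided p is uncapped, antisymmetric and decreasing in z", {
  z <- seq(-6, 6, by = 0.25)
  expect_equal(p_from_z(z, "two") + p_from_z(-z, "two"), rep(2, length(z)))
  expect_true(all(diff(p_from_z(z, "one")) < 0))
  expect_true(all(diff(p_from_z(z, "two")) < 0))
})

test_that("normal tail agrees with an erf-based high-precision reference", {
  skip_if_not_installed("pracma")
  z <- seq(-8, 8, by = 0.01)
  ref <- 0.5 * pracma::erfc(z / sqrt(2))   # 1 - Phi(z)
  expect_lt(max(abs(p_from_z(z, "one") - ref)), 1e-12)
})

test_that("adjust_fdr handles explicit n_tests for both methods", {
  expect_equal(adjust_fdr(0.01, "bonferroni", n_tests = 5), 0.05)
  # BH step-up by hand: (0.01*3/1, 0.02*3/2, 0.03*3/3) -> cummin from top
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  # order-preserving and order-independent
  p <- c(0.04, 0.001, 0.2, 0.01)
  o <- sample(4)
  expect_equal(adjust_fdr(p, "bh")[o], adjust_fdr(p[o], "bh"))
  expect_error(adjust_fdr(c(0.1, 0.2), n_tests = 1), "n_tests")
})

test_that("BH lies between raw p and Bonferroni and matches p.adjust", {
  set.seed(9)
  p <- runif(40)^2
  bh <- adjust_fdr(p, "bh")
  bonf <- adjust_fdr(p, "bonferroni")
  expect_true(all(bh >= p - 1e-12))
  expect_true(all(bh <= bonf + 1e-12))
  # monotone non-decreasing along the p-value ranks
  expect_true(all(diff(bh[order(p)]) >= -1e-12))
  # cross-check against the reference implementation where it applies
  expect_equal(pmin(bh, 1), p.adjust(p, "BH"))
  expect_equal(pmin(bonf, 1), p.adjust(p, "bonferroni"))
})

test_that("coverage filter applies the strict more-than rule", {
  d <- data.frame(Maa = c(0, 2, 3), Mab = c(0, 1, 1),
                  Paa = c(0, 1, 1), Pab = c(0, 1, 1))  # totals 0, 5, 6
  expect_equal(nrow(filter_polymorphic(d, 5)), 1)
  expect_equal(nrow(filter_polymorphic(d[1, ], 5)), 0)
})

test_that("bsa_scan excludes low-coverage and undefined markers from mu0/S/n", {
  d <- rbind(tiny_depths(),
             data.frame(marker_id = c("lowcov", "nodenom"), chrom = 3,
                        pos = c(1L, 2L), Maa = c(1, 40), Mab = c(1, 0),
                        Paa = c(1, 40), Pab = c(1, 0)))
  s <- bsa_scan(d, z_mode = "classic")
  expect_s3_class(s, "bsa_scan")
  expect_equal(s$n, 4)
  expect_setequal(s$excluded$marker_id, c("lowcov", "nodenom"))
  expect_setequal(s$excluded$reason, c("low_coverage", "undefined_index"))
  expect_equal(sort(s$markers$marker_id), sort(tiny_depths()$marker_id))
})

test_that("call_linked applies a strict threshold", {
  tab <- data.frame(marker_id = letters[1:3], fdr = c(1, 0.05, 0.01))
  expect_equal(call_linked(tab, 0.05)$marker_id, "c")
  expect_equal(nrow(call_linked(tab, 0)), 0)
  expect_equal(nrow(call_linked(data.frame(marker_id = "a", fdr = 1), 0.05)), 0)
})

test_that("scan summary surfaces the BH-vs-Bonferroni method note", {
  s <- bsa_scan(tiny_depths(), z_mode = "classic", method = "bh")
  out <- capture.output(print(summary(s)))
  expect_true(any(grepl("Bonferroni", out)))
})
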