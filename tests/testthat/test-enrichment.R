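test_that("empirical_p_z matches the standard normal upper tail", {
  null <- list(mean = 10, sd = 2)
  expect_equal(empirical_p_z(10, null)$p, 0.5)
  expect_equal(empirical_p_z(10 + 1.96 * 2, null)$p, 0.0250, tolerance = 1e-3)
  expect_equal(empirical_p_z(10 + 5 * 2, null)$p, 2.87e-7, tolerance = 1e-2)
  expect_equal(empirical_p_z(8, null, direction = "depletion")$p, pnorm(-1))
  expect_error(empirical_p_z(10, list(mean = 10, sd = 0)), "degenerate")
})

test_that("ks_gc_test reproduces the exhaustive CDF-gap oracle and ks.test", {
  x <- c(0.3, 0.4, 0.5)
  expect_equal(ks_gc_test(x, x)$D, 0)
  expect_equal(ks_gc_test(x, x)$p, 1)
  expect_equal(ks_gc_test(c(0, 0), c(1, 1))$D, 1)
  expect_error(ks_gc_test(numeric(), x), "empty")

  set.seed(5)
  for (i in 1:10) {
    a <- runif(sample(5:40, 1))
    b <- runif(sample(5:40, 1), max = 1.2)
    got <- ks_gc_test(a, b)
    expect_equal(got$D, oracle_ks_D(a, b))
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$D, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-4)
  }
})

test_that("bonferroni caps at one and scales by the family size", {
  expect_equal(bonferroni(0.5, 9), 1)
  expect_equal(bonferroni(0.004, 9), 0.036)
  expect_equal(bonferroni(0), 0)
  expect_error(bonferroni(1.2), "outside")
})

test_that("p_value_se implements the binomial SE of a p-value", {
  expect_equal(signif(p_value_se(3.7e-8, 63), 2), 2.4e-5)
  expect_equal(signif(p_value_se(0.09, 13), 1), 0.08)
  expect_equal(p_value_se(0, 63), 0)
  expect_error(p_value_se(0.5, 0), "n_regions")
  expect_error(p_value_se(2, 10), "outside")
})

test_that("permute_regions preserves lengths and respects the allowed space", {
  allowed <- region_tbl(c("chrA", "chrB"), c(0, 0), c(100, 49))

  # forced placement: one segment exactly the region's length
  forced <- permute_regions(region_tbl("x", 0, 49), allowed[2, ])
  expect_equal(c(forced$chrom, forced$start, forced$end), c("chrB", "0", "49"))

  # a region longer than every allowed segment errors, naming the region
  expect_error(permute_regions(region_tbl("x", 0, 100, name = "big"),
                               region_tbl("y", c(0, 0), c(99, 50))),
               "big")

  set.seed(3)
  placed <- permute_regions(region_tbl(rep("x", 50), 0, 30), allowed)
  expect_true(all(placed$end - placed$start == 30))
  expect_true(all(placed$chrom %in% c("chrA", "chrB")))
  for (i in seq_len(nrow(placed))) {
    seg <- allowed[allowed$chrom == placed$chrom[i] &
                     allowed$start <= placed$start[i] &
                     allowed$end >= placed$end[i], ]
    expect_equal(nrow(seg), 1) # fits entirely inside one allowed segment
  }
})

test_that("permuted starts of a 1 bp region are uniform over the allowed space", {
  set.seed(17)
  allowed <- region_tbl("chrA", 0, 100)
  reg <- region_tbl("x", 0, 1)
  starts <- replicate(5000, permute_regions(reg, allowed)$start)
  counts <- table(factor(starts, levels = 0:99))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("null distributions are deterministic and centred under homogeneity", {
  sim <- tiny_landscape(seed = 21, sine_gc_coupling = 1)
  regions <- region_tbl(rep("chr1", 25), seq(0, 24) * 6e4, seq(0, 24) * 6e4 + 3e4)
  n1 <- null_distribution(regions, sim$landscape, "sine", n_permutations = 60, seed = 9)
  n2 <- null_distribution(regions, sim$landscape, "sine", n_permutations = 60, seed = 9)
  expect_identical(n1$per_permutation_values, n2$per_permutation_values)

  # homogeneous feature density: E approx 1
  obs <- observed_feature(regions, sim$landscape, "sine")
  n3 <- null_distribution(regions, sim$landscape, "sine", n_permutations = 300, seed = 10)
  expect_equal(obs$aggregate / n3$mean, 1, tolerance = 0.15)
})

test_that("Monte-Carlo rank p agrees with the Z-transform p for normal-ish nulls", {
  sim <- tiny_landscape(seed = 31)
  regions <- region_tbl(rep("chr2", 20), seq(0, 19) * 9e4, seq(0, 19) * 9e4 + 4e4)
  obs <- observed_feature(regions, sim$landscape, "sine")$aggregate
  null <- null_distribution(regions, sim$landscape, "sine",
                            n_permutations = 400, seed = 12)
  p_z <- empirical_p_z(obs, null)$p
  p_rank <- (sum(null$per_permutation_values >= obs) + 1) / (null$n_permutations + 1)
  if (p_z > 1e-3) {
    expect_lt(max(p_z / p_rank, p_rank / p_z), 3)
  } else {
    succeed("observed value beyond the Monte-Carlo resolution")
  }
})

test_that("run_enrichment assembles one corrected test per set x feature", {
  sim <- tiny_landscape(seed = 41)
  h <- simulate_duplication_history(sim, n_blocks = 8,
                                    donor_size_range_kbp = c(10, 40), seed = 42)
  sets <- list(donors = h$donors, acceptors = h$acceptors,
               pre_integration = region_tbl(h$pre_integration$chrom,
                                            h$pre_integration$anchor_start,
                                            h$pre_integration$anchor_start + 5000,
                                            role = "pre_integration"))
  res <- run_enrichment(sim$landscape, sets, n_permutations = 40, seed = 2)
  expect_s3_class(res, "enrichment_result")
  expect_equal(nrow(res), 9)
  expect_equal(attr(res, "n_tests"), 9)
  expect_equal(res$p_corrected, pmin(1, res$p_raw * 9))
  expect_equal(res$se, sqrt(res$p_raw * (1 - res$p_raw) / res$n_regions))
  expect_equal(res$significant, res$p_corrected + res$se <= 0.05)
  expect_true(all(res$E[res$null_mean > 0] > 0))
  # GC rows carry both the KS and the Z-based p
  gc_rows <- res[res$feature == "gc", ]
  expect_true(all(!is.na(gc_rows$p_ks)))
  expect_equal(gc_rows$p_raw, gc_rows$p_ks)

  # single set, single feature: correction factor 1
  one <- run_enrichment(sim$landscape, sets["donors"], features = "sine",
                        n_permutations = 40, seed = 2)
  expect_equal(one$p_corrected, one$p_raw)
})

test_that("identical inputs and seed give bit-identical serialized output", {
  sim <- tiny_landscape(seed = 51)
  h <- simulate_duplication_history(sim, n_blocks = 6,
                                    donor_size_range_kbp = c(10, 30), seed = 52)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  r1 <- run_enrichment(sim$landscape, list(donors = h$donors),
                       n_permutations = 30, seed = 77)
  r2 <- run_enrichment(sim$landscape, list(donors = h$donors),
                       n_permutations = 30, seed = 77)
  format_enrichment_table(r1, f1)
  format_enrichment_table(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$p_raw, r2$p_raw)
})

test_that("tidiers and autoplot work on enrichment results", {
  sim <- tiny_landscape(seed = 61)
  h <- simulate_duplication_history(sim, n_blocks = 5,
                                    donor_size_range_kbp = c(10, 30), seed = 62)
  res <- run_enrichment(sim$landscape, list(donors = h$donors),
                        features = "sine", n_permutations = 20, seed = 3)
  g <- glance(res)
  expect_equal(g$n_tests, 1)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
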