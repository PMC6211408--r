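region_A <- function(len = 10000) {
  interval_set(data.frame(arm = "A", start = 0, end = len))
}

test_that("coverage fractions are exact set arithmetic", {
  r <- region_A()
  half <- interval_set(data.frame(arm = "A", start = 0, end = 5000))
  expect_equal(coverage_fraction(half, r), 0.5)
  far <- interval_set(data.frame(arm = "B", start = 0, end = 100))
  expect_equal(coverage_fraction(far, r), 0)
  expect_error(coverage_fraction(half, empty_intervals()), "empty region")
  # the planted truth reproduces its target coverage from the BED alone
  truth <- generate_truth(seed = 4, n_genes = 0)
  expect_equal(coverage_fraction(truth$domains$Lam,
                                 cha_windows(truth$assembly)),
               0.4, tolerance = 1e-3)
})

test_that("overlap statistics report both directions and the region share", {
  r <- region_A()
  a <- interval_set(data.frame(arm = "A", start = 0, end = 4000))
  st <- overlap_stats(a, a, r)
  expect_equal(st$pct_of_a, 100)
  expect_equal(st$pct_of_b, 100)
  expect_equal(st$pct_of_region, 40)
  b <- interval_set(data.frame(arm = "A", start = 5000, end = 6000))
  st2 <- overlap_stats(a, b, r)
  expect_equal(st2$length_bp, 0)
  expect_warning(st3 <- overlap_stats(empty_intervals(), a, r), "empty")
  expect_equal(st3$pct_of_a, 0)
})

test_that("conserved regions are strict intersections, order-invariant", {
  r <- region_A()
  d1 <- interval_set(data.frame(arm = "A", start = c(0, 6000),
                                end = c(3000, 8000)))
  d2 <- interval_set(data.frame(arm = "A", start = c(1000, 6000),
                                end = c(3000, 7000)))
  d3 <- interval_set(data.frame(arm = "A", start = c(2000, 5000),
                                end = c(4000, 9000)))
  cr <- conserved_regions(list(d1, d2, d3), r)
  cr_rev <- conserved_regions(list(d3, d1, d2), r)
  expect_equal(as.data.frame(cr$domains), as.data.frame(cr_rev$domains))
  expect_equal(as.data.frame(cr$inter_domains),
               as.data.frame(cr_rev$inter_domains))
  # hand check: common bases are [2000,3000) and [6000,7000)
  expect_equal(as.numeric(cr$domains$start), c(2000, 6000))
  expect_equal(total_length(cr$domains), 2000)
  # identical sets conserve themselves; an empty set kills conservation
  expect_equal(as.data.frame(conserved_regions(list(d1, d1), r)$domains),
               as.data.frame(d1))
  expect_equal(nrow(conserved_regions(
    list(d1, interval_set(empty_intervals())), r)$domains), 0)
  # inter-domains + per-set domains partition sanity
  expect_equal(total_length(interval_intersect(cr$domains,
                                               cr$inter_domains)), 0)
  # k-of-n relaxation admits bases covered by most sets
  cr2 <- conserved_regions(list(d1, d2, d3), r, min_sets = 2)
  expect_gt(total_length(cr2$domains), total_length(cr$domains))
})

test_that("permutation p-values match exact placement enumeration", {
  # one 1-kb element on a 10-kb arm: every placement is enumerable
  r <- region_A()
  b <- interval_set(data.frame(arm = "A", start = c(2000, 7000),
                               end = c(3000, 7500)))
  a <- interval_set(data.frame(arm = "A", start = 2200, end = 3200))
  obs <- total_length(interval_intersect(a, b))
  starts <- 0:9000
  # closed-form overlap of [s, s+1000) with the two fixed b intervals
  null_exact <- pmax(0, pmin(starts + 1000, 3000) - pmax(starts, 2000)) +
    pmax(0, pmin(starts + 1000, 7500) - pmax(starts, 7000))
  p_exact <- mean(null_exact >= obs)
  res <- permutation_overlap_test(a, b, r, n_perm = 4000, seed = 7)
  expect_lt(abs(res$p - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
  expect_equal(res$observed, obs)
  expect_equal(res$null_mean, mean(null_exact), tolerance = 0.1)
})

test_that("permutation extremes hit the defined p bounds", {
  r <- region_A()
  # element as large as the region: every shuffle reproduces full overlap
  res <- permutation_overlap_test(r, r, r, n_perm = 50, seed = 1)
  expect_equal(res$p, 1)
  # strong planted enrichment bottoms out at the add-one floor
  withr::local_seed(2)
  a <- interval_set(data.frame(arm = "A", start = seq(0, 9000, 1000),
                               end = seq(0, 9000, 1000) + 200))
  res2 <- permutation_overlap_test(a, a, r, n_perm = 999, seed = 3,
                                   statistic = "count")
  expect_equal(res2$p, 1 / 1000)
  expect_gte(res2$p, 1 / (res2$n_perm + 1))
  # an element longer than every region window is rejected
  long <- interval_set(data.frame(arm = "A", start = 0, end = 9999))
  gap <- interval_set(data.frame(arm = "A", start = c(0, 5000),
                                 end = c(4000, 9000)))
  expect_error(permutation_overlap_test(long, a, gap, n_perm = 5),
               "longer than")
})

test_that("X-versus-autosome shift detects a planted offset", {
  asm <- genome_assembly(c(X = 1e6, `2L` = 1e6, `2R` = 1e6), x_arms = "X")
  g <- bin_grid(asm, 1000)
  withr::local_seed(5)
  base <- rnorm(g$n_bins, 0, 0.5)
  xbins <- bins_in_intervals(g, cha_windows(asm, "X"))
  shifted <- base + ifelse(xbins, 0.5, 0)
  res <- chrom_profile_shift_test(ratio_profile(shifted, g, poi = "HP1a"))
  expect_lt(res$p, 1e-6)
  expect_gt(res$shift, 0.3)
  # null: no planted shift, several seeds stay unremarkable overall
  ps <- vapply(1:6, function(s) {
    set.seed(100 + s)
    chrom_profile_shift_test(ratio_profile(rnorm(g$n_bins), g))$p
  }, numeric(1))
  expect_gt(max(ps), 0.2)
  asm0 <- genome_assembly(c(`2L` = 1e6))
  expect_error(chrom_profile_shift_test(
    ratio_profile(rnorm(1000), bin_grid(asm0, 1000))), "no X arm")
})

test_that("per-chromosome coverage tables separate X from autosomes", {
  asm <- genome_assembly(c(X = 1e6, `2L` = 1e6), x_arms = "X")
  tab0 <- domain_coverage_by_chrom(interval_set(empty_intervals()), asm)
  expect_equal(tab0$percent, c(0, 0))
  tab1 <- domain_coverage_by_chrom(cha_windows(asm), asm)
  expect_equal(tab1$percent, c(100, 100))
  xdom <- interval_set(data.frame(arm = "X", start = 0, end = 5e5))
  tab2 <- domain_coverage_by_chrom(xdom, asm)
  expect_gt(tab2$percent[tab2$class == "X"],
            tab2$percent[tab2$class == "autosome"])
})
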