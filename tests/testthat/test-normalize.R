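make_counts <- function(v, grid, label = "s") bin_counts(v, grid, label)

test_that("RPM conversion and log2 ratio follow the defining arithmetic", {
  g <- three_bin_grid()
  dam <- make_counts(c(2, 3, 5), g)
  poi <- make_counts(c(2, 3, 5), g)
  p <- merge_and_normalize(dam, poi, pseudocount = 0)
  # counts [2,3,5] scale to RPM [2e5, 3e5, 5e5]; equal samples give ratio 0
  expect_equal(dam$counts * 1e6 / sum(dam$counts), c(2e5, 3e5, 5e5))
  expect_equal(p$value, c(0, 0, 0))
})

test_that("bins without merged Dam reads are masked missing", {
  g <- bin_grid(genome_assembly(c(A = 5000)), 1000)
  dam <- list(make_counts(c(0, 2, 3, 0, 1), g), make_counts(c(0, 1, 1, 2, 0), g))
  poi <- list(make_counts(c(5, 2, 3, 1, 1), g), make_counts(c(4, 1, 1, 1, 0), g))
  p <- merge_and_normalize(dam, poi)
  expect_equal(p$mask, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(is.na(p$value[p$mask])))
  expect_true(all(is.finite(p$value[!p$mask])))
  # zero POI count over covered Dam is a valid strong-negative bin, not missing
  dam2 <- make_counts(c(3, 3, 3, 3, 3), g)
  poi2 <- make_counts(c(0, 3, 3, 3, 3), g)
  p2 <- merge_and_normalize(dam2, poi2)
  expect_false(p2$mask[1])
  expect_lt(p2$value[1], 0)
})

test_that("merging is invariant to replicate order and errors are raised", {
  g <- bin_grid(genome_assembly(c(A = 4000)), 1000)
  r1 <- make_counts(c(1, 2, 3, 4), g); r2 <- make_counts(c(4, 3, 2, 1), g)
  q1 <- make_counts(c(2, 2, 2, 2), g); q2 <- make_counts(c(1, 1, 3, 3), g)
  a <- merge_and_normalize(list(r1, r2), list(q1, q2))
  b <- merge_and_normalize(list(r2, r1), list(q2, q1))
  expect_identical(a$value, b$value)
  expect_error(merge_and_normalize(make_counts(rep(0, 4), g), q1),
               "zero total")
  g2 <- bin_grid(genome_assembly(c(A = 6000)), 1000)
  expect_error(merge_and_normalize(r1, make_counts(rep(1, 6), g2)),
               "grids do not match")
})

test_that("replicate correlation behaves at both extremes", {
  g <- bin_grid(genome_assembly(c(A = 1e7)), 1000)
  withr::local_seed(3)
  v <- rnbinom(g$n_bins, mu = 50, size = 5)
  a <- make_counts(v, g)
  expect_equal(replicate_correlation(a, a), 1)
  b <- make_counts(sample(v), g)
  expect_lt(abs(replicate_correlation(a, b)), 0.1)
})

test_that("replicate correlation follows the shared-signal decomposition", {
  truth <- generate_truth(seed = 21, n_genes = 0)
  # replicates share the planted enrichment; independent counting noise
  # attenuates r as sig^2 / (sig^2 + noise^2), so low overdispersion gives
  # near-perfect correlation and heavy overdispersion drags it down
  sim <- simulate_damid_counts(truth, dispersion = 100, dropout = 0,
                               seed = 22)
  p1 <- merge_and_normalize(sim$dam[[1]], sim$poi[[1]])
  p2 <- merge_and_normalize(sim$dam[[2]], sim$poi[[2]])
  expect_gt(replicate_correlation(p1, p2), 0.8)
  simO <- simulate_damid_counts(truth, dispersion = 5, dropout = 0,
                                seed = 23)
  q1 <- merge_and_normalize(simO$dam[[1]], simO$poi[[1]])
  q2 <- merge_and_normalize(simO$dam[[2]], simO$poi[[2]])
  r_over <- replicate_correlation(q1, q2)
  expect_lt(r_over, replicate_correlation(p1, p2))
  # variance-decomposition prediction at dispersion 5, depth 1e6
  inb <- bins_in_intervals(truth$grid, truth$domains$Lam)
  p <- mean(inb)
  sig2 <- p * (1 - p) * 1.5^2
  mu <- 1e6 / truth$grid$n_bins
  noise2 <- (1 / mu + 1 / (mu * 2^1.5) + 2 / 5) / log(2)^2
  expect_equal(r_over, sig2 / (sig2 + noise2), tolerance = 0.15)
})

test_that("quantile normalization reproduces the mean-quantile reference", {
  g <- three_bin_grid()
  a <- ratio_profile(c(1, 2, 3), g, cell_type = "brain")
  b <- ratio_profile(c(4, 6, 8), g, cell_type = "glia")
  out <- quantile_normalize_profiles(list(a, b))
  expect_equal(out[[1]]$value, c(2.5, 4, 5.5))
  expect_equal(out[[2]]$value, c(2.5, 4, 5.5))
  expect_true(out[[1]]$qnorm)
  # identical inputs are unchanged
  out2 <- quantile_normalize_profiles(list(a, a))
  expect_equal(out2[[1]]$value, a$value)
  expect_warning(quantile_normalize_profiles(list(a)), "identity")
})

test_that("quantile normalization equalizes distributions, keeps masks and ranks", {
  g <- bin_grid(genome_assembly(c(A = 2e5)), 1000)
  withr::local_seed(9)
  v1 <- rnorm(200); v1[sample(200, 17)] <- NA
  v2 <- rnorm(200, 1, 3); v2[sample(200, 11)] <- NA
  out <- quantile_normalize_profiles(list(ratio_profile(v1, g),
                                          ratio_profile(v2, g)))
  s1 <- sort(out[[1]]$value[!out[[1]]$mask])
  s2 <- sort(out[[2]]$value[!out[[2]]$mask])
  # sorted non-missing vectors are (interpolation-)identical across outputs
  expect_lt(max(abs(stats::quantile(s1, 1:19 / 20) -
                    stats::quantile(s2, 1:19 / 20))), 0.05)
  expect_identical(out[[1]]$mask, is.na(v1))
  expect_identical(order(out[[1]]$value[!out[[1]]$mask]),
                   order(v1[!is.na(v1)]))
})

test_that("profile TSV and bedGraph writers round-trip the mask", {
  g <- bin_grid(genome_assembly(c(A = 5000)), 1000)
  p <- ratio_profile(c(0.5, NA, -1, 2, NA), g, poi = "HP1a")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  q <- read_profile_tsv(f, g, poi = "HP1a")
  expect_equal(q$value, p$value)
  expect_equal(q$mask, p$mask)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile_bedgraph(p, bg)
  expect_equal(length(readLines(bg)), 3)  # masked bins omitted
})
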