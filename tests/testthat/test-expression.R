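simple_genes <- function() {
  gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"),
    arm = "A", strand = c("+", "+", "-"),
    start = c(1000, 1999, 5000), end = c(1500, 2500, 6000),
    stringsAsFactors = FALSE))
}

one_domain <- function() {
  list(Lam = domain_set(data.frame(arm = "A", start = 2000, end = 3000),
                        "Lam", "t"))
}

test_that("TSS membership uses half-open single-base containment", {
  genes <- gene_annotation(data.frame(
    gene_id = c("at_start", "one_left", "at_end_edge"),
    arm = "A", strand = "+",
    start = c(2000, 1999, 2999), end = c(2600, 2600, 3600)))
  m <- classify_tss_by_domains(genes, one_domain())
  expect_equal(m$tss_in_Lam, c(TRUE, FALSE, TRUE))
  # body overlap needs >= 1 bp
  g2 <- gene_annotation(data.frame(gene_id = "touch", arm = "A",
                                   strand = "+", start = 3000, end = 3500))
  expect_false(classify_tss_by_domains(g2, one_domain())$body_in_Lam)
})

test_that("minus-strand distal TSS is the 5'-most start on its own strand", {
  g <- gene_annotation(data.frame(gene_id = "m", arm = "A", strand = "-",
                                  start = 5000, end = 6000,
                                  tss_list = "5000,5500,5999"))
  expect_equal(g$tss, 5999)
  gp <- gene_annotation(data.frame(gene_id = "p", arm = "A", strand = "+",
                                   start = 5000, end = 6000,
                                   tss_list = "5000,5500,5999"))
  expect_equal(gp$tss, 5000)
})

test_that("membership agrees with the planted truth labels", {
  truth <- generate_truth(seed = 23, n_genes = 400)
  ex <- simulate_expression(truth, seed = 24)
  m <- classify_tss_by_domains(truth$genes, truth$domains)
  expect_equal(m$tss_in_Lam, ex$in_domain)
  expect_true(all(c("LAD_HP1a", "LAD_only", "LAD_Pc") %in% names(m)))
})

test_that("group comparison summarizes and tests planted differences", {
  withr::local_seed(6)
  tpm <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                    tpm = 2^rnorm(1000, rep(c(1, 4), each = 500), 1.5))
  grp <- data.frame(gene_id = tpm$gene_id,
                    group = rep(c("in", "out"), each = 500))
  res <- expression_comparison(tpm, grp)
  med <- setNames(res$summary$median, res$summary$group)
  expect_lt(med[["in"]], med[["out"]])
  expect_lt(res$pairwise_p["in", "out"], 1e-3)
  # identical groups: exchangeable, p = 1 under the normal approximation
  tpm2 <- data.frame(gene_id = c("a", "b", "c", "d"), tpm = c(1, 2, 1, 2))
  res2 <- expression_comparison(tpm2, c(a = "x", b = "x", c = "y", d = "y"))
  expect_gt(res2$pairwise_p["x", "y"], 0.9)
  expect_error(expression_comparison(tpm, data.frame(gene_id = "none",
                                                     group = "z")),
               "empty group")
  # zero-TPM exclusion changes group sizes
  tpm3 <- data.frame(gene_id = letters[1:6], tpm = c(0, 0, 5, 1, 2, 3))
  grp3 <- setNames(rep(c("u", "v"), each = 3), letters[1:6])
  res3 <- expression_comparison(tpm3, grp3, exclude_zero = TRUE)
  expect_equal(sum(res3$summary$n), 4)
})

test_that("subclass ordering is recovered when planted", {
  # genes in LAD+HP1a lowest, LAD-only intermediate, outside highest
  withr::local_seed(12)
  n <- 300
  cls <- rep(c("LAD_HP1a", "LAD_only", "outside"), each = n)
  tpm <- data.frame(gene_id = sprintf("g%04d", seq_len(3 * n)),
                    tpm = 2^rnorm(3 * n, rep(c(0, 2, 5), each = n), 1.2))
  res <- expression_comparison(tpm, setNames(cls, tpm$gene_id))
  med <- setNames(res$summary$median, res$summary$group)
  expect_lt(med[["LAD_HP1a"]], med[["LAD_only"]])
  expect_lt(med[["LAD_only"]], med[["outside"]])
  expect_lt(res$pairwise_p["LAD_HP1a", "LAD_only"], 0.01)
})

test_that("ubiquitous transcripts need 3 of 4 present calls in all tissues", {
  tissues <- paste0("t", 1:15)
  full_calls <- function(tx, drop_tissue = NULL, present = 4) {
    do.call(rbind, lapply(tissues, function(ti) {
      if (ti %in% drop_tissue) return(NULL)
      k <- if (!is.null(attr(present, "tissue")) &&
               ti == attr(present, "tissue")) attr(present, "n") else present
      data.frame(transcript = tx, tissue = ti, array = 1:4,
                 present = as.integer(1:4 <= k))
    }))
  }
  weak <- structure(4, tissue = "t7", n = 2)
  calls <- rbind(full_calls("tx1"),              # 4/4 everywhere
                 full_calls("tx2", present = weak),  # 2/4 in one tissue
                 full_calls("tx3"),              # qualifies
                 full_calls("tx4", drop_tissue = "t3"))  # missing tissue
  map <- data.frame(transcript = c("tx1", "tx2", "tx3", "tx4"),
                    gene_id = c("gA", "gB", "gC", "gC"))
  expect_message(ub <- ubiquitous_genes(calls, map), "missing tissues")
  expect_true("gA" %in% ub)
  expect_false("gB" %in% ub)
  expect_true("gC" %in% ub)  # one qualifying transcript suffices
})

test_that("adding present calls never removes a gene (monotonicity)", {
  tissues <- paste0("t", 1:15)
  withr::local_seed(31)
  base <- do.call(rbind, lapply(tissues, function(ti)
    data.frame(transcript = "tx", tissue = ti, array = 1:4,
               present = as.integer(runif(4) < 0.7))))
  map <- data.frame(transcript = "tx", gene_id = "g")
  before <- ubiquitous_genes(base, map)
  more <- base
  more$present <- pmax(more$present, as.integer(runif(nrow(more)) < 0.5))
  after <- ubiquitous_genes(more, map)
  expect_true(all(before %in% after))
})

test_that("tissue-specific lists subtract the ubiquitous genes", {
  tpm <- data.frame(gene_id = c("a", "b", "c", "d"),
                    tpm = c(0.99, 1, 50, 0))
  expect_equal(tissue_specific_genes(tpm, ubiquitous = "c"), "b")
  expect_equal(tissue_specific_genes(tpm, ubiquitous = character(0)),
               c("b", "c"))
})

test_that("expression strata follow the published TPM cutoffs", {
  tpm <- data.frame(gene_id = paste0("g", 1:6),
                    tpm = c(0.5, 1, 9.9, 10, 44, 45))
  gr <- expression_groups(tpm, cutoffs = c(1, 10, 44))
  expect_equal(as.character(gr$group),
               c("silent", "low", "low", "medium", "medium", "high"))
  # data-driven mode balances the three expressed strata
  withr::local_seed(2)
  tpm2 <- data.frame(gene_id = sprintf("g%04d", 1:500),
                     tpm = c(runif(100), 2^runif(400, 0, 8)))
  gr2 <- expression_groups(tpm2, data_driven = TRUE)
  sizes <- table(gr2$group)[c("low", "medium", "high")]
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("metagene medians respect orientation and bin filters", {
  g <- bin_grid(genome_assembly(c(A = 30000)), 1000)
  genes <- gene_annotation(data.frame(
    gene_id = "plus", arm = "A", strand = "+", start = 10100, end = 14500))
  flat <- ratio_profile(rep(0.7, 30), g)
  m <- metagene_profile(flat, genes, domains = NULL)
  expect_equal(as.numeric(m), rep(0.7, 7))
  # an asymmetric profile mirror-reverses for a minus-strand gene
  v <- seq(0.1, 3.0, by = 0.1)
  prof <- ratio_profile(v, g)
  minus <- gene_annotation(data.frame(
    gene_id = "minus", arm = "A", strand = "-", start = 15500, end = 19900))
  mm <- metagene_profile(prof, minus, domains = NULL)
  # TSS at 19899 -> bin 20; gene offsets +1.. run to lower genomic bins
  expect_equal(as.numeric(mm), v[c(23, 22, 21, 20, 19, 18, 17)])
  # upstream bins covered by another gene are dropped
  blocker <- gene_annotation(data.frame(
    gene_id = c("plus", "up_nb"), arm = "A", strand = "+",
    start = c(10100, 7000), end = c(14500, 9500)))
  mb <- metagene_profile(prof, blocker[1, ], domains = NULL)
  m_with <- metagene_profile(prof, blocker, domains = NULL)
  expect_true(is.na(m_with[["-3"]]) || m_with[["-3"]] != mb[["-3"]])
  expect_error(metagene_profile(flat, genes,
                                domains = domain_set(
                                  data.frame(arm = "A", start = 0, end = 100),
                                  "Lam", "t")),
               "no qualifying genes")
})

test_that("a planted TSS dip lands in the central metagene bin", {
  truth <- generate_truth(seed = 51, n_genes = 300)
  g <- truth$grid
  dom_bins <- bins_in_intervals(g, truth$domains$Lam)
  v <- ifelse(dom_bins, 1, 0.5)
  # carve a dip at each gene TSS bin
  genes <- gene_annotation(truth$genes)
  for (i in seq_len(nrow(genes))) {
    b <- g$offset[[genes$arm[i]]] + floor(genes$tss[i] / g$bin_width) + 1
    v[b] <- v[b] - 1
  }
  prof <- ratio_profile(v, g, poi = "Lam")
  m <- metagene_profile(prof, genes, domains = truth$domains$Lam)
  expect_equal(names(which.min(m)), "0")
  # half_window = 0 reduces to the TSS-bin median
  m0 <- metagene_profile(prof, genes, domains = truth$domains$Lam,
                         half_window = 0)
  expect_length(m0, 1)
  expect_equal(as.numeric(m0), as.numeric(m["0"]))
})

test_that("DE summaries tally direct targets by body overlap", {
  doms <- list(
    HP1a = domain_set(data.frame(arm = "A", start = 0, end = 2000),
                      "HP1a", "t"),
    Lam = domain_set(data.frame(arm = "A", start = 5000, end = 7000),
                     "Lam", "t"))
  genes <- gene_annotation(data.frame(
    gene_id = paste0("g", 1:5), arm = "A", strand = "+",
    start = c(100, 1500, 5100, 8000, 9000),
    end = c(900, 2600, 6200, 8800, 9900)))
  de <- data.frame(gene_id = paste0("g", 1:5),
                   log2fc = c(1.5, -0.5, 2.5, -3, 0.2),
                   adj_p = c(0.01, 0.04, 0.2, 0.001, 0.03))
  tab <- de_domain_summary(de, genes, doms)
  get <- function(cl) tab[tab$class == cl, ]
  # significant: g1, g2, g4, g5 (g3 fails p); bodies: g1,g2 in HP1a; none in Lam
  expect_equal(get("body_in_HP1a")$n, 2)
  expect_equal(get("body_in_HP1a")$up, 1)
  expect_equal(get("body_in_HP1a")$down, 1)
  expect_equal(get("body_in_Lam")$n, 0)
  expect_equal(get("none")$n, 2)
  # fold filter keeps only |fc| > 2
  tab2 <- de_domain_summary(de, genes, doms, fold_cutoff = 2)
  expect_equal(tab2[tab2$class == "none", "n"], 1)
  # empty table
  tab0 <- de_domain_summary(de[0, ], genes, doms)
  expect_true(all(tab0$n == 0))
})
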