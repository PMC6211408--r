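#' Generate a planted domain architecture with genes
#'
#' Builds the ground truth every downstream stage is tested against: LADs
#' (Lam), HP1a and Pc domains planted on the euchromatic analysis windows of
#' an assembly, plus gene annotations. Domain lengths are geometric in bins
#' (mean `mean_len_bins`); gaps between domains are geometric with the mean
#' implied by the coverage target, so realized coverage fluctuates around
#' the target. A configurable fraction of total HP1a domain length is
#' planted inside LADs to emulate the strong HP1a/LAD overlap of
#' differentiated cells.
#'
#' All randomness derives from `seed`; the same configuration and seed
#' reproduce the truth exactly.
#'
#' @param assembly a `GenomeAssembly` (default: [toy_assembly()], two 5-Mb
#'   arms plus a 500-kb CHet arm).
#' @param bin_width bin width in bp.
#' @param coverage named vector of target coverage fractions in (0,1) per
#'   POI over the ChA windows.
#' @param hp1a_in_lad design fraction in [0,1] of HP1a domain length planted
#'   inside LADs.
#' @param hp1a_host_fraction fraction of total LAD length eligible to host
#'   HP1a domains: HP1a concentrates in a subset of LADs, so a substantial
#'   HP1a-free LAD class remains (as in real cell types, where HP1a covers
#'   only part of total LAD length even when most HP1a lies inside LADs).
#' @param mean_len_bins named vector of mean domain lengths in bins.
#' @param n_genes number of genes to place.
#' @param n_tes default number of TE insertions for [simulate_tes()].
#' @param seed integer seed (mandatory).
#' @return a `SyntheticTruth`: assembly, grid, `domains` (list of
#'   `DomainSet` per POI), `genes` (annotation data.frame), and `params`.
#' @export
generate_truth <- function(assembly = toy_assembly(), bin_width = 1000,
                           coverage = c(Lam = 0.4, HP1a = 0.15, Pc = 0.15),
                           hp1a_in_lad = 0.8, hp1a_host_fraction = 0.5,
                           mean_len_bins = c(Lam = 50, HP1a = 10, Pc = 10),
                           n_genes = 1000, n_tes = 3000, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (any(coverage <= 0) || any(coverage >= 1))
    stop("coverage targets must lie in (0, 1)")
  if (hp1a_in_lad < 0 || hp1a_in_lad > 1)
    stop("hp1a_in_lad must lie in [0, 1]")
  if (any(mean_len_bins < 1)) stop("mean domain length must be >= 1 bin")
  grid <- bin_grid(assembly, bin_width)
  win <- cha_windows(assembly)
  withr::with_seed(seed, {
    lam <- .plant_alternating(win, bin_width, coverage[["Lam"]],
                              mean_len_bins[["Lam"]])
    hp1a <- .plant_conditional(win, bin_width, coverage[["HP1a"]],
                               mean_len_bins[["HP1a"]], lam, hp1a_in_lad,
                               hp1a_host_fraction)
    pc <- .plant_alternating(win, bin_width, coverage[["Pc"]],
                             mean_len_bins[["Pc"]])
    genes <- .plant_genes(win, n_genes)
  })
  structure(list(
    assembly = assembly, grid = grid,
    domains = list(
      Lam = domain_set(lam, "Lam", "synthetic", assembly),
      HP1a = domain_set(hp1a, "HP1a", "synthetic", assembly),
      Pc = domain_set(pc, "Pc", "synthetic", assembly)),
    genes = genes,
    params = list(coverage = coverage, hp1a_in_lad = hp1a_in_lad,
                  hp1a_host_fraction = hp1a_host_fraction,
                  mean_len_bins = mean_len_bins, bin_width = bin_width,
                  n_genes = n_genes, n_tes = n_tes, seed = seed)),
    class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth (seed ", x$params$seed, "):\n", sep = "")
  win <- cha_windows(x$assembly)
  for (p in names(x$domains)) {
    cat(sprintf("  %-5s %4d domains, coverage %.3f of ChA windows\n", p,
                nrow(x$domains[[p]]),
                coverage_fraction(x$domains[[p]], win)))
  }
  cat(" ", nrow(x$genes), "genes\n")
  invisible(x)
}

# A mutable pool of disjoint bin-unit intervals supporting sequential
# packing: place a domain of `len` bins at a uniform valid position, then
# remove it (plus a 1-bin buffer) from the pool so later domains cannot
# touch it. Intervals are data.frame(arm, s, e) in bins (arm-local).
.pool_place <- function(pool, len, weight = c("position", "interval")) {
  weight <- match.arg(weight)
  cap <- pool$e - pool$s
  fits <- cap >= len
  if (!any(fits)) {
    # no interval can hold it: truncate into the largest remaining interval
    i <- which.max(cap)
    if (cap[i] < 1) return(NULL)
    len <- cap[i]
  } else {
    prob <- if (weight == "position") ifelse(fits, cap - len + 1, 0)
            else as.numeric(fits)
    i <- sample.int(nrow(pool), 1, prob = prob)
  }
  at <- pool$s[i] + floor(stats::runif(1) * (pool$e[i] - pool$s[i] - len + 1))
  placed <- data.frame(arm = pool$arm[i], s = at, e = at + len,
                       stringsAsFactors = FALSE)
  left <- data.frame(arm = pool$arm[i], s = pool$s[i], e = at - 1)
  right <- data.frame(arm = pool$arm[i], s = at + len + 1, e = pool$e[i])
  repl <- rbind(left, right)
  repl <- repl[repl$e - repl$s >= 1, , drop = FALSE]
  list(placed = placed, pool = rbind(pool[-i, , drop = FALSE], repl))
}

.win_bin_pool <- function(win, bw) {
  n_bins <- floor((win$end - win$start) / bw)
  data.frame(arm = win$arm, s = 0, e = n_bins, stringsAsFactors = FALSE)
}

.bins_to_bp <- function(placed, win, bw) {
  w0 <- stats::setNames(win$start, win$arm)
  data.frame(arm = placed$arm,
             start = w0[placed$arm] + placed$s * bw,
             end = w0[placed$arm] + placed$e * bw, stringsAsFactors = FALSE)
}

# Plant domains totalling ~cov of the windows, geometric lengths, by
# sequential packing: lengths are drawn until the target total is reached
# (last one trimmed), so realized coverage tracks the target to within one
# domain length.
.plant_alternating <- function(win, bw, cov, mean_len) {
  pool <- .win_bin_pool(win, bw)
  target <- round(cov * sum(pool$e - pool$s))
  placed <- list()
  got <- 0
  while (got < target && nrow(pool)) {
    len <- min(stats::rgeom(1, 1 / mean_len) + 1, target - got)
    hit <- .pool_place(pool, len)
    if (is.null(hit)) break
    placed[[length(placed) + 1]] <- hit$placed
    pool <- hit$pool
    got <- got + hit$placed$e - hit$placed$s
  }
  if (!length(placed)) return(interval_set(empty_intervals()))
  interval_set(.bins_to_bp(do.call(rbind, placed), win, bw))
}

# Plant domains with a design fraction of total length inside host
# domains; a greedy length quota keeps the realized inside fraction tight.
.plant_conditional <- function(win, bw, cov, mean_len, host, frac_in_host,
                               host_fraction = 1) {
  host <- clip_to_region(host, interval_set(win))
  w0 <- stats::setNames(win$start, win$arm)
  host_bins <- data.frame(arm = host$arm,
                          s = round((host$start - w0[host$arm]) / bw),
                          e = round((host$end - w0[host$arm]) / bw),
                          stringsAsFactors = FALSE)
  full <- .win_bin_pool(win, bw)
  pool_in <- host_bins
  if (host_fraction < 1 && nrow(host_bins)) {
    # only a random subset of hosts (by length) is eligible, so a
    # substantial host-free class remains
    ord <- sample.int(nrow(host_bins))
    cum <- cumsum(host_bins$e[ord] - host_bins$s[ord])
    keep <- ord[seq_len(which(cum >= host_fraction * sum(
      host_bins$e - host_bins$s))[1])]
    pool_in <- host_bins[sort(keep), , drop = FALSE]
  }
  gaps <- interval_setdiff(interval_set(win), host)
  pool_out <- data.frame(arm = gaps$arm,
                         s = round((gaps$start - w0[gaps$arm]) / bw),
                         e = round((gaps$end - w0[gaps$arm]) / bw),
                         stringsAsFactors = FALSE)
  target <- round(cov * sum(full$e - full$s))
  placed <- list()
  got_in <- 0; got_out <- 0
  while (got_in + got_out < target) {
    len <- min(stats::rgeom(1, 1 / mean_len) + 1,
               target - got_in - got_out)
    inside <- got_in < frac_in_host * (got_in + got_out + len)
    pool <- if (inside) pool_in else pool_out
    if (!nrow(pool)) break
    # hosts are chosen uniformly per interval (each LAD an equally likely
    # nucleation site), so bound and free hosts stay length-comparable
    hit <- .pool_place(pool, len, weight = if (inside) "interval"
                                          else "position")
    if (is.null(hit)) break
    placed[[length(placed) + 1]] <- hit$placed
    glen <- hit$placed$e - hit$placed$s
    if (inside) { pool_in <- hit$pool; got_in <- got_in + glen }
    else { pool_out <- hit$pool; got_out <- got_out + glen }
  }
  if (!length(placed)) return(interval_set(empty_intervals()))
  interval_set(.bins_to_bp(do.call(rbind, placed), win, bw))
}

.plant_genes <- function(win, n_genes) {
  if (n_genes == 0)
    return(data.frame(gene_id = character(), arm = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), tss = numeric(),
                      tss_list = character(), stringsAsFactors = FALSE))
  wlen <- win$end - win$start
  arm_i <- sample.int(nrow(win), n_genes, replace = TRUE, prob = wlen)
  len <- pmin(pmax(round(stats::rlnorm(n_genes, log(3000), 0.6)), 500), 30000)
  start <- win$start[arm_i] +
    floor(stats::runif(n_genes) * pmax(wlen[arm_i] - len, 1))
  end <- start + len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1)
  extra_n <- sample(0:2, n_genes, replace = TRUE)
  tss_list <- vapply(seq_len(n_genes), function(i) {
    alt <- if (extra_n[i] > 0)
      start[i] + sort(sample.int(len[i] - 1, extra_n[i]))
    else numeric(0)
    paste(sort(unique(c(tss[i], alt))), collapse = ",")
  }, "")
  data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
             arm = win$arm[arm_i], strand = strand, start = start, end = end,
             tss = tss, tss_list = tss_list, stringsAsFactors = FALSE)
}

#' Simulate replicate DamID bin counts from a planted truth
#'
#' Dam counts are negative binomial with mean `depth / n_bins` and size
#' `dispersion` in every bin; Dam-POI counts share that mean outside planted
#' domains and are enriched by `2^delta` inside. A `dropout` fraction of
#' bins is set to zero Dam counts in every replicate, exercising the
#' missing-bin path of normalization and segmentation.
#'
#' @param truth a `SyntheticTruth`.
#' @param poi which planted domain set drives the enrichment.
#' @param cell_type label carried to the samples.
#' @param depth expected total Dam read count per replicate.
#' @param n_replicates replicates per sample.
#' @param delta log2 enrichment inside domains (>= 0).
#' @param dispersion NB size parameter.
#' @param dropout fraction of bins forced to zero Dam counts.
#' @param seed integer seed.
#' @return list with `dam` and `poi` (lists of `BinCounts`), the truth
#'   `domain_bins` mask, and the simulation parameters.
#' @export
simulate_damid_counts <- function(truth, poi = "Lam",
                                  cell_type = "synthetic", depth = 1e6,
                                  n_replicates = 2, delta = 1.5,
                                  dispersion = 5, dropout = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(inherits(truth, "SyntheticTruth"), depth > 0, delta >= 0,
            dropout >= 0, dropout < 1)
  grid <- truth$grid
  domain_bins <- bins_in_intervals(grid, truth$domains[[poi]])
  n <- grid$n_bins
  mu0 <- depth / n
  mu_poi <- ifelse(domain_bins, mu0 * 2^delta, mu0)
  withr::with_seed(seed, {
    drop_idx <- if (dropout > 0) sample.int(n, round(dropout * n)) else integer(0)
    dam <- lapply(seq_len(n_replicates), function(r) {
      cts <- stats::rnbinom(n, mu = mu0, size = dispersion)
      cts[drop_idx] <- 0
      bin_counts(cts, grid, sprintf("Dam_%s_rep%d", cell_type, r))
    })
    poi_s <- lapply(seq_len(n_replicates), function(r) {
      bin_counts(stats::rnbinom(n, mu = mu_poi, size = dispersion), grid,
                 sprintf("Dam-%s_%s_rep%d", poi, cell_type, r))
    })
  })
  list(dam = dam, poi = poi_s, domain_bins = domain_bins,
       params = list(poi = poi, cell_type = cell_type, depth = depth,
                     n_replicates = n_replicates, delta = delta,
                     dispersion = dispersion, dropout = dropout,
                     seed = seed))
}

#' Simulate a TPM expression table anticorrelated with domain membership
#'
#' Genes whose distal TSS lies inside a planted domain draw their log2 TPM
#' from the low-mean component; all others from the high-mean component.
#'
#' @param truth a `SyntheticTruth`.
#' @param in_mean,out_mean mean log2 TPM inside / outside domains.
#' @param sd log2 TPM standard deviation.
#' @param poi which planted domain set defines membership.
#' @param seed integer seed.
#' @return data.frame with `gene_id`, `tpm`, and the truth label
#'   `in_domain`.
#' @export
simulate_expression <- function(truth, in_mean = 1, out_mean = 4, sd = 1.5,
                                poi = "Lam", seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(is.finite(in_mean), is.finite(out_mean), sd > 0)
  g <- truth$genes
  if (!nrow(g))
    return(data.frame(gene_id = character(), tpm = numeric(),
                      in_domain = logical(), stringsAsFactors = FALSE))
  flat <- .flatten_by_arm(truth$domains[[poi]])
  in_dom <- vapply(seq_len(nrow(g)), function(i) {
    f <- flat[[g$arm[i]]]
    !is.null(f) && .flat_overlap_len(f, g$tss[i], g$tss[i] + 1) > 0
  }, logical(1))
  withr::with_seed(seed, {
    mu <- ifelse(in_dom, in_mean, out_mean)
    tpm <- 2^stats::rnorm(nrow(g), mu, sd)
  })
  data.frame(gene_id = g$gene_id, tpm = tpm, in_domain = in_dom,
             stringsAsFactors = FALSE)
}

#' Simulate TE insertions enriched near HP1a-bound LADs
#'
#' TE placement density inside (and within `flank_bp` of) HP1a-bound LADs is
#' `enrichment_factor` times the background density elsewhere on the ChA
#' windows; HP1a-free LADs receive background density, so the downstream
#' occupancy ratio recovers the planted factor.
#'
#' @param truth a `SyntheticTruth`.
#' @param n_tes number of insertions.
#' @param enrichment_factor placement density ratio (>= 1).
#' @param flank_bp how far the enriched neighbourhood extends beyond bound
#'   LADs.
#' @param te_length insertion length in bp.
#' @param seed integer seed.
#' @return a `TEInsertionSet` restricted to the ChA windows.
#' @export
simulate_tes <- function(truth, n_tes = truth$params$n_tes,
                         enrichment_factor = 2, flank_bp = 500,
                         te_length = 500, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(enrichment_factor >= 1, flank_bp >= 0, te_length >= 1)
  win <- cha_windows(truth$assembly)
  split <- split_lads_by_hp1a(truth$domains$Lam, truth$domains$HP1a)
  near <- clip_to_region(expand_intervals(split$bound, flank_bp,
                                          truth$assembly), win)
  far <- interval_setdiff(win, near)
  pools <- list(near = near, far = far)
  wts <- c(near = enrichment_factor * total_length(near),
           far = total_length(far))
  withr::with_seed(seed, {
    cls <- sample(c("near", "far"), n_tes, replace = TRUE, prob = wts)
    pos <- numeric(n_tes); arm <- character(n_tes)
    for (cl in c("near", "far")) {
      idx <- which(cls == cl)
      if (!length(idx)) next
      hit <- .uniform_positions(pools[[cl]], length(idx))
      arm[idx] <- hit$arm
      pos[idx] <- hit$pos
    }
  })
  end <- pmin(pos + te_length, truth$assembly$lengths[arm])
  te_insertion_set(data.frame(arm = arm, start = pos, end = end,
                              stringsAsFactors = FALSE))
}

# Sample n positions uniformly over the bases of an interval set.
.uniform_positions <- function(x, n) {
  stopifnot(NROW(x) > 0)
  len <- x$end - x$start
  cum <- c(0, cumsum(len))
  u <- stats::runif(n) * cum[length(cum)]
  i <- findInterval(u, cum, rightmost.closed = TRUE)
  i[i > NROW(x)] <- NROW(x)
  list(arm = x$arm[i], pos = floor(x$start[i] + (u - cum[i])))
}

#' Score called domains against a planted truth
#'
#' Bin-level precision/recall/F1 of the called domains versus the planted
#' ones, plus the median absolute boundary error: for every planted domain
#' edge, the distance to the nearest called edge of the same side
#' (start-to-start, end-to-end).
#'
#' @param called a `DomainSet` from [decode_domains()].
#' @param truth_domains the planted `DomainSet`.
#' @param grid the `BinGrid` both live on.
#' @return list with `precision`, `recall`, `f1`,
#'   `median_boundary_error_bp`, and the confusion counts.
#' @export
domain_recovery_stats <- function(called, truth_domains, grid) {
  cb <- bins_in_intervals(grid, called)
  tb <- bins_in_intervals(grid, truth_domains)
  tp <- sum(cb & tb); fp <- sum(cb & !tb); fn <- sum(!cb & tb)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  berr <- NA_real_
  if (nrow(called) && nrow(truth_domains)) {
    err <- unlist(lapply(unique(truth_domains$arm), function(arm) {
      tr <- truth_domains[truth_domains$arm == arm, , drop = FALSE]
      ca <- called[called$arm == arm, , drop = FALSE]
      if (!nrow(ca)) return(NULL)
      c(vapply(tr$start, function(s) min(abs(ca$start - s)), numeric(1)),
        vapply(tr$end, function(e) min(abs(ca$end - e)), numeric(1)))
    }))
    if (length(err)) berr <- stats::median(err)
  }
  list(precision = precision, recall = recall, f1 = f1,
       median_boundary_error_bp = berr,
       tp = tp, fp = fp, fn = fn)
}

#' Write a synthetic truth to disk
#'
#' Emits per-POI planted-domain BEDs, a gene TSV and a params JSON, in the
#' formats the readers of this package consume, so recovery can be scored
#' from files alone.
#'
#' @param truth a `SyntheticTruth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(truth$domains)) {
    write_bed(truth$domains[[p]], file.path(dir, paste0("truth_", p, ".bed")),
              header = paste0("planted ", p, " domains (synthetic)"))
  }
  utils::write.table(truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth$params, file.path(dir, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
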