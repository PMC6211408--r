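#' Fraction of a region covered by domains
#'
#' @param domains a `DomainSet` or `IntervalSet`.
#' @param region an `IntervalSet` (e.g. the ChA windows).
#' @return `len(domains intersect region) / len(region)`.
#' @export
coverage_fraction <- function(domains, region) {
  region <- interval_set(region)
  if (!nrow(region)) stop("empty region")
  total_length(interval_intersect(domains, region)) / total_length(region)
}

#' Pairwise overlap statistics between two domain sets over a region
#'
#' Both sets are clipped to the region first; the intersection length is
#' reported in bp and as percentages of each set's clipped length and of
#' the region length.
#'
#' @param a,b `DomainSet`s (or `IntervalSet`s).
#' @param region an `IntervalSet`.
#' @return an `OverlapStats` list: `length_bp`, `pct_of_a`, `pct_of_b`,
#'   `pct_of_region`.
#' @export
overlap_stats <- function(a, b, region) {
  region <- interval_set(region)
  if (!nrow(region)) stop("empty region")
  a <- clip_to_region(a, region)
  b <- clip_to_region(b, region)
  if (!nrow(a) || !nrow(b))
    warning("empty domain set after clipping: percentages reported as 0")
  ab <- total_length(interval_intersect(a, b))
  la <- total_length(a); lb <- total_length(b)
  structure(list(
    length_bp = ab,
    pct_of_a = if (la > 0) 100 * ab / la else 0,
    pct_of_b = if (lb > 0) 100 * ab / lb else 0,
    pct_of_region = 100 * ab / total_length(region)),
    class = "OverlapStats")
}

#' @export
print.OverlapStats <- function(x, ...) {
  cat(sprintf(
    "Overlap: %s bp = %.1f%% of A, %.1f%% of B, %.2f%% of region\n",
    format(x$length_bp, big.mark = ","), x$pct_of_a, x$pct_of_b,
    x$pct_of_region))
  invisible(x)
}

#' Regions conserved across cell types
#'
#' Conserved domains are the bases inside the domain set of every cell
#' type (strict intersection, clipped to the region); conserved
#' inter-domains are the bases outside every set. A k-of-n relaxation is
#' available via `min_sets`.
#'
#' @param domain_sets list of `DomainSet`s, one per cell type.
#' @param region an `IntervalSet`.
#' @param min_sets number of sets a base must fall in (out of n) to count
#'   as conserved domain; default `length(domain_sets)` (all).
#' @return list with `domains` and `inter_domains` (`IntervalSet`s).
#' @export
conserved_regions <- function(domain_sets, region,
                              min_sets = length(domain_sets)) {
  stopifnot(length(domain_sets) >= 2)
  region <- interval_set(region)
  clipped <- lapply(domain_sets, clip_to_region, region = region)
  n <- length(clipped)
  if (min_sets >= n) {
    doms <- Reduce(interval_intersect, clipped)
  } else {
    # count per-base membership via coverage on a shared seqinfo
    lv <- unique(region$arm)
    sl <- vapply(lv, function(a) max(region$end[region$arm == a]),
                 numeric(1))
    grl <- lapply(clipped, function(d) {
      gr <- .is_to_gr(d, lv)
      GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
      gr
    })
    cov <- Reduce(`+`, lapply(grl, GenomicRanges::coverage))
    hit <- IRanges::slice(cov, lower = min_sets, rangesOnly = TRUE)
    df <- do.call(rbind, lapply(names(hit), function(arm) {
      r <- hit[[arm]]
      if (!length(r)) return(NULL)
      data.frame(arm = arm, start = IRanges::start(r) - 1,
                 end = IRanges::end(r), stringsAsFactors = FALSE)
    }))
    doms <- clip_to_region(
      interval_set(if (is.null(df)) empty_intervals() else df), region)
  }
  inter <- Reduce(interval_intersect,
                  lapply(clipped, interval_complement, region = region))
  list(domains = doms, inter_domains = inter)
}

#' Permutation test for overlap between two interval sets
#'
#' `b` is held fixed. In each permutation every element of `a` is
#' independently re-placed uniformly among the positions of its own arm's
#' region that can hold it, preserving its length; shuffled elements may
#' overlap one another. The statistic is either the summed bp overlap with
#' `b` or the number of `a` elements overlapping `b` by at least 1 bp. The
#' empirical p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)` for enrichment
#' (`alternative = "greater"`); the depletion side counts `null <= observed`.
#'
#' @param a,b `IntervalSet`s (or `DomainSet`s); clipped to `region`.
#' @param region an `IntervalSet` defining where elements may land.
#' @param statistic "overlap-length" or "count".
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alternative "greater" (enrichment) or "less" (depletion).
#' @return a `PermutationResult`: observed, null_mean, enrichment
#'   (observed / null mean), p, n_perm, seed.
#' @export
permutation_overlap_test <- function(a, b, region,
                                     statistic = c("overlap-length", "count"),
                                     n_perm = 10000, seed = 1,
                                     alternative = c("greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  region <- interval_set(region)
  a <- interval_set(a)
  # an element that no region interval on its own arm can hold is a design
  # error, caught before clipping would silently fragment it
  for (k in seq_len(nrow(a))) {
    ra <- region[region$arm == a$arm[k], , drop = FALSE]
    if (nrow(ra) && max(ra$end - ra$start) < a$end[k] - a$start[k])
      stop("element ", k, " (", a$end[k] - a$start[k], " bp) is longer ",
           "than any region interval on arm ", a$arm[k])
  }
  a <- clip_to_region(a, region)
  b <- clip_to_region(interval_set(b), region)
  if (!nrow(a)) stop("no elements of `a` inside the region")
  flat_b <- .flatten_by_arm(b)
  reg_by_arm <- split(region[, c("start", "end")], region$arm)

  elem_overlap <- function(arm, s, e) {
    f <- flat_b[[arm]]
    if (is.null(f)) return(numeric(length(s)))
    .flat_overlap_len(f, s, e)
  }
  obs_per_elem <- elem_overlap_all(a, elem_overlap)
  observed <- if (statistic == "count") sum(obs_per_elem > 0)
              else sum(obs_per_elem)

  null_stat <- numeric(n_perm)
  withr::with_seed(seed, {
    for (k in seq_len(nrow(a))) {
      arm <- a$arm[k]
      L <- a$end[k] - a$start[k]
      segs <- reg_by_arm[[arm]]
      npos <- pmax(segs$end - segs$start - L + 1, 0)
      if (sum(npos) == 0)
        stop("element ", k, " (", L, " bp) is longer than any region ",
             "interval on arm ", arm)
      seg_i <- sample.int(nrow(segs), n_perm, replace = TRUE, prob = npos)
      s <- segs$start[seg_i] +
        floor(stats::runif(n_perm) * npos[seg_i])
      ov <- elem_overlap(arm, s, s + L)
      null_stat <- null_stat +
        if (statistic == "count") as.numeric(ov > 0) else ov
    }
  })
  extreme <- if (alternative == "greater") sum(null_stat >= observed)
             else sum(null_stat <= observed)
  structure(list(observed = observed, null_mean = mean(null_stat),
                 enrichment = observed / mean(null_stat),
                 p = (1 + extreme) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, statistic = statistic,
                 alternative = alternative),
            class = "PermutationResult")
}

# observed per-element overlap lengths with b (helper shared with the null)
elem_overlap_all <- function(a, elem_overlap) {
  vapply(seq_len(nrow(a)),
         function(k) elem_overlap(a$arm[k], a$start[k], a$end[k]),
         numeric(1))
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s): observed %.4g, null mean %.4g, ",
    x$statistic, x$alternative, x$observed, x$null_mean),
    sprintf("enrichment %.3g, p = %.4g (n_perm = %d)\n",
            x$enrichment, x$p, x$n_perm), sep = "")
  invisible(x)
}

#' Serialize a permutation result to JSON (including the seed, for replay)
#'
#' @param x a `PermutationResult`.
#' @param path output path.
#' @export
write_permutation_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' X-versus-autosome shift of profile values
#'
#' Compares non-missing log2 ratio values on the X-chromosome ChA window
#' against the pooled autosomal ChA windows with a two-sided Mann-Whitney
#' U test (normal approximation with tie correction). The 4th chromosome
#' is excluded from the autosome pool by default, since its domain pattern
#' differs from the major arms.
#'
#' @param profile a `RatioProfile`.
#' @param assembly a `GenomeAssembly` with `x_arms` set; defaults to the
#'   profile grid's assembly.
#' @param exclude_chr4 drop chr4 arms from the autosome pool.
#' @return list with `p`, `median_x`, `median_autosomes`, `shift`
#'   (median difference, X minus autosomes), group sizes and the two value
#'   vectors.
#' @export
chrom_profile_shift_test <- function(profile,
                                     assembly = profile$grid$assembly,
                                     exclude_chr4 = TRUE) {
  if (!length(assembly$x_arms)) stop("assembly defines no X arm")
  grid <- profile$grid
  x_win <- assembly$cha_windows$arm %in% assembly$x_arms
  if (!any(x_win)) stop("no ChA window on the X chromosome")
  auto_arms <- setdiff(assembly$cha_windows$arm, assembly$x_arms)
  if (exclude_chr4) auto_arms <- setdiff(auto_arms, assembly$chr4_arms)
  xv <- profile$value[bins_in_intervals(grid, cha_windows(assembly,
                                                          assembly$x_arms))]
  av <- profile$value[bins_in_intervals(grid, cha_windows(assembly,
                                                          auto_arms))]
  xv <- xv[!is.na(xv)]; av <- av[!is.na(av)]
  if (!length(xv) || !length(av)) stop("empty value group")
  w <- stats::wilcox.test(xv, av, alternative = "two.sided", exact = FALSE,
                          correct = TRUE)
  list(p = w$p.value, statistic = unname(w$statistic),
       median_x = stats::median(xv), median_autosomes = stats::median(av),
       shift = stats::median(xv) - stats::median(av),
       n_x = length(xv), n_autosomes = length(av),
       values = list(X = xv, autosomes = av))
}

#' Per-chromosome domain coverage
#'
#' Coverage of each arm's ChA window by the domains, as percent of window
#' length, with the arm's region class (X / autosome / chr4).
#'
#' @param domains a `DomainSet`.
#' @param assembly a `GenomeAssembly`.
#' @return data.frame with `arm`, `percent`, `class`.
#' @export
domain_coverage_by_chrom <- function(domains, assembly) {
  w <- assembly$cha_windows
  pct <- vapply(seq_len(nrow(w)), function(i) {
    100 * coverage_fraction(domains, interval_set(w[i, , drop = FALSE]))
  }, numeric(1))
  cls <- ifelse(w$arm %in% assembly$x_arms, "X",
                ifelse(w$arm %in% assembly$chr4_arms, "chr4", "autosome"))
  data.frame(arm = w$arm, percent = pct, class = cls,
             stringsAsFactors = FALSE)
}
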