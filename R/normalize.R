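#' Per-bin read counts for one sample
#'
#' @param counts non-negative integer vector, one value per bin of `grid`.
#' @param grid a `BinGrid`.
#' @param label sample label.
#' @return a `BinCounts` object.
#' @export
bin_counts <- function(counts, grid, label = "sample") {
  stopifnot(inherits(grid, "BinGrid"))
  if (length(counts) != grid$n_bins)
    stop("counts length (", length(counts), ") does not match grid (",
         grid$n_bins, " bins)")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  structure(list(counts = as.numeric(counts), grid = grid, label = label),
            class = "BinCounts")
}

#' Read a bin-count TSV (arm, start, end, count) aligned to a grid
#'
#' @param path TSV path with a header.
#' @param grid a `BinGrid` the rows must match bin-for-bin.
#' @param label sample label (defaults to the file name).
#' @return a `BinCounts`.
#' @export
read_bin_counts <- function(path, grid, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("arm", "start", "end", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bt <- bin_table(grid)
  if (nrow(df) != nrow(bt) || !all(df$arm == bt$arm) ||
      !all(df$start == bt$start))
    stop("count table rows do not align with the bin grid")
  bin_counts(df$count, grid, label)
}

#' Write bin counts as TSV
#' @param x a `BinCounts`.
#' @param path output path.
#' @export
write_bin_counts <- function(x, path) {
  df <- bin_table(x$grid)
  df$count <- as.integer(x$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation between two samples over shared usable bins
#'
#' For `RatioProfile`s the correlation runs over bins non-missing in both;
#' for `BinCounts` over all bins.
#'
#' @param a,b two `BinCounts` or two `RatioProfile`s on the same grid.
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(a, b) {
  va <- if (inherits(a, "RatioProfile")) ifelse(a$mask, NA, a$value) else a$counts
  vb <- if (inherits(b, "RatioProfile")) ifelse(b$mask, NA, b$value) else b$counts
  ga <- if (inherits(a, "RatioProfile")) a$grid else a$grid
  gb <- if (inherits(b, "RatioProfile")) b$grid else b$grid
  if (ga$n_bins != gb$n_bins || !identical(ga$bin_width, gb$bin_width))
    stop("samples are not on the same bin grid")
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 2) stop("fewer than 2 shared non-missing bins")
  stats::cor(va[ok], vb[ok])
}

#' Merge replicates and compute the log2(Dam-POI/Dam) profile
#'
#' Replicate counts are summed per bin; each merged sample is scaled to
#' reads per million (RPM); bins whose merged raw Dam count is zero are
#' masked as missing; elsewhere the per-bin value is
#' `log2((RPM_POI + eps_POI) / (RPM_Dam + eps_Dam))` with `eps` the RPM
#' equivalent of `pseudocount` raw reads in the respective sample.
#'
#' @param dam_reps list of `BinCounts` for the Dam-only samples.
#' @param poi_reps list of `BinCounts` for the Dam-POI samples.
#' @param pseudocount raw-read pseudocount (default 1).
#' @param poi,cell_type labels stored on the profile.
#' @return a `RatioProfile`: list with `grid`, `value` (NA where masked),
#'   `mask`, `qnorm` flag and labels.
#' @export
merge_and_normalize <- function(dam_reps, poi_reps, pseudocount = 1,
                                poi = "POI", cell_type = "sample") {
  if (inherits(dam_reps, "BinCounts")) dam_reps <- list(dam_reps)
  if (inherits(poi_reps, "BinCounts")) poi_reps <- list(poi_reps)
  stopifnot(length(dam_reps) >= 1, length(poi_reps) >= 1)
  grid <- dam_reps[[1]]$grid
  for (x in c(dam_reps, poi_reps)) {
    if (!inherits(x, "BinCounts")) stop("replicates must be BinCounts")
    if (x$grid$n_bins != grid$n_bins ||
        !identical(x$grid$bin_width, grid$bin_width))
      stop("replicate bin grids do not match")
  }
  dam <- Reduce(`+`, lapply(dam_reps, `[[`, "counts"))
  pc <- Reduce(`+`, lapply(poi_reps, `[[`, "counts"))
  if (sum(dam) == 0) stop("merged Dam sample has zero total counts")
  if (sum(pc) == 0) stop("merged Dam-POI sample has zero total counts")
  mask <- dam == 0
  dam_rpm <- dam * 1e6 / sum(dam)
  poi_rpm <- pc * 1e6 / sum(pc)
  eps_dam <- pseudocount * 1e6 / sum(dam)
  eps_poi <- pseudocount * 1e6 / sum(pc)
  value <- log2((poi_rpm + eps_poi) / (dam_rpm + eps_dam))
  value[mask] <- NA_real_
  structure(list(grid = grid, value = value, mask = mask, qnorm = FALSE,
                 poi = poi, cell_type = cell_type),
            class = "RatioProfile")
}

#' @export
print.RatioProfile <- function(x, ...) {
  cat("RatioProfile [", x$poi, "/", x$cell_type, "]: ",
      x$grid$n_bins, " bins, ", sum(x$mask), " masked",
      if (x$qnorm) ", quantile-normalized" else "", "\n", sep = "")
  invisible(x)
}

#' Construct a RatioProfile directly from per-bin values
#'
#' Mainly for simulation and tests; `NA` values are masked.
#'
#' @param value numeric vector over the grid's bins (NA = missing).
#' @param grid a `BinGrid`.
#' @param poi,cell_type labels.
#' @param qnorm quantile-normalized flag.
#' @return a `RatioProfile`.
#' @export
ratio_profile <- function(value, grid, poi = "POI", cell_type = "sample",
                          qnorm = FALSE) {
  stopifnot(length(value) == grid$n_bins)
  structure(list(grid = grid, value = as.numeric(value), mask = is.na(value),
                 qnorm = qnorm, poi = poi, cell_type = cell_type),
            class = "RatioProfile")
}

#' Quantile-normalize log2 ratio profiles across cell types
#'
#' Makes the value distributions of the same POI comparable across
#' organs/cell types: over each profile's non-missing bins, values are
#' replaced by the corresponding order statistic of the reference
#' distribution (the mean of the sorted per-profile vectors; ties averaged;
#' interpolated when profiles have unequal numbers of non-missing bins).
#' Missing masks are unchanged. Delegates to [limma::normalizeQuantiles()].
#'
#' @param profiles list of `RatioProfile`s on one grid (same POI across
#'   cell types).
#' @return list of `RatioProfile`s flagged `qnorm = TRUE`.
#' @export
quantile_normalize_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (length(profiles) == 1) {
    warning("single profile: quantile normalization is the identity")
    profiles[[1]]$qnorm <- TRUE
    return(profiles)
  }
  grid <- profiles[[1]]$grid
  for (p in profiles) {
    stopifnot(inherits(p, "RatioProfile"))
    if (p$grid$n_bins != grid$n_bins)
      stop("profiles are not on the same bin grid")
  }
  m <- vapply(profiles, function(p) ifelse(p$mask, NA_real_, p$value),
              numeric(grid$n_bins))
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    v <- qn[, i]
    v[p$mask] <- NA_real_
    p$value <- v
    p$qnorm <- TRUE
    p
  })
}

#' Write a profile as bedGraph (masked bins omitted)
#'
#' @param profile a `RatioProfile`.
#' @param path output path.
#' @export
write_profile_bedgraph <- function(profile, path) {
  bt <- bin_table(profile$grid)
  keep <- !profile$mask
  df <- bt[keep, , drop = FALSE]
  df$value <- profile$value[keep]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%.6g", df$arm, as.integer(df$start),
                     as.integer(df$end), df$value), con)
  invisible(path)
}

#' Write / read a profile TSV preserving the missing mask
#'
#' Columns: arm, start, end, value (NA when masked), masked (0/1).
#'
#' @param profile a `RatioProfile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- bin_table(profile$grid)
  df$value <- profile$value
  df$masked <- as.integer(profile$mask)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param grid a `BinGrid` the file must align to.
#' @param poi,cell_type labels for the returned profile.
#' @param qnorm quantile-normalized flag.
#' @export
read_profile_tsv <- function(path, grid, poi = "POI", cell_type = "sample",
                             qnorm = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bt <- bin_table(grid)
  if (nrow(df) != nrow(bt) || !all(df$arm == bt$arm) ||
      !all(df$start == bt$start))
    stop("profile table rows do not align with the bin grid")
  v <- df$value
  v[df$masked == 1] <- NA_real_
  ratio_profile(v, grid, poi = poi, cell_type = cell_type, qnorm = qnorm)
}
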