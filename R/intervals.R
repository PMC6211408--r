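#' Interval sets on chromosome arms
#'
#' `IntervalSet` is the package's container for genomic intervals: a
#' data.frame with columns `arm`, `start`, `end` in 0-based half-open bp
#' coordinates, kept normalized — sorted by arm then start, with overlapping
#' or book-ended intervals within an arm merged. Interval algebra is
#' delegated to GenomicRanges.
#'
#' @param x data.frame with columns `arm`, `start`, `end` (further columns
#'   are dropped), or an existing `IntervalSet`.
#' @return normalized `IntervalSet`.
#' @export
interval_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("arm", "start", "end") %in% names(x)))
  x <- x[, c("arm", "start", "end")]
  x$arm <- as.character(x$arm)
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
      stop("non-finite interval coordinates")
    if (any(x$end <= x$start)) stop("intervals must have end > start")
    if (any(x$start < 0)) stop("negative interval start")
    x <- .gr_to_is(GenomicRanges::reduce(.is_to_gr(x)))
  }
  rownames(x) <- NULL
  class(x) <- c("IntervalSet", "data.frame")
  x
}

#' @export
empty_intervals <- function() {
  data.frame(arm = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

.is_to_gr <- function(x, seqlevels = NULL) {
  lv <- unique(c(seqlevels, x$arm))
  if (!length(lv)) lv <- "none"
  GenomicRanges::GRanges(factor(x$arm, levels = lv),
                         IRanges::IRanges(x$start + 1, x$end))
}

.gr_to_is <- function(gr) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  data.frame(arm = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' A set of domains called for one protein in one cell type
#'
#' A `DomainSet` is an `IntervalSet` carrying the protein-of-interest (POI)
#' and cell-type labels of the profile it was called from.
#'
#' @param intervals an `IntervalSet` or coercible data.frame.
#' @param poi label of the Dam-fusion protein, e.g. "Lam", "HP1a", "Pc".
#' @param cell_type cell-type/organ label.
#' @param assembly optional `GenomeAssembly`; if given, intervals are checked
#'   against arm bounds.
#' @return a `DomainSet` (also an `IntervalSet`).
#' @export
domain_set <- function(intervals, poi, cell_type, assembly = NULL) {
  x <- interval_set(intervals)
  if (!is.null(assembly)) {
    bad <- setdiff(x$arm, assembly$arms)
    if (length(bad)) stop("domain on unknown arm(s): ",
                          paste(bad, collapse = ", "))
    if (nrow(x) && any(x$end > assembly$lengths[x$arm]))
      stop("domain extends beyond arm end")
  }
  attr(x, "poi") <- poi
  attr(x, "cell_type") <- cell_type
  class(x) <- c("DomainSet", class(x))
  x
}

#' @export
print.IntervalSet <- function(x, ...) {
  if (inherits(x, "DomainSet"))
    cat("DomainSet [", attr(x, "poi"), "/", attr(x, "cell_type"), "]: ",
        nrow(x), " intervals, ", format(total_length(x), big.mark = ","),
        " bp\n", sep = "")
  else
    cat("IntervalSet:", nrow(x), "intervals,",
        format(total_length(x), big.mark = ","), "bp\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Parse genomic intervals from a file
#'
#' Supported dialects: `"bed"` (BED3+, 0-based half-open, `track`/`browser`/
#' `#` lines skipped), `"gff"` (GFF3, 1-based closed, converted to half-open
#' on read; optionally filtered to one feature type), and `"tsv"`
#' (tab-separated with a header naming at least `arm`, `start`, `end`;
#' 0-based half-open).
#'
#' @param path file path.
#' @param dialect one of "bed", "gff", "tsv".
#' @param feature for GFF: keep only records of this feature type
#'   (column 3); NULL keeps all.
#' @return a normalized `IntervalSet`.
#' @export
parse_intervals <- function(path, dialect = c("bed", "gff", "tsv"),
                            feature = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- switch(dialect,
    bed = .parse_bed(path),
    tsv = .parse_tsv_intervals(path),
    gff = .parse_gff_intervals(path, feature))
  interval_set(df)
}

.parse_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_intervals())
  parts <- strsplit(lines[idx], "[ \t]+")
  n <- lengths(parts)
  bad <- which(n < 3)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": fewer than 3 fields")
  arm <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": end <= start")
  data.frame(arm = arm, start = start, end = end, stringsAsFactors = FALSE)
}

.parse_tsv_intervals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(c("arm", "start", "end"), names(df))
  if (length(miss))
    stop("TSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("malformed TSV line ", bad[1] + 1, ": end <= start")
  df[, c("arm", "start", "end")]
}

.parse_gff_intervals <- function(path, feature = NULL) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(feature)) gr <- gr[gr$type %in% feature]
    if (!length(gr)) return(empty_intervals())
    return(data.frame(arm = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE))
  }
  # minimal fallback: 9-column GFF, 1-based closed
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_intervals())
  parts <- strsplit(lines[idx], "\t")
  bad <- which(lengths(parts) < 8)
  if (length(bad)) stop("malformed GFF line ", idx[bad[1]])
  type <- vapply(parts, `[[`, "", 3)
  sel <- if (is.null(feature)) rep(TRUE, length(parts)) else type %in% feature
  if (!any(sel)) return(empty_intervals())
  parts <- parts[sel]
  start1 <- as.numeric(vapply(parts, `[[`, "", 4))
  end1 <- as.numeric(vapply(parts, `[[`, "", 5))
  if (any(is.na(start1)) || any(is.na(end1)) || any(end1 < start1))
    stop("malformed GFF coordinates in ", path)
  data.frame(arm = vapply(parts, `[[`, "", 1), start = start1 - 1,
             end = end1, stringsAsFactors = FALSE)
}

#' Write intervals as BED3
#'
#' @param x an `IntervalSet` (or data.frame with arm/start/end).
#' @param path output path.
#' @param header optional comment line(s) written with a leading `#`.
#' @export
write_bed <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (NROW(x))
    writeLines(sprintf("%s\t%d\t%d", x$arm, as.integer(x$start),
                       as.integer(x$end)), con)
  invisible(path)
}

#' Interval algebra on base pairs
#'
#' Set-theoretic operations computed exactly on bp via GenomicRanges.
#' `"complement-in-region"` returns `region` minus `a`; `"total-length"`
#' returns the summed bp length of `a`.
#'
#' @param a,b `IntervalSet`s (or coercible data.frames); `b` ignored for
#'   complement and total-length.
#' @param op operation name.
#' @param region required for "complement-in-region".
#' @return an `IntervalSet`, or a numeric length for "total-length".
#' @export
interval_algebra <- function(a, b = NULL,
                             op = c("intersect", "union",
                                    "complement-in-region", "total-length"),
                             region = NULL) {
  op <- match.arg(op)
  switch(op,
    intersect = interval_intersect(a, b),
    union = interval_union(a, b),
    `complement-in-region` = {
      if (is.null(region)) stop("complement requires a `region` argument")
      interval_complement(a, region)
    },
    `total-length` = total_length(a))
}

#' @rdname interval_algebra
#' @export
interval_intersect <- function(a, b) {
  a <- interval_set(a); b <- interval_set(b)
  if (!nrow(a) || !nrow(b)) return(interval_set(empty_intervals()))
  lv <- union(a$arm, b$arm)
  interval_set(.gr_to_is(GenomicRanges::intersect(.is_to_gr(a, lv),
                                                  .is_to_gr(b, lv))))
}

#' @rdname interval_algebra
#' @export
interval_union <- function(a, b) {
  a <- interval_set(a); b <- interval_set(b)
  interval_set(rbind(as.data.frame(a), as.data.frame(b)))
}

#' @rdname interval_algebra
#' @export
interval_setdiff <- function(a, b) {
  a <- interval_set(a); b <- interval_set(b)
  if (!nrow(a)) return(a)
  if (!nrow(b)) return(a)
  lv <- union(a$arm, b$arm)
  interval_set(.gr_to_is(GenomicRanges::setdiff(.is_to_gr(a, lv),
                                                .is_to_gr(b, lv))))
}

#' @rdname interval_algebra
#' @export
interval_complement <- function(a, region) {
  interval_setdiff(interval_set(region), a)
}

#' @rdname interval_algebra
#' @export
total_length <- function(a) {
  if (!NROW(a)) return(0)
  sum(a$end - a$start)
}

#' Clip intervals to a region
#'
#' @param a an `IntervalSet`.
#' @param region an `IntervalSet`.
#' @return `a` intersected with `region`.
#' @export
clip_to_region <- function(a, region) interval_intersect(a, region)

#' Expand intervals by a flank on both sides
#'
#' @param x an `IntervalSet` or coercible data.frame.
#' @param flank bp added to each side.
#' @param assembly optional `GenomeAssembly` to clip at arm ends.
#' @return an `IntervalSet` (adjacent expansions merge).
#' @export
expand_intervals <- function(x, flank, assembly = NULL) {
  if (!NROW(x)) return(interval_set(empty_intervals()))
  s <- pmax(x$start - flank, 0)
  e <- x$end + flank
  if (!is.null(assembly)) e <- pmin(e, assembly$lengths[x$arm])
  interval_set(data.frame(arm = x$arm, start = s, end = unname(e),
                          stringsAsFactors = FALSE))
}

#' ChA analysis windows of an assembly as an IntervalSet
#'
#' @param assembly a `GenomeAssembly`.
#' @param arms optional subset of arms.
#' @return an `IntervalSet` of the per-arm analysis windows.
#' @export
cha_windows <- function(assembly, arms = NULL) {
  w <- assembly$cha_windows
  if (!is.null(arms)) w <- w[w$arm %in% arms, , drop = FALSE]
  interval_set(w)
}

# Flattened per-arm lookup for fast overlap-length queries:
# for each arm, sorted disjoint interval starts/ends with cumulative lengths.
.flatten_by_arm <- function(x) {
  x <- interval_set(x)
  lapply(split(x[, c("start", "end")], x$arm), function(d) {
    o <- order(d$start)
    s <- d$start[o]; e <- d$end[o]
    list(start = s, end = e, cum = c(0, cumsum(e - s)))
  })
}

# Total bp of the flattened set below coordinate x (vectorized over x).
.flat_cdf <- function(flat, x) {
  i <- findInterval(x, flat$start)
  out <- numeric(length(x))
  nz <- i > 0
  if (any(nz)) {
    ii <- i[nz]
    out[nz] <- flat$cum[ii] +
      pmin(pmax(x[nz] - flat$start[ii], 0), flat$end[ii] - flat$start[ii])
  }
  out
}

# bp overlap of [s, e) with the flattened set (vectorized).
.flat_overlap_len <- function(flat, s, e) .flat_cdf(flat, e) - .flat_cdf(flat, s)
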