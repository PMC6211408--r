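#' Describe a genome assembly for DamID analysis
#'
#' An assembly is the set of chromosome arms the analysis runs on, with the
#' per-arm windows ("chromosome arms" in the euchromatic sense, ChA) used for
#' coverage and enrichment statistics, plus region-class annotations:
#' pericentromeric heterochromatin (CHet) arms, the 4th chromosome, and which
#' arms belong to the X chromosome (for X-versus-autosome comparisons).
#'
#' All coordinates are 0-based, half-open base pairs.
#'
#' @param lengths named numeric vector of arm lengths in bp; names are arm
#'   names.
#' @param cha_windows data.frame with columns `arm`, `start`, `end` giving the
#'   analysis window per arm. Defaults to the full span of every arm not
#'   listed in `het_arms`.
#' @param het_arms character vector of arms that are constitutive
#'   pericentromeric heterochromatin.
#' @param x_arms character vector of arms belonging to the X chromosome.
#' @param chr4_arms character vector of arms belonging to the 4th chromosome
#'   (excluded by default from autosome pools).
#' @return an object of class `GenomeAssembly`.
#' @export
genome_assembly <- function(lengths, cha_windows = NULL,
                            het_arms = character(), x_arms = character(),
                            chr4_arms = character()) {
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("`lengths` must be a named vector of arm lengths")
  if (anyDuplicated(names(lengths)))
    stop("duplicated arm names in `lengths`")
  if (any(lengths <= 0)) stop("arm lengths must be positive")
  arms <- names(lengths)
  for (v in list(het_arms, x_arms, chr4_arms)) {
    bad <- setdiff(v, arms)
    if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cha_windows)) {
    eu <- setdiff(arms, het_arms)
    cha_windows <- data.frame(arm = eu, start = 0,
                              end = unname(lengths[eu]),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("arm", "start", "end") %in% names(cha_windows)))
  cha_windows <- cha_windows[, c("arm", "start", "end")]
  bad <- setdiff(cha_windows$arm, arms)
  if (length(bad)) stop("ChA window on unknown arm(s): ",
                        paste(bad, collapse = ", "))
  if (any(cha_windows$start < 0) ||
      any(cha_windows$end > lengths[cha_windows$arm]))
    stop("ChA windows must lie within arm bounds")
  if (any(cha_windows$end <= cha_windows$start))
    stop("ChA windows must have end > start")
  structure(list(arms = arms, lengths = lengths,
                 cha_windows = cha_windows, het_arms = het_arms,
                 x_arms = x_arms, chr4_arms = chr4_arms),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$arms), "arms,",
      format(sum(x$lengths), big.mark = ","), "bp\n")
  for (a in x$arms) {
    cls <- c(if (a %in% x$het_arms) "CHet",
             if (a %in% x$x_arms) "X",
             if (a %in% x$chr4_arms) "chr4")
    cat(sprintf("  %-6s %12s bp%s\n", a,
                format(x$lengths[[a]], big.mark = ","),
                if (length(cls)) paste0("  [", paste(cls, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

#' The Drosophila dm3/R5 assembly with euchromatic arm windows
#'
#' Chromosome-arm (ChA) analysis windows are the non-pericentromeric portions
#' of the five major arms: X 0-22,300 kb, 2L 0-22,000 kb, 2R 1,600-21,147 kb,
#' 3L 0-22,900 kb and 3R 0-27,900 kb (the 2R window is clipped to the arm
#' end, which falls 292 bp short of 21,147 kb in dm3). Pericentromeric
#' heterochromatin scaffolds and the 4th chromosome are carried as separate
#' region classes.
#'
#' @return a `GenomeAssembly`.
#' @export
dmel_cha_assembly <- function() {
  lengths <- c(X = 22422827, `2L` = 23011544, `2R` = 21146708,
               `3L` = 24543557, `3R` = 27905053, `4` = 1351857,
               XHet = 204112, `2LHet` = 368872, `2RHet` = 3288761,
               `3LHet` = 2555491, `3RHet` = 2517507)
  cha <- data.frame(
    arm   = c("X", "2L", "2R", "3L", "3R"),
    start = c(0, 0, 1600000, 0, 0),
    end   = c(22300000, 22000000, 21146708, 22900000, 27900000),
    stringsAsFactors = FALSE)
  genome_assembly(lengths, cha_windows = cha,
                  het_arms = c("XHet", "2LHet", "2RHet", "3LHet", "3RHet"),
                  x_arms = c("X", "XHet"),
                  chr4_arms = "4")
}

#' A desk-scale toy assembly for simulation
#'
#' Two euchromatic 5-Mb arms plus one 500-kb pericentromeric (CHet) arm;
#' runs through the whole pipeline in seconds at 1-kb bins.
#'
#' @param arm_length euchromatic arm length in bp.
#' @param chet_length CHet arm length in bp.
#' @return a `GenomeAssembly`.
#' @export
toy_assembly <- function(arm_length = 5e6, chet_length = 5e5) {
  lengths <- c(`2L` = arm_length, `3L` = arm_length, CHet = chet_length)
  genome_assembly(lengths, het_arms = "CHet")
}

#' Tile an assembly with fixed-width bins
#'
#' Bins tile each arm left to right; the last, possibly partial, bin is
#' retained. Bins are indexed 1..n_bins globally, arm by arm in assembly
#' order.
#'
#' @param assembly a `GenomeAssembly`.
#' @param bin_width bin width in bp (default 1000).
#' @return an object of class `BinGrid`.
#' @export
bin_grid <- function(assembly, bin_width = 1000) {
  stopifnot(inherits(assembly, "GenomeAssembly"), bin_width >= 1)
  n <- ceiling(assembly$lengths / bin_width)
  offset <- c(0, cumsum(n))[seq_along(n)]
  names(offset) <- assembly$arms
  structure(list(assembly = assembly, bin_width = bin_width,
                 n_per_arm = n, offset = offset, n_bins = sum(n)),
            class = "BinGrid")
}

#' @export
print.BinGrid <- function(x, ...) {
  cat("BinGrid:", x$n_bins, "bins of", x$bin_width, "bp on",
      length(x$assembly$arms), "arms\n")
  invisible(x)
}

#' Bin coordinates of a grid as a table
#'
#' @param grid a `BinGrid`.
#' @return data.frame with columns `arm`, `start`, `end` (0-based half-open),
#'   one row per bin in global bin order; the last bin of an arm is clipped
#'   to the arm end.
#' @export
bin_table <- function(grid) {
  a <- grid$assembly
  out <- lapply(a$arms, function(arm) {
    n <- grid$n_per_arm[[arm]]
    s <- (seq_len(n) - 1) * grid$bin_width
    data.frame(arm = arm, start = s,
               end = pmin(s + grid$bin_width, a$lengths[[arm]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mark bins overlapping a set of intervals
#'
#' A bin is marked if it shares at least 1 bp with any interval.
#'
#' @param grid a `BinGrid`.
#' @param intervals an `IntervalSet` (or any data.frame with `arm`, `start`,
#'   `end` in 0-based half-open coordinates).
#' @return logical vector over global bins.
#' @export
bins_in_intervals <- function(grid, intervals) {
  out <- logical(grid$n_bins)
  if (NROW(intervals) == 0) return(out)
  w <- grid$bin_width
  for (arm in intersect(unique(intervals$arm), grid$assembly$arms)) {
    iv <- intervals[intervals$arm == arm, , drop = FALSE]
    n <- grid$n_per_arm[[arm]]
    off <- grid$offset[[arm]]
    for (k in seq_len(nrow(iv))) {
      first <- floor(iv$start[k] / w) + 1
      last  <- ceiling(iv$end[k] / w)
      first <- max(1L, first); last <- min(n, last)
      if (first <= last) out[(off + first):(off + last)] <- TRUE
    }
  }
  out
}

#' Convert a logical bin mask back to intervals
#'
#' Consecutive marked bins within an arm merge into one interval.
#'
#' @param grid a `BinGrid`.
#' @param mask logical vector over global bins.
#' @return an `IntervalSet`.
#' @export
intervals_from_bins <- function(grid, mask) {
  stopifnot(length(mask) == grid$n_bins)
  a <- grid$assembly
  res <- list()
  for (arm in a$arms) {
    n <- grid$n_per_arm[[arm]]
    off <- grid$offset[[arm]]
    m <- mask[(off + 1):(off + n)]
    if (!any(m)) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    res[[arm]] <- data.frame(
      arm = arm,
      start = (starts[keep] - 1) * grid$bin_width,
      end = pmin(ends[keep] * grid$bin_width, a$lengths[[arm]]),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(interval_set(empty_intervals()))
  interval_set(do.call(rbind, res))
}
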