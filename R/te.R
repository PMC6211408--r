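#' A set of transposable-element insertions
#'
#' Unlike `IntervalSet`, insertions are kept as individual records —
#' overlapping elements are never merged, since each insertion is an event.
#'
#' @param x data.frame with `arm`, `start`, `end` (0-based half-open).
#' @return a `TEInsertionSet`.
#' @export
te_insertion_set <- function(x) {
  stopifnot(is.data.frame(x), all(c("arm", "start", "end") %in% names(x)))
  x <- x[, c("arm", "start", "end")]
  x$arm <- as.character(x$arm)
  if (nrow(x) && any(x$end <= x$start)) stop("TE records must have end > start")
  rownames(x) <- NULL
  class(x) <- c("TEInsertionSet", "data.frame")
  x
}

#' @export
print.TEInsertionSet <- function(x, ...) {
  cat("TEInsertionSet:", nrow(x), "insertions\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Split LADs into HP1a-bound and HP1a-free classes
#'
#' A LAD is HP1a-bound iff it shares at least 1 bp with any HP1a domain.
#'
#' @param lads a `DomainSet` of LADs.
#' @param hp1a a `DomainSet` of HP1a domains.
#' @return list with `bound` and `free` `DomainSet`s.
#' @export
split_lads_by_hp1a <- function(lads, hp1a) {
  ct <- attr(lads, "cell_type")
  if (is.null(ct)) ct <- "sample"
  lads_is <- interval_set(lads)
  if (!nrow(lads_is))
    return(list(bound = domain_set(lads_is, "Lam+HP1a", ct),
                free = domain_set(lads_is, "Lam-HP1a", ct)))
  flat <- .flatten_by_arm(interval_set(hp1a))
  bound <- vapply(seq_len(nrow(lads_is)), function(k) {
    f <- flat[[lads_is$arm[k]]]
    !is.null(f) && .flat_overlap_len(f, lads_is$start[k], lads_is$end[k]) > 0
  }, logical(1))
  list(bound = domain_set(lads_is[bound, , drop = FALSE], "Lam+HP1a", ct),
       free = domain_set(lads_is[!bound, , drop = FALSE], "Lam-HP1a", ct))
}

# events: number of (TE +/- extend, domain) overlapping pairs.
# doms must be normalized (disjoint, sorted within arm).
.te_event_count <- function(te_s, te_e, dom_starts, dom_ends) {
  # overlap iff dom_start < te_e and dom_end > te_s (half-open)
  findInterval(te_e - 0.5, dom_starts) - findInterval(te_s + 0.5, dom_ends)
}

#' TE occupancy near HP1a-bound versus HP1a-free LADs
#'
#' Each TE is extended by `extend` bp on both ends; the observed statistic
#' per class is the number of (TE, domain) overlapping pairs, normalized
#' per Mb of class length ("occupancy"), and the headline value is the
#' bound/free occupancy ratio. The null re-places every TE uniformly within
#' the ChA windows of its own arm (lengths preserved) `n_perm` times; the
#' p-value is the add-one estimator for `null ratio >= observed ratio`.
#'
#' @param tes a `TEInsertionSet`.
#' @param bound,free `DomainSet`s from [split_lads_by_hp1a()].
#' @param region `IntervalSet` of ChA windows TEs are shuffled within.
#' @param extend bp added to each TE end before counting (default 500).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with per-class `events`, `occupancy_per_mb`, `mb` lengths,
#'   `ratio`, `null_ratio_mean`, `p`, `n_perm`, `seed`. When a class has no
#'   domains the ratio is `NA` and `flag` records why.
#' @export
te_proximity_enrichment <- function(tes, bound, free, region, extend = 500,
                                    n_perm = 10000, seed = 1) {
  stopifnot(extend >= 0, n_perm >= 1)
  region <- interval_set(region)
  bound <- clip_to_region(bound, region)
  free <- clip_to_region(free, region)
  mb <- c(bound = total_length(bound) / 1e6,
          free = total_length(free) / 1e6)
  if (any(mb == 0)) {
    return(list(events = c(bound = NA, free = NA),
                occupancy_per_mb = c(bound = NA, free = NA), mb = mb,
                ratio = NA_real_, null_ratio_mean = NA_real_, p = NA_real_,
                n_perm = n_perm, seed = seed,
                flag = "empty domain class: ratio undefined"))
  }
  cls_flat <- lapply(list(bound = bound, free = free), function(d)
    lapply(split(d[, c("start", "end")], d$arm), function(x) {
      o <- order(x$start)
      list(starts = x$start[o], ends = x$end[o])
    }))
  count_events <- function(arm, s, e) {
    vapply(c("bound", "free"), function(cl) {
      f <- cls_flat[[cl]][[arm]]
      if (is.null(f)) return(numeric(length(s)))
      sum(.te_event_count(s, e, f$starts, f$ends))
    }, numeric(1))
  }
  te_s <- pmax(tes$start - extend, 0)
  te_e <- tes$end + extend
  obs <- c(bound = 0, free = 0)
  for (arm in unique(tes$arm)) {
    i <- tes$arm == arm
    obs <- obs + count_events(arm, te_s[i], te_e[i])
  }
  occ <- obs / mb
  ratio <- unname(occ["bound"] / occ["free"])

  reg_by_arm <- split(region[, c("start", "end")], region$arm)
  te_len <- tes$end - tes$start
  withr::with_seed(seed, {
    # chunk the permutations so the position matrices stay small
    chunk <- max(1, min(n_perm, floor(2e6 / max(nrow(tes), 1))))
    done <- 0
    nb <- numeric(n_perm); nf <- numeric(n_perm)
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      cols <- (done + 1):(done + m)
      for (arm in unique(tes$arm)) {
        i <- which(tes$arm == arm)
        segs <- reg_by_arm[[arm]]
        if (is.null(segs)) stop("TE on arm without a region window: ", arm)
        L <- te_len[i]
        # sample starts for all TEs on this arm x m permutations
        npos <- outer(L, segs$end - segs$start, function(l, w) pmax(w - l + 1, 0))
        tot <- rowSums(npos)
        if (any(tot == 0)) stop("TE longer than any region interval on ", arm)
        u <- matrix(stats::runif(length(i) * m), length(i), m) * tot
        cumn <- npos
        if (ncol(npos) > 1)
          for (jj in 2:ncol(npos)) cumn[, jj] <- cumn[, jj - 1] + npos[, jj]
        for (cl in c("bound", "free")) {
          f <- cls_flat[[cl]][[arm]]
          if (is.null(f)) next
          # map u -> (segment, offset) -> start
          seg_idx <- matrix(0L, length(i), m)
          for (jj in seq_len(nrow(segs)))
            seg_idx <- seg_idx + (u > cumn[, jj])
          seg_idx <- seg_idx + 1L
          prev <- cbind(0, cumn)[cbind(rep(seq_along(i), m),
                                       as.vector(seg_idx))]
          s0 <- segs$start[as.vector(seg_idx)] + floor(as.vector(u) - prev)
          e0 <- s0 + rep(L, m)
          cnt <- .te_event_count(pmax(s0 - extend, 0), e0 + extend,
                                 f$starts, f$ends)
          add <- colSums(matrix(cnt, length(i), m))
          if (cl == "bound") nb[cols] <- nb[cols] + add
          else nf[cols] <- nf[cols] + add
        }
      }
      done <- done + m
    }
  })
  null_ratio <- (nb / mb["bound"]) / (nf / mb["free"])
  null_ratio[!is.finite(null_ratio)] <- NA
  p <- (1 + sum(null_ratio >= ratio, na.rm = TRUE)) / (1 + n_perm)
  list(events = obs, occupancy_per_mb = occ, mb = mb, ratio = ratio,
       null_ratio_mean = mean(null_ratio, na.rm = TRUE), p = p,
       n_perm = n_perm, seed = seed, flag = NULL)
}
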