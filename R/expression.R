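#' Validate a gene annotation table
#'
#' Genes are rows with `gene_id`, `arm`, `strand` (+/-), body `start`/`end`
#' (0-based half-open), the distal TSS position `tss` and optionally a
#' comma-separated `tss_list`. The distal TSS is the transcription start
#' farthest from the gene's 3' end — the 5'-most start on the sense strand;
#' when absent it is derived from the body and strand. The body must contain
#' every TSS.
#'
#' @param df data.frame of genes.
#' @return validated annotation data.frame (class `GeneAnnotation`).
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "arm", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$end <= df$start)) stop("gene bodies must have end > start")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(df[["tss_list"]]))
    df$tss_list <- as.character(ifelse(df$strand == "+", df$start,
                                       df$end - 1))
  if (is.null(df[["tss"]])) {
    df$tss <- vapply(seq_len(nrow(df)), function(i) {
      tl <- as.numeric(strsplit(df$tss_list[i], ",")[[1]])
      if (df$strand[i] == "+") min(tl) else max(tl)
    }, numeric(1))
  }
  inside <- df$tss >= df$start & df$tss < df$end
  if (any(!inside)) stop("distal TSS outside gene body for ",
                         df$gene_id[which(!inside)[1]])
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Classify gene promoters and bodies by domain membership
#'
#' A promoter is in-domain iff the single base pair of its distal TSS falls
#' inside a domain interval (half-open containment: a TSS at the domain
#' start coordinate is inside, one base to the left is not). Body membership
#' requires at least 1 bp of overlap. When the domain list contains `Lam`,
#' `HP1a` and `Pc`, LAD subclasses are added: `LAD_HP1a` (TSS in a LAD that
#' also carries HP1a at the TSS), `LAD_only` (TSS in a LAD, no HP1a or Pc
#' there) and `LAD_Pc`.
#'
#' @param genes a `GeneAnnotation` (or coercible data.frame).
#' @param domain_sets named list of `DomainSet`s (names are POI labels).
#' @param assembly optional assembly; genes on arms absent from every
#'   domain set and the assembly are skipped with a warning.
#' @return data.frame: `gene_id` plus, per POI, `tss_in_<POI>` and
#'   `body_in_<POI>` logicals, and LAD subclass columns when applicable.
#' @export
classify_tss_by_domains <- function(genes, domain_sets, assembly = NULL) {
  genes <- gene_annotation(as.data.frame(genes))
  if (!is.null(assembly)) {
    bad <- !(genes$arm %in% assembly$arms)
    if (any(bad)) {
      warning(sum(bad), " gene(s) on unknown arms skipped")
      genes <- genes[!bad, , drop = FALSE]
    }
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (p in names(domain_sets)) {
    flat <- .flatten_by_arm(interval_set(domain_sets[[p]]))
    hit <- function(s, e, arm) {
      f <- flat[[arm]]
      if (is.null(f)) return(FALSE)
      .flat_overlap_len(f, s, e) > 0
    }
    out[[paste0("tss_in_", p)]] <- vapply(seq_len(nrow(genes)), function(i)
      hit(genes$tss[i], genes$tss[i] + 1, genes$arm[i]), logical(1))
    out[[paste0("body_in_", p)]] <- vapply(seq_len(nrow(genes)), function(i)
      hit(genes$start[i], genes$end[i], genes$arm[i]), logical(1))
  }
  if (all(c("Lam", "HP1a", "Pc") %in% names(domain_sets))) {
    out$LAD_HP1a <- out$tss_in_Lam & out$tss_in_HP1a
    out$LAD_Pc <- out$tss_in_Lam & out$tss_in_Pc
    out$LAD_only <- out$tss_in_Lam & !out$tss_in_HP1a & !out$tss_in_Pc
  }
  out
}

#' Compare expression distributions between gene groups
#'
#' Per-group median and quartiles plus pairwise two-sided Mann-Whitney U
#' tests (normal approximation with tie correction). Zero-TPM genes can be
#' excluded first, as done when comparing subclasses of domain-resident
#' genes.
#'
#' @param tpm data.frame with `gene_id` and `tpm`.
#' @param groups named factor/character vector or data.frame with
#'   `gene_id` and `group`.
#' @param exclude_zero drop genes with TPM == 0 before testing.
#' @return list with `summary` (data.frame n/median/q25/q75 per group) and
#'   `pairwise_p` (matrix of M-W p-values).
#' @export
expression_comparison <- function(tpm, groups, exclude_zero = FALSE) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups$group), groups$gene_id)
  } else {
    g <- stats::setNames(as.character(groups), names(groups))
  }
  df <- data.frame(gene_id = tpm$gene_id, tpm = tpm$tpm,
                   group = g[tpm$gene_id], stringsAsFactors = FALSE)
  df <- df[!is.na(df$group), , drop = FALSE]
  if (exclude_zero) df <- df[df$tpm > 0, , drop = FALSE]
  if (!nrow(df)) stop("empty group: no genes matched any group")
  lev <- unique(df$group)
  sizes <- table(df$group)
  empty <- setdiff(lev, names(sizes)[sizes > 0])
  if (length(empty) || any(sizes == 0))
    stop("empty group: ", paste(c(empty, names(sizes)[sizes == 0]),
                                collapse = ", "))
  summ <- do.call(rbind, lapply(lev, function(l) {
    v <- df$tpm[df$group == l]
    data.frame(group = l, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  pw <- matrix(NA_real_, length(lev), length(lev),
               dimnames = list(lev, lev))
  if (length(lev) > 1) {
    for (i in seq_along(lev)[-length(lev)]) {
      for (j in (i + 1):length(lev)) {
        p <- stats::wilcox.test(df$tpm[df$group == lev[i]],
                                df$tpm[df$group == lev[j]],
                                alternative = "two.sided",
                                exact = FALSE, correct = TRUE)$p.value
        pw[i, j] <- pw[j, i] <- p
      }
    }
  }
  list(summary = summ, pairwise_p = pw)
}

#' Ubiquitously expressed genes from microarray present calls
#'
#' A transcript is ubiquitously represented iff it has at least 3 of 4
#' present calls in every one of the 15 tissues; a gene is ubiquitously
#' expressed iff at least one of its transcripts qualifies. A transcript
#' with a tissue entirely missing from the call table fails that tissue.
#'
#' @param calls long data.frame with `transcript`, `tissue`, `present`
#'   (0/1 or logical), one row per (transcript, tissue, array) slot.
#' @param tx2gene data.frame with `transcript`, `gene_id`.
#' @param n_tissues required number of tissues (default 15).
#' @param min_present present calls required per tissue (default 3).
#' @return sorted character vector of ubiquitous gene ids.
#' @export
ubiquitous_genes <- function(calls, tx2gene, n_tissues = 15,
                             min_present = 3) {
  stopifnot(all(c("transcript", "tissue", "present") %in% names(calls)))
  agg <- stats::aggregate(present ~ transcript + tissue, data = calls,
                          FUN = sum)
  ok_tissue <- agg$present >= min_present
  per_tx <- tapply(ok_tissue, agg$transcript, sum)
  n_seen <- tapply(agg$tissue, agg$transcript, function(x) length(unique(x)))
  incomplete <- names(n_seen)[n_seen < n_tissues]
  if (length(incomplete))
    message(length(incomplete),
            " transcript(s) missing tissues: treated as failing them")
  ubi_tx <- names(per_tx)[per_tx == n_tissues & n_seen == n_tissues]
  map <- stats::setNames(tx2gene$gene_id, tx2gene$transcript)
  sort(unique(stats::na.omit(map[ubi_tx])))
}

#' Tissue-specifically expressed genes
#'
#' Genes expressed in the cell type (TPM at or above `threshold`) minus the
#' ubiquitous list.
#'
#' @param tpm data.frame with `gene_id` and `tpm` for one cell type.
#' @param ubiquitous character vector of ubiquitous gene ids.
#' @param threshold TPM expression cutoff (default 1).
#' @return character vector of tissue-specific gene ids.
#' @export
tissue_specific_genes <- function(tpm, ubiquitous, threshold = 1) {
  expressed <- tpm$gene_id[tpm$tpm >= threshold]
  sort(setdiff(expressed, ubiquitous))
}

#' Stratify genes into silent/low/medium/high expression groups
#'
#' Half-open TPM ranges: silent `[0, c1)`, low `[c1, c2)`, medium
#' `[c2, c3]`, high `> c3` — with the published cutoffs 1/10/44 for neurons
#' (1/10/42 for glia). In data-driven mode the upper two boundaries are
#' chosen so the three expressed strata hold equal gene counts (within 1).
#'
#' @param tpm data.frame with `gene_id` and `tpm`.
#' @param cutoffs ascending numeric cutoffs `c(c1, c2, c3)`.
#' @param data_driven if TRUE, keep `c1` and re-derive `c2`, `c3` from the
#'   ranked expressed genes.
#' @return data.frame with `gene_id`, `tpm`, `group` (ordered factor) and
#'   the cutoffs used as an attribute.
#' @export
expression_groups <- function(tpm, cutoffs = c(1, 10, 44),
                              data_driven = FALSE) {
  stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
  if (data_driven) {
    ex <- sort(tpm$tpm[tpm$tpm >= cutoffs[1]])
    n <- length(ex)
    if (n >= 3) {
      i1 <- ceiling(n / 3); i2 <- ceiling(2 * n / 3)
      cutoffs <- c(cutoffs[1], ex[i1], ex[i2])
    }
  }
  # [0,c1) silent, [c1,c2) low, [c2,c3] medium, > c3 high
  lab <- cut(tpm$tpm, breaks = c(-Inf, cutoffs, Inf), right = FALSE,
             labels = c("silent", "low", "medium", "high"))
  lab[tpm$tpm == cutoffs[3]] <- "medium"
  if (data_driven) lab[tpm$tpm == cutoffs[2]] <- "low"
  out <- data.frame(gene_id = tpm$gene_id, tpm = tpm$tpm, group = lab,
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Metagene profile of log2 ratio values around distal TSSs
#'
#' Medians of non-quantile-normalized log2(Dam-POI/Dam) values across the
#' `2 * half_window + 1` bins centered at the bin containing each gene's
#' distal TSS, with bins taken in the 5'-to-3' orientation of the gene
#' (mirror-reversed for minus-strand genes). Only genes whose bodies
#' overlap the given domain set contribute; upstream bins overlapping
#' another gene are dropped for that gene, and downstream bins must overlap
#' the gene's own body. Missing bins are excluded from the medians.
#'
#' @param profile a raw (non-quantile-normalized) `RatioProfile`.
#' @param genes a `GeneAnnotation`.
#' @param domains a `DomainSet` gene bodies must overlap; NULL admits all
#'   genes.
#' @param half_window bins on each side of the TSS bin (default 3).
#' @return named numeric vector of medians at offsets
#'   `-half_window .. +half_window` (gene orientation), with the number of
#'   contributing genes as attribute `n_genes`.
#' @export
metagene_profile <- function(profile, genes, domains = NULL,
                             half_window = 3) {
  if (isTRUE(profile$qnorm))
    warning("metagene profiles are defined on non-quantile-normalized ",
            "profiles")
  genes <- gene_annotation(as.data.frame(genes))
  grid <- profile$grid
  w <- grid$bin_width
  if (!is.null(domains)) {
    flat <- .flatten_by_arm(interval_set(domains))
    keep <- vapply(seq_len(nrow(genes)), function(i) {
      f <- flat[[genes$arm[i]]]
      !is.null(f) && .flat_overlap_len(f, genes$start[i], genes$end[i]) > 0
    }, logical(1))
    genes <- genes[keep, , drop = FALSE]
  }
  if (!nrow(genes)) stop("no qualifying genes for the metagene profile")
  gene_flat <- .flatten_by_arm(
    data.frame(arm = genes$arm, start = genes$start, end = genes$end))
  offs <- -half_window:half_window
  acc <- matrix(NA_real_, nrow(genes), length(offs))
  for (i in seq_len(nrow(genes))) {
    arm <- genes$arm[i]
    if (!(arm %in% grid$assembly$arms)) next
    n_arm <- grid$n_per_arm[[arm]]
    tss_bin <- floor(genes$tss[i] / w) + 1
    sgn <- if (genes$strand[i] == "+") 1 else -1
    for (k in seq_along(offs)) {
      b <- tss_bin + sgn * offs[k]         # genomic bin at gene offset
      if (b < 1 || b > n_arm) next
      bs <- (b - 1) * w; be <- min(b * w, grid$assembly$lengths[[arm]])
      if (offs[k] < 0) {
        # upstream: drop if the bin overlaps any *other* gene
        f <- gene_flat[[arm]]
        other <- .flat_overlap_len(f, bs, be) -
          max(0, min(be, genes$end[i]) - max(bs, genes$start[i]))
        if (other > 0) next
      } else if (offs[k] > 0) {
        # downstream: the bin must carry the gene itself
        if (min(be, genes$end[i]) - max(bs, genes$start[i]) <= 0) next
      }
      acc[i, k] <- profile$value[grid$offset[[arm]] + b]
    }
  }
  med <- apply(acc, 2, stats::median, na.rm = TRUE)
  names(med) <- as.character(offs)
  attr(med, "n_genes") <- nrow(genes)
  med
}

#' Summarize differentially expressed genes by domain class
#'
#' Significant genes (adjusted p below `p_cutoff`, optionally also
#' `|log2 fold change| > log2(fold_cutoff)`) are counted per body-overlap
#' class — direct targets of each POI — split into up- and down-regulated
#' by the sign of the log2 fold change. Classes are not mutually exclusive
#' except `none` (no body overlap with any domain set).
#'
#' @param de data.frame with `gene_id`, `log2fc`, `adj_p`.
#' @param genes a `GeneAnnotation` covering the DE genes.
#' @param domain_sets named list of `DomainSet`s.
#' @param p_cutoff adjusted-p threshold (default 0.05).
#' @param fold_cutoff optional linear fold-change threshold (e.g. 2).
#' @return data.frame with `class`, `n`, `up`, `down`.
#' @export
de_domain_summary <- function(de, genes, domain_sets, p_cutoff = 0.05,
                              fold_cutoff = NULL) {
  stopifnot(all(c("gene_id", "log2fc", "adj_p") %in% names(de)))
  if (any(de$adj_p < 0 | de$adj_p > 1, na.rm = TRUE))
    stop("adjusted p-values must lie in [0, 1]")
  sig <- de[!is.na(de$adj_p) & de$adj_p < p_cutoff, , drop = FALSE]
  if (!is.null(fold_cutoff))
    sig <- sig[abs(sig$log2fc) > log2(fold_cutoff), , drop = FALSE]
  classes <- c(paste0("body_in_", names(domain_sets)), "none")
  if (!nrow(sig)) {
    return(data.frame(class = classes, n = 0L, up = 0L, down = 0L,
                      stringsAsFactors = FALSE))
  }
  memb <- classify_tss_by_domains(genes, domain_sets)
  m <- memb[match(sig$gene_id, memb$gene_id), , drop = FALSE]
  body_cols <- paste0("body_in_", names(domain_sets))
  none <- !Reduce(`|`, lapply(body_cols, function(cl) m[[cl]] %in% TRUE))
  tab <- lapply(classes, function(cl) {
    inc <- if (cl == "none") none else m[[cl]] %in% TRUE
    data.frame(class = cl, n = sum(inc),
               up = sum(inc & sig$log2fc > 0),
               down = sum(inc & sig$log2fc < 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, tab)
}
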