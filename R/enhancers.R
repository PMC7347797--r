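#' Directionality score of a bidirectional locus
#'
#' `D = (F - R) / (F + R)` on pooled forward (downstream, + strand) and
#' reverse (upstream, - strand) tag totals. Balanced, enhancer-like
#' transcription has D near 0; the enhancer gate is the strict inequality
#' `|D| < 0.8`.
#'
#' @param F_total,R_total Pooled forward / reverse tag counts (>= 0, not
#'   both zero).
#' @return D in \[-1, 1\].
#' @export
directionality <- function(F_total, R_total) {
  stopifnot(all(F_total >= 0), all(R_total >= 0))
  if (any(F_total + R_total == 0))
    stop("no transcription at locus: forward and reverse totals are both zero")
  (F_total - R_total) / (F_total + R_total)
}

#' Find candidate bidirectional (enhancer-like) loci
#'
#' Aggregates CTSS into strand-specific tag clusters and pairs every
#' divergent combination (a reverse-strand cluster upstream of a
#' forward-strand cluster) whose gap is at most `pairing_max_gap` bp. Each
#' pair defines a locus at the gap midpoint; per-sample forward tags are
#' tallied in `[mid, mid + window_half)` on the + strand and reverse tags
#' in `[mid - window_half, mid)` on the - strand. Overlapping loci are
#' merged keeping the higher-expressed one.
#'
#' @param ctss A [read_ctss()] table.
#' @param pairing_max_gap Maximum divergent gap in bp; default 400.
#' @param window_half Half-width of the tally window; default 200.
#' @param cluster_gap CTSS aggregation gap used per strand; default 20.
#' @return Object of class `bidir_loci`: list with `loci` (data frame
#'   locus_id, chrom, midpoint, window_half, F_total, R_total, D_pooled,
#'   samples_bidirectional), per-sample matrices `F` and `R`, and
#'   `samples`.
#' @export
find_bidirectional_loci <- function(ctss, pairing_max_gap = 400,
                                    window_half = 200, cluster_gap = 20) {
  stopifnot(inherits(ctss, "ctss_table"), pairing_max_gap >= 0,
            window_half > 0)
  tc <- aggregate_ctss(ctss, max_gap = cluster_gap)
  cl <- tc$clusters
  sites <- ctss$sites
  loci <- list()
  for (ch in unique(cl$chrom)) {
    rev_cl <- cl[cl$chrom == ch & cl$strand == "-", , drop = FALSE]
    fwd_cl <- cl[cl$chrom == ch & cl$strand == "+", , drop = FALSE]
    if (nrow(rev_cl) == 0 || nrow(fwd_cl) == 0) next
    for (i in seq_len(nrow(rev_cl))) {
      gap <- fwd_cl$start - rev_cl$end[i]
      hit <- which(gap >= 0 & gap <= pairing_max_gap)
      for (j in hit)
        loci[[length(loci) + 1L]] <- data.frame(
          chrom = ch,
          midpoint = floor((rev_cl$end[i] + fwd_cl$start[j]) / 2),
          stringsAsFactors = FALSE)
    }
  }
  if (length(loci) == 0)
    return(structure(list(loci = data.frame(), F = NULL, R = NULL,
                          samples = ctss$samples), class = "bidir_loci"))
  loci <- unique(do.call(rbind, loci))
  nS <- ncol(ctss$counts)
  Fm <- matrix(0, nrow(loci), nS, dimnames = list(NULL, colnames(ctss$counts)))
  Rm <- Fm
  for (i in seq_len(nrow(loci))) {
    inF <- sites$chrom == loci$chrom[i] & sites$strand == "+" &
      sites$pos >= loci$midpoint[i] & sites$pos < loci$midpoint[i] + window_half
    inR <- sites$chrom == loci$chrom[i] & sites$strand == "-" &
      sites$pos >= loci$midpoint[i] - window_half & sites$pos < loci$midpoint[i]
    Fm[i, ] <- colSums(ctss$counts[inF, , drop = FALSE])
    Rm[i, ] <- colSums(ctss$counts[inR, , drop = FALSE])
  }
  tot <- rowSums(Fm) + rowSums(Rm)
  # merge overlapping windows, keeping the higher-expressed locus
  ord <- order(loci$chrom, loci$midpoint)
  keep <- logical(nrow(loci))
  last_kept <- -1L; last_chrom <- ""
  for (i in ord) {
    if (loci$chrom[i] != last_chrom ||
        loci$midpoint[i] - loci$midpoint[last_kept] >= 2 * window_half) {
      keep[i] <- TRUE; last_kept <- i; last_chrom <- loci$chrom[i]
    } else if (tot[i] > tot[last_kept]) {
      keep[last_kept] <- FALSE; keep[i] <- TRUE; last_kept <- i
    }
  }
  loci <- loci[keep, , drop = FALSE]
  Fm <- Fm[keep, , drop = FALSE]; Rm <- Rm[keep, , drop = FALSE]
  ok <- rowSums(Fm) + rowSums(Rm) > 0
  loci <- loci[ok, , drop = FALSE]
  Fm <- Fm[ok, , drop = FALSE]; Rm <- Rm[ok, , drop = FALSE]
  loci$locus_id <- sprintf("BDL%04d", seq_len(nrow(loci)))
  loci$window_half <- window_half
  loci$F_total <- rowSums(Fm)
  loci$R_total <- rowSums(Rm)
  loci$D_pooled <- directionality(loci$F_total, loci$R_total)
  loci$samples_bidirectional <- rowSums(Fm > 0 & Rm > 0)
  rownames(loci) <- rownames(Fm) <- rownames(Rm) <- loci$locus_id
  structure(list(loci = loci[c("locus_id", "chrom", "midpoint", "window_half",
                               "F_total", "R_total", "D_pooled",
                               "samples_bidirectional")],
                 F = Fm, R = Rm, samples = ctss$samples),
            class = "bidir_loci")
}

#' @export
print.bidir_loci <- function(x, ...) {
  cat(sprintf("Bidirectional loci: %d candidates across %d samples\n",
              nrow(x$loci), if (is.null(x$F)) 0 else ncol(x$F)))
  invisible(x)
}

# subset helper keeping loci/F/R aligned
subset_loci <- function(x, keep) {
  x$loci <- x$loci[keep, , drop = FALSE]
  x$F <- x$F[keep, , drop = FALSE]
  x$R <- x$R[keep, , drop = FALSE]
  x
}

#' Apply an enhancer stringency tier
#'
#' Stringent tier: each flank has more than one raw tag in at least two
#' samples, pooled `|D| < 0.8` (strict), and bidirectional tags in more
#' than two samples (strict). Lenient tier: each flank has more than one
#' tag in at least one sample and bidirectional tags in at least one
#' sample. The stringent set is a subset of the lenient set by
#' construction.
#'
#' @param loci A [find_bidirectional_loci()] object.
#' @param level `"stringent"` or `"lenient"`.
#' @return The filtered `bidir_loci` object.
#' @export
apply_stringency <- function(loci, level = c("stringent", "lenient")) {
  level <- match.arg(level)
  stopifnot(inherits(loci, "bidir_loci"))
  if (nrow(loci$loci) == 0) return(loci)
  f_gt1 <- rowSums(loci$F > 1)
  r_gt1 <- rowSums(loci$R > 1)
  nbid <- loci$loci$samples_bidirectional
  keep <- if (level == "stringent")
    f_gt1 >= 2 & r_gt1 >= 2 & abs(loci$loci$D_pooled) < 0.8 & nbid > 2
  else
    f_gt1 >= 1 & r_gt1 >= 1 & nbid >= 1
  out <- subset_loci(loci, keep)
  out$stringency <- level
  out
}

#' Remove loci near annotated TSS or exons
#'
#' Removes a locus when its midpoint lies closer than `tss_dist` bp to an
#' annotated TSS or closer than `exon_dist` bp to an exon interval
#' (distance 0 inside an interval; strict inequalities, so a locus exactly
#' `tss_dist` away is kept). With `mode = "or"` (default) either proximity
#' removes the locus, matching the purpose of avoiding promoter detection;
#' `mode = "and"` requires both.
#'
#' @param loci A [find_bidirectional_loci()] object.
#' @param annotation A [read_annotation()] list (fields `tss`, `exons`) or
#'   GTF path.
#' @param tss_dist,exon_dist Removal distances in bp; defaults 500 and 100.
#' @param mode `"or"` or `"and"`.
#' @return The filtered `bidir_loci` object.
#' @export
mask_annotated <- function(loci, annotation, tss_dist = 500, exon_dist = 100,
                           mode = c("or", "and")) {
  mode <- match.arg(mode)
  stopifnot(inherits(loci, "bidir_loci"), tss_dist >= 0, exon_dist >= 0)
  if (nrow(loci$loci) == 0) return(loci)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  mid <- loci$loci$midpoint; ch <- loci$loci$chrom
  d_tss <- rep(Inf, length(mid))
  if (!is.null(annotation$tss) && nrow(annotation$tss)) {
    tss <- annotation$tss
    for (i in seq_along(mid)) {
      p <- tss$pos[tss$chrom == ch[i]]
      if (length(p)) d_tss[i] <- min(abs(p - mid[i]))
    }
  }
  d_exon <- rep(Inf, length(mid))
  if (!is.null(annotation$exons) && nrow(annotation$exons)) {
    ex <- annotation$exons
    for (i in seq_along(mid)) {
      e <- ex[ex$chrom == ch[i], , drop = FALSE]
      if (nrow(e) == 0) next
      # 0 inside the half-open interval, else bp to the nearest exon base
      d <- pmax(0, pmax(e$start - mid[i], mid[i] - (e$end - 1)))
      d_exon[i] <- min(d)
    }
  }
  near <- if (mode == "or") d_tss < tss_dist | d_exon < exon_dist
          else d_tss < tss_dist & d_exon < exon_dist
  subset_loci(loci, !near)
}

#' Overlap candidate loci with a reference enhancer set
#'
#' A locus overlaps when its `[midpoint - window_half, midpoint +
#' window_half)` interval intersects a reference interval by at least 1 bp
#' (half-open: adjacent intervals do not overlap).
#'
#' @param loci A [find_bidirectional_loci()] object (possibly filtered).
#' @param reference Data frame with chrom/start/end (0-based half-open) or
#'   a BED file path.
#' @return List with `count`, `fraction` and logical vector `hits` per
#'   locus.
#' @export
overlap_reference <- function(loci, reference) {
  stopifnot(inherits(loci, "bidir_loci"))
  if (is.character(reference)) {
    gr <- rtracklayer::import(reference, format = "bed")
    reference <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                            start = GenomicRanges::start(gr) - 1L,
                            end = GenomicRanges::end(gr))
  }
  if (nrow(loci$loci) == 0)
    return(list(count = 0L, fraction = NaN, hits = logical(0)))
  wh <- loci$loci$window_half
  q <- GenomicRanges::GRanges(loci$loci$chrom,
    IRanges::IRanges(loci$loci$midpoint - wh + 1, loci$loci$midpoint + wh))
  s <- GenomicRanges::GRanges(reference$chrom,
    IRanges::IRanges(reference$start + 1, reference$end))
  hits <- GenomicRanges::countOverlaps(q, s, minoverlap = 1L) > 0
  list(count = sum(hits), fraction = mean(hits),
       hits = setNames(hits, loci$loci$locus_id))
}
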