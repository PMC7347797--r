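#' Read per-sample CTSS tracks into a merged table
#'
#' Reads BED6 files of single-base CAGE transcription start sites (score
#' column = tag count, 0-based half-open coordinates) and merges them on
#' (chrom, position, strand); positions absent from a sample get count 0.
#'
#' @param paths Character vector of BED6 file paths, one per sample.
#' @param metadata Data frame with columns `sample_id`, `time_h`,
#'   `replicate`, one row per path (matched by position, or by a `path`
#'   column if present).
#' @return An object of class `ctss_table`: a list with `sites` (data frame
#'   chrom/pos/strand), `counts` (sites x samples integer matrix) and
#'   `samples` (the metadata).
#' @export
read_ctss <- function(paths, metadata) {
  if (!is.null(metadata$path)) paths <- metadata$path
  stopifnot(length(paths) == nrow(metadata),
            all(c("sample_id", "time_h", "replicate") %in% names(metadata)))
  per_file <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i])
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) {
      warning("empty CTSS file: ", paths[i], " (all-zero sample)")
      per_file[[i]] <- data.frame(chrom = character(0), pos = integer(0),
                                  strand = character(0), count = integer(0))
      next
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6))
      stop(sprintf("malformed BED line (need 6 fields) in %s at line %d",
                   paths[i], which(nf < 6)[1]))
    chrom <- vapply(fields, `[[`, character(1), 1)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5)))
    strand <- vapply(fields, `[[`, character(1), 6)
    bad <- which(is.na(start) | is.na(end) | is.na(score) | end != start + 1 |
                   score < 0)
    if (length(bad))
      stop(sprintf("malformed CTSS record in %s at line %d (need single-base, numeric score)",
                   paths[i], bad[1]))
    badstrand <- which(!strand %in% c("+", "-"))
    if (length(badstrand))
      stop(sprintf("invalid strand '%s' in %s at line %d (CTSS must be + or -)",
                   strand[badstrand[1]], paths[i], badstrand[1]))
    key <- paste(chrom, start, strand)
    if (anyDuplicated(key))
      stop(sprintf("duplicate (chrom,pos,strand) in %s at line %d",
                   paths[i], which(duplicated(key))[1]))
    per_file[[i]] <- data.frame(chrom = chrom, pos = start, strand = strand,
                                count = score, stringsAsFactors = FALSE)
  }
  all_sites <- unique(do.call(rbind, lapply(per_file, function(d)
    d[c("chrom", "pos", "strand")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$strand,
                               all_sites$pos), , drop = FALSE]
  rownames(all_sites) <- NULL
  key <- paste(all_sites$chrom, all_sites$pos, all_sites$strand)
  counts <- matrix(0, nrow = nrow(all_sites), ncol = length(paths),
                   dimnames = list(NULL, metadata$sample_id))
  for (i in seq_along(per_file)) {
    d <- per_file[[i]]
    if (nrow(d))
      counts[match(paste(d$chrom, d$pos, d$strand), key), i] <- d$count
  }
  structure(list(sites = all_sites, counts = counts,
                 samples = metadata[c("sample_id", "time_h", "replicate")]),
            class = "ctss_table")
}

#' @export
print.ctss_table <- function(x, ...) {
  cat(sprintf("CTSS table: %d sites x %d samples (%d time points)\n",
              nrow(x$sites), ncol(x$counts), length(unique(x$samples$time_h))))
  invisible(x)
}

#' Aggregate CTSS into tag clusters
#'
#' Single-linkage chaining per (chromosome, strand): consecutive CTSS whose
#' positional gap is at most `max_gap` bp merge into one tag cluster; the
#' cluster's per-sample value is the sum over member CTSS, and its dominant
#' position is the member with the highest pooled count (smallest position
#' on ties).
#'
#' @param ctss A [read_ctss()] table.
#' @param max_gap Maximum gap in bp between consecutive member CTSS.
#' @return An object of class `tag_clusters`: list with `clusters`
#'   (cluster_id, chrom, start, end (0-based half-open), strand,
#'   dominant_pos, n_ctss), `counts` (clusters x samples) and `samples`.
#' @export
aggregate_ctss <- function(ctss, max_gap = 20) {
  stopifnot(inherits(ctss, "ctss_table"), max_gap >= 0)
  s <- ctss$sites
  ord <- order(s$chrom, s$strand, s$pos)
  s <- s[ord, , drop = FALSE]
  cnt <- ctss$counts[ord, , drop = FALSE]
  grp <- paste(s$chrom, s$strand)
  new_cluster <- c(TRUE, grp[-1] != grp[-length(grp)] |
                     diff(s$pos) > max_gap)
  cid <- cumsum(new_cluster)
  pooled <- rowSums(cnt)
  cl_list <- split(seq_along(cid), cid)
  clusters <- data.frame(
    cluster_id = sprintf("TC%05d", seq_along(cl_list)),
    chrom = vapply(cl_list, function(i) s$chrom[i[1]], character(1)),
    start = vapply(cl_list, function(i) min(s$pos[i]), numeric(1)),
    end = vapply(cl_list, function(i) max(s$pos[i]) + 1, numeric(1)),
    strand = vapply(cl_list, function(i) s$strand[i[1]], character(1)),
    dominant_pos = vapply(cl_list, function(i) {
      p <- pooled[i]; s$pos[i][which.max(p)]  # which.max -> smallest pos on tie
    }, numeric(1)),
    n_ctss = lengths(cl_list),
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  mat <- do.call(rbind, lapply(cl_list, function(i)
    colSums(cnt[i, , drop = FALSE])))
  rownames(mat) <- clusters$cluster_id
  structure(list(clusters = clusters, counts = mat, samples = ctss$samples),
            class = "tag_clusters")
}

#' @export
print.tag_clusters <- function(x, ...) {
  cat(sprintf("Tag clusters: %d clusters x %d samples (median width %g bp)\n",
              nrow(x$clusters), ncol(x$counts),
              median(x$clusters$end - x$clusters$start)))
  invisible(x)
}

#' Read TSS and exon annotation from a GTF file
#'
#' Extracts one TSS per transcript (strand-aware, converted to 0-based
#' positions) and exon intervals (0-based half-open) from a standard GTF.
#'
#' @param path GTF file path.
#' @return List with `tss` (data frame gene/chrom/pos/strand) and `exons`
#'   (data frame chrom/start/end).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type %in% c("transcript", "gene")]
  gene <- if (!is.null(tx$gene_name)) tx$gene_name else tx$gene_id
  tss_pos <- ifelse(as.character(GenomicRanges::strand(tx)) == "+",
                    GenomicRanges::start(tx) - 1L,
                    GenomicRanges::end(tx) - 1L)
  tss <- unique(data.frame(gene = gene,
                           chrom = as.character(GenomicRanges::seqnames(tx)),
                           pos = tss_pos,
                           strand = as.character(GenomicRanges::strand(tx)),
                           stringsAsFactors = FALSE))
  ex <- gr[gr$type == "exon"]
  exons <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                      start = GenomicRanges::start(ex) - 1L,
                      end = GenomicRanges::end(ex),
                      stringsAsFactors = FALSE)
  list(tss = tss, exons = unique(exons))
}

#' Annotate tag clusters with gene symbols
#'
#' Assigns each cluster the symbol of the nearest same-strand annotated TSS
#' within `max_tss_dist` bp of the cluster's dominant position; clusters
#' with no such TSS stay unannotated (NA). Ties are broken by smaller
#' distance, then lexicographically smallest symbol.
#'
#' @param clusters A [aggregate_ctss()] object.
#' @param annotation A [read_annotation()] list, or a GTF path.
#' @param max_tss_dist Maximum distance in bp (inclusive).
#' @return `clusters` with a `gene` column added to `$clusters`.
#' @export
annotate_clusters <- function(clusters, annotation, max_tss_dist = 500) {
  stopifnot(inherits(clusters, "tag_clusters"), max_tss_dist >= 0)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  tss <- annotation$tss
  tss <- tss[order(tss$gene), , drop = FALSE]  # lexicographic tie-break
  cl <- clusters$clusters
  gene <- rep(NA_character_, nrow(cl))
  tss_by <- split(seq_len(nrow(tss)), paste(tss$chrom, tss$strand))
  for (i in seq_len(nrow(cl))) {
    cand <- tss_by[[paste(cl$chrom[i], cl$strand[i])]]
    if (is.null(cand)) next
    d <- abs(tss$pos[cand] - cl$dominant_pos[i])
    ok <- d <= max_tss_dist
    if (any(ok)) {
      cand <- cand[ok]; d <- d[ok]
      gene[i] <- tss$gene[cand[which.min(d)]]  # first (lexicographic) on tie
    }
  }
  clusters$clusters$gene <- gene
  clusters
}
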