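#' Exact hypergeometric tail probability
#'
#' Exact tail of the hypergeometric distribution for drawing `k` members of
#' a `K`-member class in a size-`n` draw from a population of `N`:
#' `tail = "over"` gives P(X >= k), `tail = "under"` gives P(X <= k).
#' Computed exactly (via the log-space-capable distribution function), not
#' by a normal or chi-square approximation, so that departures from
#' expectation near P ~ 1e-6 are trustworthy.
#'
#' @param N Population size.
#' @param K Class members in the population (0 <= K <= N).
#' @param n Draw (cluster) size (0 <= n <= N).
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param tail `"over"` or `"under"`.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k, tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(K, n))
    stop("inconsistent counts: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  if (tail == "over") phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else phyper(k, K, N - K, n, lower.tail = TRUE)
}

# Bonferroni family-wise correction.
p_bonferroni <- function(p, m_tests) pmin(1, p * m_tests)

#' Test clusters for gene-set over/under-representation
#'
#' For each cluster, counts the overlap between its (gene-deduplicated)
#' members and a gene set, computes both exact hypergeometric tails against
#' the clustered universe, reports the smaller tail with its direction, and
#' applies a Bonferroni correction over the number of clusters tested.
#' The universe is the set of clustered, gene-annotated nodes (not the
#' whole genome).
#'
#' @param membership Named vector node id -> cluster label (e.g.
#'   `mcl_result$membership`).
#' @param node_genes Named vector node id -> gene symbol (NA = unannotated).
#' @param geneset Character vector of gene symbols (intersected with the
#'   universe), or a list with `name` and `members`.
#' @param dedupe_genes Count a gene once even when several promoters
#'   (nodes) map to it; default TRUE.
#' @return Data frame with one row per cluster: `cluster, N, K, n, k,
#'   expected, tail, p, p_bonferroni, m_tests`.
#' @export
test_cluster_enrichment <- function(membership, node_genes, geneset,
                                    dedupe_genes = TRUE) {
  if (is.list(geneset)) geneset <- geneset$members
  node_genes <- node_genes[names(membership)]
  ok <- !is.na(node_genes)
  membership <- membership[ok]; node_genes <- node_genes[ok]
  if (dedupe_genes) {
    first <- !duplicated(node_genes)
    membership <- membership[first]; node_genes <- node_genes[first]
  }
  universe <- unique(node_genes)
  set_in <- intersect(geneset, universe)
  if (length(set_in) == 0)
    stop("gene set has no members in the clustered universe")
  N <- length(universe); K <- length(set_in)
  labs <- sort(unique(membership))
  m <- length(labs)
  res <- do.call(rbind, lapply(labs, function(cl) {
    genes <- node_genes[membership == cl]
    n <- length(genes); k <- sum(genes %in% set_in)
    p_over <- hypergeom_tail(N, K, n, k, "over")
    p_under <- hypergeom_tail(N, K, n, k, "under")
    tail <- if (p_over <= p_under) "over" else "under"
    data.frame(cluster = cl, N = N, K = K, n = n, k = k,
               expected = n * K / N, tail = tail,
               p = min(p_over, p_under), stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- p_bonferroni(res$p, m)
  res$m_tests <- m
  rownames(res) <- NULL
  res
}

#' Cell-cycle-phase composition of clusters
#'
#' Per cluster and phase label (e.g. S vs G2M), counts labelled members,
#' the expected count under uniform draw, the exact over- and under-tails,
#' and a two-sided P-value (`2 * min(tail)` capped at 1).
#'
#' @param membership Named vector node id -> cluster label.
#' @param node_genes Named vector node id -> gene symbol.
#' @param phases Named vector gene symbol -> phase label.
#' @param dedupe_genes Count each gene once; default TRUE.
#' @return Data frame: `cluster, phase, N, K, n, k, expected, p_over,
#'   p_under, p_two_sided`.
#' @export
phase_composition <- function(membership, node_genes, phases,
                              dedupe_genes = TRUE) {
  if (anyNA(phases)) stop("unknown (NA) phase label in phases")
  node_genes <- node_genes[names(membership)]
  ok <- !is.na(node_genes)
  membership <- membership[ok]; node_genes <- node_genes[ok]
  if (dedupe_genes) {
    first <- !duplicated(node_genes)
    membership <- membership[first]; node_genes <- node_genes[first]
  }
  universe <- unique(node_genes)
  phases <- phases[names(phases) %in% universe]
  if (length(phases) == 0) stop("phase labels cover no gene in the universe")
  N <- length(universe)
  labs <- sort(unique(membership))
  out <- do.call(rbind, lapply(labs, function(cl) {
    genes <- node_genes[membership == cl]
    n <- length(genes)
    do.call(rbind, lapply(sort(unique(phases)), function(ph) {
      K <- sum(phases == ph)
      k <- sum(genes %in% names(phases)[phases == ph])
      p_over <- hypergeom_tail(N, K, n, k, "over")
      p_under <- hypergeom_tail(N, K, n, k, "under")
      data.frame(cluster = cl, phase = ph, N = N, K = K, n = n, k = k,
                 expected = n * K / N, p_over = p_over, p_under = p_under,
                 p_two_sided = min(1, 2 * min(p_over, p_under)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read a gene set from a text file
#'
#' One symbol per line, or two tab-separated columns (symbol, phase label).
#'
#' @param path File path.
#' @param name Optional set name (defaults to the file name).
#' @return List with `name`, `members` and, for two-column input, `phases`
#'   (named vector symbol -> label).
#' @export
read_geneset <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  members <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(members)) members <- unique(members)
  out <- list(name = name, members = members)
  if (all(lengths(parts) >= 2))
    out$phases <- setNames(vapply(parts, `[[`, character(1), 2),
                           vapply(parts, `[[`, character(1), 1))
  out
}
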