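#' Build a thresholded Pearson correlation graph
#'
#' Computes pairwise Pearson correlations between rows (`axis = "genes"`) or
#' columns (`axis = "samples"`) of an expression matrix and keeps an edge
#' whenever `r >= r_min` (inclusive, matching the convention "correlations
#' of >= 0.85"). Zero-variance profiles have undefined correlations and are
#' excluded; their ids are reported.
#'
#' @param mat Expression matrix (typically replicate-averaged TPM).
#' @param r_min Correlation threshold in (-1, 1].
#' @param axis `"genes"` (correlate rows) or `"samples"` (columns).
#' @return Object of class `coexpr_graph`: list with `nodes`, `edges`
#'   (data frame from/to/weight), `r_min`, `axis`, `excluded`.
#' @export
build_correlation_graph <- function(mat, r_min, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(mat), r_min > -1, r_min <= 1)
  m <- if (axis == "genes") t(mat) else mat  # observations in rows for cor()
  if (nrow(m) < 3)
    stop("need >= 3 observations along the correlation axis, got ", nrow(m))
  if (is.null(colnames(m))) colnames(m) <- sprintf("n%d", seq_len(ncol(m)))
  v <- apply(m, 2, var)
  excluded <- colnames(m)[v == 0 | is.na(v)]
  keep <- setdiff(colnames(m), excluded)
  m <- m[, keep, drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0))
  if (ncol(m) >= 2) {
    r <- cor(m)
    r[lower.tri(r, diag = TRUE)] <- NA
    hit <- which(r >= r_min, arr.ind = TRUE)
    if (nrow(hit))
      edges <- data.frame(from = keep[hit[, 1]], to = keep[hit[, 2]],
                          weight = r[hit], stringsAsFactors = FALSE)
  }
  structure(list(nodes = keep, edges = edges, r_min = r_min, axis = axis,
                 excluded = excluded),
            class = "coexpr_graph")
}

#' @export
print.coexpr_graph <- function(x, ...) {
  cat(sprintf("Co-expression graph (%s): %d nodes, %d edges at r >= %g (%d excluded)\n",
              x$axis, length(x$nodes), nrow(x$edges), x$r_min,
              length(x$excluded)))
  invisible(x)
}

# Symmetric weighted adjacency matrix from a coexpr_graph.
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  A
}

#' Markov Clustering (MCL) of a weighted graph
#'
#' From-scratch canonical MCL on the weighted adjacency matrix with
#' self-loops (loop weight = maximum incident edge weight, or 1 for isolated
#' nodes): column-normalize, then iterate expansion (matrix power),
#' inflation (elementwise power followed by column renormalization) and
#' pruning of entries below `prune`, until the maximum column change falls
#' below `tol` or `max_iter` is reached. Clusters are read off attractor
#' rows (nonzero diagonal); a node claimed by several attractors is assigned
#' to the lowest-indexed one. Cluster labels are ordered by size
#' (`Cluster001` = largest; ties by smallest member index).
#'
#' @param graph A [build_correlation_graph()] object, or a symmetric
#'   nonnegative adjacency matrix.
#' @param inflation Inflation exponent (> 1); default 1.7.
#' @param expansion Expansion power (integer >= 2); default 2.
#' @param prune Entries below this are zeroed each iteration; default 1e-5.
#' @param max_iter Iteration cap; default 200.
#' @param tol Convergence tolerance on the max absolute change; default 1e-8.
#' @return Object of class `mcl_result`: `membership` (named character
#'   vector node -> cluster label), plus `inflation`, `iterations`,
#'   `converged`, `sizes`.
#' @export
mcl_cluster <- function(graph, inflation = 1.7, expansion = 2, prune = 1e-5,
                        max_iter = 200, tol = 1e-8) {
  A <- if (inherits(graph, "coexpr_graph")) graph_adjacency(graph) else graph
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(A >= 0), inflation > 0,
            expansion >= 2)
  if (nrow(A) == 0) stop("empty graph")
  if (is.null(rownames(A)))
    dimnames(A) <- list(sprintf("n%d", seq_len(nrow(A))),
                        sprintf("n%d", seq_len(nrow(A))))
  nodes <- rownames(A)
  diag(A) <- 0
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1  # isolated nodes still need a stochastic column
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    Mold <- M
    Mexp <- M
    for (e in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    M <- Mexp^inflation
    M[M < prune] <- 0
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M <- sweep(M, 2, cs, "/")
    if (max(abs(M - Mold)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  attractors <- which(diag(M) > prune)
  claim <- M[attractors, , drop = FALSE] > prune
  memb_idx <- apply(claim, 2, function(col) {
    hit <- which(col)
    if (length(hit)) attractors[hit[1]] else NA_integer_
  })
  # unclaimed nodes (fully pruned columns): attach to their strongest row
  for (j in which(is.na(memb_idx)))
    memb_idx[j] <- which.max(M[, j] + A[, j])
  fac <- factor(memb_idx)
  sizes <- table(fac)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  labels <- character(nlevels(fac))
  labels[ord] <- sprintf("Cluster%03d", seq_along(ord))
  membership <- setNames(labels[as.integer(fac)], nodes)
  structure(list(membership = membership, inflation = inflation,
                 iterations = iter, converged = converged,
                 sizes = sort(table(membership), decreasing = TRUE)),
            class = "mcl_result")
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("MCL result: %d nodes in %d clusters (inflation %g, %d iterations%s)\n",
              length(x$membership), length(x$sizes), x$inflation,
              x$iterations, if (x$converged) "" else ", NOT converged"))
  big <- sum(x$sizes >= 10)
  cat(sprintf("  %d cluster(s) with >= 10 nodes; largest: %s (%d nodes)\n",
              big, names(x$sizes)[1], x$sizes[1]))
  invisible(x)
}

#' Mean expression profile per cluster
#'
#' @param result A [mcl_cluster()] result.
#' @param mat Expression matrix containing every clustered node as a row.
#' @param scale `"none"` or `"max"` (each member profile divided by its own
#'   maximum before averaging).
#' @return Clusters x time-points matrix of mean profiles, with attribute
#'   `scale`.
#' @export
cluster_mean_profiles <- function(result, mat, scale = c("none", "max")) {
  scale <- match.arg(scale)
  stopifnot(inherits(result, "mcl_result"),
            all(names(result$membership) %in% rownames(mat)))
  m <- mat[names(result$membership), , drop = FALSE]
  if (scale == "max") {
    mx <- apply(m, 1, max)
    mx[mx == 0] <- 1
    m <- m / mx
  }
  labs <- sort(unique(result$membership))
  out <- t(vapply(labs, function(cl)
    colMeans(m[result$membership == cl, , drop = FALSE]),
    numeric(ncol(m))))
  dimnames(out) <- list(labs, colnames(mat))
  attr(out, "scale") <- scale
  out
}

#' Re-cluster one expression cluster at higher stringency
#'
#' Composes [build_correlation_graph()] and [mcl_cluster()] on the rows of
#' `mat` (typically a single parent cluster's members); nodes failing
#' `r_min` against every other node are reported as excluded.
#'
#' @param mat Expression matrix restricted to the members of one cluster.
#' @param r_min Correlation threshold.
#' @param inflation MCL inflation.
#' @return List with `result` (an `mcl_result` over connected nodes) and
#'   `excluded` (node ids dropped: zero-variance or unconnected).
#' @export
subcluster <- function(mat, r_min, inflation = 1.7) {
  g <- build_correlation_graph(mat, r_min, axis = "genes")
  connected <- union(g$edges$from, g$edges$to)
  unconnected <- setdiff(g$nodes, connected)
  g$nodes <- intersect(g$nodes, connected)
  if (length(g$nodes) == 0)
    return(list(result = NULL, excluded = c(g$excluded, unconnected)))
  res <- mcl_cluster(g, inflation = inflation)
  list(result = res, excluded = c(g$excluded, unconnected))
}

#' Rand index between two partitions
#'
#' Fraction of node pairs on which two partitions agree (same/different
#' cluster). Used to score cluster recovery against simulation truth.
#'
#' @param a,b Cluster label vectors over the same nodes (names matched when
#'   both are named).
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b)) &&
      all(names(a) %in% names(b)))
    b <- b[names(a)]
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  sum(same_a[ut] == same_b[ut]) / sum(ut)
}
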