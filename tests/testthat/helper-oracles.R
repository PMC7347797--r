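# Independent reference implementations used only as test oracles.

# Minimal Markov Clustering, written independently of the package's
# implementation: no pruning, fixed expansion 2, long deterministic
# iteration; membership read off attractor rows.
oracle_mcl <- function(A, inflation = 1.7, iters = 400) {
  diag(A) <- 0
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- A
  for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
  }
  M[M < 1e-9] <- 0
  att <- which(diag(M) > 1e-9)
  vapply(seq_len(ncol(M)), function(j) att[which(M[att, j] > 1e-9)[1]],
         numeric(1))
}

# Exhaustive hypergeometric tails by enumerating every size-n subset of a
# population of N in which the first K elements form the class.
oracle_hyper_dist <- function(N, K, n) {
  if (n == 0) return(c(`0` = 1))
  subsets <- combn(N, n)
  k <- colSums(subsets <= K)
  table(factor(k, levels = 0:min(K, n))) / ncol(subsets)
}

oracle_hyper_tail <- function(N, K, n, k, tail) {
  d <- oracle_hyper_dist(N, K, n)
  ks <- as.integer(names(d))
  if (tail == "over") sum(d[ks >= k]) else sum(d[ks <= k])
}

# Brute-force PFM hit counting: explicit per-position score loop on both
# strands, with the same scoring convention (pseudocount 0.5, uniform
# background, threshold = frac * max achievable).
oracle_count_hits <- function(seq, pfm, score_frac) {
  lods <- log2(sweep(pfm + 0.5, 2, colSums(pfm) + 2, "/") / 0.25)
  thr <- score_frac * sum(apply(lods, 2, max))
  count_on <- function(s) {
    ch <- strsplit(s, "")[[1]]
    L <- ncol(lods)
    hits <- 0
    if (length(ch) < L) return(0)
    for (p in 1:(length(ch) - L + 1)) {
      sc <- 0
      for (j in 1:L) {
        b <- match(ch[p + j - 1], c("A", "C", "G", "T"))
        if (is.na(b)) { sc <- NA; break }
        sc <- sc + lods[b, j]
      }
      if (!is.na(sc) && sc >= thr) hits <- hits + 1
    }
    hits
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                     collapse = ""))
  count_on(seq) + count_on(rc)
}

# Partitions equal up to label names.
same_partition <- function(a, b) {
  isTRUE(all.equal(rand_index(unname(as.character(a)),
                              unname(as.character(b))), 1))
}
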