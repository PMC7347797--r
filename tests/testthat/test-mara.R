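make_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

test_that("promoter windows follow the strand-aware -300..+100 contract", {
  set.seed(31)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  fa <- make_genome(c(chrT = chr))
  cl <- data.frame(cluster_id = c("p", "m", "edge"), chrom = "chrT",
                   dominant_pos = c(1000, 1000, 50),
                   strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- extract_promoter_windows(cl, fa)
  expect_equal(as.character(w[["p"]]), substr(chr, 701, 1100))
  expect_equal(Biostrings::width(w)[1], 400)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 901, 1300))))
  expect_equal(as.character(w[["m"]]), rc)
  expect_true(S4Vectors::mcols(w)$truncated[3])
  expect_false(any(S4Vectors::mcols(w)$truncated[1:2]))
  expect_error(extract_promoter_windows(
    data.frame(cluster_id = "x", chrom = "nope", dominant_pos = 10,
               strand = "+"), fa), "absent")
})

test_that("JASPAR matrices round-trip through the text parser", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 MOTIF_A",
    "A  [ 10  0  0 ]",
    "C  [  0 10  0 ]",
    "G  [  0  0 10 ]",
    "T  [  0  0  0 ]",
    ">MA0002.1 MOTIF_B",
    "A 1 2", "C 3 4", "G 5 6", "T 7 8"), path)
  pwms <- read_jaspar(path)
  expect_named(pwms, c("MOTIF_A", "MOTIF_B"))
  expect_equal(dim(pwms$MOTIF_A), c(4, 3))
  expect_equal(unname(pwms$MOTIF_A["A", 1]), 10)
  expect_equal(unname(pwms$MOTIF_B["T", 2]), 8)
})

test_that("motif counting finds consensus sites on both strands", {
  pfm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm["A", 1] <- pfm["C", 2] <- pfm["G", 3] <- pfm["T", 4] <- 20
  # one forward consensus ACGT... plus one reverse-complement occurrence
  win <- c(w1 = "GGGGACGTGGGG", w2 = "GGGGACGTGGGG")
  n <- count_motifs(win, list(M = pfm), score_frac = 1)
  # ACGT is its own reverse complement, so the scan sees it on both strands
  expect_equal(unname(n[, "M"]), c(2, 2))
  asym <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  asym["A", 1] <- asym["A", 2] <- asym["C", 3] <- 20
  n2 <- count_motifs(c(f = "TTAACTT", r = "TTAGTTT"), list(M = asym),
                     score_frac = 1)
  expect_equal(unname(n2[, 1]), c(1, 1))  # AAC forward, GTT = revcomp(AAC)
})

test_that("motif counting agrees with the brute-force oracle", {
  set.seed(32)
  pfms <- list(
    uniform = matrix(5, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL)),
    skewed = matrix(rpois(4 * 6, 3) + 1, 4, 6,
                    dimnames = list(c("A", "C", "G", "T"), NULL)),
    sharp = {
      m <- matrix(0, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
      m[cbind(sample(4, 5, TRUE), 1:5)] <- 12
      m
    })
  wins <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""),
    character(1))
  names(wins) <- sprintf("w%d", 1:6)
  for (frac in c(1, 0.9, 0.7)) {
    got <- count_motifs(wins, pfms, score_frac = frac)
    want <- sapply(pfms, function(p)
      vapply(wins, oracle_count_hits, numeric(1), pfm = p, score_frac = frac))
    expect_equal(unname(got), unname(want), info = paste("frac", frac))
  }
  # motif longer than the window counts zero with a warning
  expect_warning(
    n <- count_motifs(c(short = "ACG"),
                      list(long = matrix(3, 4, 10,
                        dimnames = list(c("A", "C", "G", "T"), NULL)))),
    "longer")
  expect_equal(unname(n[1, 1]), 0L)
})

test_that("an identity design at lambda 0 returns the double-centered expression", {
  set.seed(33)
  E <- matrix(rnorm(30), 6, 5,
              dimnames = list(sprintf("p%d", 1:6), sprintf("s%d", 1:5)))
  N <- diag(6); dimnames(N) <- list(rownames(E), sprintf("m%d", 1:6))
  fit <- fit_mara(E, N, lambda = 0)
  Edc <- sweep(E - rowMeans(E), 2, colMeans(E - rowMeans(E)))
  expect_equal(unname(coef(fit)), unname(Edc), tolerance = 1e-10)
})

test_that("a noiseless planted design is recovered exactly at lambda 0", {
  set.seed(34)
  P <- 80; M <- 5; S <- 7
  N <- matrix(rpois(P * M, 1), P, M,
              dimnames = list(sprintf("p%d", 1:P), sprintf("m%d", 1:M)))
  A_true <- matrix(rnorm(M * S), M, S)
  A_true <- A_true - rowMeans(A_true)
  E <- outer(rnorm(P), rep(1, S)) + rep(1, P) %o% rnorm(S) + N %*% A_true
  dimnames(E) <- list(rownames(N), sprintf("s%d", 1:S))
  fit <- fit_mara(E, N, lambda = 0)
  expect_equal(unname(coef(fit)), unname(A_true), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
  # collinear motifs are refused at lambda 0
  N_bad <- cbind(N, dup = N[, 1])
  expect_error(fit_mara(E, N_bad, lambda = 0), "rank-deficient")
})

test_that("activities vanish under an overwhelming ridge penalty", {
  set.seed(35)
  E <- matrix(rnorm(60), 12, 5)
  N <- matrix(rpois(12 * 3, 1), 12, 3)
  big <- 1e6 * max(svd(scale(N, scale = FALSE))$d)^2
  fit <- fit_mara(E, N, lambda = big)
  expect_lt(max(abs(coef(fit))), 1e-4)
})

test_that("activities are invariant to row and column offsets of E", {
  set.seed(36)
  E <- matrix(rnorm(60), 12, 5)
  N <- matrix(rpois(12 * 3, 1), 12, 3)
  f0 <- fit_mara(E, N, lambda = 1)
  E_shift <- E; E_shift[3, ] <- E_shift[3, ] + 7
  E_shift <- sweep(E_shift, 2, c(-2, 0, 5, 1, 3), "+")
  f1 <- fit_mara(E_shift, N, lambda = 1)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-8)
})

test_that("the residual never decreases as the penalty grows", {
  set.seed(37)
  E <- matrix(rnorm(200), 40, 5)
  N <- matrix(rpois(40 * 4, 1), 40, 4)
  rss <- vapply(c(0, 0.1, 1, 10, 100, 1e4),
                function(l) fit_mara(E, N, lambda = l)$rss, numeric(1))
  expect_true(all(diff(rss) >= -1e-9))
})

test_that("activity clustering separates rising from declining archetypes", {
  set.seed(38)
  tp <- c(0, 1, 2, 4, 8, 12, 24, 48)
  up <- t(replicate(4, tp / 48 + rnorm(8, 0, 0.02)))
  down <- t(replicate(4, -tp / 48 + rnorm(8, 0, 0.02)))
  A <- rbind(up, down)
  rownames(A) <- sprintf("motif%d", 1:8)
  cl <- cluster_activities(A, r_min = 0.6)
  expect_true(same_partition(cl$result$membership[rownames(A)],
                             rep(1:2, each = 4)))
  # degenerate inputs
  one <- cluster_activities(A[1, , drop = FALSE])
  expect_equal(unname(one$result$membership), "Cluster001")
  same <- A[rep(1, 4), ]; rownames(same) <- sprintf("m%d", 1:4)
  cl_same <- cluster_activities(same)
  expect_length(cl_same$result$sizes, 1)
})
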