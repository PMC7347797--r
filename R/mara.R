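#' Extract promoter windows around CTSS midpoints
#'
#' For each tag cluster, extracts the `-upstream..+downstream` window
#' (default -300..+100 bp) around the cluster's dominant CTSS position: on
#' the + strand `[mid - upstream, mid + downstream)`, on the - strand
#' `[mid - downstream, mid + upstream)` reverse-complemented. Windows
#' truncated at chromosome edges are flagged.
#'
#' @param clusters A [aggregate_ctss()] object, or a data frame with
#'   `cluster_id`, `chrom`, `dominant_pos`, `strand`.
#' @param genome `Biostrings::DNAStringSet` or FASTA path.
#' @param upstream,downstream Window extent in bp; defaults 300 and 100.
#' @return `DNAStringSet` named by cluster id, with metadata column
#'   `truncated`.
#' @export
extract_promoter_windows <- function(clusters, genome, upstream = 300,
                                     downstream = 100) {
  cl <- if (inherits(clusters, "tag_clusters")) clusters$clusters else clusters
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  missing <- setdiff(unique(cl$chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  mid <- cl$dominant_pos
  s0 <- ifelse(cl$strand == "+", mid - upstream, mid - downstream)
  e0 <- ifelse(cl$strand == "+", mid + downstream, mid + upstream)
  # clip to [1, chrlen] in 1-based coordinates
  s1 <- pmax(s0 + 1, 1)
  e1 <- pmin(e0, lens[cl$chrom])
  truncated <- s1 != s0 + 1 | e1 != e0
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(cl)), function(i)
    as.character(Biostrings::subseq(genome[[cl$chrom[i]]], s1[i], e1[i])),
    character(1)))
  minus <- cl$strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- cl$cluster_id
  S4Vectors::mcols(seqs)$truncated <- truncated
  seqs
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses records of the form `>ID name` followed by four lines
#' `A [ 3 5 ... ]` (brackets optional) giving base counts per position.
#'
#' @param path File path.
#' @return Named list of 4 x L numeric matrices with rownames ACGT.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no JASPAR records (no '>' headers) in ", path)
  pwms <- list()
  for (h in seq_along(hdr)) {
    block <- lines[(hdr[h] + 1):(if (h < length(hdr)) hdr[h + 1] - 1
                                 else length(lines))]
    if (length(block) != 4) stop("JASPAR record needs 4 base rows: ",
                                 lines[hdr[h]])
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(v[-1])  # drop the base letter
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged JASPAR record: ", lines[hdr[h]])
    m <- do.call(rbind, rows)
    rownames(m) <- toupper(substr(trimws(block), 1, 1))
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    name <- strsplit(sub("^>\\s*", "", lines[hdr[h]]), "\\s+")[[1]]
    pwms[[tail(name, 1)]] <- m
  }
  pwms
}

# Log-odds score matrix for a PFM: uniform background, pseudocount 0.5.
pfm_logodds <- function(pfm) {
  stopifnot(all(pfm >= 0), all(colSums(pfm) > 0))
  p <- sweep(pfm + 0.5, 2, colSums(pfm) + 2, "/")
  log2(p / 0.25)
}

# Count hits of one PFM on one integer-encoded sequence (one strand).
scan_one_strand <- function(code, lods, min_score) {
  L <- ncol(lods)
  P <- length(code) - L + 1
  if (P < 1) return(0L)
  idx <- outer(seq_len(P) - 1L, seq_len(L), "+")
  base <- code[idx]                       # P x L base codes (NA for N)
  sc <- matrix(lods[cbind(as.vector(base), rep(seq_len(L), each = P))],
               nrow = P)
  scores <- rowSums(sc)
  sum(!is.na(scores) & scores >= min_score)
}

#' Count motif occurrences in promoter windows
#'
#' Log-odds scan (uniform background, pseudocount 0.5) of each PFM over
#' both strands of each window; a hit is a position scoring at least
#' `score_frac` times the motif's maximum achievable score.
#'
#' @param windows `DNAStringSet` (e.g. from [extract_promoter_windows()])
#'   or character vector of sequences.
#' @param pwms Named list of 4 x L PFMs (rownames ACGT), e.g. from
#'   [read_jaspar()].
#' @param score_frac Fraction of the maximum score in (0, 1]; default 0.85.
#' @return Nonnegative integer matrix, windows x motifs.
#' @export
count_motifs <- function(windows, pwms, score_frac = 0.85) {
  stopifnot(score_frac > 0, score_frac <= 1)
  seqs <- as.character(windows)
  codes <- lapply(strsplit(toupper(seqs), ""), function(ch)
    match(ch, c("A", "C", "G", "T")))
  N <- matrix(0L, length(seqs), length(pwms),
              dimnames = list(names(windows), names(pwms)))
  for (m in seq_along(pwms)) {
    lods <- pfm_logodds(pwms[[m]])
    rc <- lods[4:1, rev(seq_len(ncol(lods))), drop = FALSE]  # revcomp scan
    min_score <- score_frac * sum(apply(lods, 2, max))
    too_long <- FALSE
    for (w in seq_along(codes)) {
      if (length(codes[[w]]) < ncol(lods)) { too_long <- TRUE; next }
      N[w, m] <- scan_one_strand(codes[[w]], lods, min_score) +
        scan_one_strand(codes[[w]], rc, min_score)
    }
    if (too_long)
      warning("motif ", names(pwms)[m],
              " longer than some window(s); counted 0 there")
  }
  N
}

#' Fit motif activities by MARA-style ridge regression
#'
#' Fits the linear model `E_ps = c_p + c_s + sum_m N_pm A_ms` for
#' log-expression `E` (promoters x samples) and motif counts `N`
#' (promoters x motifs): `E` is double-centered (promoter and sample means
#' removed), `N` column-centered, and the activities solved as
#' `A = (N'N + lambda I)^-1 N' E`, then re-centered per motif so each
#' motif's activities sum to zero across samples. Z-scores are
#' `A / SE(A)` with standard errors from the ridge covariance
#' (`sigma^2 (N'N + lambda I)^-1 N'N (N'N + lambda I)^-1`).
#'
#' @param E Promoters x samples matrix of log-expression (e.g.
#'   `log2(TPM + 1)`); rows aligned with `N`.
#' @param N Promoters x motifs nonnegative count matrix.
#' @param lambda Ridge penalty (>= 0), or `"gcv"` (default) to minimize
#'   generalized cross-validation over a log-spaced grid.
#' @return Object of class `mara_fit` with `activities` (motifs x samples,
#'   rows sum to 0), `zscores`, `se`, `lambda`, `rss`, `fitted`,
#'   `residuals`, and the centering components.
#' @export
fit_mara <- function(E, N, lambda = "gcv") {
  stopifnot(is.matrix(E), is.matrix(N), nrow(E) == nrow(N))
  if (!is.null(rownames(E)) && !is.null(rownames(N)) &&
      !identical(unname(rownames(E)), unname(rownames(N))))
    stop("promoters of E and N are not aligned")
  row_means <- rowMeans(E)
  Ec <- E - row_means
  col_means <- colMeans(Ec)
  Ec <- sweep(Ec, 2, col_means)
  Nc <- scale(N, center = TRUE, scale = FALSE)
  sv <- svd(Nc)
  d2 <- sv$d^2
  if (identical(lambda, "gcv")) {
    grid <- 10^seq(-2, 4, length.out = 25)
    UtE <- crossprod(sv$u, Ec)
    gcv <- vapply(grid, function(l) {
      shrink <- d2 / (d2 + l)
      rss <- sum((UtE * (shrink - 1))^2) +
        (sum(Ec^2) - sum(UtE^2))  # component orthogonal to col(Nc)
      df <- sum(shrink)
      rss / (1 - df / nrow(E))^2
    }, numeric(1))
    lambda <- grid[which.min(gcv)]
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  # column-centering always loses (at most) the constant direction, which the
  # activity re-centering absorbs; genuine collinearity beyond that is an error
  # at lambda = 0
  tol <- max(dim(Nc)) * max(sv$d, 0) * .Machine$double.eps
  rank_nc <- sum(sv$d > tol)
  if (lambda == 0 && rank_nc < min(ncol(Nc), nrow(Nc) - 1))
    stop("N is rank-deficient after centering; use lambda > 0")
  dinv <- ifelse(sv$d > tol, sv$d / (sv$d^2 + lambda), 0)
  A <- sv$v %*% (dinv * crossprod(sv$u, Ec))
  A <- A - rowMeans(A)
  fitted_c <- Nc %*% A
  resid <- Ec - fitted_c
  rss <- sum(resid^2)
  df <- sum(d2 / (d2 + lambda))
  sigma2 <- rss / max(1, (nrow(E) - df - 1) * ncol(E))
  se_m <- sqrt(pmax(0, sigma2 * colSums(t(sv$v^2) * dinv^2)))
  se <- matrix(se_m, nrow(A), ncol(A))
  dimnames(A) <- list(colnames(N), colnames(E))
  dimnames(se) <- dimnames(A)
  z <- A / ifelse(se == 0, NA, se)
  fit <- list(activities = A, zscores = z, se = se, lambda = lambda,
              rss = rss, fitted = fitted_c, residuals = resid,
              row_means = row_means, col_means = col_means,
              n_promoters = nrow(E))
  class(fit) <- "mara_fit"
  fit
}

#' @export
print.mara_fit <- function(x, ...) {
  cat(sprintf("MARA fit: %d motifs x %d samples (%d promoters), lambda = %.4g\n",
              nrow(x$activities), ncol(x$activities), x$n_promoters,
              x$lambda))
  cat(sprintf("  residual sum of squares: %.4g\n", x$rss))
  invisible(x)
}

#' @method coef mara_fit
#' @export
coef.mara_fit <- function(object, ...) object$activities

#' @method residuals mara_fit
#' @export
residuals.mara_fit <- function(object, ...) object$residuals

#' @method predict mara_fit
#' @export
predict.mara_fit <- function(object, N = NULL, ...) {
  if (is.null(N)) {
    fit <- object$fitted
  } else {
    Nc <- scale(N, center = TRUE, scale = FALSE)
    fit <- Nc %*% object$activities
  }
  sweep(fit + object$row_means, 2, -object$col_means)
}

#' @method summary mara_fit
#' @export
summary.mara_fit <- function(object, ...) {
  zr <- apply(abs(object$zscores), 1, max, na.rm = TRUE)
  out <- data.frame(motif = rownames(object$activities),
                    activity_range = apply(object$activities, 1,
                                           function(a) diff(range(a))),
                    max_abs_z = zr, stringsAsFactors = FALSE)
  out[order(-out$max_abs_z), ]
}

#' @method plot mara_fit
#' @export
plot.mara_fit <- function(x, ...) {
  matplot(t(x$activities), type = "l", lty = 1, xlab = "sample",
          ylab = "motif activity", ...)
  legend("topleft", legend = rownames(x$activities), lty = 1,
         col = seq_len(nrow(x$activities)), cex = 0.7, bty = "n")
  invisible(x)
}

#' Cluster motif activity profiles
#'
#' Builds a correlation graph over motif activity profiles (default
#' r >= 0.60) and partitions it with MCL at inflation 1.7.
#'
#' @param fit A [fit_mara()] object or a motifs x samples activity matrix.
#' @param r_min Correlation threshold; default 0.60.
#' @param inflation MCL inflation; default 1.7.
#' @return An `mcl_result` over the connected motifs (see [subcluster()]):
#'   list with `result` and `excluded`.
#' @export
cluster_activities <- function(fit, r_min = 0.60, inflation = 1.7) {
  A <- if (inherits(fit, "mara_fit")) fit$activities else fit
  if (nrow(A) == 1)
    return(list(result = structure(
      list(membership = setNames("Cluster001", rownames(A)),
           inflation = inflation, iterations = 0L, converged = TRUE,
           sizes = table(c(Cluster001 = "Cluster001"))),
      class = "mcl_result"), excluded = character(0)))
  subcluster(A, r_min = r_min, inflation = inflation)
}
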