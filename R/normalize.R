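#' Fit a power law to a tag-count distribution
#'
#' Fits a least-squares line to the log10 reverse-cumulative frequency of
#' CTSS tag counts, restricted to counts inside `fit_range`: for each
#' distinct count value x, the number of CTSS with count >= x. The fitted
#' tail exponent is `alpha = -slope`.
#'
#' @param counts Nonnegative tag counts (one sample).
#' @param fit_range Length-2 numeric, counts included in the fit
#'   (inclusive); default `c(10, 1000)`.
#' @return Object of class `power_law_fit` with fields `alpha`,
#'   `log_intercept`, `fit_range`, `r2`, `n_points`.
#' @export
fit_power_law <- function(counts, fit_range = c(10, 1000)) {
  stopifnot(all(counts >= 0), length(fit_range) == 2, fit_range[1] > 0)
  x <- sort(unique(counts[counts >= fit_range[1] & counts <= fit_range[2]]))
  if (length(x) < 10)
    stop("fewer than 10 distinct count values in fit_range [",
         fit_range[1], ", ", fit_range[2],
         "]; widen the range or supply deeper data")
  revcum <- vapply(x, function(v) sum(counts >= v), numeric(1))
  fit <- lm(log10(revcum) ~ log10(x))
  structure(list(alpha = -unname(coef(fit)[2]),
                 log_intercept = unname(coef(fit)[1]),
                 fit_range = fit_range,
                 r2 = summary(fit)$r.squared,
                 n_points = length(x)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: alpha = %.3f (r2 = %.3f, %d distinct counts in [%g, %g])\n",
    x$alpha, x$r2, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Normalize tag counts to a reference power law
#'
#' Applies the monotone transform `x -> b * x^(alpha / alpha_ref)` per
#' sample, where `alpha` is the sample's fitted tail exponent and `b` is
#' chosen so the normalized sample total equals `total_ref`. Rank order
#' within a sample is preserved and zero counts map to zero. When
#' `alpha == alpha_ref` the transform reduces to pure rescaling
#' `x * total_ref / sum(x)`.
#'
#' @param x Numeric vector of one sample's counts, or a sites/clusters x
#'   samples matrix.
#' @param fit Optional [fit_power_law()] result for a vector `x`; fitted
#'   from `x` when NULL. Ignored for matrices.
#' @param alpha_ref Reference tail exponent (> 0); default 1.25.
#' @param total_ref Normalized per-sample total; default 1e6.
#' @param fit_range Count range used when fitting; see [fit_power_law()].
#' @param pool_alpha For matrices only: use the median of the per-sample
#'   fitted exponents as one common exponent (default TRUE). Samples of one
#'   experiment share a tail exponent; pooling removes the sizeable
#'   sample-to-sample jitter of the exponent estimate at modest CTSS
#'   numbers, which would otherwise distort high counts differently in
#'   every sample. Set FALSE for fully independent per-sample fits.
#' @return Normalized values, same shape as `x`. Matrices carry the
#'   attribute `alphas` (per-sample fitted exponents) and `alpha_used`.
#' @export
normalize_power_law <- function(x, fit = NULL, alpha_ref = 1.25,
                                total_ref = 1e6, fit_range = c(10, 1000),
                                pool_alpha = TRUE) {
  if (alpha_ref <= 0) stop("alpha_ref must be > 0")
  if (total_ref <= 0) stop("total_ref must be > 0")
  if (is.matrix(x)) {
    fits <- apply(x, 2, fit_power_law, fit_range = fit_range)
    alphas <- vapply(fits, `[[`, numeric(1), "alpha")
    if (pool_alpha) {
      pooled <- median(alphas)
      out <- apply(x, 2, function(col) {
        y <- col^(pooled / alpha_ref)
        y * (total_ref / sum(y))
      })
    } else {
      out <- vapply(seq_len(ncol(x)), function(j)
        normalize_power_law(x[, j], fit = fits[[j]], alpha_ref = alpha_ref,
                            total_ref = total_ref, fit_range = fit_range),
        numeric(nrow(x)))
    }
    dimnames(out) <- dimnames(x)
    attr(out, "alphas") <- alphas
    attr(out, "alpha_used") <- if (pool_alpha) median(alphas) else alphas
    return(out)
  }
  if (is.null(fit)) fit <- fit_power_law(x, fit_range)
  stopifnot(inherits(fit, "power_law_fit"))
  y <- x^(fit$alpha / alpha_ref)
  tot <- sum(y)
  if (tot == 0) stop("sample total is zero; cannot normalize")
  y * (total_ref / tot)
}

#' Convert a value matrix to tags per million
#'
#' Rescales every column so it sums to 1e6. Immediately after conversion
#' (before any row filtering) every column sum is 1e6 up to floating
#' point.
#'
#' @param mat Nonnegative clusters x samples matrix.
#' @return TPM matrix of the same shape.
#' @export
to_tpm <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  cs <- colSums(mat)
  if (any(cs == 0)) stop("sample(s) with zero total: ",
                         paste(colnames(mat)[cs == 0], collapse = ", "))
  sweep(mat, 2, cs / 1e6, "/")
}

#' Filter to expressed rows
#'
#' Keeps rows with at least `min_samples` samples at value >= `min_tpm`
#' (inclusive thresholds: "at least 10 TPM in at least one sample").
#'
#' @param mat TPM matrix (rows = tag clusters).
#' @param min_tpm Inclusive expression threshold; default 10.
#' @param min_samples Inclusive sample-count threshold; default 1.
#' @return The filtered matrix (possibly zero rows).
#' @export
filter_expressed <- function(mat, min_tpm = 10, min_samples = 1) {
  stopifnot(is.matrix(mat), min_tpm >= 0, min_samples >= 0)
  keep <- rowSums(mat >= min_tpm) >= min_samples
  mat[keep, , drop = FALSE]
}

#' Average expression over replicates per time point
#'
#' @param mat Clusters x samples matrix; columns must match
#'   `samples$sample_id`.
#' @param samples Data frame with `sample_id` and `time_h`.
#' @return Clusters x time-points matrix (columns `t<hours>`, ordered by
#'   time), with attribute `n_replicates` (replicates per time point) and
#'   `time_h`.
#' @export
average_replicates <- function(mat, samples) {
  stopifnot(is.matrix(mat), all(colnames(mat) %in% samples$sample_id))
  if (anyNA(mat)) stop("NaN/NA in expression matrix; upstream must not emit NaN")
  time_h <- samples$time_h[match(colnames(mat), samples$sample_id)]
  tps <- sort(unique(time_h))
  out <- vapply(tps, function(tt) {
    idx <- which(time_h == tt)
    if (length(idx) == 0) stop("time point with zero samples: ", tt)
    rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1) out <- matrix(out, nrow = 1)
  labs <- if (all(tps == round(tps))) sprintf("t%03d", as.integer(tps))
          else sprintf("t%g", tps)
  dimnames(out) <- list(rownames(mat), labs)
  attr(out, "n_replicates") <- as.integer(table(factor(time_h, levels = tps)))
  attr(out, "time_h") <- tps
  out
}
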