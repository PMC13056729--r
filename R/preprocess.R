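#' Variance-stabilised highly-variable-gene statistic
#'
#' The Seurat-v3 "vst" flavour: a loess trend (span 0.3) of log10 variance on
#' log10 mean predicts each gene's expected standard deviation; counts are
#' standardised by the predicted sd, clipped at `sqrt(n)`, and genes are
#' ranked by the variance of the standardised counts. Ties break by gene
#' order.
#'
#' @param counts spots x genes integer matrix.
#' @return numeric vector of standardised variances, one per gene.
#' @export
hvg_vst_statistic <- function(counts) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  mu <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  est <- numeric(ncol(counts))
  use <- v > 0 & mu > 0
  if (sum(use) > 1) {
    fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = 0.3, degree = 2)
    est[use] <- 10^fit$fitted
  }
  clip <- sqrt(n)
  out <- numeric(ncol(counts))
  for (g in which(use)) {
    z <- (counts[, g] - mu[g]) / sqrt(est[g])
    z <- pmin(pmax(z, -clip), clip)
    # variance of clipped standardised counts about the (pre-clip) zero mean
    out[g] <- sum(z^2) / (n - 1)
  }
  out
}

#' Preprocess a dataset for the encoder
#'
#' Selects the top `n_hvg` highly variable genes (vst ranking), restricts the
#' raw counts (the ZINB reconstruction target) to those genes, and builds the
#' encoder input: library-size normalisation to the median library size,
#' `log1p`, then per-gene scaling to zero mean / unit variance with values
#' clipped at `+/- scale_clip`.
#'
#' @param ds a [spot_dataset()] holding raw counts.
#' @param n_hvg number of highly variable genes to keep (default 3000; all
#'   genes are kept when fewer are present).
#' @param target_sum library-size target; default the median library size.
#' @param scale_clip clip for scaled values (default 10).
#' @return A new [spot_dataset()] with `expr` replaced and genes subset.
#' @export
preprocess <- function(ds, n_hvg = 3000, target_sum = NULL, scale_clip = 10) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (n_hvg < 1) stopf("n_hvg must be >= 1")
  counts <- ds$counts
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    stopf("spot(s) with zero total count: %s (filter before preprocessing)",
          paste(ds$spot_ids[lib == 0], collapse = ", "))
  }
  d <- ncol(counts)
  keep <- seq_len(d)
  if (n_hvg < d) {
    stat <- hvg_vst_statistic(counts)
    keep <- sort(order(-stat, seq_len(d))[seq_len(n_hvg)])
  }
  counts <- counts[, keep, drop = FALSE]
  gene_names <- ds$gene_names[keep]

  if (is.null(target_sum)) target_sum <- stats::median(lib)
  norm <- counts * (target_sum / lib)       # recycles by row
  lg <- log1p(norm)
  mu <- colMeans(lg)
  sd_ <- apply(lg, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  expr <- sweep(sweep(lg, 2, mu), 2, sd_, "/")
  expr <- pmin(pmax(expr, -scale_clip), scale_clip)

  out <- spot_dataset(counts = counts, coords = ds$coords, expr = expr,
                      gene_names = gene_names, spot_ids = ds$spot_ids,
                      labels = ds$labels,
                      mu_true = if (!is.null(ds$mu_true)) ds$mu_true[, keep, drop = FALSE])
  attr(out, "preprocess") <- list(n_hvg = n_hvg, target_sum = target_sum,
                                  scale_clip = scale_clip, hvg_index = keep)
  attr(out, "sim_config") <- attr(ds, "sim_config")
  out
}
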