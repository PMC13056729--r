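#' Container for one spatial transcriptomics section
#'
#' Bundles the raw UMI count matrix, the (optionally preprocessed) expression
#' matrix fed to the encoder, 2-D spot coordinates, identifiers, and optional
#' ground-truth domain labels. Rows of every matrix are spots, in one shared
#' order.
#'
#' @param counts non-negative integer matrix, spots x genes (raw UMI counts).
#' @param coords numeric matrix, spots x 2, platform coordinate units.
#' @param expr numeric matrix, spots x genes' -- the encoder input. Defaults to
#'   `counts` until [preprocess()] replaces it with the normalised/scaled form.
#' @param gene_names character vector, one per column of `expr`.
#' @param spot_ids character vector, one per spot; must be unique.
#' @param labels optional integer vector of ground-truth domains (0-based or
#'   1-based, used only for evaluation).
#' @param mu_true optional numeric matrix of true means (synthetic data only).
#'
#' @return An object of class `spot_dataset`.
#' @export
spot_dataset <- function(counts, coords, expr = NULL, gene_names = NULL,
                         spot_ids = NULL, labels = NULL, mu_true = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  n <- nrow(counts)
  if (is.null(expr)) expr <- counts
  expr <- as.matrix(expr)
  if (is.null(gene_names)) {
    gene_names <- colnames(expr) %||% sprintf("gene_%d", seq_len(ncol(expr)))
  }
  if (is.null(spot_ids)) {
    spot_ids <- rownames(counts) %||% sprintf("spot_%d", seq_len(n))
  }
  bad <- which(counts < 0 | (is.finite(counts) & counts != round(counts)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("counts must be non-negative integers; offending cell: spot '%s', gene column %d (value %g)",
          spot_ids[bad[1, 1]], bad[1, 2], counts[bad[1, 1], bad[1, 2]])
  }
  if (!all(is.finite(expr))) stopf("expr contains non-finite values")
  if (!all(is.finite(coords))) stopf("coords contains non-finite values")
  if (nrow(coords) != n || ncol(coords) != 2) {
    stopf("coords must be an n x 2 matrix matching counts rows (got %d x %d for n = %d)",
          nrow(coords), ncol(coords), n)
  }
  if (nrow(expr) != n) stopf("expr must have one row per spot")
  if (anyDuplicated(spot_ids)) stopf("duplicated spot_ids")
  if (length(spot_ids) != n) stopf("spot_ids length %d != n spots %d", length(spot_ids), n)
  if (length(gene_names) != ncol(expr)) stopf("gene_names length must match expr columns")
  if (!is.null(labels) && length(labels) != n) stopf("labels length must equal n spots")
  structure(
    list(counts = counts, expr = expr, coords = coords,
         gene_names = as.character(gene_names), spot_ids = as.character(spot_ids),
         labels = labels, mu_true = mu_true),
    class = "spot_dataset"
  )
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes (counts), expr %d x %d%s\n",
              nrow(x$counts), ncol(x$counts), nrow(x$expr), ncol(x$expr),
              if (!is.null(x$labels)) sprintf(", %d labelled domains", length(unique(x$labels))) else ""))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)
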