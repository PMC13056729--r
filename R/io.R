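# Readers and writers for the standard on-disk forms: MatrixMarket directories,
# CSV pairs, and h5ad (AnnData) via a subprocess bridge to Python's anndata.

h5ad_bridge_script <- function() {
  p <- system.file("python", "h5ad_bridge.py", package = "spatialDG")
  if (p == "") stopf("h5ad bridge script not found in installed package")
  p
}

run_h5ad_bridge <- function(args) {
  py <- Sys.which("python")
  if (py == "") stopf("h5ad support requires a 'python' with the anndata package on PATH")
  out <- suppressWarnings(system2(py, c(shQuote(h5ad_bridge_script()), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0) stopf("h5ad bridge failed:\n%s", paste(out, collapse = "\n"))
  invisible(out)
}

#' Load a spatial transcriptomics dataset
#'
#' Supported formats: `h5ad` (AnnData with coordinates in the per-observation
#' `spatial` slot; read through a Python `anndata` subprocess), `mtx_dir` (a
#' directory holding `matrix.mtx` spots x genes, `genes.tsv`, `barcodes.tsv`
#' and `coordinates.csv` with columns `spot_id,x,y`), or `csv_pair`
#' (`<stem>_counts.csv` spots x genes with row names, plus
#' `<stem>_coords.csv`).
#'
#' @param path file (h5ad, csv stem) or directory (mtx_dir).
#' @param format one of `"h5ad"`, `"mtx_dir"`, `"csv_pair"`; default guessed
#'   from `path`.
#' @return A [spot_dataset()]; counts are kept as integers and coordinate
#'   order matches matrix row order.
#' @export
load_dataset <- function(path, format = c("auto", "h5ad", "mtx_dir", "csv_pair")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx_dir"
      else if (grepl("\\.h5ad$", path)) "h5ad" else "csv_pair"
  }
  switch(format,
    h5ad = load_h5ad(path),
    mtx_dir = load_mtx_dir(path),
    csv_pair = load_csv_pair(path))
}

load_mtx_dir <- function(path) {
  if (!dir.exists(path)) stopf("mtx_dir '%s' does not exist", path)
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "coordinates.csv")
  miss <- need[!file.exists(file.path(path, need))]
  if ("coordinates.csv" %in% miss) stopf("no spatial coordinates: '%s' lacks coordinates.csv", path)
  if (length(miss)) stopf("mtx_dir '%s' is missing: %s", path, paste(miss, collapse = ", "))
  M <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
  genes <- utils::read.table(file.path(path, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(file.path(path, "barcodes.tsv"), sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  if (length(barcodes) != nrow(M)) {
    stopf("barcode count (%d) does not match matrix rows (%d)", length(barcodes), nrow(M))
  }
  if (length(genes) != ncol(M)) {
    stopf("gene count (%d) does not match matrix columns (%d)", length(genes), ncol(M))
  }
  co <- utils::read.csv(file.path(path, "coordinates.csv"), stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(co))) {
    stopf("coordinates.csv must have columns spot_id, x, y")
  }
  ord <- match(barcodes, co$spot_id)
  if (anyNA(ord)) stopf("no spatial coordinates for barcode(s): %s",
                        paste(utils::head(barcodes[is.na(ord)], 3), collapse = ", "))
  co <- co[ord, ]
  lab <- if ("ground_truth" %in% names(co)) as.integer(co$ground_truth) else NULL
  spot_dataset(counts = M, coords = cbind(co$x, co$y), gene_names = genes,
               spot_ids = barcodes, labels = lab)
}

load_csv_pair <- function(stem) {
  fc <- paste0(stem, "_counts.csv"); fx <- paste0(stem, "_coords.csv")
  if (!file.exists(fc)) stopf("counts file '%s' does not exist", fc)
  if (!file.exists(fx)) stopf("no spatial coordinates: '%s' missing", fx)
  M <- as.matrix(utils::read.csv(fc, row.names = 1, check.names = FALSE))
  co <- utils::read.csv(fx, stringsAsFactors = FALSE)
  ord <- match(rownames(M), co$spot_id)
  if (anyNA(ord)) stopf("no spatial coordinates for spot(s): %s",
                        paste(utils::head(rownames(M)[is.na(ord)], 3), collapse = ", "))
  co <- co[ord, ]
  lab <- if ("ground_truth" %in% names(co)) as.integer(co$ground_truth) else NULL
  spot_dataset(counts = M, coords = cbind(co$x, co$y), gene_names = colnames(M),
               spot_ids = rownames(M), labels = lab)
}

#' Write a dataset as an mtx directory
#'
#' Inverse of `load_dataset(..., format = "mtx_dir")`; raw counts only.
#'
#' @param ds a [spot_dataset()].
#' @param path directory to create.
#' @export
save_mtx_dir <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(ds$counts, sparse = TRUE), "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  gn <- if (length(ds$gene_names) == ncol(ds$counts)) ds$gene_names
        else colnames(ds$counts) %||% sprintf("gene_%d", seq_len(ncol(ds$counts)))
  writeLines(gn, file.path(path, "genes.tsv"))
  writeLines(ds$spot_ids, file.path(path, "barcodes.tsv"))
  co <- data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2])
  if (!is.null(ds$labels)) co$ground_truth <- ds$labels
  utils::write.csv(co, file.path(path, "coordinates.csv"), row.names = FALSE)
  invisible(path)
}

load_h5ad <- function(path) {
  if (!file.exists(path)) stopf("h5ad file '%s' does not exist", path)
  tmp <- tempfile("h5ad_in_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_h5ad_bridge(c("export", shQuote(path), shQuote(tmp)))
  load_mtx_dir(tmp)
}

#' Write a dataset (and optional results) as h5ad
#'
#' Builds an AnnData file through the Python bridge: `X` holds raw counts,
#' `obsm["spatial"]` the coordinates, and optionally `obsm["X_spatialdg"]`
#' (embeddings), `obs["spatialdg_domain"]` (called domains),
#' `obs["ground_truth"]` and `layers["spatialdg_imputed"]`.
#'
#' @param ds a [spot_dataset()].
#' @param path output `.h5ad` path.
#' @param embeddings optional n x h matrix.
#' @param domains optional integer vector of called domains.
#' @param imputed optional n x d matrix (same genes as `ds$counts`).
#' @export
save_h5ad <- function(ds, path, embeddings = NULL, domains = NULL, imputed = NULL) {
  tmp <- tempfile("h5ad_out_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  save_mtx_dir(ds, tmp)
  if (!is.null(embeddings)) {
    utils::write.csv(as.data.frame(embeddings), file.path(tmp, "embeddings.csv"),
                     row.names = FALSE)
  }
  if (!is.null(domains)) {
    writeLines(as.character(domains), file.path(tmp, "domains.txt"))
  }
  if (!is.null(imputed)) {
    utils::write.csv(as.data.frame(imputed), file.path(tmp, "imputed.csv"),
                     row.names = FALSE)
  }
  run_h5ad_bridge(c("import", shQuote(tmp), shQuote(path)))
  invisible(path)
}
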