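#' Simulation settings for ground-truthed spatial transcriptomics data
#'
#' The generator emulates the structure the model assumes: spots on a planar
#' layout partitioned into spatially contiguous domains, per-domain marker-gene
#' programs, and ZINB-distributed counts (gamma-Poisson mixture followed by
#' independent Bernoulli zeroing) with tunable dropout and overdispersion.
#'
#' @param n_spots number of spots.
#' @param layout spot layout: `"hex"` (Visium-like hexagonal lattice, spacing
#'   100 units so a radius of 150 covers the six immediate neighbours),
#'   `"grid"` (square lattice, spacing 100) or `"random"` (uniform square).
#' @param K_true number of ground-truth domains (>= 2).
#' @param domain_geometry `"stripes"` (parallel bands, cortical-layer-like),
#'   `"voronoi"` (nearest of K random seeds) or `"blobs"` (multiplicatively
#'   weighted voronoi, irregular region sizes).
#' @param n_genes,markers_per_domain gene panel size and per-domain markers.
#' @param base_mean baseline NB mean per gene.
#' @param fold_change multiplicative elevation of a marker gene in its domain
#'   (> 1).
#' @param theta_sim NB dispersion (smaller = more overdispersed).
#' @param pi_sim structural dropout probability in \[0, 1).
#' @param library_size_cv sdlog of the per-spot lognormal library factor.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   config.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_spots = 1000, layout = c("hex", "grid", "random"),
                       K_true = 5, domain_geometry = c("stripes", "blobs", "voronoi"),
                       n_genes = 200, markers_per_domain = 20,
                       base_mean = 1, fold_change = 4, theta_sim = 2,
                       pi_sim = 0.3, library_size_cv = 0.2, seed = 0L) {
  layout <- match.arg(layout)
  domain_geometry <- match.arg(domain_geometry)
  if (K_true < 2) stopf("K_true must be >= 2")
  if (pi_sim < 0 || pi_sim >= 1) stopf("pi_sim must lie in [0, 1)")
  if (fold_change <= 1) stopf("fold_change must exceed 1")
  if (markers_per_domain * K_true > n_genes) {
    stopf("markers_per_domain * K_true (%d) exceeds n_genes (%d)",
          markers_per_domain * K_true, n_genes)
  }
  structure(as.list(environment()), class = "sim_config")
}

# Hexagonal lattice with unit spacing `spacing`; odd rows offset by half.
hex_layout <- function(n, spacing = 100) {
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  ij <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  ij <- ij[seq_len(n), ]
  x <- (ij$col - 1) * spacing + ifelse(ij$row %% 2 == 0, spacing / 2, 0)
  y <- (ij$row - 1) * spacing * sqrt(3) / 2
  cbind(x = x, y = y)
}

grid_layout <- function(n, spacing = 100) {
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  ij <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))
  ij <- ij[seq_len(n), ]
  cbind(x = (ij$col - 1) * spacing, y = (ij$row - 1) * spacing)
}

#' Suggested spatial radius for a generated layout
#'
#' Lattice layouts use spacing 100, so 150 covers exactly the first (six- or
#' four-) neighbour shell and excludes the second; random layouts get the
#' radius that yields about six expected neighbours.
#'
#' @param cfg a [sim_config()].
#' @return radius in coordinate units.
#' @export
suggested_radius <- function(cfg) {
  if (cfg$layout %in% c("hex", "grid")) 150 else {
    side <- sqrt(cfg$n_spots) * 100
    sqrt(6 * side^2 / (pi * cfg$n_spots))
  }
}

assign_domains <- function(coords, cfg) {
  K <- cfg$K_true
  switch(cfg$domain_geometry,
    stripes = {
      # K contiguous bands with (near-)equal spot counts along y
      qs <- stats::quantile(coords[, 2], probs = seq(0, 1, length.out = K + 1))
      lab <- as.integer(cut(coords[, 2], breaks = unique(qs), include.lowest = TRUE,
                            labels = FALSE))
      # collapsed quantiles (ties) can drop levels; re-index densely
      as.integer(factor(lab))
    },
    voronoi = {
      seeds <- coords[sample.int(nrow(coords), K), , drop = FALSE]
      d2 <- outer(rowSums(coords^2), rowSums(seeds^2), "+") - 2 * coords %*% t(seeds)
      max.col(-d2, ties.method = "first")
    },
    blobs = {
      seeds <- coords[sample.int(nrow(coords), K), , drop = FALSE]
      wts <- stats::runif(K, 0.6, 1.6)
      d2 <- (outer(rowSums(coords^2), rowSums(seeds^2), "+") - 2 * coords %*% t(seeds))
      d2 <- sweep(pmax(d2, 0), 2, wts^2, "/")
      max.col(-d2, ties.method = "first")
    })
}

#' Generate a ground-truthed synthetic dataset
#'
#' Draws counts from a zero-inflated negative binomial: per-gene, per-domain
#' means `base_mean * fold_change^(gene is marker of domain)`, a lognormal
#' per-spot library factor, NB sampling via the gamma-Poisson mixture at
#' dispersion `theta_sim`, then independent zeroing with probability `pi_sim`.
#' Ground-truth labels and the true mean matrix are stored on the result.
#'
#' @param cfg a [sim_config()].
#' @return A [spot_dataset()] with `labels` and `mu_true` filled in.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$K_true > cfg$n_spots) stopf("infeasible geometry: K_true > n_spots")
  set.seed(cfg$seed)
  n <- cfg$n_spots
  d <- cfg$n_genes
  coords <- switch(cfg$layout,
    hex = hex_layout(n),
    grid = grid_layout(n),
    random = cbind(x = stats::runif(n, 0, sqrt(n) * 100),
                   y = stats::runif(n, 0, sqrt(n) * 100)))
  labels <- assign_domains(coords, cfg)
  K <- length(unique(labels))

  # domain x gene mean profile
  marker_of <- rep(NA_integer_, d)
  idx <- seq_len(cfg$markers_per_domain * cfg$K_true)
  marker_of[idx] <- rep(seq_len(cfg$K_true), each = cfg$markers_per_domain)
  prof <- matrix(cfg$base_mean, K, d)
  for (dom in seq_len(min(K, cfg$K_true))) {
    prof[dom, which(marker_of == dom)] <- cfg$base_mean * cfg$fold_change
  }

  lib <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$library_size_cv)
  mu_true <- prof[labels, , drop = FALSE] * lib
  # gamma-Poisson: lambda ~ Gamma(shape = theta, scale = mu/theta) => NB(mu, theta)
  lam <- matrix(stats::rgamma(n * d, shape = cfg$theta_sim,
                              scale = as.vector(mu_true) / cfg$theta_sim), n, d)
  counts <- matrix(stats::rpois(n * d, as.vector(lam)), n, d)
  if (cfg$pi_sim > 0) {
    keep <- matrix(stats::rbinom(n * d, 1L, 1 - cfg$pi_sim), n, d)
    counts <- counts * keep
  }
  # a spot with all-zero counts cannot be library-normalised; bump one gene
  z <- which(rowSums(counts) == 0)
  if (length(z)) counts[cbind(z, sample.int(d, length(z), replace = TRUE))] <- 1L

  gene_names <- sprintf("gene_%03d", seq_len(d))
  ds <- spot_dataset(counts = counts, coords = coords,
                     gene_names = gene_names,
                     spot_ids = sprintf("spot_%04d", seq_len(n)),
                     labels = as.integer(labels), mu_true = mu_true)
  attr(ds, "sim_config") <- cfg
  attr(ds, "marker_of") <- marker_of
  ds
}

#' Canonical synthetic benchmark
#'
#' A hex layout with 1000 spots, five stripe domains, 200 genes with 20 markers
#' per domain at fold change 4, dispersion 2 and dropout 0.3 -- an easy but
#' non-trivial fixture for end-to-end checks. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @return A [spot_dataset()].
#' @export
easy_benchmark <- function(seed = 0L) {
  generate_dataset(sim_config(
    n_spots = 1000, layout = "hex", K_true = 5, domain_geometry = "stripes",
    n_genes = 200, markers_per_domain = 20, base_mean = 1, fold_change = 4,
    theta_sim = 2, pi_sim = 0.3, library_size_cv = 0.2, seed = as.integer(seed)))
}
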