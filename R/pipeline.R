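# End-to-end workflow and command-line entry points.

#' Run configuration
#'
#' Aggregates every stage's tunables into one serialisable object; every
#' value can be overridden from a YAML config file.
#'
#' @param input input path (h5ad / mtx dir / csv stem); `NULL` for in-memory use.
#' @param output output directory.
#' @param n_clusters number of domains K.
#' @param radius spatial graph radius (550 suits Visium pixel coordinates; 50
#'   Slide-seqV2; lattice simulations use 150).
#' @param knn feature-graph neighbours (default 15).
#' @param n_hvg highly variable genes to keep (default 3000).
#' @param seed integer seed.
#' @param weights a [loss_weights()].
#' @param train a [train_config()].
#' @param ablation an [ablate()] switch set.
#' @param refine apply majority-vote label smoothing (default `FALSE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, output = NULL, n_clusters = 7,
                       radius = 550, knn = 15, n_hvg = 3000, seed = 0L,
                       weights = loss_weights(), train = train_config(seed = seed),
                       ablation = ablate(), refine = FALSE) {
  structure(list(input = input, output = output, n_clusters = n_clusters,
                 radius = radius, knn = knn, n_hvg = n_hvg, seed = as.integer(seed),
                 weights = weights, train = train, ablation = ablation,
                 refine = refine),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return [run_config()] for `read_run_config`; `path` invisibly for the
#'   writer.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in c("input", "output", "n_clusters", "radius", "knn", "n_hvg",
               "seed", "refine")) {
    if (!is.null(y[[nm]])) cfg[[nm]] <- y[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(y$weights)) cfg$weights <- do.call(loss_weights, y$weights)
  if (!is.null(y$train)) cfg$train <- do.call(train_config, y$train)
  if (!is.null(y$ablation)) cfg$ablation <- do.call(ablate, y$ablation)
  cfg
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  y <- list(input = cfg$input, output = cfg$output, n_clusters = cfg$n_clusters,
            radius = cfg$radius, knn = cfg$knn, n_hvg = cfg$n_hvg,
            seed = cfg$seed, refine = cfg$refine,
            weights = unclass(cfg$weights),
            train = unclass(cfg$train)[c("lr", "weight_decay", "max_epochs",
                                         "patience", "min_delta", "seed",
                                         "hidden_dims", "dropout", "clip_norm")],
            ablation = unclass(cfg$ablation))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Full analysis on an in-memory dataset
#'
#' Preprocess, build both graphs, train, decode, and call domains. The
#' returned object carries everything downstream consumers need: embeddings,
#' labels, imputed expression, training history and the fitted parameters.
#'
#' @param ds a raw [spot_dataset()].
#' @param K number of domains.
#' @param radius,knn graph construction parameters.
#' @param n_hvg highly variable genes to keep.
#' @param cfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param ablation an [ablate()] switch set.
#' @param refine majority-vote smoothing of the called labels.
#' @return list of class `sdg_result` with `embeddings`, `domains` (0-based),
#'   `imputed`, `history`, `fit`, `graph`, `dataset` (preprocessed), and
#'   `ari` when ground-truth labels are present.
#' @export
run_spatialdg <- function(ds, K, radius, knn = 15, n_hvg = 3000,
                          cfg = train_config(), weights = loss_weights(),
                          ablation = ablate(), refine = FALSE) {
  dsp <- preprocess(ds, n_hvg = n_hvg)
  G <- build_dual_graph(dsp, r = radius, k = knn)
  fit <- train(dsp, G, cfg = cfg, weights = weights, ablation = ablation)
  ev <- encode(dsp$expr, fit$G, fit$params, mode = "eval")
  zp <- zinb_heads(ev$H, fit$params)
  dom <- cluster_domains(ev$H, K, seed = cfg$seed)
  labels <- refine_spatial(dom$labels + 1L, G$A_s, enabled = refine) - 1L
  res <- list(embeddings = ev$H, domains = labels, assignment = dom,
              imputed = impute_expression(zp), history = fit$history,
              fit = fit, graph = G, dataset = dsp)
  if (!is.null(dsp$labels)) res$ari <- ari(labels, dsp$labels)
  structure(res, class = "sdg_result")
}

#' @export
print.sdg_result <- function(x, ...) {
  cat(sprintf("sdg_result: %d spots, %d domains, %d training epochs%s\n",
              length(x$domains), x$assignment$K, nrow(x$history),
              if (!is.null(x$ari)) sprintf(", ARI vs ground truth %.3f", x$ari) else ""))
  invisible(x)
}

write_result_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- res$dataset
  utils::write.csv(data.frame(spot_id = ds$spot_ids,
                              x = ds$coords[, 1], y = ds$coords[, 2],
                              domain = res$domains),
                   file.path(outdir, "domains.csv"), row.names = FALSE)
  utils::write.csv(res$history, file.path(outdir, "history.csv"), row.names = FALSE)
  saveRDS(list(params = res$fit$params, cfg = res$fit$cfg,
               weights = res$fit$weights, seed = res$fit$cfg$seed),
          file.path(outdir, "checkpoint.rds"))
  save_h5ad(ds, file.path(outdir, "result.h5ad"), embeddings = res$embeddings,
            domains = res$domains, imputed = res$imputed)
  invisible(outdir)
}

#' Command-line `run` stage
#'
#' load -> preprocess -> graphs -> train -> cluster -> write (h5ad, domains
#' CSV, history CSV, checkpoint). Prints the ARI when ground-truth labels are
#' present.
#'
#' @param cfg a [run_config()] with `input` and `output` set.
#' @return exit code 0 invisibly; stage errors abort with the stage name.
#' @export
cmd_run <- function(cfg) {
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) stopf("stage '%s' failed: %s", nm, conditionMessage(e)))
  }
  ds <- stage("load", load_dataset(cfg$input))
  res <- stage("pipeline",
               run_spatialdg(ds, K = cfg$n_clusters, radius = cfg$radius,
                             knn = cfg$knn, n_hvg = cfg$n_hvg, cfg = cfg$train,
                             weights = cfg$weights, ablation = cfg$ablation,
                             refine = cfg$refine))
  stage("write", write_result_outputs(res, cfg$output))
  if (!is.null(res$ari)) message(sprintf("ARI vs ground truth: %.4f", res$ari))
  invisible(0L)
}

#' Command-line `simulate` stage
#'
#' @param preset `"easy"` for the canonical benchmark, or a [sim_config()].
#' @param seed integer seed.
#' @param out output `.h5ad` path (or mtx directory if it has no extension).
#' @return exit code 0 invisibly.
#' @export
cmd_simulate <- function(preset = "easy", seed = 0L, out = "sim.h5ad") {
  ds <- if (inherits(preset, "sim_config")) generate_dataset(preset)
        else easy_benchmark(seed)
  if (grepl("\\.h5ad$", out)) save_h5ad(ds, out) else save_mtx_dir(ds, out)
  invisible(0L)
}

#' Command-line `evaluate` stage
#'
#' Computes the ARI between a predicted-labels CSV (columns `spot_id`,
#' `domain`) and a ground-truth column of a second CSV (or the same file).
#'
#' @param pred_csv predictions CSV.
#' @param truth_csv CSV holding the truth column (default: `pred_csv`).
#' @param truth_col truth column name (default `"ground_truth"`).
#' @return the ARI, invisibly; also printed.
#' @export
cmd_evaluate <- function(pred_csv, truth_csv = pred_csv, truth_col = "ground_truth") {
  pred <- utils::read.csv(pred_csv, stringsAsFactors = FALSE)
  truth <- utils::read.csv(truth_csv, stringsAsFactors = FALSE)
  m <- match(pred$spot_id, truth$spot_id)
  if (anyNA(m)) stopf("spot_id mismatch between predictions and truth")
  a <- ari(pred$domain, truth[[truth_col]][m])
  message(sprintf("ARI: %.4f", a))
  invisible(a)
}
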