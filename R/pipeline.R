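#' Run the full portrayal pipeline
#'
#' End-to-end driver: read (or generate) the spot data, preprocess, train
#' the SOM, extract modules, and — when the corresponding inputs are given
#' — run enrichment, receptor-ligand mapping and pathway signal flow. All
#' inputs are validated up front so a bad path fails before any expensive
#' computation, and one seed governs every stochastic step. A manifest
#' JSON recording package version, seed and configuration (with its hash)
#' is written alongside the outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param input_dir Visium-style input directory; mutually exclusive with
#'   `synthetic`.
#' @param synthetic a [synthetic_config()] to generate the input instead.
#' @param labels_path optional spot labels CSV (barcode, label) — e.g.
#'   precomputed Seurat clusters; labels are never computed internally.
#' @param gmt_path optional GMT file; triggers module enrichment.
#' @param rli_path optional receptor-ligand pair TSV; triggers RLI calls.
#' @param pathway_path optional pathway edge-list TSV; with labels,
#'   triggers pathway signal flow.
#' @param preprocess_cfg a [preprocess_config()].
#' @param som_cfg a [som_config()]; its seed is overridden by `seed`.
#' @param module_quantile,module_min_units group-overexpression
#'   segmentation parameters.
#' @param rli_threshold expression threshold for RLI calls.
#' @param seed master seed.
#' @param render write PNG images for module spatial scores (and the RLI
#'   map when computed)?
#' @return (invisibly) list with the model, modules, scores and the paths
#'   of everything written.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL, synthetic = NULL,
                         labels_path = NULL, gmt_path = NULL,
                         rli_path = NULL, pathway_path = NULL,
                         preprocess_cfg = preprocess_config(),
                         som_cfg = som_config(grid_rows = 20, grid_cols = 20),
                         module_quantile = 0.9, module_min_units = 4L,
                         rli_threshold = 0, seed = 1L, render = FALSE) {
  # fail-fast validation of every input before any computation
  if (is.null(input_dir) == is.null(synthetic))
    stop2("give exactly one of input_dir or synthetic")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop2("input directory not found: %s", input_dir)
  for (p in c(labels_path, gmt_path, rli_path, pathway_path)) {
    if (!is.null(p) && !file.exists(p)) stop2("input file not found: %s", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  labels <- if (!is.null(labels_path)) read_spot_labels(labels_path)
  collection <- if (!is.null(gmt_path)) read_gmt(gmt_path)
  pairs <- if (!is.null(rli_path)) read_rli_table(rli_path)
  graph <- if (!is.null(pathway_path)) read_pathway_graph(pathway_path)

  if (!is.null(synthetic)) {
    synthetic$seed <- as.integer(seed)
    fx <- generate_synthetic(synthetic)
    raw <- fx$matrix; layout <- fx$layout
    if (is.null(labels))
      labels <- spot_labels(names(fx$truth$domains),
                            paste0("domain", fx$truth$domains))
  } else {
    vis <- read_visium(input_dir)
    raw <- vis$matrix; layout <- vis$layout
  }

  pp <- preprocess(raw, preprocess_cfg)
  som_cfg$seed <- as.integer(seed)
  model <- train_som(pp$centralized, som_cfg)
  paths$model <- file.path(out_dir, "som_model.tar.gz")
  save_som_model(model, paths$model)

  portraits <- if (!is.null(labels)) group_portraits_by_label(model, labels)
  else lapply(model$spot_barcodes, function(b) spot_portrait(model, b))
  modules <- overexpression_modules(
    model, portraits, module_quantile, module_min_units,
    method = if (is.null(labels)) "single_spot_overexpression"
    else "group_overexpression")

  if (length(modules$modules) > 0) {
    paths$modules_gmt <- file.path(out_dir, "modules.gmt")
    write_gmt(gene_set_collection(
      lapply(modules$modules, `[[`, "gene_ids"),
      category = modules$method), paths$modules_gmt)
    mask <- matrix("", model$grid_rows, model$grid_cols)
    for (m in modules$modules) mask[m$units] <- m$label
    paths$module_units <- file.path(out_dir, "module_units.csv")
    write.table(mask, paths$module_units, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    scores <- vapply(names(modules$modules), function(l)
      module_spatial_score(model, modules, l),
      numeric(length(model$spot_barcodes)))
    paths$module_scores <- file.path(out_dir, "module_scores.tsv")
    write.table(data.frame(barcode = model$spot_barcodes, scores,
                           check.names = FALSE),
                paths$module_scores, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (render) {
      for (l in names(modules$modules)) {
        f <- file.path(out_dir, sprintf("module_%s_spatial.png", l))
        render_spatial(scores[, l], layout, file = f)
        paths[[paste0("render_module_", l)]] <- f
      }
    }
  }

  if (!is.null(collection) && length(modules$modules) > 0) {
    enr <- enrich_modules(modules, collection, universe = model$gene_ids)
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  rli_calls <- NULL
  if (!is.null(pairs)) {
    rli_calls <- pathway_rli_map(pp$log, pairs, rli_threshold)
    paths$rli <- file.path(out_dir, "rli_calls.tsv")
    write.table(rli_calls, paths$rli, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (render) {
      paths$rli_png <- file.path(out_dir, "rli_map.png")
      render_rli(rli_calls, layout, file = paths$rli_png)
    }
  }

  if (!is.null(graph) && !is.null(labels)) {
    psf <- psf_by_cluster(pp$centralized, labels, graph)
    paths$psf <- file.path(out_dir, "psf_sinks.tsv")
    write.table(psf, paths$psf, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  config <- list(preprocess = unclass(preprocess_cfg),
                 som = unclass(som_cfg),
                 module_quantile = module_quantile,
                 module_min_units = module_min_units,
                 rli_threshold = rli_threshold, seed = as.integer(seed),
                 synthetic = if (!is.null(synthetic)) unclass(synthetic))
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "spotsom",
                   package_version = as.character(packageVersion("spotsom")),
                   seed = as.integer(seed),
                   config = config,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   n_genes = length(model$gene_ids),
                   n_spots = length(model$spot_barcodes),
                   modules = names(modules$modules),
                   outputs = paths)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  unlink(cfg_file)
  invisible(list(model = model, modules = modules, labels = labels,
                 rli = rli_calls, paths = paths))
}
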