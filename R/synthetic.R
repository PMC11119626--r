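#' Synthetic spatial-transcriptomics configuration
#'
#' Desk-scale fixture emulating a Visium capture area: a hexagonal lattice
#' of spots partitioned into contiguous spatial domains, one planted
#' module of co-expressed genes per domain, background genes without
#' spatial structure, and overdispersed (negative binomial) count noise
#' with spot-to-spot library size variation.
#'
#' @param n_rows,n_cols hex lattice size (default 20 x 20 = 400 spots).
#' @param n_domains number of contiguous spatial domains (default 4).
#' @param genes_per_module genes planted per domain module (default 50).
#' @param n_background_genes unstructured genes (default 500).
#' @param base_mean baseline negative-binomial mean per gene (default 5).
#' @param fold_change mean fold increase of a module gene inside its home
#'   domain (default 4).
#' @param dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); default 0.5.
#' @param library_size_mean expected total counts per spot before noise
#'   (default 5000); spot totals vary log-normally (CV about 0.25) around
#'   it.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_rows = 20L, n_cols = 20L, n_domains = 4L,
                             genes_per_module = 50L,
                             n_background_genes = 500L,
                             base_mean = 5, fold_change = 4,
                             dispersion = 0.5, library_size_mean = 5000,
                             seed = 1L) {
  if (n_domains < 2) stop2("need at least 2 domains")
  if (n_domains > n_rows * n_cols) stop2("more domains than spots")
  if (genes_per_module < 1 && n_background_genes < 1)
    stop2("config yields zero genes")
  if (base_mean <= 0 || dispersion <= 0 || library_size_mean <= 0)
    stop2("base_mean, dispersion and library_size_mean must be positive")
  if (fold_change <= 1) stop2("fold_change must exceed 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_domains = as.integer(n_domains),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 base_mean = base_mean, fold_change = fold_change,
                 dispersion = dispersion,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic spatial transcriptomics fixture
#'
#' Spots sit on a hex lattice (Visium-style doubled-width array
#' coordinates, all in-tissue). Domains are the hex-distance Voronoi cells
#' of randomly placed domain centres (ties to the lowest centre index),
#' which makes them contiguous. Module gene g of domain d has negative
#' binomial mean `base_mean * fold_change` inside d and `base_mean`
#' elsewhere; background genes have mean `base_mean` everywhere. Per-spot
#' means are rescaled so the expected spot total matches a log-normally
#' drawn library size.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrix` (an [expression_matrix()], stage
#'   `raw_counts`), `layout` (a [spatial_layout()]) and `truth` (list with
#'   `domains`: named spot -> domain integer; `modules`: named list module
#'   -> gene ids; `module_domain`: named module -> domain integer).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  n_spots <- nr * nc
  grid <- expand.grid(col0 = seq_len(nc) - 1L, row0 = seq_len(nr) - 1L)
  array_row <- grid$row0
  array_col <- 2L * grid$col0 + array_row %% 2L  # doubled-width hex coords
  barcodes <- sprintf("SYN%04d-1", seq_len(n_spots))
  layout <- spatial_layout(barcode = barcodes, in_tissue = TRUE,
                           array_row = array_row, array_col = array_col,
                           pixel_x = array_col * 50,
                           pixel_y = array_row * 87)

  centers <- sample.int(n_spots, config$n_domains)
  dmat <- vapply(centers, function(ci)
    hex_distance(array_row[[ci]], array_col[[ci]], array_row, array_col),
    numeric(n_spots))
  domain <- apply(dmat, 1, which.min)  # ties -> lowest centre index

  n_mod_genes <- config$n_domains * config$genes_per_module
  gene_ids <- c(
    if (n_mod_genes > 0)
      sprintf("MOD%d_G%03d", rep(seq_len(config$n_domains),
                                 each = config$genes_per_module),
              rep(seq_len(config$genes_per_module), config$n_domains)),
    if (config$n_background_genes > 0)
      sprintf("BG_G%04d", seq_len(config$n_background_genes)))

  mu <- matrix(config$base_mean, length(gene_ids), n_spots,
               dimnames = list(gene_ids, barcodes))
  modules <- list()
  for (d in seq_len(config$n_domains)) {
    if (config$genes_per_module == 0) break
    genes_d <- gene_ids[seq_len(config$genes_per_module) +
                          (d - 1L) * config$genes_per_module]
    mu[genes_d, domain == d] <- config$base_mean * config$fold_change
    modules[[paste0("M", d)]] <- genes_d
  }

  lib <- rlnorm(n_spots, meanlog = log(config$library_size_mean) - 0.25^2 / 2,
                sdlog = 0.25)
  mu <- sweep(mu, 2, lib / colSums(mu), `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))

  truth <- list(domains = setNames(as.integer(domain), barcodes),
                modules = modules,
                module_domain = setNames(seq_along(modules),
                                         names(modules)))
  list(matrix = expression_matrix(counts, "raw_counts"),
       layout = layout, truth = truth)
}

#' Write a synthetic fixture as a Visium-style directory
#'
#' Emits the same layout [read_visium()] consumes, plus ground-truth TSVs
#' (`truth_domains.tsv`, `truth_modules.gmt`).
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return the generated fixture (invisibly).
#' @export
write_synthetic_visium <- function(config, dir) {
  fx <- generate_synthetic(config)
  write_visium(fx$matrix, fx$layout, dir)
  write.table(data.frame(barcode = names(fx$truth$domains),
                         domain = fx$truth$domains),
              file.path(dir, "truth_domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(gene_set_collection(fx$truth$modules, category = "planted"),
            file.path(dir, "truth_modules.gmt"))
  invisible(fx)
}
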