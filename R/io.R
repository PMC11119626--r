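#' Read a 10x-Visium-style directory
#'
#' Expects a Matrix-Market count matrix (`matrix.mtx`, optionally gzipped)
#' with companion `barcodes.tsv` and `features.tsv` files, plus a tissue
#' positions CSV either next to them or under a `spatial/` subdirectory.
#' Both Space Ranger dialects of the positions file are handled: the older
#' headerless six-column `tissue_positions_list.csv` and the headered
#' `tissue_positions.csv` (auto-detected from the first line).
#'
#' The count matrix is canonicalized to genes x spots regardless of on-disk
#' orientation (detected by matching dimensions against the barcode list)
#' and restricted to barcodes present in both the matrix and the layout;
#' the returned layout keeps all of its rows.
#'
#' @param dir directory path.
#' @param feature_column which column of `features.tsv` supplies gene ids
#'   (1 = feature id, 2 = symbol). Ids must end up unique.
#' @return list with elements `matrix` (an [expression_matrix()] at stage
#'   `raw_counts`) and `layout` (a [spatial_layout()]).
#' @export
read_visium <- function(dir, feature_column = 1L) {
  if (!dir.exists(dir)) stop2("Visium directory not found: %s", dir)
  mtx <- find_input_file(dir, c("matrix.mtx", "matrix.mtx.gz"))
  bcf <- find_input_file(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  ftf <- find_input_file(dir, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  posf <- find_input_file(dir, c("tissue_positions.csv",
                                 "tissue_positions_list.csv",
                                 file.path("spatial", "tissue_positions.csv"),
                                 file.path("spatial", "tissue_positions_list.csv")))
  barcodes <- read_single_column(bcf)
  features <- read.delim(ftf, header = FALSE, stringsAsFactors = FALSE)
  if (feature_column > ncol(features))
    stop2("features file %s has no column %d", ftf, feature_column)
  gene_ids <- trimws(as.character(features[[feature_column]]))
  m <- as.matrix(Matrix::readMM(mtx))
  if (ncol(m) != length(barcodes)) {
    if (nrow(m) == length(barcodes)) m <- t(m)
    else stop2("matrix dimensions %dx%d match neither orientation of %d barcodes x %d features",
               nrow(m), ncol(m), length(barcodes), length(gene_ids))
  }
  if (nrow(m) != length(gene_ids))
    stop2("matrix has %d rows but features file lists %d genes",
          nrow(m), length(gene_ids))
  dimnames(m) <- list(gene_ids, barcodes)
  layout <- read_tissue_positions(posf)
  common <- intersect(barcodes, layout$barcode)
  if (length(common) == 0)
    stop2("no barcode shared between matrix and tissue positions")
  n_drop <- length(barcodes) - length(common)
  if (n_drop > 0 || length(common) < sum(layout$in_tissue))
    warn2("barcode sets differ: %d matrix barcodes dropped, %d layout-only barcodes kept in layout",
          n_drop, nrow(layout) - length(common))
  m <- m[, common, drop = FALSE]
  list(matrix = expression_matrix(m, "raw_counts"), layout = layout)
}

find_input_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop2("missing required file: %s (looked for %s in %s)",
        candidates[[1]], paste(candidates, collapse = ", "), dir)
}

read_single_column <- function(path) {
  x <- readLines(path)
  trimws(x[nzchar(trimws(x))])
}

# Parse either tissue-positions dialect. Headered files are recognized by a
# "barcode" token on the first line. Column order follows Space Ranger:
# barcode, in_tissue, array_row, array_col, pxl_row_in_fullres,
# pxl_col_in_fullres (pixel row = y, pixel col = x).
read_tissue_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop2("tissue positions file %s is empty", path)
  has_header <- grepl("barcode", lines[[1]], ignore.case = TRUE)
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0)
    stop2("malformed tissue positions row at line %d of %s (expected 6 comma-separated fields, got %d)",
          bad[[1]] + offset, path, lengths(fields)[bad[[1]]])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  if (anyNA(num)) {
    bad_row <- which(rowSums(is.na(num)) > 0)[[1]]
    stop2("malformed tissue positions row at line %d of %s (non-numeric field)",
          bad_row + offset, path)
  }
  spatial_layout(barcode = trimws(m[, 1]),
                 in_tissue = num[, 1] != 0,
                 array_row = num[, 2], array_col = num[, 3],
                 pixel_y = num[, 4], pixel_x = num[, 5])
}

#' Write a Visium-style directory
#'
#' Inverse of [read_visium()]: writes `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv` and `spatial/tissue_positions.csv` (headered dialect).
#'
#' @param em an [expression_matrix()] at stage `raw_counts`.
#' @param layout a [spatial_layout()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_visium <- function(em, layout, dir) {
  if (expr_stage(em) != "raw_counts")
    stop2("write_visium expects raw counts, got stage '%s'", expr_stage(em))
  dir.create(file.path(dir, "spatial"), recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::Matrix(unclass_matrix(em), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(em), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(rownames(em), rownames(em), "Gene Expression"),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pos <- data.frame(barcode = layout$barcode,
                    in_tissue = as.integer(layout$in_tissue),
                    array_row = layout$array_row,
                    array_col = layout$array_col,
                    pxl_row_in_fullres = layout$pixel_y,
                    pxl_col_in_fullres = layout$pixel_x)
  write.table(pos, file.path(dir, "spatial", "tissue_positions.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

unclass_matrix <- function(em) {
  attr(em, "stage") <- NULL
  class(em) <- NULL
  em
}

#' Read spot labels from CSV/TSV
#'
#' Two columns: barcode and label (header optional; separator sniffed from
#' the first line).
#'
#' @param path file path.
#' @param kind `"cluster"` or `"cell_type"`.
#' @return a [spot_labels()] object.
#' @export
read_spot_labels <- function(path, kind = c("cluster", "cell_type")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("labels file not found: %s", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("barcode", first, ignore.case = TRUE)
  df <- read.delim(path, sep = sep, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("labels file %s needs two columns", path)
  spot_labels(df[[1]], df[[2]], kind = kind)
}

#' Read a GMT gene set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path file path.
#' @return a [gene_set_collection()]; the description field becomes the
#'   set's category.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("GMT file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- list()
  cats <- character()
  for (i in seq_along(lines)) {
    if (!keep[[i]]) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop2("GMT line %d has %d fields; need name, description and at least one gene",
            i, length(f))
    name <- trimws(f[[1]])
    genes <- trimws(f[-(1:2)])
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0)
      stop2("GMT line %d (set '%s') has an empty gene list", i, name)
    if (name %in% names(sets))
      stop2("duplicate gene set name '%s' at GMT line %d", name, i)
    sets[[name]] <- genes
    cats <- c(cats, trimws(f[[2]]))
  }
  gene_set_collection(sets, category = cats)
}

#' Write a GMT gene set file
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  cats <- attr(collection, "category")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[[i]], cats[[i]], collection[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a receptor-ligand pair table
#'
#' TSV with receptor and ligand columns (omnipath-style export) and an
#' optional pathway column whose entries may hold several tags joined by a
#' delimiter. Duplicate (receptor, ligand) rows are collapsed with their
#' pathway tags merged.
#'
#' @param path file path.
#' @param receptor_col,ligand_col,pathway_col column names; `pathway_col`
#'   may be absent from the file.
#' @param tag_delim delimiter splitting multiple pathway tags in one cell.
#' @return an `rli_pairs` data frame with columns `receptor`, `ligand` and
#'   list-column `pathways`.
#' @export
read_rli_table <- function(path, receptor_col = "receptor",
                           ligand_col = "ligand", pathway_col = "pathway",
                           tag_delim = ";") {
  if (!file.exists(path)) stop2("receptor-ligand table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(receptor_col, ligand_col)) {
    if (!col %in% names(df))
      stop2("receptor-ligand table %s is missing mandatory column '%s'",
            path, col)
  }
  receptor <- trimws(as.character(df[[receptor_col]]))
  ligand <- trimws(as.character(df[[ligand_col]]))
  tags <- if (pathway_col %in% names(df)) {
    lapply(strsplit(as.character(df[[pathway_col]]), tag_delim, fixed = TRUE),
           function(x) unique(trimws(x[nzchar(trimws(x))])))
  } else rep(list(character()), nrow(df))
  both <- nzchar(receptor) & nzchar(ligand)
  if (any(both & receptor == ligand))
    stop2("receptor equals ligand for pair(s): %s",
          paste(unique(receptor[both & receptor == ligand]), collapse = ", "))
  rli_pairs(receptor, ligand, tags)
}

#' Construct a receptor-ligand pair set
#'
#' @param receptor,ligand character vectors of gene ids.
#' @param pathways list of character vectors of pathway tags (optional).
#' @return an `rli_pairs` data frame; duplicates collapsed (tags unioned).
#' @export
rli_pairs <- function(receptor, ligand, pathways = NULL) {
  if (is.null(pathways)) pathways <- rep(list(character()), length(receptor))
  key <- paste(receptor, ligand, sep = "\r")
  first <- !duplicated(key)
  merged <- lapply(split(pathways, factor(key, levels = key[first])),
                   function(p) unique(unlist(p)))
  out <- data.frame(receptor = receptor[first], ligand = ligand[first],
                    stringsAsFactors = FALSE)
  out$pathways <- unname(merged)
  class(out) <- c("rli_pairs", "data.frame")
  out
}

#' Read a signed directed pathway graph
#'
#' Edge-list TSV with columns source, target, sign (header optional). Signs
#' may be `1`/`+1`/`activation` or `-1`/`inhibition`. Nodes are inferred
#' from the edges (plus an optional node list); unless declared explicitly,
#' source nodes are those with in-degree zero and sink nodes those with
#' out-degree zero.
#'
#' @param path file path.
#' @param nodes,sources,sinks optional explicit node / source / sink sets.
#' @return a [pathway_graph()].
#' @export
read_pathway_graph <- function(path, nodes = NULL, sources = NULL,
                               sinks = NULL) {
  if (!file.exists(path)) stop2("pathway graph file not found: %s", path)
  first <- readLines(path, n = 1)
  header <- grepl("source", first, ignore.case = TRUE)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop2("pathway edge list %s needs 3 columns", path)
  sign_raw <- trimws(tolower(as.character(df[[3]])))
  sign <- ifelse(sign_raw %in% c("1", "+1", "activation"), 1L,
                 ifelse(sign_raw %in% c("-1", "inhibition"), -1L, NA_integer_))
  if (anyNA(sign))
    stop2("unrecognized edge sign '%s' (use +1/-1/activation/inhibition)",
          sign_raw[which(is.na(sign))[[1]]])
  pathway_graph(data.frame(source = trimws(as.character(df[[1]])),
                           target = trimws(as.character(df[[2]])),
                           sign = sign, stringsAsFactors = FALSE),
                nodes = nodes, sources = sources, sinks = sinks)
}

#' Construct a signed directed pathway graph
#'
#' @param edges data frame with columns `source`, `target`, `sign`
#'   (+1 activation, -1 inhibition).
#' @param nodes,sources,sinks optional explicit node / source / sink sets;
#'   by default nodes come from the edges, sources are in-degree-zero nodes
#'   and sinks out-degree-zero nodes.
#' @return a `pathway_graph` list with elements `nodes`, `edges`,
#'   `sources`, `sinks`.
#' @export
pathway_graph <- function(edges, nodes = NULL, sources = NULL, sinks = NULL) {
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  if (!all(edges$sign %in% c(-1L, 1L)))
    stop2("edge signs must be +1 or -1")
  inferred <- unique(c(edges$source, edges$target))
  nodes <- if (is.null(nodes)) inferred else unique(c(nodes, inferred))
  missing_ref <- setdiff(c(edges$source, edges$target), nodes)
  if (length(missing_ref) > 0)
    stop2("edges reference undeclared nodes: %s",
          paste(missing_ref, collapse = ", "))
  if (is.null(sources)) sources <- setdiff(nodes, edges$target)
  if (is.null(sinks)) sinks <- setdiff(nodes, edges$source)
  structure(list(nodes = nodes, edges = edges,
                 sources = sources, sinks = sinks),
            class = "pathway_graph")
}

# ---- model archive ---------------------------------------------------------

SOM_ARCHIVE_VERSION <- "1"

#' Save a trained SOM model to a portable archive
#'
#' The archive is a gzipped tar of plain-text members: a JSON manifest
#' (format version, training configuration, quantization errors), the
#' codebook written at full double precision (so a load reproduces the
#' weights bit-exactly), the gene-to-unit assignment and the spot barcode
#' order.
#'
#' @param model a [train_som()] result.
#' @param path output file path (conventionally `.tar.gz`).
#' @return `path`, invisibly.
#' @export
save_som_model <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  stage <- tempfile("som_archive_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  manifest <- list(format_version = SOM_ARCHIVE_VERSION,
                   package = "spotsom",
                   package_version = as.character(packageVersion("spotsom")),
                   config = unclass(model$config),
                   grid_rows = model$grid_rows, grid_cols = model$grid_cols,
                   n_spots = length(model$spot_barcodes),
                   n_genes = length(model$gene_ids),
                   qe_initial = model$qe_initial, qe_final = model$qe_final)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(apply(model$weights, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")),
    file.path(stage, "weights.tsv"))
  writeLines(model$spot_barcodes, file.path(stage, "spot_barcodes.txt"))
  asg <- data.frame(gene_id = model$gene_ids,
                    row = model$assignment[, "row"],
                    col = model$assignment[, "col"])
  write.table(asg, file.path(stage, "gene_assignment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- if (grepl("^/", path)) path else file.path(getwd(), path)
  old <- setwd(stage)
  on.exit(setwd(old), add = TRUE)
  tar(out, files = list.files(stage), compression = "gzip", tar = "internal")
  invisible(path)
}

#' Load a SOM model archive
#'
#' @param path archive written by [save_som_model()].
#' @return a `som_model` identical to the saved one.
#' @export
load_som_model <- function(path) {
  if (!file.exists(path)) stop2("model archive not found: %s", path)
  stage <- tempfile("som_load_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  cons_before <- getAllConnections()
  ok <- tryCatch({ untar(path, exdir = stage, tar = "internal"); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  # untar aborts mid-member on truncated archives and can leak a connection
  for (co in setdiff(getAllConnections(), cons_before))
    try(close(getConnection(co)), silent = TRUE)
  members <- c("manifest.json", "weights.tsv", "spot_barcodes.txt",
               "gene_assignment.tsv")
  if (!ok || !all(file.exists(file.path(stage, members))))
    stop2("model archive %s is corrupt or truncated; refusing partial load",
          path)
  manifest <- jsonlite::read_json(file.path(stage, "manifest.json"))
  if (!identical(as.character(manifest$format_version), SOM_ARCHIVE_VERSION))
    stop2("model archive format version '%s' not supported by this build (expects '%s')",
          manifest$format_version, SOM_ARCHIVE_VERSION)
  w_lines <- readLines(file.path(stage, "weights.tsv"))
  W <- do.call(rbind, lapply(strsplit(w_lines, "\t", fixed = TRUE), as.numeric))
  barcodes <- readLines(file.path(stage, "spot_barcodes.txt"))
  asg <- read.delim(file.path(stage, "gene_assignment.tsv"),
                    stringsAsFactors = FALSE)
  config <- manifest$config
  config[] <- lapply(config, function(x) if (is.list(x)) unlist(x) else x)
  assignment <- cbind(row = as.integer(asg$row), col = as.integer(asg$col))
  rownames(assignment) <- asg$gene_id
  structure(list(config = config,
                 grid_rows = as.integer(manifest$grid_rows),
                 grid_cols = as.integer(manifest$grid_cols),
                 weights = W,
                 gene_ids = asg$gene_id,
                 spot_barcodes = barcodes,
                 assignment = assignment,
                 qe_initial = as.numeric(manifest$qe_initial),
                 qe_final = as.numeric(manifest$qe_final)),
            class = "som_model")
}
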